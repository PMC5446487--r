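#' Read and write trial tables
#'
#' Trial tables are serialized as tab-separated text with a one-line
#' header; column names and units are fixed by the schema documented in
#' [simulate_responder()].
#'
#' @param trials A trial table data.frame.
#' @param path File path.
#' @return `read_trials` returns the trial table; `write_trials` its
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial", "type")
  if (!all(need %in% names(tb)))
    stop("not a trial table: missing columns ", paste(setdiff(need, names(tb)), collapse = ", "))
  tb
}

#' Read and write epoch sets
#'
#' An epoch set is stored as a directory holding `meta.json` (sampling
#' rate, lock, windows, trial alignment, covariate) and `data.tsv`
#' (trials x samples voltage matrix).
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory path (created if needed).
#' @return `read_epochs` returns the `epoch_set`; `write_epochs` the
#'   directory, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- epochs[setdiff(names(epochs), "data")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(epochs$data, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"), sep = "\t"))
  dimnames(dat) <- NULL
  structure(c(list(data = dat), meta), class = "epoch_set")
}

#' Read and write time-frequency epochs
#'
#' Stored as a directory with `meta.json` (axes, lock, flags, trial
#' alignment) and `power.tsv` (trials x (freqs * times), frequency
#' fastest).
#'
#' @param tf A `tf_epochs` object.
#' @param dir Directory path.
#' @return `read_tfr` returns the `tf_epochs`; `write_tfr` the
#'   directory, invisibly.
#' @export
write_tfr <- function(tf, dir) {
  stopifnot(inherits(tf, "tf_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(tf$power)
  meta <- c(tf[setdiff(names(tf), "power")], list(dim = d))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(matrix(tf$power, d[1L], d[2L] * d[3L]),
                     file.path(dir, "power.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_tfr
#' @export
read_tfr <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  pw <- as.matrix(utils::read.table(file.path(dir, "power.tsv"), sep = "\t"))
  out <- meta[setdiff(names(meta), "dim")]
  out$power <- array(as.numeric(pw), dim = d)
  structure(out, class = "tf_epochs")
}
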