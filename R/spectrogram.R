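#' Construct a spectrogram object
#'
#' A spectrogram is the signal that flows between model modules: a
#' channel-by-time matrix of nonnegative (pre-compression) channel envelopes,
#' together with the channel center frequencies and the temporal bin duration.
#'
#' @param values numeric matrix, channels (rows) by time bins (columns).
#' @param center_freqs strictly increasing numeric vector of channel center
#'   frequencies in Hz, one per row of `values`.
#' @param bin_duration temporal bin duration in seconds.
#' @return An object of class `"spectrogram"`.
#' @export
spectrogram <- function(values, center_freqs, bin_duration) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("spectrogram values must be finite")
  if (length(center_freqs) != nrow(values))
    stop("length(center_freqs) must equal nrow(values)")
  if (nrow(values) > 1 && any(diff(center_freqs) <= 0))
    stop("center_freqs must be strictly increasing")
  if (!is.numeric(bin_duration) || length(bin_duration) != 1 || bin_duration <= 0)
    stop("bin_duration must be a positive scalar")
  structure(list(values = values, center_freqs = as.numeric(center_freqs),
                 bin_duration = bin_duration),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d channels x %d bins (%.1f Hz bin rate, %.0f-%.0f Hz)\n",
              nrow(x$values), ncol(x$values), 1 / x$bin_duration,
              min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

as_spectrogram <- function(x, template = NULL) {
  if (inherits(x, "spectrogram")) return(x)
  if (is.matrix(x) && !is.null(template))
    return(spectrogram(x, template$center_freqs, template$bin_duration))
  stop("cannot coerce to spectrogram")
}

#' Write / read a spectrogram as a delimited text table
#'
#' The format is plain tab-separated text: a metadata comment line carrying the
#' bin duration, a header row of channel center frequencies, then one row per
#' channel.
#'
#' @param x a [spectrogram()].
#' @param path file path.
#' @return `write_spectrogram` returns `path` invisibly; `read_spectrogram`
#'   returns a [spectrogram()].
#' @export
write_spectrogram <- function(x, path) {
  stopifnot(inherits(x, "spectrogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_duration\t%.17g", x$bin_duration), con)
  writeLines(paste(sprintf("%.17g", x$center_freqs), collapse = "\t"), con)
  utils::write.table(x$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrogram
#' @export
read_spectrogram <- function(path) {
  lines <- readLines(path, n = 2)
  meta <- strsplit(lines[1], "\t")[[1]]
  if (!grepl("bin_duration", meta[1]))
    stop("not a spectrogram table: missing bin_duration metadata line")
  bin_duration <- as.numeric(meta[2])
  cf <- as.numeric(strsplit(lines[2], "\t")[[1]])
  vals <- as.matrix(utils::read.table(path, sep = "\t", skip = 2))
  dimnames(vals) <- NULL
  spectrogram(vals, cf, bin_duration)
}

#' Write / read a trial-by-time response matrix as delimited text
#'
#' @param trials numeric matrix, trials (rows) by time bins (columns).
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(as.matrix(trials), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  m
}
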