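#' Read a multichannel EEG record from delimited text
#'
#' Expected dialect: header row; first column time in seconds, remaining
#' columns channel-labeled amplitudes in microvolts.  The sampling rate is
#' inferred from the median time step.
#'
#' @param path CSV file path.
#' @return List with `record` (samples x channels matrix) and `fs` (Hz).
#' @export
read_record_csv <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L) stop("record CSV needs a time column plus channels")
  tm <- d[[1]]
  dt <- stats::median(diff(tm))
  if (!is.finite(dt) || dt <= 0) stop("non-increasing time column")
  rec <- as.matrix(d[, -1, drop = FALSE])
  list(record = rec, fs = 1 / dt)
}

#' Write a multichannel record as delimited text
#'
#' Inverse of [read_record_csv()].
#'
#' @param record samples x channels matrix with column names.
#' @param fs sampling rate in Hz.
#' @param path output CSV path.
#' @export
write_record_csv <- function(record, fs, path) {
  d <- data.frame(time = seq_len(nrow(record)) / fs, record,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
}
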