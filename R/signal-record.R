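#' Measurement record of one calorimetric session segment
#'
#' A `signal_record` is a data frame with the five channels logged by the
#' acquisition system at 1 Hz, plus elapsed time:
#' \describe{
#'   \item{t}{elapsed time, s (strictly increasing, uniform grid)}
#'   \item{y}{calorimetric thermopile signal, V}
#'   \item{T2}{thermostat temperature, degC}
#'   \item{W2}{thermostat Joule heating power, W}
#'   \item{Ipel}{Peltier supply current, A}
#'   \item{Troom}{room temperature, degC}
#' }
#'
#' @param t,y,T2,W2,Ipel,Troom channel vectors; scalars are recycled to the
#'   grid length.
#' @return A data frame of class `signal_record`.
#' @export
signal_record <- function(t, y, T2, W2 = 0, Ipel = 0, Troom = 20) {
  n <- length(t)
  if (n < 2L) stop("a signal record needs at least 2 samples")
  rec <- data.frame(t = as.numeric(t),
                    y = rep_len(as.numeric(y), n),
                    T2 = rep_len(as.numeric(T2), n),
                    W2 = rep_len(as.numeric(W2), n),
                    Ipel = rep_len(as.numeric(Ipel), n),
                    Troom = rep_len(as.numeric(Troom), n))
  validate_record(rec)
  class(rec) <- c("signal_record", "data.frame")
  rec
}

record_channels <- c("t", "y", "T2", "W2", "Ipel", "Troom")

validate_record <- function(rec) {
  missing <- setdiff(record_channels, names(rec))
  if (length(missing))
    stop("record is missing channel(s): ", paste(missing, collapse = ", "))
  if (anyNA(rec[record_channels]) ||
      !all(vapply(rec[record_channels], function(x) all(is.finite(x)), TRUE)))
    stop("record channels must be finite and free of missing values")
  dt <- diff(rec$t)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (length(dt) && diff(range(dt)) > 1e-9 * max(dt))
    stop("time grid must be uniform")
  invisible(rec)
}

#' @export
print.signal_record <- function(x, ...) {
  dt <- diff(x$t[1:2])
  cat(sprintf("<signal_record> %d samples, dt = %g s, span %g s\n",
              nrow(x), dt, x$t[nrow(x)] - x$t[1]))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

record_dt <- function(rec) rec$t[2] - rec$t[1]

#' Read and write signal-record CSV files
#'
#' The canonical on-disk form is a headered CSV with columns
#' `t,y,T2,W2,Ipel,Troom` in the units of [signal_record()].  Reading
#' validates the channel set, finiteness and grid uniformity and fails with
#' a message naming the offending column.
#'
#' @param path file path.
#' @param record a `signal_record`.
#' @return `read_record()` returns a `signal_record`; `write_record()`
#'   returns `path` invisibly.
#' @export
read_record <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  missing <- setdiff(record_channels, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  rec <- df[record_channels]
  validate_record(rec)
  class(rec) <- c("signal_record", "data.frame")
  rec
}

#' @rdname read_record
#' @export
write_record <- function(record, path) {
  validate_record(record)
  utils::write.csv(as.data.frame(record)[record_channels], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
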