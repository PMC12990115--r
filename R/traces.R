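#' Construct a uniformly sampled distance trace
#'
#' A `distance_trace` holds one scalar observable sampled at a constant
#' interval: times in ps, values in nm (or nm^2 for SASA-like inputs).
#'
#' @param times Numeric vector of sample times (ps), uniformly spaced.
#' @param values Numeric vector of observable values (nm), same length.
#' @param label Short name of the observable (e.g. `"Ree"`).
#' @return An object of class `distance_trace` with elements `times`,
#'   `values`, `label` and `dt` (sampling interval, ps).
#' @examples
#' tr <- distance_trace(seq(0, 99, by = 1), rnorm(100, 0.9, 0.1), "Ree")
#' tr$dt
#' @export
distance_trace <- function(times, values, label = "trace") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("trace values must be finite")
  dts <- diff(times)
  dt <- dts[1L]
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * abs(dt)))
    stop("times must be uniformly spaced and increasing")
  structure(list(times = times, values = values,
                 label = as.character(label)[1L], dt = dt),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("<distance_trace '%s': %d samples, dt = %g ps, mean = %.4g>\n",
              x$label, length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

#' @export
length.distance_trace <- function(x) length(x$values)

#' Read a distance trace from delimited text
#'
#' Expects a header line and two columns, `time_ps` and `value_nm`
#' (any delimiter `read.table` accepts).
#'
#' @param path Path to the trace file.
#' @param label Observable label; defaults to the file name.
#' @return A [distance_trace].
#' @export
read_trace <- function(path, label = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.table(path, header = TRUE)
  if (ncol(df) < 2L) stop("trace file needs columns time_ps, value_nm")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  distance_trace(df[[1L]], df[[2L]], label)
}

#' Write a distance trace to delimited text
#'
#' @param trace A [distance_trace].
#' @param path Output path; columns `time_ps`, `value_nm` with a header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "distance_trace"))
  df <- data.frame(time_ps = trace$times, value_nm = trace$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
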