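#' Multi-sensor time-series container
#'
#' Thin S3 wrapper around a T x N x C numeric array (T samples, N sensor
#' sites, C channels per sensor) with sampling metadata.
#'
#' @param data T x N x C array; dimnames 2 and 3 name sensors and channels
#' @param rate sampling rate in Hz (> 0)
#' @return object of class \code{sensor_array}
#' @export
sensor_array <- function(data, rate = 100) {
  stopifnot(is.array(data), length(dim(data)) == 3L, rate > 0)
  if (is.null(dimnames(data)[[2]]) || is.null(dimnames(data)[[3]]))
    stop("sensor and channel dimnames are required")
  structure(list(data = data, rate = rate,
                 sensor_names = dimnames(data)[[2]],
                 channel_names = dimnames(data)[[3]]),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sensor array: %d samples x %d sensors x %d channels at %g Hz\n",
              d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Flatten a sensor array to a T x (N*C) matrix
#'
#' Column names are \code{sensor.channel}; column order is fixed
#' (sensor-major) so feature manifests and model inputs are stable.
#'
#' @param sa a \code{\link{sensor_array}}
#' @return numeric matrix
#' @export
sensor_matrix <- function(sa) {
  d <- dim(sa$data)
  out <- matrix(NA_real_, d[1], d[2] * d[3])
  k <- 0L
  for (s in seq_len(d[2])) for (ch in seq_len(d[3])) {
    k <- k + 1L
    out[, k] <- sa$data[, s, ch]
  }
  colnames(out) <- as.vector(vapply(sa$sensor_names, function(s)
    paste(s, sa$channel_names, sep = "."), character(d[3])))
  out
}
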