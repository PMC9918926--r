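# Injection/measurement protocols.
#
# A protocol lists the current injection pairs and, for each injection, which
# single-ended electrode potentials (against the zero-mean ground reference)
# enter the measurement frame. The frame length m is the number of
# measurement definitions.

#' Construct a measurement protocol
#'
#' @param injections Data frame (or tibble) with columns `source`, `sink`
#'   (electrode indices) and `amplitude` (amperes).
#' @param measurements Data frame with columns `injection` (row index into
#'   `injections`) and `electrode` (electrode whose potential is recorded).
#' @param electrode_count Total number of electrodes addressed.
#' @return An `eit_protocol` object; `frame_length(p)` equals
#'   `nrow(measurements)`.
#' @export
eit_protocol <- function(injections, measurements, electrode_count) {
  injections <- tibble::as_tibble(injections)
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("source", "sink", "amplitude") %in% names(injections)),
            all(c("injection", "electrode") %in% names(measurements)))
  electrode_count <- as.integer(electrode_count)
  idx <- c(injections$source, injections$sink, measurements$electrode)
  if (any(idx < 1L) || any(idx > electrode_count)) {
    stop("electrode index out of range for this protocol", call. = FALSE)
  }
  if (any(injections$source == injections$sink)) {
    stop("injection pair must use two distinct electrodes", call. = FALSE)
  }
  if (any(injections$amplitude <= 0)) {
    stop("injection amplitude must be positive", call. = FALSE)
  }
  if (any(measurements$injection < 1L) ||
      any(measurements$injection > nrow(injections))) {
    stop("measurement references a missing injection", call. = FALSE)
  }
  structure(list(
    injections = injections,
    measurements = measurements,
    electrode_count = electrode_count
  ), class = "eit_protocol")
}

#' Default opposite-pair protocol
#'
#' For an even number of electrodes, injects between opposite-style pairs
#' `(i, i + count/2)` at 1 mA and records the single-ended potential at every
#' electrode for each injection. With the default 8 electrodes this yields 4
#' injection pairs and a frame of m = 32 voltages.
#'
#' @param electrode_count Even number of electrodes; default 8.
#' @param amplitude Injection current in amperes (default 1 mA).
#' @return An `eit_protocol`.
#' @export
default_protocol <- function(electrode_count = 8L, amplitude = 1e-3) {
  electrode_count <- as.integer(electrode_count)
  if (electrode_count < 2L || electrode_count %% 2L != 0L) {
    stop("default_protocol requires an even electrode count >= 2", call. = FALSE)
  }
  half <- electrode_count %/% 2L
  injections <- tibble::tibble(
    source = seq_len(half),
    sink = seq_len(half) + half,
    amplitude = amplitude
  )
  measurements <- tidyr::expand_grid(
    injection = seq_len(half),
    electrode = seq_len(electrode_count)
  )
  eit_protocol(injections, measurements, electrode_count)
}

#' Frame length of a protocol
#' @param protocol An `eit_protocol`.
#' @return Integer m, the number of voltages per measurement frame.
#' @export
frame_length <- function(protocol) {
  stopifnot(inherits(protocol, "eit_protocol"))
  nrow(protocol$measurements)
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %d electrodes, %d injections, frame length m = %d\n",
              x$electrode_count, nrow(x$injections), frame_length(x)))
  invisible(x)
}

# Stable identifier used to check that a frame and a classifier bank were
# produced under the same protocol.
protocol_id <- function(protocol) {
  paste0(
    "e", protocol$electrode_count, ":",
    paste(protocol$injections$source, protocol$injections$sink,
          signif(protocol$injections$amplitude, 12), sep = "-", collapse = ","),
    ":", paste(protocol$measurements$injection, protocol$measurements$electrode,
               sep = "-", collapse = ",")
  )
}
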