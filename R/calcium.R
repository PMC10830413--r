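# Synchronized-firing extraction from calcium dF/F traces. The per-FOV
# synchronous trace is the pointwise mean over somata; network events are
# detected on it with the standard peak semantics (height, interpolated
# width at half prominence, minimum separation) and the parameter set
# height = 0.15, width in (2, 20) samples, distance = 20 samples.

#' Default peak-detection parameters
#' @export
peak_params <- function(min_height = 0.15, width_range = c(2, 20),
                        min_distance = 20) {
  stopifnot(width_range[1] < width_range[2], min_distance >= 1)
  list(min_height = min_height, width_range = width_range,
       min_distance = min_distance)
}

#' Synchronous firing trace of a field of view
#'
#' Pointwise mean of the dF/F traces of all detected somata.
#'
#' @param traces cells x timepoints matrix.
#' @return numeric vector of length \code{ncol(traces)}.
#' @export
synchronous_trace <- function(traces) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
  if (nrow(traces) == 0L) stop("no cell traces")
  colMeans(traces)
}

.find_local_maxima <- function(x) {
  # strict local maxima; plateaus reduced to their (floor) midpoint
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
      } else i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

.peak_prominence <- function(x, p) {
  n <- length(x)
  # left base: minimum between the peak and the previous higher point
  i <- p; lmin <- x[p]; lbase <- p
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > x[p]) break
    if (x[i] < lmin) { lmin <- x[i]; lbase <- i }
  }
  i <- p; rmin <- x[p]; rbase <- p
  while (i < n) {
    i <- i + 1L
    if (x[i] > x[p]) break
    if (x[i] < rmin) { rmin <- x[i]; rbase <- i }
  }
  list(prominence = x[p] - max(lmin, rmin), lbase = lbase, rbase = rbase)
}

.peak_width <- function(x, p, prom, rel_height = 0.5) {
  h <- x[p] - rel_height * prom$prominence
  # walk left within the base interval to the crossing, interpolating
  i <- p
  while (i > prom$lbase && x[i - 1L] > h) i <- i - 1L
  lp <- if (i > prom$lbase && x[i - 1L] <= h)
    (i - 1L) + (h - x[i - 1L]) / (x[i] - x[i - 1L])
  else i
  i <- p
  while (i < prom$rbase && x[i + 1L] > h) i <- i + 1L
  rp <- if (i < prom$rbase && x[i + 1L] <= h)
    i + (x[i] - h) / (x[i] - x[i + 1L])
  else i
  rp - lp
}

#' Detect network events on a trace
#'
#' Events are local maxima (plateaus reduced to their midpoint) with value
#' >= \code{min_height}, minimum pairwise separation \code{min_distance}
#' samples (enforced by keeping taller peaks first; equal heights keep the
#' earlier peak), and interpolated width at half prominence within
#' \code{width_range}.
#'
#' @param trace numeric dF/F trace.
#' @param params list from \code{\link{peak_params}}.
#' @return data.frame with \code{index} (1-based sample), \code{height},
#'   \code{prominence}, \code{width}; zero rows when nothing qualifies.
#' @export
detect_events <- function(trace, params = peak_params()) {
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  p <- .find_local_maxima(trace)
  p <- p[trace[p] >= params$min_height]
  if (length(p) == 0L) return(empty)
  # distance enforcement, tallest first; ties keep the earlier peak
  ord <- order(-trace[p], p)
  keep <- logical(length(p))
  for (k in ord) {
    if (!any(abs(p[keep] - p[k]) < params$min_distance))
      keep[k] <- TRUE
  }
  p <- sort(p[keep])
  prom <- lapply(p, function(i) .peak_prominence(trace, i))
  width <- mapply(function(i, pr) .peak_width(trace, i, pr), p, prom)
  ok <- width >= params$width_range[1] & width <= params$width_range[2]
  data.frame(index = p[ok], height = trace[p[ok]],
             prominence = vapply(prom[ok], `[[`, numeric(1), "prominence"),
             width = width[ok])
}

#' Summarize firing across fields of view
#'
#' Per FOV the rate is the event count divided by the recording duration;
#' the batch-level values are the median rate and the median event amplitude
#' across FOVs (amplitude per FOV = median event height).
#'
#' @param events_per_fov list of event data.frames from
#'   \code{\link{detect_events}}.
#' @param duration_s recording duration of each FOV in seconds (> 0).
#' @return list with \code{rates_hz}, \code{amplitudes}, \code{median_rate_hz},
#'   \code{median_amplitude}.
#' @export
firing_summary <- function(events_per_fov, duration_s) {
  stopifnot(duration_s > 0)
  rates <- vapply(events_per_fov, function(e) nrow(e) / duration_s,
                  numeric(1))
  amps <- vapply(events_per_fov, function(e)
    if (nrow(e) > 0L) median(e$height) else NA_real_, numeric(1))
  list(rates_hz = rates, amplitudes = amps,
       median_rate_hz = median(rates),
       median_amplitude = median(amps, na.rm = TRUE))
}

#' Read dF/F traces from CSV
#'
#' Rows are cells, columns are frames.
#'
#' @param file CSV path.
#' @param frame_interval_s sampling interval in seconds (default 0.085).
#' @return list with \code{traces} matrix and \code{frame_interval_s}.
#' @export
read_trace_matrix <- function(file, frame_interval_s = 0.085) {
  m <- as.matrix(utils::read.csv(file, header = FALSE))
  dimnames(m) <- NULL
  list(traces = m, frame_interval_s = frame_interval_s)
}
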