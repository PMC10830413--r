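# FRAP recovery fitting and BRET arithmetic.

#' Fit an exponential FRAP recovery curve
#'
#' Least-squares fit of y = a * exp(-b * x) + c with the half-time
#' t_half = ln(2) / b. Initialization: a0 = y[1] - y[n], c0 = y[n],
#' b0 = 3 / time span. The rate b is bounded below (1e-6) so the recovery
#' direction cannot flip sign during optimization; b at the bound or a
#' non-positive fitted rate is flagged invalid. Only the recovery kinetics
#' (b, t_half) are primary outputs; the plateau c and span a are reported as
#' secondary because the recovery fraction is sensitive to the (uncontrolled)
#' photobleach duration.
#'
#' @param times numeric, strictly increasing post-bleach times in seconds
#'   (>= 4 points).
#' @param intensities normalized fluorescence at \code{times}.
#' @return list with \code{a}, \code{b}, \code{c}, \code{t_half_s},
#'   \code{residual_norm}, \code{converged}, \code{valid}.
#' @export
fit_frap <- function(times, intensities) {
  stopifnot(length(times) == length(intensities), length(times) >= 4,
            all(diff(times) > 0))
  if (sd(intensities) == 0) stop("constant intensity curve; degenerate fit")
  n <- length(times)
  start <- list(a = intensities[1] - intensities[n], c = intensities[n],
                b = 3 / (times[n] - times[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                      data = data.frame(x = times, y = intensities),
                      start = start,
                      lower = c(a = -Inf, c = -Inf, b = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                t_half_s = NA_real_, residual_norm = NA_real_,
                converged = FALSE, valid = FALSE))
  cf <- stats::coef(fit)
  valid <- cf[["b"]] > 1e-6
  list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
       t_half_s = if (valid) log(2) / cf[["b"]] else NA_real_,
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       converged = TRUE, valid = valid)
}

#' Net BRET from emission ratios
#'
#' The BRET ratio is GFP2 (510 nm) over RLuc8 (395 nm) emission; net BRET
#' subtracts the mean ratio of the baseline condition (receptor dose
#' "0 ng", i.e. constitutive coupling) within each transducer pairing.
#'
#' @param measurements data.frame with columns \code{condition},
#'   \code{gfp2}, \code{rluc8}, and optionally \code{transducer}.
#' @param baseline_condition label of the baseline (default \code{"0 ng"}).
#' @return input with \code{ratio} and \code{net_bret} columns appended.
#' @export
net_bret <- function(measurements, baseline_condition = "0 ng") {
  m <- measurements
  stopifnot(all(m$gfp2 > 0), all(m$rluc8 > 0))
  if (is.null(m$transducer)) m$transducer <- "pairing"
  if (!any(m$condition == baseline_condition))
    stop("baseline condition '", baseline_condition, "' not present")
  m$ratio <- m$gfp2 / m$rluc8
  base <- tapply(m$ratio[m$condition == baseline_condition],
                 m$transducer[m$condition == baseline_condition], mean)
  if (any(!unique(m$transducer) %in% names(base)))
    stop("baseline condition missing for some transducer pairing")
  m$net_bret <- m$ratio - as.numeric(base[m$transducer])
  m
}
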