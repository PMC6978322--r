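#' Construct and validate an intensity trace
#'
#' @param time_s Frame times in seconds, strictly increasing.
#' @param I_dna,I_rnap,I_probe Per-frame intensities for the DNA template,
#'   RNAP and transcript-probe channels.
#' @return A data.frame of class `intensity_trace` with attribute `max_gap`
#'   (largest inter-frame interval, s).
#' @export
intensity_trace <- function(time_s, I_dna, I_rnap, I_probe) {
  nlen <- unique(c(length(time_s), length(I_dna), length(I_rnap),
                   length(I_probe)))
  if (length(nlen) != 1L) abort("all channels must have equal length")
  if (any(!is.finite(time_s)) || is.unsorted(time_s, strictly = TRUE))
    abort("'time_s' must be finite and strictly increasing")
  df <- data.frame(time_s = time_s, I_dna = I_dna, I_rnap = I_rnap,
                   I_probe = I_probe)
  attr(df, "max_gap") <- if (nlen > 1L) max(diff(time_s)) else NA_real_
  class(df) <- c("intensity_trace", "data.frame")
  df
}

#' Fit the elongation-phase intensity decay
#'
#' Least-squares fit of \eqn{I(t) = I_P e^{-\lambda t} + I_{mn}} to the RNAP
#' channel inside a user-chosen elongation window; the time origin is the
#' window start.  Starting values are derived without derivatives: `I_mn`
#' from the trailing intensity level, `I_P` from the first frames minus that
#' baseline, and \eqn{\lambda} from a log-linear regression of the
#' baseline-subtracted signal.
#'
#' @param trace An [intensity_trace()].
#' @param window Numeric length-2 vector `c(t_start, t_end)` in seconds.
#' @param orientation Tether orientation.  `"up"` fits a decay with time
#'   origin at the window start; `"down"` (inverted template, intensity
#'   rises during elongation) fits the time-reversed decay, with time origin
#'   at the window end.
#' @return An object of class `calibration_fit`: a list with `I_P`, `I_mn`,
#'   `lambda`, `window`, `residual_sd`, `converged` and the fitted window
#'   times/values.
#' @examples
#' t <- seq(0, 200, by = 2)
#' tr <- intensity_trace(t, 600, 800 * exp(-0.01 * t) + 100, 100)
#' fit <- fit_elongation_decay(tr, c(0, 200))
#' c(fit$I_P, fit$I_mn, fit$lambda)
#' @export
fit_elongation_decay <- function(trace, window,
                                 orientation = c("up", "down")) {
  if (!inherits(trace, "intensity_trace"))
    abort("'trace' must be an intensity_trace")
  orientation <- match.arg(orientation)
  if (length(window) != 2L || window[2] <= window[1])
    abort("'window' must be c(t_start, t_end) with t_end > t_start")
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(sel) < 10L)
    abort("elongation window contains %d frames; need >= 10", sum(sel))
  tt <- if (orientation == "up") trace$time_s[sel] - window[1]
        else window[2] - trace$time_s[sel]     # time-reversed decay
  y <- trace$I_rnap[sel]
  o <- order(tt)
  tt <- tt[o]
  y <- y[o]

  # derivative-free starting values
  mn0 <- median(tail(y, max(3L, ceiling(length(y) / 10))))
  mn0 <- min(mn0, min(y))                      # keep y - mn0 >= 0
  ip0 <- max(mean(head(y, 5)) - mn0, diff(range(y)) / 2, 1e-6)
  pos <- y - mn0 > ip0 * 0.05
  lam0 <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(y[pos] - mn0 + 1e-9) ~ tt[pos]))[2]
    max(-sl, 1e-5)
  } else 1 / max(tt)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I_P * exp(-lambda * tt) + I_mn,
                      start = list(I_P = ip0, lambda = lam0, I_mn = mn0),
                      lower = c(1e-9, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- list(I_P = NA_real_, I_mn = NA_real_, lambda = NA_real_,
                window = window, orientation = orientation,
                residual_sd = NA_real_, converged = FALSE,
                time = tt, fitted = rep(NA_real_, length(tt)))
  } else {
    cf <- coef(fit)
    out <- list(I_P = unname(cf["I_P"]), I_mn = unname(cf["I_mn"]),
                lambda = unname(cf["lambda"]), window = window,
                orientation = orientation,
                residual_sd = sd(stats::residuals(fit)), converged = TRUE,
                time = tt, fitted = stats::fitted(fit))
  }
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Elongation decay fit  I(t) = I_P exp(-lambda t) + I_mn\n")
  cat(sprintf("  I_P = %.4g   I_mn = %.4g   lambda = %.4g /s\n",
              x$I_P, x$I_mn, x$lambda))
  cat(sprintf("  window [%g, %g] s   residual SD %.3g   converged: %s\n",
              x$window[1], x$window[2], x$residual_sd, x$converged))
  invisible(x)
}

check_fit <- function(fit) {
  if (!inherits(fit, "calibration_fit")) abort("need a calibration_fit")
  if (!isTRUE(fit$converged)) abort("calibration fit did not converge")
  invisible(fit)
}

#' Elongation rate from the calibrated decay and termination intensity
#'
#' Combines the decay fit with the known promoter and terminator positions:
#' \deqn{r_{RNAP} = (z_T - z_P) / [\lambda^{-1} \ln(I_P / (I_T - I_{mn}))]}
#' where \eqn{I_T} is the RNAP intensity at probe departure.
#'
#' @param fit A converged [fit_elongation_decay()] result.
#' @param I_T RNAP intensity at the time of termination.
#' @param z_P,z_T Promoter and terminator contour positions, bp.
#' @return A list with `r_RNAP` (bp/s), the elongation duration implied by
#'   the intensities (`t_elong`, s), and `unphysical` flag (TRUE when
#'   `I_T - I_mn >= I_P`, i.e. termination at or above promoter-proximal
#'   intensity, which sends the rate to infinity).
#' @examples
#' fit <- structure(list(I_P = 800, I_mn = 100, lambda = 0.01,
#'                       converged = TRUE), class = "calibration_fit")
#' compute_elongation_rate(fit, I_T = 800 / exp(1) + 100, z_P = 0, z_T = 2100)
#' @export
compute_elongation_rate <- function(fit, I_T, z_P, z_T) {
  check_fit(fit)
  check_num(I_T, "I_T")
  if (z_T <= z_P) abort("z_T must exceed z_P")
  if (I_T <= fit$I_mn)
    abort("termination intensity at/below background (I_T <= I_mn)")
  lnterm <- log(fit$I_P / (I_T - fit$I_mn))
  unphysical <- lnterm <= 0
  r <- if (unphysical) Inf else (z_T - z_P) / (lnterm / fit$lambda)
  list(r_RNAP = r, t_elong = lnterm / fit$lambda, unphysical = unphysical)
}

#' Convert RNAP intensity to position along the DNA contour
#'
#' Inverts the calibrated decay:
#' \deqn{z(t) = r_{RNAP} \lambda^{-1} \ln(I_P / (I(t) - I_{mn})) + z_P.}
#' Frames with `I(t) <= I_mn` cannot be inverted and are masked (`NA`), never
#' extrapolated.  For a `"down"`-tethered template pass `orientation =
#' "down"`: the position axis is sign-flipped about the template so that
#' elongation still runs from `z_P` towards `z_T`.
#'
#' @param fit A converged [fit_elongation_decay()] result.
#' @param r_RNAP Elongation rate, bp/s (see [compute_elongation_rate()]).
#' @param trace An [intensity_trace()] (or any data.frame with `time_s` and
#'   `I_rnap`).
#' @param z_P Promoter contour position, bp (up orientation anchor).
#' @param frames Optional logical/integer subset of frames to convert.
#' @param template_length Optional; positions outside `[0, template_length]`
#'   are flagged in the `out_of_range` column (kept, not clipped).
#' @param orientation `"up"` or `"down"`.  For `"down"` the bright end of
#'   the intensity map is the terminator, so `z_T` anchors the inversion:
#'   \eqn{z = z_T - r \lambda^{-1} \ln(I_P/(I - I_{mn}))}.
#' @param z_T Terminator contour position, bp (required for `"down"`).
#' @return A data.frame of class `position_trace`: `time_s`, `z` (bp, `NA`
#'   where masked), `masked`, `out_of_range`; attributes `r_RNAP` and
#'   `orientation`.  A warning is logged when more than half the requested
#'   frames are masked.
#' @export
intensity_to_position <- function(fit, r_RNAP, trace, z_P,
                                  frames = NULL, template_length = NULL,
                                  orientation = c("up", "down"),
                                  z_T = NULL) {
  check_fit(fit)
  orientation <- match.arg(orientation)
  check_num(r_RNAP, "r_RNAP", lower = 1e-12)
  tt <- trace$time_s
  I <- trace$I_rnap
  if (!is.null(frames)) { tt <- tt[frames]; I <- I[frames] }
  ok <- is.finite(I) & (I > fit$I_mn)
  z <- rep(NA_real_, length(I))
  depth <- r_RNAP / fit$lambda * log(fit$I_P / (I[ok] - fit$I_mn))
  if (orientation == "up") {
    z[ok] <- depth + z_P
  } else {
    if (is.null(z_T)) abort("'z_T' is required for down orientation")
    z[ok] <- z_T - depth
  }
  if (length(ok) && mean(!ok) > 0.5)
    warning(sprintf("%.0f%% of frames masked (intensity at/below background)",
                    100 * mean(!ok)), call. = FALSE)
  oor <- if (is.null(template_length)) rep(FALSE, length(z))
         else !is.na(z) & (z < 0 | z > template_length)
  out <- data.frame(time_s = tt, z = z, masked = !ok, out_of_range = oor)
  attr(out, "r_RNAP") <- r_RNAP
  attr(out, "orientation") <- orientation
  class(out) <- c("position_trace", "data.frame")
  out
}

#' Round-trip a position trace back to intensity
#'
#' The inverse of [intensity_to_position()]; used to verify the calibration
#' algebra (`intensity -> position -> intensity` is the identity on unmasked
#' frames).
#'
#' @param fit A converged [fit_elongation_decay()] result.
#' @param r_RNAP Elongation rate, bp/s.
#' @param z Contour positions, bp.
#' @param z_P Promoter position, bp.
#' @return Numeric intensities.
#' @export
position_to_intensity <- function(fit, r_RNAP, z, z_P) {
  check_fit(fit)
  fit$I_P * exp(-fit$lambda * (z - z_P) / r_RNAP) + fit$I_mn
}
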