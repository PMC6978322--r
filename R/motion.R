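#' Time-averaged mean squared displacement of a position trace
#'
#' Computes the single-trajectory, time-averaged MSD
#' \eqn{MSD(\tau) = \langle (z(t+\tau) - z(t))^2 \rangle} over all frame
#' pairs whose true time separation matches each lag.  Acquisition gaps are
#' respected: pairs are binned by their actual \eqn{\Delta t}, so a pair
#' spanning a gap contributes to the lag it really represents, and lags not
#' realised by any pair are absent from the curve.
#'
#' @param time_s Frame times, s (strictly increasing).
#' @param z Positions, bp; `NA` frames are dropped.
#' @param max_lag Largest lag to evaluate, s.
#' @param lag_tol Lags are rounded to multiples of the median frame interval
#'   within this relative tolerance when binning pairs.
#' @return A data.frame with columns `lag` (s), `msd` (bp^2) and `n_pairs`.
#' @examples
#' t <- seq(0, 100, by = 2)
#' compute_msd(t, 3 * t, max_lag = 10)   # ballistic: MSD = 9 tau^2
#' @export
compute_msd <- function(time_s, z, max_lag, lag_tol = 0.25) {
  keep <- is.finite(z) & is.finite(time_s)
  time_s <- time_s[keep]; z <- z[keep]
  if (length(z) < 2L) abort("need at least two finite positions")
  span <- diff(range(time_s))
  if (span < 2 * max_lag)
    abort("segment duration %.3g s shorter than 2 * max_lag = %.3g s",
          span, 2 * max_lag)
  base <- median(diff(time_s))
  n <- length(z)
  max_k <- floor(max_lag / base + lag_tol)
  # all pairs up to max_lag, binned by true dt
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  dt <- time_s[j] - time_s[i]
  sel <- dt <= max_lag * (1 + lag_tol * base / max_lag)
  i <- i[sel]; j <- j[sel]; dt <- dt[sel]
  k <- round(dt / base)
  on_grid <- abs(dt - k * base) <= lag_tol * base & k >= 1 & k <= max_k
  i <- i[on_grid]; j <- j[on_grid]; k <- k[on_grid]
  if (!length(k)) abort("no frame pairs available at the requested lags")
  sq <- (z[j] - z[i])^2
  msd <- tapply(sq, k, mean)
  npr <- tapply(sq, k, length)
  lags <- as.numeric(names(msd)) * base
  data.frame(lag = lags, msd = as.numeric(msd),
             n_pairs = as.integer(npr), row.names = NULL)
}

#' Diffusion coefficient from the short-lag MSD slope
#'
#' Straight-line fit (free intercept) to the first `n_points` lags of an MSD
#' curve; for 1D diffusion \eqn{MSD(\tau) = 2 D \tau}, so `D = slope / 2`.
#' The intercept absorbs static localisation error.  Noise can drive the
#' fitted slope negative; negative `D` is reported as-is and is interpreted
#' downstream as non-sliding.
#'
#' @param msd A data.frame from [compute_msd()] (columns `lag`, `msd`).
#' @param n_points Number of leading lag points used (default 10).
#' @return A list with `D` (bp^2/s), `intercept` (bp^2) and `n_points`.
#' @examples
#' msd <- data.frame(lag = 1:10, msd = 2 * 1e4 * (1:10))
#' estimate_diffusion(msd)$D
#' @export
estimate_diffusion <- function(msd, n_points = 10L) {
  if (nrow(msd) < n_points)
    abort("MSD curve has %d lag points; need >= %d", nrow(msd), n_points)
  d <- head(msd[order(msd$lag), ], n_points)
  cf <- coef(lm(msd ~ lag, data = d))
  list(D = unname(cf[2]) / 2, intercept = unname(cf[1]),
       n_points = as.integer(n_points))
}

#' Windowed diffusion coefficients along a position trace
#'
#' Slides a `window`-second window along the trace (stride of one frame by
#' default, i.e. maximally overlapping windows) and, for each placement with
#' enough data, computes the time-averaged MSD up to `max_lag` and the
#' short-lag diffusion coefficient.
#'
#' @param time_s Frame times, s.
#' @param z Positions, bp (`NA` allowed).
#' @param window Window length, s (default 50).
#' @param stride Stride between window starts, in frames (default 1).
#' @param n_points Leading lag points for the slope fit (default 10).
#' @param max_lag Largest MSD lag, s.  Default `NULL` evaluates
#'   `n_points` lag points at the trace's own frame spacing
#'   (`n_points * median frame interval`), so the slope fit always has its
#'   full complement of points regardless of acquisition rate.
#' @return A data.frame with one row per evaluable window: `t_start`,
#'   `t_end`, `D`, `intercept`, `n_frames`.
#' @export
window_diffusion <- function(time_s, z, window = 50, stride = 1L,
                             max_lag = NULL, n_points = 10L) {
  stopifnot(length(time_s) == length(z))
  if (length(time_s) < 2L) abort("trace too short")
  if (diff(range(time_s)) < window) abort("trace shorter than one window")
  if (is.null(max_lag))
    max_lag <- n_points * median(diff(time_s))
  starts <- seq(1L, length(time_s), by = as.integer(stride))
  rows <- lapply(starts, function(s0) {
    t0 <- time_s[s0]
    sel <- time_s >= t0 & time_s <= t0 + window
    if (sum(sel & is.finite(z)) < n_points + 2L) return(NULL)
    if (max(time_s[sel]) - t0 < window * 0.99) return(NULL)  # truncated tail
    est <- tryCatch({
      m <- compute_msd(time_s[sel], z[sel], max_lag = max_lag)
      if (nrow(m) < n_points) NULL else estimate_diffusion(m, n_points)
    }, error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(t_start = t0, t_end = t0 + window, D = est$D,
               intercept = est$intercept, n_frames = sum(sel))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(t_start = numeric(), t_end = numeric(), D = numeric(),
                      intercept = numeric(), n_frames = integer())
  out
}

#' Score sliding from windowed diffusion coefficients
#'
#' A molecule is scored as sliding if any window's diffusion coefficient
#' reaches `threshold` (inclusive).  The default threshold of
#' 2.2e4 bp^2 s^-1 is the saddle point between the stuck (~0) and sliding
#' modes of the windowed-D distribution.
#'
#' @param windows Data.frame from [window_diffusion()] (column `D`).
#' @param threshold Diffusion threshold, bp^2 s^-1.
#' @return Logical flag.
#' @export
classify_sliding <- function(windows, threshold = 2.2e4) {
  if (!nrow(windows)) abort("no diffusion windows supplied")
  any(windows$D >= threshold)
}

# Hysteresis (zigzag) segmentation: split a signal into monotone swings
# whose amplitude exceeds `thresh`; robust to frame-to-frame noise.
swing_episodes <- function(y, thresh) {
  n <- length(y)
  empty <- data.frame(start = integer(), end = integer(),
                      direction = numeric())
  if (n < 2L) return(empty)
  starts <- ends <- integer(); dirs <- numeric()
  emit <- function(a, b, d) {
    starts <<- c(starts, a); ends <<- c(ends, b); dirs <<- c(dirs, d)
  }
  dir <- 0
  min_i <- max_i <- 1L   # running extremes before the first swing
  piv <- ext_i <- 1L     # last pivot / running extreme of current swing
  for (i in 2:n) {
    if (dir == 0) {
      if (y[i] >= y[max_i]) max_i <- i
      if (y[i] <= y[min_i]) min_i <- i
      if (y[max_i] - y[i] > thresh) {
        if (min_i < max_i && y[max_i] - y[min_i] > thresh)
          emit(min_i, max_i, 1)
        dir <- -1; piv <- max_i; ext_i <- i
      } else if (y[i] - y[min_i] > thresh) {
        if (max_i < min_i && y[max_i] - y[min_i] > thresh)
          emit(max_i, min_i, -1)
        dir <- 1; piv <- min_i; ext_i <- i
      }
    } else if (dir > 0) {
      if (y[i] >= y[ext_i]) ext_i <- i
      else if (y[ext_i] - y[i] > thresh) {
        emit(piv, ext_i, 1)
        dir <- -1; piv <- ext_i; ext_i <- i
      }
    } else {
      if (y[i] <= y[ext_i]) ext_i <- i
      else if (y[i] - y[ext_i] > thresh) {
        emit(piv, ext_i, -1)
        dir <- 1; piv <- ext_i; ext_i <- i
      }
    }
  }
  if (dir != 0 && abs(y[ext_i] - y[piv]) > thresh) emit(piv, ext_i, dir)
  if (!length(starts)) return(empty)
  data.frame(start = starts, end = ends, direction = dirs)
}

#' Classify post-termination secondary initiation from an intensity record
#'
#' Searches the RNAP channel after termination for episodes with the
#' signature of renewed transcript elongation: a sustained monotone intensity
#' trend that, when fit with the (possibly mirrored) exponential elongation
#' profile, yields a rate constant inside the plausible elongation range.
#' An episode qualifies as a "visible elongation profile" when it is
#' monotone for at least `min_duration_frac` of the sense elongation
#' duration and its amplitude exceeds `amp_factor` times the residual SD of
#' the calibration fit.  For an `"up"` tether, intensity rising back towards
#' the promoter level means promoter-ward (antisense) motion and a renewed
#' decay means promoter-distal (sense re-initiation) motion; directions are
#' swapped for `"down"`.  The earliest qualifying episode sets the call.
#'
#' @param trace An [intensity_trace()].
#' @param fit A converged [fit_elongation_decay()] result.
#' @param t_T Termination time (transcript-probe departure), s.
#' @param rate_range Admissible exponential rate constants, s^-1; default
#'   the 0.002-0.04 elongation window.
#' @param min_duration_frac Minimum episode duration as a fraction of the
#'   sense elongation duration (window length of `fit`).
#' @param amp_factor Minimum episode amplitude in units of the calibration
#'   residual SD (floored at 1 intensity unit for noiseless records).
#' @param smooth Half-width (frames) of the running-median pre-smoother used
#'   for episode segmentation (0 = none).
#' @param min_r2 Minimum R-squared of the exponential episode fit; episodes
#'   that are large but erratic (e.g. diffusive sliding excursions) fit the
#'   smooth elongation profile poorly and are rejected.
#' @param resid_factor Maximum episode-fit residual SD, in units of the
#'   calibration residual SD (camera noise); diffusive excursions leave
#'   position-noise residuals far above camera noise and are rejected.
#' @return A list of class `behavior_call`: flags `antisense` and
#'   `sense_reinit`, the fitted `rate` (s^-1, `NA` if no call), episode
#'   window `episode` (s), and `n_candidates` examined.  When no
#'   post-termination frames exist the result is a no-call.
#' @export
classify_secondary_initiation <- function(trace, fit, t_T,
                                          rate_range = c(0.002, 0.04),
                                          min_duration_frac = 0.25,
                                          amp_factor = 3, smooth = 2L,
                                          min_r2 = 0.8, resid_factor = 3) {
  check_fit(fit)
  no_call <- structure(list(antisense = FALSE, sense_reinit = FALSE,
                            rate = NA_real_, episode = c(NA_real_, NA_real_),
                            n_candidates = 0L),
                       class = "behavior_call")
  post <- trace$time_s > t_T
  if (sum(post) < 5L) return(no_call)
  tt <- trace$time_s[post]
  y <- trace$I_rnap[post]
  ys <- if (smooth > 0) stats::runmed(y, 2L * as.integer(smooth) + 1L) else y

  sense_dur <- diff(fit$window)
  min_dur <- min_duration_frac * sense_dur
  amp_min <- amp_factor * max(fit$residual_sd, 1, na.rm = TRUE)

  eps <- swing_episodes(ys, amp_min)
  if (!nrow(eps)) return(no_call)
  eps$dur <- tt[eps$end] - tt[eps$start]
  eps <- eps[eps$dur >= min_dur, , drop = FALSE]
  if (!nrow(eps)) return(no_call)
  eps <- eps[order(eps$start), , drop = FALSE]

  up <- identical(fit$orientation, "up") || is.null(fit$orientation)
  for (k in seq_len(nrow(eps))) {
    idx <- eps$start[k]:eps$end[k]
    rising <- eps$direction[k] > 0
    # trim the post-completion plateau: stop at the first frame within the
    # amplitude threshold of the swing's extreme
    extreme <- ys[eps$end[k]]
    reach <- if (rising) which(ys[idx] >= extreme - amp_min)
             else which(ys[idx] <= extreme + amp_min)
    if (length(reach)) idx <- idx[seq_len(max(reach[1], 3L))]
    if (tt[idx[length(idx)]] - tt[idx[1]] < min_dur) next
    te <- tt[idx]
    ye <- y[idx]
    # mirrored profile: fit a decay on time-reversed data for a rising
    # episode, with the offset pinned to the calibrated background (the
    # secondary episode shares the molecule's baseline), which keeps the
    # two-parameter fit well-conditioned on partial episodes
    t_fit <- if (rising) max(te) - te else te - min(te)
    o <- order(t_fit)
    C0 <- fit$I_mn
    efit <- tryCatch(
      minpack.lm::nlsLM(ye[o] ~ A * exp(-k1 * t_fit[o]) + C0,
        start = list(A = max(abs(diff(range(ye))), 1e-6),
                     k1 = 1 / max(eps$dur[k], 1)),
        lower = c(1e-9, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(efit)) next
    rate <- unname(coef(efit)["k1"])
    if (rate < rate_range[1] || rate > rate_range[2]) next
    r2 <- 1 - sum(stats::residuals(efit)^2) /
      max(sum((ye - mean(ye))^2), .Machine$double.eps)
    if (r2 < min_r2) next
    if (sd(stats::residuals(efit)) >
        resid_factor * max(fit$residual_sd, 1, na.rm = TRUE)) next
    promoter_ward <- if (up) rising else !rising
    return(structure(list(antisense = promoter_ward,
                          sense_reinit = !promoter_ward,
                          rate = rate,
                          episode = c(tt[eps$start[k]], tt[eps$end[k]]),
                          n_candidates = nrow(eps)),
                     class = "behavior_call"))
  }
  no_call$n_candidates <- nrow(eps)
  no_call
}

#' @export
print.behavior_call <- function(x, ...) {
  lab <- if (x$antisense) "antisense secondary initiation"
         else if (x$sense_reinit) "sense re-initiation"
         else "no secondary initiation"
  cat(sprintf("Behaviour call: %s", lab))
  if (is.finite(x$rate))
    cat(sprintf(" (rate %.4g /s, episode %.0f-%.0f s)",
                x$rate, x$episode[1], x$episode[2]))
  cat("\n")
  invisible(x)
}

#' Cohort fractions with binomial standard errors
#'
#' @param flags Logical vector (one per molecule).
#' @return A list with `fraction`, `se` (binomial s.e.m.
#'   \eqn{\sqrt{\hat p (1-\hat p)/n}}) and `n`.
#' @export
fraction_with_se <- function(flags) {
  flags <- flags[!is.na(flags)]
  n <- length(flags)
  if (!n) abort("no observations")
  p <- mean(flags)
  list(fraction = p, se = sqrt(p * (1 - p) / n), n = n)
}
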