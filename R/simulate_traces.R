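#' Configuration for single-molecule intensity-trace simulation
#'
#' Defines the generative model for a surface-tethered transcription template
#' observed by TIRF microscopy.  During elongation the RNAP moves away from
#' (orientation `"up"`) or towards (`"down"`) the coverslip so its emission
#' follows an exponential decay \eqn{I(t) = I_P e^{-\lambda t} + I_{mn}};
#' after termination a retained RNAP switches between 1D sliding and sticking,
#' and may re-initiate transcription in the antisense or sense direction.
#' Photobleaching and true dissociation are competing exponential processes.
#'
#' @param frame_interval Frame spacing in seconds.
#' @param n_frames Number of frames to simulate.
#' @param I_P Promoter-proximal RNAP fluorescence amplitude (arbitrary units).
#' @param I_mn Mean background fluorescence level.
#' @param lambda_mean,lambda_cv Mean and coefficient of variation of the
#'   per-molecule intensity decay constant \eqn{\lambda} (s^-1), drawn from a
#'   lognormal so that rates stay positive.
#' @param noise_sd Gaussian noise SD added to every channel.
#' @param D_slide Sliding diffusion coefficient, bp^2 s^-1.
#' @param p_stick,p_unstick Per-frame probabilities of switching from sliding
#'   to stuck and back.
#' @param template_length DNA contour length in bp.
#' @param z_P,z_T Promoter and terminator positions along the contour (bp).
#' @param p_retain Probability that RNAP stays DNA-bound at termination.
#' @param p_antisense,p_sense_reinit Probabilities that a retained RNAP
#'   performs antisense or sense secondary initiation.
#' @param k_PB Photobleaching rate (s^-1), acting from the start of
#'   illumination.  The default (1/2400) makes ~95% of RNAP spots survive
#'   a ~130-s elongation phase, matching the observed fraction of spots
#'   still present at termination.
#' @param k_RNAP Post-termination dissociation rate (s^-1).
#' @param tether_orientation `"up"` (biotin upstream of promoter; intensity
#'   decays during elongation) or `"down"` (inverted template; intensity
#'   rises).
#' @param tirf_decay_bp Evanescent-field decay length expressed in bp of DNA
#'   contour.  Together with \eqn{\lambda} it sets the elongation rate
#'   \eqn{r = \lambda \cdot} `tirf_decay_bp`.  Default `z_T - z_P`, so a
#'   full-length transcript decays the RNAP signal by a factor of e.
#' @param hybridization_lag Delay (s) between elongation start and transcript
#'   probe detectability.
#' @param secondary_delay_mean Mean (s) of the exponential waiting time
#'   between termination and secondary initiation, when one occurs.
#' @param antisense_start_sd SD (bp) of the antisense start position below
#'   the terminator: antisense initiation occurs at the terminator-proximal
#'   promoter-like sequence, `z_T - |N(0, sd)|`.  0 starts exactly at `z_T`.
#' @param probe_target Which transcript the fluorescent probe hybridises to.
#' @param baseline_frames Number of pre-initiation background frames.
#' @param gap_every,gap_length Optional acquisition-gap pattern: every
#'   `gap_every`-th frame interval is lengthened to `gap_length` seconds,
#'   mimicking interleaved excitation cycles.  `NULL` keeps regular spacing.
#' @param dna_amp,probe_amp Fluorescence amplitudes of the DNA and probe
#'   channels above background.
#' @param seed Integer seed; all randomness in [simulate_trace()] and
#'   [simulate_cohort()] derives from it.
#'
#' @return An object of class `trace_sim_config` (a validated list).
#' @seealso [simulate_trace()], [simulate_cohort()]
#' @export
trace_sim_config <- function(frame_interval = 2, n_frames = 400,
                             I_P = 800, I_mn = 100,
                             lambda_mean = 0.01, lambda_cv = 0.3,
                             noise_sd = 20,
                             D_slide = 3.5e4, p_stick = 0.02, p_unstick = 0.05,
                             template_length = 2100, z_P = 0, z_T = 2100,
                             p_retain = 0.87, p_antisense = 0.30,
                             p_sense_reinit = 0.02,
                             k_PB = 1 / 2400, k_RNAP = 1 / 1140,
                             tether_orientation = c("up", "down"),
                             tirf_decay_bp = NULL,
                             hybridization_lag = 10,
                             secondary_delay_mean = 30,
                             antisense_start_sd = 50,
                             probe_target = c("sense", "antisense"),
                             baseline_frames = 10,
                             gap_every = NULL, gap_length = 4,
                             dna_amp = 500, probe_amp = 400,
                             seed = 1L) {
  tether_orientation <- match.arg(tether_orientation)
  probe_target <- match.arg(probe_target)
  if (is.null(tirf_decay_bp)) tirf_decay_bp <- z_T - z_P

  check_num(frame_interval, "frame_interval", lower = 1e-9)
  check_num(n_frames, "n_frames", lower = 1)
  check_num(I_P, "I_P", lower = 0)
  check_num(I_mn, "I_mn", lower = 0)
  check_num(lambda_mean, "lambda_mean", lower = 1e-12)
  check_num(lambda_cv, "lambda_cv", lower = 0)
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(D_slide, "D_slide", lower = 0)
  for (p in c("p_stick", "p_unstick", "p_retain", "p_antisense",
              "p_sense_reinit"))
    check_num(get(p), p, lower = 0, upper = 1)
  if (p_antisense + p_sense_reinit > 1)
    abort("p_antisense + p_sense_reinit must not exceed 1")
  check_num(template_length, "template_length", lower = 1)
  check_num(z_P, "z_P", lower = 0)
  check_num(z_T, "z_T", lower = 0)
  if (!(z_P < z_T && z_T <= template_length))
    abort("need 0 <= z_P < z_T <= template_length")
  check_num(k_PB, "k_PB", lower = 0)
  check_num(k_RNAP, "k_RNAP", lower = 0)
  check_num(tirf_decay_bp, "tirf_decay_bp", lower = 1e-9)
  check_num(hybridization_lag, "hybridization_lag", lower = 0)
  check_num(secondary_delay_mean, "secondary_delay_mean", lower = 1e-9)
  check_num(antisense_start_sd, "antisense_start_sd", lower = 0)
  check_num(baseline_frames, "baseline_frames", lower = 0)
  if (!is.null(gap_every)) check_num(gap_every, "gap_every", lower = 2)

  cfg <- list(
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    I_P = I_P, I_mn = I_mn, lambda_mean = lambda_mean, lambda_cv = lambda_cv,
    noise_sd = noise_sd, D_slide = D_slide,
    p_stick = p_stick, p_unstick = p_unstick,
    template_length = template_length, z_P = z_P, z_T = z_T,
    p_retain = p_retain, p_antisense = p_antisense,
    p_sense_reinit = p_sense_reinit,
    k_PB = k_PB, k_RNAP = k_RNAP,
    tether_orientation = tether_orientation,
    tirf_decay_bp = tirf_decay_bp,
    hybridization_lag = hybridization_lag,
    secondary_delay_mean = secondary_delay_mean,
    antisense_start_sd = antisense_start_sd,
    probe_target = probe_target,
    baseline_frames = as.integer(baseline_frames),
    gap_every = gap_every, gap_length = gap_length,
    dna_amp = dna_amp, probe_amp = probe_amp,
    seed = as.integer(seed))
  class(cfg) <- "trace_sim_config"
  cfg
}

# Frame time grid, optionally with a lengthened every-k-th interval
frame_times <- function(cfg) {
  dt <- rep(cfg$frame_interval, cfg$n_frames - 1L)
  if (!is.null(cfg$gap_every))
    dt[seq_along(dt) %% cfg$gap_every == 0] <- cfg$gap_length
  c(0, cumsum(dt))
}

# Lognormal draw parameterised by mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# TIRF intensity map: contour position (bp) -> mean RNAP intensity
intensity_map <- function(z, cfg) {
  depth <- if (cfg$tether_orientation == "up") z - cfg$z_P
           else (cfg$template_length - z) - (cfg$template_length - cfg$z_T)
  cfg$I_P * exp(-depth / cfg$tirf_decay_bp) + cfg$I_mn
}

# Fold positions into [0, L] (reflecting boundaries)
reflect_into <- function(x, L) {
  r <- x %% (2 * L)
  ifelse(r > L, 2 * L - r, r)
}

#' Simulate a bounded 1D random walk with reflecting boundaries
#'
#' Gaussian increments with variance \eqn{2 D \Delta t} are folded back into
#' `[0, L]` at the boundaries.  This is the sliding model for a
#' post-termination RNAP confined to the DNA template.
#'
#' @param D Diffusion coefficient, bp^2 s^-1.
#' @param L Template length, bp.
#' @param dt Time step, s; may be a scalar or a vector of length `n - 1`.
#' @param n Number of positions returned (including the start).
#' @param x0 Starting position, bp.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positions in `[0, L]`.
#' @examples
#' z <- simulate_bounded_walk(D = 3.5e4, L = 2100, dt = 2, n = 500, seed = 1)
#' range(z)
#' @export
simulate_bounded_walk <- function(D, L, dt, n, x0 = L / 2, seed = NULL) {
  check_num(D, "D", lower = 0)
  check_num(L, "L", lower = 1e-12)
  check_num(n, "n", lower = 1)
  if (any(!is.finite(dt)) || any(dt <= 0)) abort("'dt' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 1L) return(x0)
  dt <- rep_len(dt, n - 1L)
  steps <- rnorm(n - 1L, 0, sqrt(2 * D * dt))
  c(x0, reflect_into(x0 + cumsum(steps), L))
}

#' Simulate censored exponential spot lifetimes
#'
#' Draws observed spot lifetimes as the minimum of an exponential waiting
#' time with rate `k_RNAP + k_PB` (dissociation and photobleaching are
#' competing exponentials; only the first event is observable) and the
#' acquisition horizon `t_censor`.
#'
#' @param k_RNAP Dissociation rate, s^-1.
#' @param k_PB Photobleaching rate, s^-1.
#' @param t_censor Acquisition end (censoring time), s; `Inf` for none.
#' @param n Number of molecules.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `duration` (s) and `censored` (logical).
#' @examples
#' lt <- simulate_lifetimes(1 / 1140, 1 / 600, t_censor = 2000, n = 5, seed = 1)
#' @export
simulate_lifetimes <- function(k_RNAP, k_PB, t_censor, n, seed = NULL) {
  check_num(k_RNAP, "k_RNAP", lower = 0)
  check_num(k_PB, "k_PB", lower = 0)
  if (k_RNAP + k_PB <= 0) abort("k_RNAP and k_PB must not both be zero")
  if (t_censor < 0) abort("'t_censor' must be >= 0")
  check_num(n, "n", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  tt <- rexp(n, rate = k_RNAP + k_PB)
  cens <- tt >= t_censor
  data.frame(duration = pmin(tt, t_censor), censored = cens)
}

#' Simulate one single-molecule intensity trace with ground truth
#'
#' Generates a three-channel fluorescence record (DNA, RNAP, transcript
#' probe) for one surface-tethered template.  The elongation phase has
#' noiseless mean \eqn{I_P e^{-\lambda (t - t_{start})} + I_{mn}} (mirrored
#' for `"down"` tethering); post-termination frames follow a reflected
#' Brownian slide/stick walk; an antisense episode retraces the intensity
#' curve in reverse with the same molecule's \eqn{\lambda}.
#'
#' @param config A [trace_sim_config()].
#' @param molecule Integer label stored in the outputs (used by
#'   [simulate_cohort()] to derive per-molecule seeds).
#' @return A list with components
#'   \describe{
#'     \item{trace}{an `intensity_trace` data.frame: `time_s`, `I_dna`,
#'       `I_rnap`, `I_probe`.}
#'     \item{frames}{per-frame ground truth: `state` (one of `pre`,
#'       `elongating`, `sliding`, `stuck`, `antisense`, `sense_reinit`,
#'       `dissociated`, `bleached`), true `z` (bp), presence flags and the
#'       noiseless mean RNAP intensity `mu_rnap`.}
#'     \item{truth}{one-row molecule summary: `lambda`, `r_RNAP`, `t_start`,
#'       `t_T`, `retained`, `fate` (the drawn fate, whether or not the
#'       episode fit inside the observation), `t_rnap_depart`,
#'       `rnap_censored`, `t_secondary_start`, `t_secondary_end`,
#'       `secondary_completed` (episode finished before RNAP loss and
#'       acquisition end).}
#'   }
#' @examples
#' cfg <- trace_sim_config(noise_sd = 0, seed = 7)
#' sim <- simulate_trace(cfg)
#' head(sim$trace)
#' sim$truth
#' @export
simulate_trace <- function(config, molecule = 1L) {
  if (!inherits(config, "trace_sim_config"))
    abort("'config' must be created by trace_sim_config()")
  cfg <- config
  set.seed(cfg$seed + 7919L * (as.integer(molecule) - 1L))

  times <- frame_times(cfg)
  n <- cfg$n_frames
  lambda <- rlnorm_mean_cv(1, cfg$lambda_mean, cfg$lambda_cv)
  r <- lambda * cfg$tirf_decay_bp               # elongation rate, bp/s
  i_start <- min(cfg$baseline_frames + 1L, n)
  t_start <- times[i_start]
  t_T <- t_start + (cfg$z_T - cfg$z_P) / r
  t_end <- times[n]

  retained <- runif(1) < cfg$p_retain
  u <- runif(1)
  fate <- if (!retained) "none"
          else if (u < cfg$p_antisense) "antisense"
          else if (u < cfg$p_antisense + cfg$p_sense_reinit) "sense_reinit"
          else "none"
  t_bleach <- if (cfg$k_PB > 0) rexp(1, cfg$k_PB) else Inf
  t_diss <- if (!retained) t_T
            else if (cfg$k_RNAP > 0) t_T + rexp(1, cfg$k_RNAP) else Inf
  t_off <- min(t_diss, t_bleach)
  off_kind <- if (t_off == Inf) "censored"
              else if (t_bleach < t_diss) "bleached" else "dissociated"

  t_sec_start <- t_sec_end <- NA_real_
  if (fate != "none")
    t_sec_start <- t_T + rexp(1, 1 / cfg$secondary_delay_mean)

  state <- character(n)
  z <- rep(NA_real_, n)

  pre <- times < t_start
  state[pre] <- "pre"
  el <- times >= t_start & times < t_T
  state[el] <- "elongating"
  z[el] <- cfg$z_P + r * (times[el] - t_start)

  post <- which(times >= t_T)
  if (length(post)) {
    # slide/stick walk from z_T over post-termination frames
    zp <- numeric(length(post))
    st <- character(length(post))
    cur <- cfg$z_T
    sliding <- TRUE
    prev_t <- t_T
    for (j in seq_along(post)) {
      dtj <- times[post[j]] - prev_t
      prev_t <- times[post[j]]
      if (sliding && cfg$D_slide > 0 && dtj > 0)
        cur <- reflect_into(cur + rnorm(1, 0, sqrt(2 * cfg$D_slide * dtj)),
                            cfg$template_length)
      zp[j] <- cur
      st[j] <- if (sliding) "sliding" else "stuck"
      sliding <- if (sliding) runif(1) >= cfg$p_stick
                 else runif(1) < cfg$p_unstick
    }
    z[post] <- zp
    state[post] <- st

    if (fate == "antisense") {
      # initiation at the terminator-proximal promoter-like sequence
      z0 <- max(cfg$z_P,
                cfg$z_T - abs(rnorm(1, 0, cfg$antisense_start_sd)))
      dur <- (z0 - cfg$z_P) / r
      t_sec_end <- t_sec_start + max(dur, 0)
      seg <- post[times[post] >= t_sec_start & times[post] < t_sec_end]
      z[seg] <- z0 - r * (times[seg] - t_sec_start)
      state[seg] <- "antisense"
      after <- post[times[post] >= t_sec_end]
      z[after] <- cfg$z_P
      state[after] <- "stuck"
    } else if (fate == "sense_reinit") {
      # re-initiation at the promoter; a second forward elongation episode
      dur <- (cfg$z_T - cfg$z_P) / r
      t_sec_end <- t_sec_start + dur
      seg <- post[times[post] >= t_sec_start & times[post] < t_sec_end]
      z[seg] <- cfg$z_P + r * (times[seg] - t_sec_start)
      state[seg] <- "sense_reinit"
      after <- post[times[post] >= t_sec_end]
      z[after] <- cfg$z_T
      state[after] <- "stuck"
    }
  }

  gone <- times >= t_off
  state[gone] <- if (off_kind == "bleached") "bleached" else "dissociated"
  z[gone] <- NA_real_

  rnap_present <- !(state %in% c("pre", "dissociated", "bleached"))
  mu_rnap <- ifelse(rnap_present, intensity_map(z, cfg), cfg$I_mn)

  sec_completed <- fate != "none" && !is.na(t_sec_end) &&
    t_sec_end <= min(t_off, t_end)
  probe_present <- if (cfg$probe_target == "sense") {
    times >= t_start + cfg$hybridization_lag & times < t_T
  } else {
    if (fate != "antisense" || !sec_completed) rep(FALSE, n)
    else times >= t_sec_end
  }
  mu_probe <- cfg$I_mn + ifelse(probe_present, cfg$probe_amp, 0)
  mu_dna <- rep(cfg$I_mn + cfg$dna_amp, n)

  noise <- function() if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  trace <- intensity_trace(time_s = times,
                           I_dna = mu_dna + noise(),
                           I_rnap = mu_rnap + noise(),
                           I_probe = mu_probe + noise())

  frames <- data.frame(molecule = molecule, time_s = times, state = state,
                       z = z, rnap_present = rnap_present,
                       probe_present = probe_present, mu_rnap = mu_rnap)
  truth <- data.frame(
    molecule = molecule, lambda = lambda, r_RNAP = r,
    t_start = t_start, t_T = t_T, retained = retained, fate = fate,
    t_rnap_depart = if (t_off <= t_end) t_off else NA_real_,
    rnap_censored = t_off > t_end,
    t_secondary_start = if (fate == "none") NA_real_ else t_sec_start,
    t_secondary_end = t_sec_end,
    secondary_completed = sec_completed,
    t_acq_end = t_end)
  list(trace = trace, frames = frames, truth = truth)
}

#' Simulate a cohort of single-molecule traces
#'
#' @param config A [trace_sim_config()]; its `seed` deterministically derives
#'   one seed per molecule.
#' @param n_molecules Number of molecules.
#' @return A list with `traces` (list of `intensity_trace`), `frames`
#'   (row-bound per-frame truth) and `truth` (one row per molecule).
#' @examples
#' coh <- simulate_cohort(trace_sim_config(seed = 2), n_molecules = 3)
#' coh$truth$fate
#' @export
simulate_cohort <- function(config, n_molecules) {
  check_num(n_molecules, "n_molecules", lower = 1)
  sims <- lapply(seq_len(n_molecules),
                 function(i) simulate_trace(config, molecule = i))
  list(traces = lapply(sims, `[[`, "trace"),
       frames = do.call(rbind, lapply(sims, `[[`, "frames")),
       truth = do.call(rbind, lapply(sims, `[[`, "truth")))
}
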