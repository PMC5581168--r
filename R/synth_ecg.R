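# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic 12-lead ECG generator
#'
#' The generator emulates a supine-standing-like recording: an RR series with
#' a step change (rest then standing), a configurable frontal heart axis and
#' T axis, per-lead projections of parametric P/QRS/T bumps from a fixed
#' dipole geometry, LQT-like T morphologies, and additive broadband noise,
#' 50 Hz interference and slow baseline wander. Defaults follow the dynamics
#' the method was designed for: RR 1000 -> 650 ms, heart axis 42 deg, T axis
#' 26 deg, QT 400 ms.
#'
#' @param duration recording length in seconds (default 300, a 5-minute
#'   test).
#' @param fs sample rate in Hz (>= 250; default 1000).
#' @param rr_baseline,rr_step RR level before/after the step change, ms
#'   (defaults 1000 and 650).
#' @param step_time time of the step change in seconds (default half the
#'   duration).
#' @param rr_jitter beat-to-beat Gaussian RR jitter SD in ms (default 20).
#' @param heart_axis,t_axis frontal-plane QRS and T axis angles in degrees
#'   (defaults 42 and 26).
#' @param qt_true QT interval in ms: QRS onset to the tangent-intercept T end
#'   (default 400).
#' @param qt_adapt `"fixed"` (constant QT) or `"bazett"` (QT scales with
#'   `sqrt(RR)` around `qt_true` at RR 1000 ms).
#' @param morphology T-wave preset: `"monophasic"`, `"broad"`, `"notched"`,
#'   `"biphasic"` or `"low_amplitude"`.
#' @param noise_uv broadband noise RMS per lead in microvolts (default 10).
#' @param mains_uv 50 Hz interference amplitude per electrode in microvolts
#'   (default 10).
#' @param wander_uv slow (<= 0.3 Hz) baseline-wander amplitude in microvolts
#'   (default 50).
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration = 300, fs = 1000,
                         rr_baseline = 1000, rr_step = 650,
                         step_time = duration / 2, rr_jitter = 20,
                         heart_axis = 42, t_axis = 26,
                         qt_true = 400, qt_adapt = c("fixed", "bazett"),
                         morphology = c("monophasic", "broad", "notched",
                                        "biphasic", "low_amplitude"),
                         noise_uv = 10, mains_uv = 10, wander_uv = 50,
                         seed = 1) {
  qt_adapt <- match.arg(qt_adapt)
  morphology <- match.arg(morphology)
  if (fs < 250) stop("fs must be at least 250 Hz")
  if (duration <= 0) stop("duration must be positive")
  if (rr_baseline < 300 || rr_step < 300) stop("RR levels must be >= 300 ms")
  min_rr <- min(rr_baseline, rr_step)
  qt_max <- if (qt_adapt == "bazett") qt_true * sqrt(min_rr / 1000)
            else qt_true
  if (qt_max >= min_rr - 100)
    stop(sprintf("infeasible QT: %g ms leaves no room within RR %g ms",
                 qt_max, min_rr))
  structure(list(duration = duration, fs = fs, rr_baseline = rr_baseline,
                 rr_step = rr_step, step_time = step_time,
                 rr_jitter = rr_jitter, heart_axis = heart_axis,
                 t_axis = t_axis, qt_true = qt_true, qt_adapt = qt_adapt,
                 morphology = morphology, noise_uv = noise_uv,
                 mains_uv = mains_uv, wander_uv = wander_uv, seed = seed),
            class = "synth_config")
}

#' RR profile with a step change
#'
#' RR intervals at the baseline level before `step_time`, relaxing
#' exponentially (5 s time constant, the pace of a heart-rate response to
#' brisk standing) to the step level after it, with seeded Gaussian jitter
#' (clamped at 300 ms). Beats are placed until the record end, leaving room
#' for the last T wave.
#'
#' @param config a [synth_config].
#' @return numeric vector of RR intervals in ms; attribute `r_times` holds
#'   the R-peak times in seconds (first R at 0.5 s).
#' @export
rr_step_profile <- function(config) {
  with_seed(config$seed, {
    t <- 0.5
    r_times <- t
    rr <- numeric(0L)
    margin <- 0.7   # room for the last T wave
    tau <- 5        # s, rate-adaptation time constant after the step
    repeat {
      level <- if (t < config$step_time) config$rr_baseline
      else config$rr_step + (config$rr_baseline - config$rr_step) *
        exp(-(t - config$step_time) / tau)
      step <- max(level + stats::rnorm(1L, 0, config$rr_jitter), 300)
      if (t + step / 1000 > config$duration - margin) break
      t <- t + step / 1000
      r_times <- c(r_times, t)
      rr <- c(rr, step)
    }
    structure(rr, r_times = r_times)
  })
}

# --- fixed dipole-to-lead geometry ------------------------------------------
# Frontal plane: x toward the patient's left, y toward the feet (so a
# positive axis angle points inferior-leftward, the clinical convention);
# z anterior. Limb electrodes sum to zero so the Wilson terminal vanishes
# and Einthoven / Goldberger relations hold exactly by construction.
synth_geometry <- function() {
  vI <- c(1, 0, 0)
  vII <- c(cos(pi / 3), sin(pi / 3), 0)
  eR <- -(vI + vII) / 3
  eL <- eR + vI
  eF <- eR + vII
  prec <- rbind(V1 = c(-0.40, 0.00, 0.90),
                V2 = c(-0.10, 0.10, 1.00),
                V3 = c( 0.30, 0.20, 0.90),
                V4 = c( 0.60, 0.30, 0.70),
                V5 = c( 0.90, 0.30, 0.40),
                V6 = c( 1.00, 0.20, 0.00))
  lead_vec <- rbind(I = vI, II = vII, III = vII - vI,
                    aVR = 1.5 * eR, aVL = 1.5 * eL, aVF = 1.5 * eF,
                    prec)
  list(lead_vec = lead_vec, electrodes = rbind(R = eR, L = eL, F = eF))
}

# Unit direction for a frontal-plane axis angle (degrees) with an anterior
# (z) component.
axis_unit <- function(angle_deg, z) {
  a <- angle_deg * pi / 180
  v <- c(sqrt(1 - z^2) * cos(a), sqrt(1 - z^2) * sin(a), z)
  v / sqrt(sum(v^2))
}

# T-wave preset: bumps with centers relative to the terminal bump's center,
# right-half widths (s, seconds) and relative amplitudes. The terminal bump
# (offset 0) defines the analytic tangent truth t_end = mu + 2 * s_right.
t_preset <- function(morphology) {
  switch(morphology,
    monophasic = list(offset = 0, s = 0.080, rel = 1.0),
    broad = list(offset = 0, s = 0.090, rel = 1.0),
    notched = list(offset = c(-0.110, 0), s = c(0.045, 0.045),
                   rel = c(0.85, 1.0)),
    biphasic = list(offset = c(-0.130, 0), s = c(0.045, 0.050),
                    rel = c(-0.5, 1.0)),
    low_amplitude = list(offset = 0, s = 0.080, rel = 1.0))
}

# Raised-cosine bump: amp * cos^2(pi (t - mu) / (2 w)) on the compact
# support [mu - w, mu + w], exactly zero outside. Used for P and QRS so the
# PQ segment is truly isoelectric; the second derivative is maximal at the
# support edges, which makes the QRS-onset ground truth analytic (r - w).
add_cos2_bump <- function(x, t, mu, w, amp) {
  lo <- findInterval(mu - w, t) + 1L
  hi <- findInterval(mu + w, t)
  if (lo > hi) return(x)
  tt <- t[lo:hi]
  x[lo:hi] <- x[lo:hi] + amp * cos(pi * (tt - mu) / (2 * w))^2
  x
}

# Bi-Gaussian bump: unit peak at mu, left/right standard widths sl/sr. The
# right (terminal) limb is exactly Gaussian, so its steepest-descent tangent
# crosses zero at mu + 2 * sr.
add_bump <- function(x, t, mu, sl, sr, amp) {
  lo <- findInterval(mu - 6 * sl, t) + 1L
  hi <- findInterval(mu + 6 * sr, t)
  if (lo > hi) return(x)
  tt <- t[lo:hi]
  s <- ifelse(tt < mu, sl, sr)
  x[lo:hi] <- x[lo:hi] + amp * exp(-((tt - mu) / s)^2 / 2)
  x
}

#' Generate a synthetic 12-lead ECG with ground-truth fiducials
#'
#' Builds every beat from parametric bumps (raised-cosine P and QRS with
#' compact support, so the PQ segment is exactly isoelectric; bi-Gaussian T
#' per morphology preset) on a three-dimensional dipole whose orientation
#' encodes the heart and T axes, projects it to the 12 standard leads
#' through a fixed electrode geometry, and adds seeded noise, 50 Hz
#' interference and baseline wander at the electrode level (so Einthoven's
#' identity II = I + III holds exactly). Ground truth per beat is computed
#' analytically: the QRS onset is the left support edge of the R bump, where
#' its second derivative peaks (`r - 40` ms), and the T end is the
#' tangent-line intercept of the terminal T bump (`mu_T + 2 * s_T`).
#'
#' @param config a [synth_config].
#' @return list with `record` (an [ecg_record]) and `truth` (data frame with
#'   per-beat `beat`, `r_ms`, `qrs_onset_ms`, `t_end_ms`, `qt_ms`,
#'   `rr_prev_ms`; attribute `t_amp_lead` holds the per-lead terminal T-bump
#'   peak amplitudes in microvolts).
#' @export
synth_ecg <- function(config) {
  fs <- config$fs
  rr <- rr_step_profile(config)
  r_times <- attr(rr, "r_times")
  nb <- length(r_times)
  n <- round(config$duration * fs)
  t <- (0:(n - 1)) / fs
  geom <- synth_geometry()
  lv <- geom$lead_vec

  w_R <- 0.040   # QRS half-width: support [r - 40 ms, r + 40 ms]
  u_p <- axis_unit(50, 0.15)
  u_qrs <- axis_unit(config$heart_axis, 0.30)
  u_t <- if (config$morphology == "low_amplitude")
    axis_unit(config$t_axis, sqrt(1 - 0.08^2))  # nearly anterior T axis
  else axis_unit(config$t_axis, 0.20)

  rr_prev <- c(config$rr_baseline, rr)
  qt <- if (config$qt_adapt == "bazett")
    config$qt_true * sqrt(rr_prev / 1000) else rep(config$qt_true, nb)
  onset <- r_times - w_R
  t_end <- onset + qt / 1000

  preset <- t_preset(config$morphology)
  term <- length(preset$offset)
  mu_term <- t_end - 2 * preset$s[term]

  # dipole time course along each wave axis, one scalar trace per axis
  trace_p <- numeric(n); trace_qrs <- numeric(n); trace_t <- numeric(n)
  A_P <- 120; A_QRS <- 1000; A_S <- -180; A_T <- 400
  for (k in seq_len(nb)) {
    trace_p <- add_cos2_bump(trace_p, t, r_times[k] - 0.160, 0.045, A_P)
    trace_qrs <- add_cos2_bump(trace_qrs, t, r_times[k], w_R, A_QRS)
    trace_qrs <- add_cos2_bump(trace_qrs, t, r_times[k] + 0.030, 0.015, A_S)
    for (j in seq_along(preset$offset)) {
      mu <- mu_term[k] + preset$offset[j]
      sr <- preset$s[j]
      # cap the left width so the T upstroke stays clear of the PQ baseline
      # window of its own beat
      sl <- max(min(sr, (mu - onset[k] - 0.070) / 2.5), 0.020)
      trace_t <- add_bump(trace_t, t, mu, sl, sr, A_T * preset$rel[j])
    }
  }

  proj <- function(u) as.numeric(lv %*% u)
  leads <- outer(trace_p, proj(u_p)) + outer(trace_qrs, proj(u_qrs)) +
    outer(trace_t, proj(u_t))
  colnames(leads) <- rownames(lv)

  leads <- leads + with_seed(config$seed + 1L,
                             synth_artifacts(n, fs, config))

  truth <- data.frame(beat = seq_len(nb),
                      r_ms = r_times * 1000,
                      qrs_onset_ms = onset * 1000,
                      t_end_ms = t_end * 1000,
                      qt_ms = qt,
                      rr_prev_ms = c(NA_real_, rr))
  attr(truth, "t_amp_lead") <- stats::setNames(
    A_T * preset$rel[term] * proj(u_t), rownames(lv))
  list(record = ecg_record(leads, fs = fs), truth = truth)
}

# Electrode-level artifacts projected to the 12 leads: broadband noise,
# 50 Hz interference and slow baseline wander. Limb-lead artifacts are
# differences of electrode artifacts, so Einthoven's identity is preserved.
synth_artifacts <- function(n, fs, config) {
  t <- (0:(n - 1)) / fs
  one_electrode <- function() {
    x <- numeric(n)
    if (config$noise_uv > 0)
      x <- x + stats::rnorm(n, 0, config$noise_uv / sqrt(2))
    if (config$mains_uv > 0)
      x <- x + config$mains_uv * sin(2 * pi * 50 * t +
                                       stats::runif(1L, 0, 2 * pi))
    if (config$wander_uv > 0) {
      for (a in c(1, 0.5, 0.3)) {
        f <- stats::runif(1L, 0.05, 0.3)
        x <- x + a * config$wander_uv * sin(2 * pi * f * t +
                                              stats::runif(1L, 0, 2 * pi))
      }
    }
    x
  }
  eR <- one_electrode(); eL <- one_electrode(); eF <- one_electrode()
  wct <- (eR + eL + eF) / 3
  prec <- vapply(1:6, function(i) one_electrode() - wct, numeric(n))
  out <- cbind(I = eL - eR, II = eF - eR, III = eF - eL,
               aVR = eR - (eL + eF) / 2, aVL = eL - (eR + eF) / 2,
               aVF = eF - (eR + eL) / 2, prec)
  colnames(out) <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  out
}
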