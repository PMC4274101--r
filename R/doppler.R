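#' Generate a synthetic Doppler velocity-envelope trace
#'
#' Pulsatile maximum-velocity envelope: each cardiac cycle rises from the
#' end-diastolic velocity through a smooth early-systolic pulse to the
#' peak and decays back to end diastole.  A slow multiplicative breathing
#' modulation (one breath per ~10 beats) and additive Gaussian noise can
#' be applied.  Per-beat ground-truth metrics (systolic peak,
#' end-diastolic velocity, cycle mean) are stored.
#'
#' @param heart_rate_hz Heart rate in beats/s (default 7, mouse under
#'   anaesthesia).
#' @param peak_v Systolic peak velocity, cm/s.
#' @param edv_v End-diastolic velocity, cm/s (>= 0, < `peak_v`).
#' @param n_beats Number of beats (>= 1; downstream analysis requires
#'   10).
#' @param breathing_mod Fractional amplitude of the breathing modulation
#'   (one cycle per `beats_per_breath` beats).
#' @param beats_per_breath Beats per breathing cycle (default 10).
#' @param noise Additive Gaussian noise SD, cm/s (default 0.2;
#'   auto-traced envelopes are smooth).
#' @param sample_rate Samples per second (must give >= 20 samples per
#'   beat).
#' @param pulse_decay Dimensionless diastolic decay rate of the systolic
#'   pulse shape (default 3); larger values give a shorter systole and a
#'   lower cycle mean relative to the peak.
#' @param seed Integer seed.
#' @return List with `trace` (class `doppler_trace`: data.frame `t_s`,
#'   `v_cm_s`, attribute `sample_rate`) and `truth` (per-beat boundary
#'   indices and metrics, plus their across-beat means).
#' @export
gen_doppler_trace <- function(heart_rate_hz = 7, peak_v = 45, edv_v = 8,
                              n_beats = 12, breathing_mod = 0.1,
                              beats_per_breath = 10, noise = 0.2,
                              sample_rate = 1000, pulse_decay = 3,
                              seed = 1) {
  stopifnot(heart_rate_hz > 0, n_beats >= 1, noise >= 0,
            breathing_mod >= 0, breathing_mod < 1, pulse_decay > 0)
  if (!(peak_v > edv_v && edv_v >= 0))
    stop("gen_doppler_trace: require peak_v > edv_v >= 0")
  if (sample_rate < 20 * heart_rate_hz)
    stop("gen_doppler_trace: sample rate too low to resolve beats ",
         "(< 20 samples/beat)")
  period <- 1 / heart_rate_hz
  n_per_beat <- round(sample_rate * period)
  n <- n_per_beat * n_beats
  t <- (seq_len(n) - 1) / sample_rate
  # beats laid out on the sample grid so that stored beat boundaries
  # coincide exactly with the envelope minima; the effective rate is
  # sample_rate / n_per_beat (within rounding of the requested rate)
  phase <- ((seq_len(n) - 1) %% n_per_beat) / n_per_beat
  rate_eff <- sample_rate / n_per_beat

  # smooth systolic pulse with a unique per-cycle minimum at phase 0:
  # sin^2 envelope skewed toward early systole by an exponential decay
  pulse_shape <- function(ph) sin(pi * ph)^2 * exp(-pulse_decay * ph)
  pulse <- pulse_shape(phase)
  pulse <- pulse / max(pulse)   # normalized on the sample grid, so the
                                # per-beat sampled peak is exactly peak_v
  v <- edv_v + (peak_v - edv_v) * pulse
  if (breathing_mod > 0) {
    breath <- 1 + breathing_mod *
      sin(2 * pi * t * rate_eff / beats_per_breath)
    v <- v * breath
  }
  v_clean <- v
  trace_v <- with_seed(seed, {
    if (noise > 0) v <- v + stats::rnorm(n, 0, noise)
    pmax(v, 0)
  })

  starts <- (seq_len(n_beats) - 1) * n_per_beat + 1
  ends <- starts + n_per_beat - 1
  beats <- data.frame(
    start = starts, end = ends,
    peak_v = vapply(seq_len(n_beats),
                    function(i) max(v_clean[starts[i]:ends[i]]), 0),
    edv = v_clean[starts],
    cycle_mean = vapply(seq_len(n_beats),
                        function(i) mean(v_clean[starts[i]:ends[i]]), 0))
  trace <- structure(data.frame(t_s = t, v_cm_s = trace_v),
                     sample_rate = sample_rate,
                     class = c("doppler_trace", "data.frame"))
  truth <- list(beats = beats,
                mean_metrics = c(peak_v = mean(beats$peak_v),
                                 edv = mean(beats$edv),
                                 cycle_mean = mean(beats$cycle_mean)),
                heart_rate_hz = rate_eff, seed = seed)
  list(trace = trace, truth = truth)
}

#' Construct a clean envelope matching given peak, EDV and cycle mean
#'
#' Solves for the diastolic decay of the pulse shape so that the
#' generated noise-free envelope has exactly the requested per-beat
#' systolic peak, end-diastolic velocity and (to solver tolerance) cycle
#' mean.  Useful for reconstructing envelopes from published per-beat
#' velocity tables.
#'
#' @param peak_v,edv_v,cycle_mean_v Target velocities, cm/s
#'   (`edv_v < cycle_mean_v < peak_v`).
#' @param ... Further arguments to [gen_doppler_trace()] (e.g.
#'   `n_beats`, `heart_rate_hz`).
#' @return As [gen_doppler_trace()].
#' @export
doppler_trace_from_metrics <- function(peak_v, edv_v, cycle_mean_v, ...) {
  if (!(edv_v < cycle_mean_v && cycle_mean_v < peak_v))
    stop("doppler_trace_from_metrics: need edv < cycle mean < peak")
  target <- (cycle_mean_v - edv_v) / (peak_v - edv_v)
  mp <- function(k) {
    ph <- (seq_len(2000) - 0.5) / 2000
    p <- sin(pi * ph)^2 * exp(-k * ph)
    mean(p) / max(p)
  }
  if (target >= mp(0.01) || target <= mp(60))
    stop("doppler_trace_from_metrics: cycle mean outside the ",
         "representable pulse-shape range")
  k <- stats::uniroot(function(k) mp(k) - target, c(0.01, 60),
                      tol = 1e-10)$root
  gen_doppler_trace(peak_v = peak_v, edv_v = edv_v, noise = 0,
                    breathing_mod = 0, pulse_decay = k, ...)
}

#' Segment a Doppler envelope into beats
#'
#' Detects end-diastolic minima on a low-pass-filtered envelope, with a
#' minimum separation of 0.6 cycle at the expected heart rate, and
#' returns the boundary sample indices.  Beats are the contiguous,
#' non-overlapping intervals between successive boundaries.
#'
#' @param trace A `doppler_trace` (data.frame `t_s`, `v_cm_s` with
#'   `sample_rate` attribute) or any uniformly sampled data.frame of the
#'   same shape.
#' @param expected_rate_hz Approximate heart rate, beats/s.
#' @return Integer vector of boundary indices (end-diastolic minima).
#' @export
segment_beats <- function(trace, expected_rate_hz) {
  stopifnot(expected_rate_hz > 0)
  v <- trace$v_cm_s
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) sr <- 1 / stats::median(diff(trace$t_s))
  n <- length(v)
  if (n < 2 * sr / expected_rate_hz)
    stop("segment_beats: trace shorter than 2 beats at the expected rate")
  if (stats::sd(v) < 1e-12 * max(abs(v), 1))
    stop("segment_beats: no detectable periodicity (flat trace)")
  # low-pass: moving average over ~10% of a cycle
  w <- max(3L, round(0.1 * sr / expected_rate_hz))
  if (w %% 2 == 0) w <- w + 1L
  f <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  half <- (w - 1L) / 2L
  f[seq_len(half)] <- f[half + 1L]
  f[(n - half + 1L):n] <- f[n - half]
  min_sep <- round(0.6 * sr / expected_rate_hz)
  # local minima of the filtered envelope
  cand <- which(diff(sign(diff(f))) > 0) + 1L
  if (!length(cand))
    stop("segment_beats: no detectable periodicity")
  ord <- cand[order(f[cand])]
  keep <- integer(0)
  for (i in ord)
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  boundaries <- sort(keep)
  if (length(boundaries) < 2)
    stop("segment_beats: fewer than two end-diastolic minima found")
  # snap each boundary to the unfiltered minimum nearby
  snap <- max(1L, as.integer(round(0.05 * sr / expected_rate_hz)))
  vapply(boundaries, function(b) {
    lo <- max(1L, as.integer(b) - snap)
    hi <- min(n, as.integer(b) + snap)
    lo + which.min(v[lo:hi]) - 1L
  }, integer(1))
}

#' Per-beat and averaged Doppler metrics
#'
#' For each beat (interval between successive end-diastolic boundaries):
#' the systolic peak (maximum of the envelope), the end-diastolic
#' velocity (envelope value at the beat's starting boundary) and the
#' cycle-averaged maximum velocity (time average over the beat).  The
#' three metrics are then averaged over the first `n_beats` contiguous
#' beats.
#'
#' @param trace A `doppler_trace`.
#' @param boundaries Boundary indices from [segment_beats()].
#' @param n_beats Number of contiguous beats to average (default 10).
#' @param denoise Read the end-diastolic velocity from a 5-sample
#'   running-median version of the envelope (default `TRUE`); the
#'   systolic peak and cycle mean always come from the raw envelope.
#'   Reading a pointwise minimum from a noisy envelope is biased low;
#'   the running median removes that bias while leaving clean envelopes
#'   essentially unchanged.
#' @return List with `per_beat` (data.frame) and `averages` (named
#'   vector `peak_v`, `edv`, `cycle_mean`).
#' @export
beat_metrics <- function(trace, boundaries, n_beats = 10,
                         denoise = TRUE) {
  v <- trace$v_cm_s
  vm <- if (denoise && length(v) >= 5)
    as.numeric(stats::runmed(v, 5, endrule = "median")) else v
  n_avail <- length(boundaries) - 1L
  if (n_avail < n_beats)
    stop(sprintf(
      "beat_metrics: insufficient beats (%d complete, %d required)",
      n_avail, n_beats))
  per <- lapply(seq_len(n_avail), function(i) {
    a <- boundaries[i]; b <- boundaries[i + 1L] - 1L
    seg <- v[a:b]
    data.frame(beat = i, peak_v = max(seg), edv = vm[a],
               cycle_mean = mean(seg))
  })
  per <- do.call(rbind, per)
  use <- per[seq_len(n_beats), ]
  list(per_beat = per,
       averages = c(peak_v = mean(use$peak_v), edv = mean(use$edv),
                    cycle_mean = mean(use$cycle_mean)))
}

#' Insonation-angle correction of Doppler velocities
#'
#' The instrument measures the velocity component along the beam; the
#' flow-axis velocity is `v_beam / cos(theta)`.
#'
#' @param v_beam Measured velocity.
#' @param theta_deg Insonation angle in degrees, `0 <= theta < 90`.
#' @return Corrected velocity.
#' @export
angle_correct <- function(v_beam, theta_deg) {
  if (any(theta_deg < 0) || any(theta_deg >= 90))
    stop("angle_correct: angle must be in [0, 90) degrees")
  v_beam / cos(theta_deg * pi / 180)
}
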