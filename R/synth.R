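#' Motion classes recognised by the pipeline
#'
#' The six hand and wrist motions: hand close (HC), hand open (HO), wrist
#' pronation (WP), wrist supination (WS), wrist extension (WE) and wrist
#' flexion (WF).
#'
#' @return Character vector of the six class identifiers.
#' @export
motion_classes <- function() c("HC", "HO", "WP", "WS", "WE", "WF")

#' Default per-class motion templates
#'
#' Builds one stress-trajectory template per motion class. Each template
#' carries a per-channel signed plateau amplitude (the stress level reached
#' and held mid-motion, arbitrary pressure units) plus rise, hold and fall
#' durations. Plateau vectors are drawn once from `seed` and scaled by
#' `separability`, so classes differ in both sign and magnitude across
#' channels, pairwise plateau distances scale exactly linearly with
#' `separability`, and `separability = 0` collapses all classes onto the
#' same (zero) template.
#'
#' @param n_channels Number of sensor channels (default 8).
#' @param separability Non-negative scalar multiplying between-class
#'   template differences. 0 makes all classes identical (chance-level
#'   control); 1 is the default well-separated regime.
#' @param seed Integer seed for the plateau pattern draw.
#' @return List of `rsc_template` objects, one per motion class.
#' @export
#' @examples
#' tpl <- motion_templates(n_channels = 8, separability = 1, seed = 1)
#' tpl[[1]]$class_id
motion_templates <- function(n_channels = 8, separability = 1, seed = 1) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 1)
    stop("`n_channels` must be a single count >= 1", call. = FALSE)
  if (!is.numeric(separability) || length(separability) != 1 || separability < 0)
    stop("`separability` must be a single scalar >= 0", call. = FALSE)
  classes <- motion_classes()
  # class- and channel-specific signed offsets, fixed by the seed
  delta <- with_local_seed(seed, function() {
    signs <- matrix(sample(c(-1, 1), length(classes) * n_channels,
                           replace = TRUE),
                    nrow = length(classes))
    mags <- matrix(runif(length(classes) * n_channels, 0.4, 1.6),
                   nrow = length(classes))
    signs * mags
  })
  lapply(seq_along(classes), function(k) {
    structure(
      list(class_id   = classes[k],
           plateau    = separability * delta[k, ],
           # protocol: perform the motion within the epoch *without holding
           # the contraction*, so the hold is brief and the dynamic ramps
           # carry most of the epoch
           rise_time_s = 0.70,
           hold_time_s = 0.25,
           fall_time_s = 0.70),
      class = "rsc_template")
  })
}

#' Synthetic session configuration
#'
#' Bundles every parameter of the synthetic recording protocol: 6 motion
#' classes, 30 repetitions each, 2-s motion epochs sampled at 100 Hz on
#' 8 channels, matching the acquisition protocol the pipeline targets.
#'
#' @param n_channels Sensor channel count.
#' @param classes List of templates from [motion_templates()]; built from
#'   `separability` and `seed` when `NULL`.
#' @param n_repetitions Repetitions per class (>= 4 so fourfold
#'   cross-validation is possible).
#' @param fs_hz Sampling rate in Hz.
#' @param epoch_s Motion epoch duration in seconds; the motion (rise, hold,
#'   fall) completes within the epoch.
#' @param sensor_noise_sd Standard deviation of additive i.i.d. Gaussian
#'   sensor noise, in the same arbitrary units as the RSC samples.
#' @param separability Between-class template scaling, see
#'   [motion_templates()].
#' @param duration_jitter Half-width of the per-repetition multiplicative
#'   jitter applied to rise/hold/fall durations (0.1 = +/-10%), so windows
#'   are not trivially time-aligned across repetitions.
#' @param seed Integer seed controlling the whole session.
#' @return An `rsc_session_config` list.
#' @export
session_config <- function(n_channels = 8, classes = NULL, n_repetitions = 30,
                           fs_hz = 100, epoch_s = 2, sensor_noise_sd = 0.02,
                           separability = 1, duration_jitter = 0.1, seed = 1) {
  if (fs_hz <= 0) stop("`fs_hz` must be > 0", call. = FALSE)
  if (n_repetitions < 4)
    stop("`n_repetitions` must be >= 4 (fourfold CV must be possible)",
         call. = FALSE)
  if (separability < 0) stop("`separability` must be >= 0", call. = FALSE)
  if (sensor_noise_sd < 0) stop("`sensor_noise_sd` must be >= 0", call. = FALSE)
  if (duration_jitter < 0 || duration_jitter >= 1)
    stop("`duration_jitter` must be in [0, 1)", call. = FALSE)
  if (is.null(classes))
    classes <- motion_templates(n_channels, separability, seed)
  for (tpl in classes) validate_template(tpl, n_channels, epoch_s,
                                         duration_jitter)
  structure(
    list(n_channels = as.integer(n_channels), classes = classes,
         n_repetitions = as.integer(n_repetitions), fs_hz = fs_hz,
         epoch_s = epoch_s, sensor_noise_sd = sensor_noise_sd,
         separability = separability, duration_jitter = duration_jitter,
         seed = as.integer(seed)),
    class = "rsc_session_config")
}

validate_template <- function(tpl, n_channels, epoch_s, duration_jitter = 0) {
  if (!inherits(tpl, "rsc_template")) stop("not an rsc_template", call. = FALSE)
  if (length(tpl$plateau) != n_channels)
    stop("template `", tpl$class_id, "`: plateau must have ", n_channels,
         " entries", call. = FALSE)
  dur <- c(tpl$rise_time_s, tpl$hold_time_s, tpl$fall_time_s)
  if (any(dur <= 0))
    stop("template `", tpl$class_id,
         "`: rise/hold/fall durations must be > 0", call. = FALSE)
  # worst-case jittered motion must still fit in the epoch
  if (sum(dur) * (1 + duration_jitter) > epoch_s)
    stop("template `", tpl$class_id,
         "`: rise + hold + fall exceeds the epoch", call. = FALSE)
  invisible(tpl)
}

# Piecewise raised-cosine stress trajectory, 0 -> plateau -> 0.
# Vectorised over t; cospi() keeps segment endpoints exact.
stress_trajectory <- function(t, plateau, rise, hold, fall) {
  s <- numeric(length(t))
  in_rise <- t > 0 & t < rise
  s[in_rise] <- plateau / 2 * (1 - cospi(t[in_rise] / rise))
  in_hold <- t >= rise & t <= rise + hold
  s[in_hold] <- plateau
  in_fall <- t > rise + hold & t < rise + hold + fall
  s[in_fall] <- plateau / 2 * (1 + cospi((t[in_fall] - rise - hold) / fall))
  s
}

#' Simulate one repetition of one motion
#'
#' Constructs, per channel, a smooth raised-cosine stress trajectory
#' (ramp 0 to plateau over the rise time, constant over the hold, ramp back
#' over the fall, zero afterwards) and emits the RSC signal as its sampled
#' derivative: the scaled first difference of the stress samples. The
#' discrete derivative makes the defining piezoelectret properties exact:
#' samples inside the hold segment are identically zero, and the epoch
#' integral of each channel telescopes to stress(end) - stress(0) = 0.
#' Additive i.i.d. Gaussian sensor noise (sd `cfg$sensor_noise_sd`) is
#' drawn from the current RNG stream, as is the per-repetition duration
#' jitter; [simulate_session()] seeds that stream once per session.
#'
#' @param template An `rsc_template`.
#' @param cfg An `rsc_session_config` consistent with the template.
#' @param rep_index 1-based repetition ordinal recorded in the output.
#' @return An `rsc_recording`: a `samples` matrix (rows = time samples,
#'   columns = channels), sampling rate, class label, repetition index and
#'   channel ids.
#' @export
simulate_repetition <- function(template, cfg, rep_index = 1L) {
  validate_template(template, cfg$n_channels, cfg$epoch_s,
                    cfg$duration_jitter)
  n <- round(cfg$epoch_s * cfg$fs_hz)
  j <- cfg$duration_jitter
  jit <- if (j > 0) runif(3, 1 - j, 1 + j) else rep(1, 3)
  rise <- template$rise_time_s * jit[1]
  hold <- template$hold_time_s * jit[2]
  fall <- template$fall_time_s * jit[3]
  t <- seq_len(n) / cfg$fs_hz
  samples <- matrix(0, nrow = n, ncol = cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    s <- stress_trajectory(t, template$plateau[ch], rise, hold, fall)
    # discrete derivative; s(0) = 0 by construction
    samples[, ch] <- diff(c(0, s)) * cfg$fs_hz
  }
  if (cfg$sensor_noise_sd > 0)
    samples <- samples + matrix(rnorm(n * cfg$n_channels,
                                      sd = cfg$sensor_noise_sd),
                                nrow = n)
  new_recording(samples, cfg$fs_hz, template$class_id, rep_index)
}

#' Simulate a full labelled session
#'
#' Generates `n_repetitions` recordings for each motion class in
#' `cfg$classes`, deterministically given `cfg$seed`.
#'
#' @param cfg An `rsc_session_config`.
#' @return List of `rsc_recording` objects (class-major order), with the
#'   configuration attached as attribute `config`.
#' @export
#' @examples
#' session <- simulate_session(session_config(n_repetitions = 4, seed = 1))
#' length(session)  # 6 classes x 4 repetitions
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "rsc_session_config"))
  recs <- with_local_seed(cfg$seed, function() {
    out <- vector("list", length(cfg$classes) * cfg$n_repetitions)
    i <- 0L
    for (tpl in cfg$classes) {
      for (r in seq_len(cfg$n_repetitions)) {
        i <- i + 1L
        out[[i]] <- simulate_repetition(tpl, cfg, r)
      }
    }
    out
  })
  attr(recs, "config") <- cfg
  recs
}

#' @export
print.rsc_template <- function(x, ...) {
  cat("Motion template", x$class_id, "\n")
  cat("  plateau   :", paste(signif(x$plateau, 3), collapse = " "), "\n")
  cat(sprintf("  durations : rise %.2f s, hold %.2f s, fall %.2f s\n",
              x$rise_time_s, x$hold_time_s, x$fall_time_s))
  invisible(x)
}

#' @export
print.rsc_session_config <- function(x, ...) {
  cat("RSC session configuration\n")
  cat(sprintf("  %d classes x %d repetitions, %d channels\n",
              length(x$classes), x$n_repetitions, x$n_channels))
  cat(sprintf("  fs = %g Hz, epoch = %g s, sensor noise sd = %g\n",
              x$fs_hz, x$epoch_s, x$sensor_noise_sd))
  cat(sprintf("  separability = %g, duration jitter = +/-%g%%, seed = %d\n",
              x$separability, 100 * x$duration_jitter, x$seed))
  invisible(x)
}
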