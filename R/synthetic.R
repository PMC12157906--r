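#' @include AllClasses.R
NULL

# stride waveform, a blend of two archetypes controlled by square_mix:
# (1) square loading profile (smoothed square wave at twice the stride
#     rate, duty-offset toward the low phase) - sustained ground contact
#     with long low-magnitude swings, the fatigued gait proxy;
# (2) impact profile (triangular bulk at 5x stride rate, brief positive
#     impact pulses and free-fall dips at 3x stride rate) - crisp strikes
#     over a moderate bulk, the fresh gait proxy.
# frequencies sit below the 30 Hz low-pass cutoff so the archetype shapes
# survive filtering, and fast enough that every 60-sample segment sees
# several oscillations (stable per-segment statistics).
strideWaveform <- function(theta, p) {
  sq <- tanh((sin(2 * theta) - p$square_duty) / p$square_soft)
  tri <- p$tri_amp * (2 / pi) * asin(sin(5 * theta))
  pulse <- p$pulse_amp * pmax(sin(3 * theta), 0)^4
  dip <- p$dip_amp * pmax(cos(3 * theta), 0)^4
  p$square_mix * sq + (1 - p$square_mix) * (tri + pulse - dip)
}

interpolateParams <- function(spec, label) {
  fat <- spec@fatigue_params
  non <- spec@nonfatigue_params
  mid <- Map(function(a, b) (a + b) / 2, fat, non)
  own <- if (label == .FATIGUE) fat else non
  p <- Map(function(a, m) (1 - spec@overlap) * a + spec@overlap * m, own, mid)
  # overlap also widens the within-class spread of the waveform mix, so the
  # dial moves the classes from cleanly separated (0) through a gray zone of
  # ambiguous instances (0.5) to statistically identical (1)
  p$square_mix <- min(max(
    rnorm(1, p$square_mix, 0.35 * spec@overlap), 0), 1)
  p
}

#' Generate one synthetic magnitude trace
#'
#' One 180-sample acceleration-magnitude instance at 256 Hz:
#' baseline + shaped stride oscillation (fundamental plus third harmonic)
#' + Gaussian noise + linear drift. Class parameter sets are interpolated
#' toward their midpoint by `spec@overlap`, and `user_jitter` applies the
#' per-user multiplicative offsets drawn from the user-level RNG stream.
#' Consumes the current RNG state (callers seed it; see
#' [generateDataset()]).
#'
#' @param spec a [SyntheticSpec-class].
#' @param label class of the trace to generate.
#' @param user_jitter named list of per-user multipliers
#'   (`baseline`, `amp`, `freq`); defaults to no jitter.
#' @param n_samples,fs trace geometry (defaults 180 samples at 256 Hz).
#' @return numeric vector of `n_samples` magnitudes.
#' @export
generateTrace <- function(spec, label, user_jitter = list(baseline = 1,
                                                          amp = 1, freq = 1),
                          n_samples = 180L, fs = 256) {
  label <- canonicalLabel(label)
  p <- interpolateParams(spec, label)
  t <- (seq_len(n_samples) - 1) / fs
  f <- spec@stride_freq_hz * user_jitter$freq * runif(1, 0.9, 1.1)
  theta <- 2 * pi * f * t + runif(1, 0, 2 * pi)
  p$baseline_mean * user_jitter$baseline +
    p$oscillation_amp * user_jitter$amp * strideWaveform(theta, p) +
    rnorm(n_samples, 0, p$noise_sd) +
    p$drift * (t - mean(t))
}

#' Generate a seeded synthetic dataset
#'
#' `n_users x instances_per_user` labeled traces. Two RNG streams keep the
#' data reproducible and composable: a dataset-level stream (seeded by
#' `spec@seed`) assigns per-user sub-seeds, and each user's stream draws
#' that user's jitters, labels and traces — so user u's data do not change
#' when `n_users` grows. Every user is guaranteed at least one instance of
#' each class.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [TraceSet-class] with users `user01`, `user02`, ...
#' @examples
#' ts <- generateDataset(syntheticSpec(n_users = 2, instances_per_user = 10,
#'                                     seed = 7))
#' ncol(ts)  # 20
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  user_seeds <- vapply(seq_len(spec@n_users), function(u)
    deriveSeed(spec@seed, u), integer(1))
  per_user <- lapply(seq_len(spec@n_users), function(u) {
    withSeed(user_seeds[u], {
      jit <- list(baseline = runif(1, 0.92, 1.08),
                  amp = runif(1, 0.85, 1.15),
                  freq = runif(1, 0.92, 1.08))
      m <- spec@instances_per_user
      labels <- ifelse(runif(m) < spec@class_balance, .FATIGUE, .NON_FATIGUE)
      labels[1:2] <- .LABELS   # both classes always present
      mat <- vapply(labels, function(lab)
        generateTrace(spec, lab, user_jitter = jit), numeric(180L))
      list(labels = labels, mat = mat)
    })
  })
  mat <- do.call(cbind, lapply(per_user, `[[`, "mat"))
  labels <- unlist(lapply(per_user, `[[`, "labels"))
  user_id <- rep(sprintf("user%02d", seq_len(spec@n_users)),
                 each = spec@instances_per_user)
  instance_id <- sprintf("%s_i%03d", user_id,
                         sequence(rep(spec@instances_per_user,
                                      spec@n_users)))
  traceSet(mat, user_id = user_id, instance_id = instance_id,
           label = labels, fs = 256)
}
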