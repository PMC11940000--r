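# Evaluate `code` under set.seed(seed), restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic sEMG dataset generator
#'
#' The generator emulates the statistical structure of a 30-subject
#' activities-of-daily-living reaching dataset: class-conditional context
#' distributions, class- and context-modulated EMG envelopes, per-subject gain
#' variability, and the artifacts (leading nulls, fully null recordings,
#' "free"-grasp and non-reaching records) that the curation stage must handle.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param recordings_per_subject List describing the per-subject recording
#'   count distribution: `list(type = "poisson", mean = 150)` or
#'   `list(type = "constant", n = 3)`. Poisson counts (floored at 1) give the
#'   uneven per-subject totals that drive the subject-ranking split.
#' @param p_cylindrical Prevalence of the cylindrical class (default 0.42).
#' @param sampling_rate_hz Sampling frequency in Hz (default 1000).
#' @param length_distribution Log-normal recording-length spec,
#'   `list(meanlog, sdlog, min, max)` in frames, truncated to `[min, max]`.
#'   The default (`meanlog = 7.2613`, `sdlog = 0.5`, bounds 41--6337) places
#'   about 7.8% of clean recordings below the 700-frame curation cutoff.
#' @param p_leading_nulls Fraction of recordings with zeroed leading frames.
#' @param p_all_null Fraction of fully null recordings.
#' @param p_free_grasp Fraction labeled grasp code 9 ("free").
#' @param p_nonreaching Fraction with action code other than 1 (reaching).
#' @param context_strength Scalar in `[0, 1]`: probability that a cylindrical
#'   recording draws its context from the cylindrical-class families rather
#'   than the non-cylindrical ones. 0 makes context class-independent.
#' @param emg_strength Scalar in `[0, 1]` scaling the class-1 EMG amplitude
#'   boost on the flexor-side channels. 0 makes EMG class-independent.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 30,
                         recordings_per_subject = list(type = "poisson", mean = 150),
                         p_cylindrical = 0.42,
                         sampling_rate_hz = 1000,
                         length_distribution = list(meanlog = 7.2613, sdlog = 0.5,
                                                    min = 41, max = 6337),
                         p_leading_nulls = 0.05,
                         p_all_null = 0.01,
                         p_free_grasp = 0.08,
                         p_nonreaching = 0.15,
                         context_strength = 1,
                         emg_strength = 1,
                         seed = 1) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  probs <- c(p_cylindrical = p_cylindrical, p_leading_nulls = p_leading_nulls,
             p_all_null = p_all_null, p_free_grasp = p_free_grasp,
             p_nonreaching = p_nonreaching, context_strength = context_strength,
             emg_strength = emg_strength)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad)) stop("config field(s) outside [0,1]: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ld <- cfg$length_distribution
  if (ld$min < 41 || ld$max > 6337 || ld$min > ld$max) {
    stop("length_distribution bounds must lie within [41, 6337]", call. = FALSE)
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  cfg
}

# Draw one context row given the effective class (1 = cylindrical families).
.draw_context <- function(class_eff) {
  if (class_eff == 1L) {
    span1 <- stats::rnorm(1, 65, 15)
    weight <- min(stats::rexp(1, rate = 1 / 400), 3000)
    th <- sample(1:3, 1, prob = c(0.25, 0.50, 0.25))
  } else {
    span1 <- if (stats::runif(1) < 0.78) stats::rnorm(1, 24, 10) else stats::rnorm(1, 52, 15)
    weight <- min(stats::rexp(1, rate = 1 / 300), 3000)
    th <- sample(1:3, 1, prob = c(0.15, 0.55, 0.30))
  }
  span2 <- if (stats::runif(1) < 0.8) 0 else stats::rnorm(1, 40, 10)
  list(span1 = max(span1, 0), span2 = max(span2, 0), weight = max(weight, 0),
       task_height = th)
}

# Monotonically rising reach envelope: tonic baseline, half-cosine rise over
# the final `rise` frames to 1.
.reach_envelope <- function(L, rise = 500L) {
  rise <- min(rise, L)
  env <- rep(0.15, L)
  t0 <- L - rise + 1L
  s <- seq_len(rise) / rise
  env[t0:L] <- 0.15 + 0.85 * 0.5 * (1 - cos(pi * s))
  env
}

#' Generate a synthetic dataset bundle
#'
#' Deterministic given `config$seed`. The generation model: a Bernoulli class
#' label at the configured prevalence; class-conditional context (main span
#' normal around 65 mm for cylindrical objects versus a small-object-dominated
#' mixture otherwise; secondary span absent for 80% of products; sub-kilogram
#' truncated-exponential weights; class-tilted task-height categories);
#' band-limited (25--500 Hz) noise carriers shaped by a monotonically rising
#' reach envelope, with per-subject and per-trial log-normal channel gains; a
#' span- and weight-dependent amplitude boost on channels 1--3 for cylindrical
#' recordings (the hand presets its opening, loading the finger flexors);
#' and curation-triggering artifacts (leading nulls, fully null recordings,
#' free grasps, non-reaching actions) at the configured rates. Per-subject MVC
#' profiles are the channel-wise maxima of simulated MVC draws and the
#' subject's own raw recordings, so raw amplitudes never exceed their MVC.
#'
#' @param config A [synth_config()].
#' @return A validated [dataset_bundle()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    fs <- config$sampling_rate_hz
    high <- min(500, 0.99 * fs / 2)
    bf <- signal::butter(4, c(25, high) / (fs / 2), type = "pass")
    ld <- config$length_distribution
    u_lo <- stats::plnorm(ld$min, ld$meanlog, ld$sdlog)
    u_hi <- stats::plnorm(ld$max, ld$meanlog, ld$sdlog)

    rps <- config$recordings_per_subject
    n_rec_s <- switch(rps$type,
      poisson = pmax(1L, stats::rpois(config$n_subjects, rps$mean)),
      constant = rep(as.integer(rps$n), config$n_subjects),
      stop("unknown recordings_per_subject type: ", rps$type, call. = FALSE)
    )

    recordings <- vector("list", sum(n_rec_s))
    profiles <- vector("list", config$n_subjects)
    idx <- 0L
    for (s in seq_len(config$n_subjects)) {
      gain_s <- exp(stats::rnorm(7, 0, 0.2))
      mvc_draws <- gain_s * stats::runif(7, 2.5, 4.0)
      rec_max <- rep(0, 7)
      for (r in seq_len(n_rec_s[s])) {
        idx <- idx + 1L
        y <- stats::rbinom(1, 1, config$p_cylindrical)
        is_free <- stats::runif(1) < config$p_free_grasp
        is_nonreach <- stats::runif(1) < config$p_nonreaching
        grasp <- if (is_free) 9L else if (y == 1L) 1L else sample(2:8, 1)
        action <- if (is_nonreach) sample(2:10, 1) else 1L
        class_eff <- if (y == 1L && stats::runif(1) < config$context_strength) 1L else 0L
        ctx <- .draw_context(class_eff)

        L <- as.integer(round(stats::qlnorm(stats::runif(1, u_lo, u_hi),
                                            ld$meanlog, ld$sdlog)))
        L <- max(min(L, ld$max), ld$min)
        env <- .reach_envelope(L)
        boost <- 1
        if (y == 1L) {
          full <- 1.5 * (1 + 0.004 * ctx$span1) * (1 + 0.0003 * ctx$weight)
          boost <- 1 + config$emg_strength * (full - 1)
        }
        amp <- gain_s * exp(stats::rnorm(7, 0, 0.2))
        noise <- matrix(stats::rnorm(7L * L), nrow = 7L)
        carrier <- .iir_mat_cpp(as.numeric(bf$b), as.numeric(bf$a), noise, FALSE)
        ch_boost <- c(rep(boost, 3), rep(1, 4))
        emg <- (amp * ch_boost) * carrier * rep(env, each = 7L)
        if (stats::runif(1) < config$p_all_null) {
          emg[] <- 0
        } else if (stats::runif(1) < config$p_leading_nulls && L > 61L) {
          n0 <- sample(20:min(200L, L - 41L), 1)
          emg[, seq_len(n0)] <- 0
        }
        rec_max <- pmax(rec_max, apply(abs(emg), 1, max))
        recordings[[idx]] <- raw_recording(
          id = sprintf("R%05d", idx), participant = s,
          task = sample(102:180, 1), et = sample(1:614, 1), emg = emg,
          sampling_rate_hz = fs, product_dh = sample(1:105, 1),
          weight_g = ctx$weight, span1_mm = ctx$span1, span2_mm = ctx$span2,
          grasp_dh = grasp, action_dh = action, task_height = ctx$task_height
        )
      }
      profiles[[s]] <- mvc_profile(s, pmax(mvc_draws, rec_max))
    }
    dataset_bundle(recordings, profiles,
                   provenance = sprintf("synthetic seed=%d", config$seed))
  })
}

#' Named synthetic fixtures
#'
#' Presets exercising specific regimes of the pipeline:
#' \describe{
#'   \item{tiny}{3 subjects, 12 recordings; fast unit tests and minimal
#'     1/1/1 subject splits.}
#'   \item{default}{30 subjects, ~4,500 recordings; the emulated full-study
#'     scale.}
#'   \item{separable_context}{`emg_strength = 0`: only context carries class
#'     information; EMG envelopes are statistically identical across classes.}
#'   \item{separable_emg}{`context_strength = 0`: context distributions are
#'     class-independent; only EMG is informative.}
#'   \item{complementary}{both modalities deliberately weakened
#'     (`context_strength = 0.7`, `emg_strength = 0.2`) so each unimodal
#'     model is limited and late fusion of the two is advantageous; ~1,400
#'     recordings (~1,000 surviving curation).}
#' }
#'
#' @param name One of `"tiny"`, `"default"`, `"separable_context"`,
#'   `"separable_emg"`, `"complementary"`.
#' @param seed Optional seed overriding the preset's fixed one.
#' @return A [dataset_bundle()].
#' @export
make_fixture <- function(name, seed = NULL) {
  cfg <- switch(name,
    tiny = synth_config(n_subjects = 3,
                        recordings_per_subject = list(type = "constant", n = 4),
                        p_all_null = 0, p_leading_nulls = 0.2, seed = 101),
    default = synth_config(seed = 42),
    separable_context = synth_config(
      recordings_per_subject = list(type = "poisson", mean = 47),
      emg_strength = 0, seed = 202),
    separable_emg = synth_config(
      recordings_per_subject = list(type = "poisson", mean = 47),
      context_strength = 0, seed = 303),
    complementary = synth_config(
      recordings_per_subject = list(type = "poisson", mean = 47),
      context_strength = 0.7, emg_strength = 0.2, seed = 404),
    stop("unknown fixture name: ", name, call. = FALSE)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  generate_dataset(cfg)
}
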