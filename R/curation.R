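#' Configuration for dataset curation
#'
#' @param action_keep Action code to retain (default 1 = reaching).
#' @param min_length_frames Minimum trimmed length in frames (default 700);
#'   shorter recordings are rejected as `too_short`.
#' @param target_length_frames Standardized length in frames (default 1000).
#' @param context_variables Ordered subset of
#'   `c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT")` used as model context.
#' @param n_test_subjects Subjects assigned to the test split (default 10).
#' @param n_val_subjects Subjects assigned to the validation split (default 4).
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(action_keep = 1L, min_length_frames = 700L,
                            target_length_frames = 1000L,
                            context_variables = c("WEIGHT", "SPAN_1", "SPAN_2",
                                                  "TASK_HEIGHT"),
                            n_test_subjects = 10L, n_val_subjects = 4L) {
  if (!(min_length_frames > 0 && min_length_frames <= target_length_frames)) {
    stop("require 0 < min_length_frames <= target_length_frames", call. = FALSE)
  }
  unknown <- setdiff(context_variables, c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT"))
  if (length(unknown)) stop("unknown context variable(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  structure(as.list(environment()), class = "curation_config")
}

#' Trim leading null frames from a recording
#'
#' Frames that are zero across all 7 channels at the start of a recording
#' (a recording-synchronization lag artifact) are removed. A recording that is
#' null throughout is rejected with reason `"all_null"`; rejection is a tagged
#' outcome, not an error.
#'
#' @param recording A [raw_recording()].
#' @return A list: either `list(recording = <trimmed>, rejected = FALSE)` or
#'   `list(recording = NULL, rejected = TRUE, reason = "all_null")`.
#' @export
trim_leading_nulls <- function(recording) {
  nonnull <- colSums(recording$emg != 0) > 0
  first <- match(TRUE, nonnull)
  if (is.na(first)) {
    return(list(recording = NULL, rejected = TRUE, reason = "all_null"))
  }
  if (first > 1L) {
    recording$emg <- recording$emg[, first:ncol(recording$emg), drop = FALSE]
    recording$datasize <- ncol(recording$emg)
  }
  list(recording = recording, rejected = FALSE)
}

#' Select usable reaching recordings from a bundle
#'
#' Applies the curation filters in their fixed order: leading-null trimming
#' (rejecting fully null recordings), the reaching-action filter, the
#' free-grasp filter, and the minimum-length filter on the trimmed length.
#' Every input recording lands exactly once in either the retained collection
#' or the rejection log.
#'
#' @param bundle A [dataset_bundle()].
#' @param config A [curation_config()].
#' @return A list with `retained` (list of trimmed [raw_recording()]) and
#'   `rejections` (data frame with columns `ID`, `reason`; reasons are
#'   `all_null`, `non_reaching`, `free_grasp`, `too_short`).
#' @export
select_samples <- function(bundle, config = curation_config()) {
  retained <- list()
  rej_id <- character(0)
  rej_reason <- character(0)
  for (rec in bundle$recordings) {
    tr <- trim_leading_nulls(rec)
    if (tr$rejected) {
      rej_id <- c(rej_id, rec$id); rej_reason <- c(rej_reason, "all_null")
      next
    }
    r <- tr$recording
    if (r$action_dh != config$action_keep) {
      rej_id <- c(rej_id, r$id); rej_reason <- c(rej_reason, "non_reaching")
      next
    }
    if (r$grasp_dh == 9L) {
      rej_id <- c(rej_id, r$id); rej_reason <- c(rej_reason, "free_grasp")
      next
    }
    if (r$datasize < config$min_length_frames) {
      rej_id <- c(rej_id, r$id); rej_reason <- c(rej_reason, "too_short")
      next
    }
    retained[[length(retained) + 1L]] <- r
  }
  list(retained = retained,
       rejections = data.frame(ID = rej_id, reason = rej_reason,
                               stringsAsFactors = FALSE))
}

#' Empirical retention curve of recording lengths
#'
#' Returns the function `t -> #(length >= t) / N`, the complement of the
#' length CDF used to pick a minimum-length cutoff. Non-increasing in `t`,
#' equal to 1 at `t = 0`.
#'
#' @param lengths Non-empty numeric vector of frame counts.
#' @return A function mapping a threshold (vectorized) to the retained
#'   fraction.
#' @export
length_cdf <- function(lengths) {
  if (!length(lengths)) stop("empty length collection", call. = FALSE)
  lengths <- as.numeric(lengths)
  n <- length(lengths)
  function(t) vapply(t, function(ti) sum(lengths >= ti) / n, numeric(1))
}

#' Standardize a recording to the target length
#'
#' Recordings longer than the target keep only their last
#' `target_length_frames` frames (the segment capturing the grasp); shorter
#' ones (at or above the minimum) are left-padded with zero frames. Retained
#' frames are never altered. Recordings below the minimum are rejected with
#' reason `too_short`.
#'
#' @param emg Numeric matrix, channels x L.
#' @param config A [curation_config()].
#' @return `list(emg = <channels x target matrix>, rejected = FALSE)` or
#'   `list(emg = NULL, rejected = TRUE, reason = "too_short")`.
#' @export
standardize_length <- function(emg, config = curation_config()) {
  L <- ncol(emg)
  target <- config$target_length_frames
  if (L < config$min_length_frames) {
    return(list(emg = NULL, rejected = TRUE, reason = "too_short"))
  }
  out <- if (L > target) {
    emg[, (L - target + 1L):L, drop = FALSE]
  } else if (L < target) {
    cbind(matrix(0, nrow(emg), target - L), emg)
  } else {
    emg
  }
  list(emg = out, rejected = FALSE)
}

#' Binarize a grasp code
#'
#' Maps grasp code 1 (cylindrical) to 1 and codes 2--8 to 0. Code 9 ("free")
#' must have been removed upstream; seeing it here is a pipeline-ordering bug
#' and raises an error.
#'
#' @param grasp_dh Grasp code in 1--8.
#' @return 1 if cylindrical, else 0.
#' @export
binarize_label <- function(grasp_dh) {
  if (any(grasp_dh == 9L)) {
    stop("grasp code 9 (free) reached binarize_label; free grasps must be filtered upstream",
         call. = FALSE)
  }
  as.integer(grasp_dh == 1L)
}

#' Fit a min-max context scaler on training samples
#'
#' Min and max of each continuous context variable (`WEIGHT`, `SPAN_1`,
#' `SPAN_2`) over the training subjects only; values seen at transform time
#' are mapped affinely to `(x - min) / (max - min)` and are not clipped, so
#' out-of-range test values fall outside `[0, 1]`. A constant variable is
#' mapped to 0 with a warning.
#'
#' @param train_samples List of curated samples (each with `weight_g`,
#'   `span1_mm`, `span2_mm` fields) from training subjects.
#' @return An object of class `context_scaler` with `min` and `max` vectors.
#' @export
fit_context_scaler <- function(train_samples) {
  if (!length(train_samples)) stop("empty training set", call. = FALSE)
  vals <- list(
    WEIGHT = vapply(train_samples, `[[`, numeric(1), "weight_g"),
    SPAN_1 = vapply(train_samples, `[[`, numeric(1), "span1_mm"),
    SPAN_2 = vapply(train_samples, `[[`, numeric(1), "span2_mm")
  )
  mins <- vapply(vals, min, numeric(1))
  maxs <- vapply(vals, max, numeric(1))
  const <- names(vals)[maxs == mins]
  if (length(const)) {
    warning("constant context variable(s) mapped to 0: ",
            paste(const, collapse = ", "), call. = FALSE)
  }
  structure(list(min = mins, max = maxs, levels_task_height = 1:3),
            class = "context_scaler")
}

.scale_one <- function(scaler, var, x) {
  lo <- scaler$min[[var]]; hi <- scaler$max[[var]]
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Encode a sample's context vector
#'
#' Deterministic ordering `[WEIGHT, SPAN_1, SPAN_2, TH_1, TH_2, TH_3]`
#' restricted to `included`; continuous variables min-max scaled by the
#' fitted scaler, task height one-hot over its three categories (the one-hot
#' block sums to 1 when included). Excluding a variable shrinks the vector --
#' exclusion is never implemented by zero-masking, so downstream model input
#' dimensions genuinely change.
#'
#' @param sample A curated sample (fields `weight_g`, `span1_mm`, `span2_mm`,
#'   `task_height`).
#' @param scaler A fitted [fit_context_scaler()] result.
#' @param included Character subset of
#'   `c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT")`.
#' @return Named numeric vector.
#' @export
encode_context <- function(sample, scaler,
                           included = c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT")) {
  unknown <- setdiff(included, c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT"))
  if (length(unknown)) stop("unknown context variable(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  out <- numeric(0)
  if ("WEIGHT" %in% included) {
    out <- c(out, WEIGHT = .scale_one(scaler, "WEIGHT", sample$weight_g))
  }
  if ("SPAN_1" %in% included) {
    out <- c(out, SPAN_1 = .scale_one(scaler, "SPAN_1", sample$span1_mm))
  }
  if ("SPAN_2" %in% included) {
    out <- c(out, SPAN_2 = .scale_one(scaler, "SPAN_2", sample$span2_mm))
  }
  if ("TASK_HEIGHT" %in% included) {
    oh <- as.numeric(scaler$levels_task_height == sample$task_height)
    names(oh) <- paste0("TH_", scaler$levels_task_height)
    out <- c(out, oh)
  }
  out
}

#' Subject-wise split by ascending recording count
#'
#' Subjects are ranked by their retained-recording count, ascending, with ties
#' broken by ascending subject id: the lowest `n_test_subjects` go to test,
#' the next-lowest `n_val_subjects` to validation, and the rest to training.
#' Splits are subject-disjoint by construction.
#'
#' @param participants Integer vector, one entry per retained sample.
#' @param config A [curation_config()].
#' @return An object of class `split_assignment` with `train_subjects`,
#'   `val_subjects`, `test_subjects` and per-split sample index vectors
#'   `train_idx`, `val_idx`, `test_idx`.
#' @export
split_by_subject <- function(participants, config = curation_config()) {
  counts <- table(participants)
  subjects <- as.integer(names(counts))
  n <- as.integer(counts)
  need <- config$n_test_subjects + config$n_val_subjects + 1L
  if (length(subjects) < need) {
    stop(sprintf("need at least %d subjects, got %d", need, length(subjects)),
         call. = FALSE)
  }
  ord <- order(n, subjects)
  ranked <- subjects[ord]
  test_s <- ranked[seq_len(config$n_test_subjects)]
  val_s <- ranked[config$n_test_subjects + seq_len(config$n_val_subjects)]
  train_s <- ranked[-seq_len(config$n_test_subjects + config$n_val_subjects)]
  structure(list(
    train_subjects = sort(train_s), val_subjects = sort(val_s),
    test_subjects = sort(test_s),
    train_idx = which(participants %in% train_s),
    val_idx = which(participants %in% val_s),
    test_idx = which(participants %in% test_s)
  ), class = "split_assignment")
}

#' Curate a bundle end to end
#'
#' Runs the full curation pipeline: leading-null trimming, reaching/free-grasp
#' selection and the minimum-length filter ([select_samples()]); per-subject
#' MVC profiles on the conditioned scale ([compute_mvc_profile()], using all
#' of a subject's retained recordings); the conditioning chain
#' ([preprocess()]); and length standardization ([standardize_length()]).
#' Context is left unencoded here because the min-max scaler must be fitted on
#' training subjects only -- see [prepare_model_inputs()].
#'
#' @param bundle A [dataset_bundle()].
#' @param config A [curation_config()].
#' @param pre_config A [preprocess_config()].
#' @return An object of class `curated_set`: a list with `samples` (each a
#'   list with `id`, `participant`, `emg_fixed` (target_length x 7 matrix,
#'   frames x channels), `label`, `original_length_frames` and the raw context
#'   fields) and `rejections` (the rejection log).
#' @export
curate_bundle <- function(bundle, config = curation_config(),
                          pre_config = preprocess_config()) {
  sel <- select_samples(bundle, config)
  by_subject <- split(sel$retained,
                      vapply(sel$retained, `[[`, integer(1), "participant"))
  samples <- list()
  # the conditioning chain may warn identically for every recording (e.g. the
  # Nyquist band-edge cap); surface each distinct warning once
  seen_warnings <- character(0)
  withCallingHandlers(
  for (grp in by_subject) {
    # condition once per recording; the subject MVC profile is the channel
    # max over these conditioned envelopes (equivalent to running
    # compute_mvc_profile then preprocess, at half the filtering cost)
    envs <- lapply(grp, function(rec) {
      .condition(rec$emg, rec$sampling_rate_hz, pre_config)
    })
    cmax <- Reduce(pmax, lapply(envs, function(e) apply(e, 1, max)))
    if (any(cmax <= 0)) {
      stop("channel(s) ", paste(which(cmax <= 0), collapse = ", "),
           " have zero maximum amplitude; MVC normalization undefined",
           call. = FALSE)
    }
    prof <- mvc_profile(grp[[1]]$participant, cmax)
    for (j in seq_along(grp)) {
      rec <- grp[[j]]
      st <- standardize_length(normalize_by_mvc(envs[[j]], prof), config)
      samples[[length(samples) + 1L]] <- list(
        id = rec$id, participant = rec$participant,
        emg_fixed = t(st$emg), label = binarize_label(rec$grasp_dh),
        original_length_frames = rec$datasize,
        weight_g = rec$weight_g, span1_mm = rec$span1_mm,
        span2_mm = rec$span2_mm, task_height = rec$task_height
      )
    }
  },
  warning = function(w) {
    msg <- conditionMessage(w)
    if (msg %in% seen_warnings) {
      invokeRestart("muffleWarning")
    } else {
      seen_warnings <<- c(seen_warnings, msg)
    }
  })
  # restore input order (grouping by subject reordered the samples)
  input_order <- vapply(bundle$recordings, `[[`, character(1), "id")
  ids <- vapply(samples, `[[`, character(1), "id")
  samples <- samples[order(match(ids, input_order))]
  structure(list(samples = samples, rejections = sel$rejections,
                 config = config), class = "curated_set")
}

#' @export
print.curated_set <- function(x, ...) {
  cat(sprintf("<curated_set> %d samples retained, %d rejected (%s)\n",
              length(x$samples), nrow(x$rejections),
              paste(sprintf("%s=%d", names(table(x$rejections$reason)),
                            as.integer(table(x$rejections$reason))),
                    collapse = ", ")))
  invisible(x)
}
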