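#' Assemble model-ready tensors from a curated set
#'
#' Builds the EMG array (samples x frames x channels), the encoded context
#' matrix and the label vector, computes (or accepts) the subject-wise split,
#' and fits the min-max context scaler on training subjects only before
#' encoding every sample with it.
#'
#' @param curated A [curate_bundle()] result.
#' @param split Optional [split_by_subject()] result; computed from the
#'   curated set's own config when omitted.
#' @param included Context variables to encode (ordered subset of
#'   `c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT")`).
#' @return An object of class `model_inputs`: `train`, `val`, `test` (each
#'   `list(X, Cx, y, ids)`), plus `split`, `scaler`, `included`,
#'   `context_dim`.
#' @export
prepare_model_inputs <- function(curated, split = NULL,
                                 included = c("WEIGHT", "SPAN_1", "SPAN_2",
                                              "TASK_HEIGHT")) {
  samples <- curated$samples
  if (!length(samples)) stop("curated set is empty", call. = FALSE)
  participants <- vapply(samples, `[[`, integer(1), "participant")
  if (is.null(split)) split <- split_by_subject(participants, curated$config)
  scaler <- fit_context_scaler(samples[split$train_idx])
  d <- .context_dim(included)
  Cx <- t(vapply(samples, function(s) encode_context(s, scaler, included),
                 numeric(d)))
  n <- length(samples)
  frames <- nrow(samples[[1]]$emg_fixed)
  X <- array(0, c(n, frames, 7L))
  for (i in seq_len(n)) X[i, , ] <- samples[[i]]$emg_fixed
  y <- vapply(samples, `[[`, integer(1), "label")
  ids <- vapply(samples, `[[`, character(1), "id")
  slice <- function(idx) list(X = X[idx, , , drop = FALSE],
                              Cx = Cx[idx, , drop = FALSE], y = y[idx],
                              ids = ids[idx])
  structure(list(train = slice(split$train_idx), val = slice(split$val_idx),
                 test = slice(split$test_idx), split = split, scaler = scaler,
                 included = included, context_dim = d),
            class = "model_inputs")
}

# A stable fingerprint of a split assignment, asserted across paired runs.
split_fingerprint <- function(split) {
  paste(
    paste(split$train_subjects, collapse = ","),
    paste(split$val_subjects, collapse = ","),
    paste(split$test_subjects, collapse = ","),
    paste(split$test_idx, collapse = ","), sep = "|"
  )
}

.fit_and_report <- function(name, inputs, config, splits = c("train", "val", "test")) {
  spec <- build_model(name, if (name == "M_EMG") NULL else inputs$context_dim)
  fitted <- train_model(spec, list(train = inputs$train, val = inputs$val), config)
  reports <- lapply(splits, function(s) evaluate(fitted, inputs[[s]], s))
  names(reports) <- splits
  list(fitted = fitted, reports = reports, spec = spec)
}

.report_row <- function(model, seed, rep) {
  cm <- rep$confusion_matrix
  data.frame(model = model, split = rep$split_name, seed = seed, loss = rep$loss,
             accuracy = rep$accuracy, precision = rep$precision,
             recall = rep$recall, tn = cm["0", "0"], fp = cm["0", "1"],
             fn = cm["1", "0"], tp = cm["1", "1"], n = rep$n_samples,
             stringsAsFactors = FALSE)
}

#' Unimodal-versus-multimodal comparison
#'
#' Trains `M_EMG`, `M_CONTEXT` and `M_HYBRID` on identical curated inputs and
#' split assignments (a paired design: every model and seed sees the same
#' tensors, asserted by fingerprinting the split), evaluating each on the
#' train, validation and test splits, and summarizing with the per-model
#' median over seeds.
#'
#' @param curated A [curate_bundle()] result.
#' @param config A [train_config()]; its seed field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of training seeds (default `1:3`).
#' @param models Model names to compare.
#' @return An object of class `comparison_result`: `reports` (one row per
#'   model x split x seed), `summary` (median over seeds), `split`,
#'   `split_fingerprint`.
#' @export
run_comparison <- function(curated, config = train_config(), seeds = 1:3,
                           models = c("M_EMG", "M_CONTEXT", "M_HYBRID")) {
  inputs <- prepare_model_inputs(curated)
  fp <- split_fingerprint(inputs$split)
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    for (m in models) {
      stopifnot(identical(split_fingerprint(inputs$split), fp))
      fr <- .fit_and_report(m, inputs, cfg)
      for (s in names(fr$reports)) {
        rows[[length(rows) + 1L]] <- .report_row(m, seed, fr$reports[[s]])
      }
    }
  }
  reports <- do.call(rbind, rows)
  summary <- stats::aggregate(
    reports[, c("loss", "accuracy", "precision", "recall")],
    by = list(model = reports$model, split = reports$split), FUN = stats::median)
  structure(list(reports = reports, summary = summary, split = inputs$split,
                 split_fingerprint = fp),
            class = "comparison_result")
}

#' Context-variable ablation study
#'
#' Trains the three base models and the five exclusion variants of the hybrid
#' model (`MH_NO_SPAN1`, `MH_NO_SPAN2`, `MH_NO_SPAN`, `MH_NO_WEIGHT`,
#' `MH_NO_THEIGHT`) on the shared split. Exclusion happens at the context
#' encoding step, so the first context dense layer genuinely shrinks and the
#' parameter deltas versus the full hybrid (192 per scalar variable, 576 for
#' the three-category task height) are realized in the instantiated networks.
#' All variants share the same EMG tensors, split and seeds; with a common
#' seed the EMG branches start from identical initial weights.
#'
#' @inheritParams run_comparison
#' @return An object of class `ablation_result`: `table` (one row per model
#'   with parameter accounting and median-over-seeds test metrics), `reports`
#'   (per-seed test rows), `split`, `split_fingerprint`.
#' @export
run_ablation <- function(curated, config = train_config(), seeds = 1:3) {
  variant_names <- c("M_EMG", "M_CONTEXT", "M_HYBRID", "MH_NO_SPAN1",
                     "MH_NO_SPAN2", "MH_NO_SPAN", "MH_NO_WEIGHT", "MH_NO_THEIGHT")
  base_inputs <- prepare_model_inputs(curated)
  fp <- split_fingerprint(base_inputs$split)
  full_params <- build_model("M_HYBRID")$total_params
  rows <- list()
  table_rows <- list()
  for (m in variant_names) {
    inputs <- if (m %in% c("M_EMG", "M_CONTEXT")) {
      base_inputs
    } else if (m == "M_HYBRID") {
      base_inputs
    } else {
      prepare_model_inputs(curated, split = base_inputs$split,
                           included = context_vars_for(m))
    }
    stopifnot(identical(split_fingerprint(inputs$split), fp))
    spec <- build_model(m, if (m == "M_EMG") NULL else inputs$context_dim)
    seed_rows <- list()
    for (seed in seeds) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      fr <- .fit_and_report(m, inputs, cfg, splits = "test")
      seed_rows[[length(seed_rows) + 1L]] <- .report_row(m, seed, fr$reports$test)
    }
    seed_df <- do.call(rbind, seed_rows)
    rows[[length(rows) + 1L]] <- seed_df
    is_hybrid <- !(m %in% c("M_EMG", "M_CONTEXT"))
    table_rows[[length(table_rows) + 1L]] <- data.frame(
      model_name = m,
      excluded_variables = if (is_hybrid) {
        paste(.excluded_vars[[m]], collapse = "+")
      } else NA_character_,
      context_input_dim = spec$context_input_dim,
      total_params = spec$total_params,
      param_delta_vs_full = if (is_hybrid) full_params - spec$total_params else NA_integer_,
      loss = stats::median(seed_df$loss),
      accuracy = stats::median(seed_df$accuracy),
      precision = stats::median(seed_df$precision),
      recall = stats::median(seed_df$recall),
      stringsAsFactors = FALSE
    )
  }
  structure(list(table = do.call(rbind, table_rows),
                 reports = do.call(rbind, rows), split = base_inputs$split,
                 split_fingerprint = fp),
            class = "ablation_result")
}

#' Write comparison and ablation reports to disk
#'
#' Emits CSV and aligned-text versions of the supplied tables, plus a
#' parameter ledger listing each ablation variant's parameter delta against
#' the full hybrid model and its percentage of the full model's total
#' (one decimal).
#'
#' @param tables A list with optional elements `comparison` (a
#'   `comparison_result`) and `ablation` (an `ablation_result`); at least one
#'   non-empty table is required.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
render_reports <- function(tables, out_dir) {
  has_cmp <- !is.null(tables$comparison) && nrow(tables$comparison$reports) > 0
  has_abl <- !is.null(tables$ablation) && nrow(tables$ablation$table) > 0
  if (!has_cmp && !has_abl) stop("no non-empty tables to render", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_txt <- function(df, path) {
    writeLines(utils::capture.output(print(df, row.names = FALSE)), path)
  }
  if (has_cmp) {
    utils::write.csv(tables$comparison$reports,
                     file.path(out_dir, "comparison_reports.csv"), row.names = FALSE)
    utils::write.csv(tables$comparison$summary,
                     file.path(out_dir, "comparison_summary.csv"), row.names = FALSE)
    write_txt(tables$comparison$summary, file.path(out_dir, "comparison_summary.txt"))
  }
  if (has_abl) {
    tab <- tables$ablation$table
    utils::write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
    write_txt(tab, file.path(out_dir, "ablation.txt"))
    full <- tab$total_params[tab$model_name == "M_HYBRID"]
    led <- tab[!is.na(tab$param_delta_vs_full) & tab$model_name != "M_HYBRID", ]
    ledger <- c(
      sprintf("full hybrid model: %d trainable parameters", full),
      sprintf("%-14s delta %4d params (%.1f%% of full)", led$model_name,
              led$param_delta_vs_full, 100 * led$param_delta_vs_full / full)
    )
    writeLines(ledger, file.path(out_dir, "param_ledger.txt"))
  }
  invisible(out_dir)
}
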