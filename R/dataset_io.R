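#' Construct a single sEMG recording
#'
#' A `raw_recording` holds one elementary-task recording: a 7-channel surface
#' EMG matrix plus the task/product annotations used by the contextual models.
#' Channel count is fixed at 7 (the seven forearm electrode sites).
#'
#' @param id Unique recording identifier (character or integer-like).
#' @param participant Subject identifier (integer; 1--30 in the emulated regime).
#' @param task Task code.
#' @param et Elementary-task code.
#' @param emg Numeric matrix, channels x frames, with exactly 7 rows.
#' @param sampling_rate_hz Sampling frequency in Hz. Stored explicitly rather
#'   than assumed; all frequency-domain operations read it from here.
#' @param product_dh Product identifier.
#' @param weight_g Product weight in grams (>= 0).
#' @param span1_mm Width of the main grasped cross-section in mm (>= 0).
#' @param span2_mm Width of the secondary cross-section in mm; 0 when the
#'   object has a single grasp zone.
#' @param grasp_dh Grasp code, 1--9 (1 = cylindrical, 9 = free).
#' @param action_dh Action code, 1--10 (1 = reaching).
#' @param task_height Task height category in `{1, 2, 3}`.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(id, participant, task, et, emg, sampling_rate_hz,
                          product_dh, weight_g, span1_mm, span2_mm,
                          grasp_dh, action_dh, task_height) {
  rec <- structure(
    list(
      id = as.character(id),
      participant = as.integer(participant),
      task = as.integer(task),
      et = as.integer(et),
      emg = emg,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      datasize = ncol(emg),
      product_dh = as.integer(product_dh),
      weight_g = as.numeric(weight_g),
      span1_mm = as.numeric(span1_mm),
      span2_mm = as.numeric(span2_mm),
      grasp_dh = as.integer(grasp_dh),
      action_dh = as.integer(action_dh),
      task_height = as.integer(task_height)
    ),
    class = "raw_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate a raw recording against the schema
#'
#' Checks every schema invariant; the error message names the offending field.
#'
#' @param rec A [raw_recording()].
#' @return `rec`, invisibly, if valid.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$emg) || !is.numeric(rec$emg)) {
    stop("field 'emg': must be a numeric matrix (channels x frames)", call. = FALSE)
  }
  if (nrow(rec$emg) != 7L) {
    stop(sprintf("field 'emg': expected exactly 7 channels (rows), got %d", nrow(rec$emg)),
         call. = FALSE)
  }
  if (rec$datasize != ncol(rec$emg)) {
    stop(sprintf("field 'datasize': %d does not match emg frame count %d",
                 rec$datasize, ncol(rec$emg)), call. = FALSE)
  }
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("field 'sampling_rate_hz': must be a positive number", call. = FALSE)
  }
  if (is.na(rec$grasp_dh) || !(rec$grasp_dh %in% 1:9)) {
    stop(sprintf("field 'grasp_dh': %s not in 1..9", rec$grasp_dh), call. = FALSE)
  }
  if (is.na(rec$action_dh) || !(rec$action_dh %in% 1:10)) {
    stop(sprintf("field 'action_dh': %s not in 1..10", rec$action_dh), call. = FALSE)
  }
  if (is.na(rec$task_height) || !(rec$task_height %in% 1:3)) {
    stop(sprintf("field 'task_height': %s not in {1,2,3}", rec$task_height), call. = FALSE)
  }
  for (f in c("weight_g", "span1_mm", "span2_mm")) {
    v <- rec[[f]]
    if (!is.na(v) && v < 0) {
      stop(sprintf("field '%s': must be >= 0, got %s", f, v), call. = FALSE)
    }
  }
  invisible(rec)
}

#' Construct an MVC normalization profile
#'
#' Per-subject, per-channel maximum voluntary contraction (MVC) amplitudes used
#' as normalization denominators.
#'
#' @param participant Subject identifier.
#' @param channel_max Numeric vector of 7 strictly positive per-channel maxima.
#' @return An object of class `mvc_profile`.
#' @export
mvc_profile <- function(participant, channel_max) {
  channel_max <- as.numeric(channel_max)
  if (length(channel_max) != 7L) {
    stop("field 'channel_max': expected 7 values, got ", length(channel_max), call. = FALSE)
  }
  if (any(!is.finite(channel_max)) || any(channel_max <= 0)) {
    stop("field 'channel_max': all 7 values must be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(participant = as.integer(participant), channel_max = channel_max),
            class = "mvc_profile")
}

#' Construct a dataset bundle
#'
#' A `dataset_bundle` couples an ordered collection of recordings with the
#' per-subject MVC profiles and a free-text provenance tag, so that real and
#' synthetic data flow through identical code.
#'
#' @param recordings List of [raw_recording()] objects.
#' @param mvc_profiles List of [mvc_profile()] objects, one per participant
#'   appearing in `recordings`.
#' @param provenance Free-text source tag (synthetic seed or file path).
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(recordings, mvc_profiles, provenance = "") {
  b <- structure(
    list(recordings = recordings, mvc_profiles = mvc_profiles,
         provenance = as.character(provenance)),
    class = "dataset_bundle"
  )
  validate_bundle(b)
  b
}

#' Validate a dataset bundle
#'
#' Checks every recording, uniqueness of recording ids, and that every
#' participant has an MVC profile.
#'
#' @param bundle A [dataset_bundle()].
#' @return `bundle`, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  for (rec in bundle$recordings) validate_recording(rec)
  ids <- vapply(bundle$recordings, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("field 'ID': duplicate recording ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  parts <- unique(vapply(bundle$recordings, `[[`, integer(1), "participant"))
  prof_parts <- vapply(bundle$mvc_profiles, `[[`, integer(1), "participant")
  missing <- setdiff(parts, prof_parts)
  if (length(missing)) {
    stop("field 'mvc_profiles': participants without an MVC profile: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(bundle)
}

#' @export
print.dataset_bundle <- function(x, ...) {
  n <- length(x$recordings)
  parts <- unique(vapply(x$recordings, `[[`, integer(1), "participant"))
  cat(sprintf("<dataset_bundle> %d recordings, %d subjects, provenance: %s\n",
              n, length(parts), x$provenance))
  invisible(x)
}

# Annotation columns, named exactly as in the source database schema.
.annotation_cols <- c("ID", "PARTICIPANT", "T", "ET", "datasize", "PRODUCT_DH",
                      "WEIGHT", "SPAN_1", "SPAN_2", "GRASP_DH", "ACTION_DH",
                      "TASK_HEIGHT", "SAMPLING_RATE_HZ")

.bundle_annotations <- function(bundle) {
  recs <- bundle$recordings
  data.frame(
    ID = vapply(recs, `[[`, character(1), "id"),
    PARTICIPANT = vapply(recs, `[[`, integer(1), "participant"),
    T = vapply(recs, `[[`, integer(1), "task"),
    ET = vapply(recs, `[[`, integer(1), "et"),
    datasize = vapply(recs, `[[`, integer(1), "datasize"),
    PRODUCT_DH = vapply(recs, `[[`, integer(1), "product_dh"),
    WEIGHT = vapply(recs, `[[`, numeric(1), "weight_g"),
    SPAN_1 = vapply(recs, `[[`, numeric(1), "span1_mm"),
    SPAN_2 = vapply(recs, `[[`, numeric(1), "span2_mm"),
    GRASP_DH = vapply(recs, `[[`, integer(1), "grasp_dh"),
    ACTION_DH = vapply(recs, `[[`, integer(1), "action_dh"),
    TASK_HEIGHT = vapply(recs, `[[`, integer(1), "task_height"),
    SAMPLING_RATE_HZ = vapply(recs, `[[`, numeric(1), "sampling_rate_hz"),
    stringsAsFactors = FALSE
  )
}

.mvc_table <- function(bundle) {
  profs <- bundle$mvc_profiles
  m <- do.call(rbind, lapply(profs, `[[`, "channel_max"))
  df <- data.frame(PARTICIPANT = vapply(profs, `[[`, integer(1), "participant"))
  if (length(profs)) {
    colnames(m) <- paste0("CH_", 1:7)
    df <- cbind(df, as.data.frame(m))
  } else {
    for (i in 1:7) df[[paste0("CH_", i)]] <- numeric(0)
  }
  rownames(df) <- NULL
  df
}

#' Write a dataset bundle to disk
#'
#' Annotations are stored as one table row per recording, with the original
#' database column names (`ID`, `PARTICIPANT`, `T`, `ET`, `datasize`,
#' `PRODUCT_DH`, `WEIGHT`, `SPAN_1`, `SPAN_2`, `GRASP_DH`, `ACTION_DH`,
#' `TASK_HEIGHT`) plus `SAMPLING_RATE_HZ`. For parquet the EMG matrices are a
#' nested list column (`EMG`, the 7 x L matrix flattened column-major, i.e.
#' channel-fastest) on the same table and the round trip is bit-exact. For CSV
#' the EMG payload is a separate long table `emg.csv` keyed by
#' `(ID, CHANNEL, FRAME)`, kept for inspectability of small bundles.
#'
#' @param bundle A validated [dataset_bundle()].
#' @param path Directory to write into (created if absent).
#' @param format `"parquet"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(bundle, path, format = c("parquet", "csv")) {
  format <- match.arg(format)
  validate_bundle(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ann <- .bundle_annotations(bundle)
  mvc <- .mvc_table(bundle)
  jsonlite::write_json(
    list(format = format, provenance = bundle$provenance,
         n_recordings = length(bundle$recordings)),
    file.path(path, "meta.json"), auto_unbox = TRUE
  )
  if (format == "parquet") {
    ann$EMG <- lapply(bundle$recordings, function(r) as.numeric(r$emg))
    arrow::write_parquet(ann, file.path(path, "recordings.parquet"))
    arrow::write_parquet(mvc, file.path(path, "mvc.parquet"))
  } else {
    utils::write.csv(ann, file.path(path, "recordings.csv"), row.names = FALSE)
    utils::write.csv(mvc, file.path(path, "mvc.csv"), row.names = FALSE)
    n_per <- vapply(bundle$recordings, function(r) length(r$emg), integer(1))
    long <- data.frame(
      ID = rep(ann$ID, n_per),
      CHANNEL = as.integer(unlist(lapply(n_per, function(n) rep_len(1:7, n)),
                                  use.names = FALSE)),
      FRAME = as.integer(unlist(lapply(n_per, function(n) rep(seq_len(n %/% 7L), each = 7L)),
                                use.names = FALSE)),
      VALUE = as.numeric(unlist(lapply(bundle$recordings, function(r) as.numeric(r$emg)),
                                use.names = FALSE))
    )
    utils::write.csv(long, file.path(path, "emg.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset bundle from disk
#'
#' Reads a directory produced by [write_dataset()] (or conforming to its
#' documented schema), validating columns, ids and recording invariants.
#'
#' @param path Directory containing the dataset files.
#' @return A validated [dataset_bundle()].
#' @export
read_dataset <- function(path) {
  if (file.exists(file.path(path, "recordings.parquet"))) {
    ann <- as.data.frame(arrow::read_parquet(file.path(path, "recordings.parquet")))
    mvc <- as.data.frame(arrow::read_parquet(file.path(path, "mvc.parquet")))
    fmt <- "parquet"
  } else if (file.exists(file.path(path, "recordings.csv"))) {
    ann <- utils::read.csv(file.path(path, "recordings.csv"), stringsAsFactors = FALSE)
    mvc <- utils::read.csv(file.path(path, "mvc.csv"), stringsAsFactors = FALSE)
    fmt <- "csv"
  } else {
    stop("no recordings.parquet or recordings.csv under ", path, call. = FALSE)
  }
  missing <- setdiff(.annotation_cols, names(ann))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$ID)) {
    stop("field 'ID': duplicate recording ids: ",
         paste(unique(ann$ID[duplicated(ann$ID)]), collapse = ", "), call. = FALSE)
  }
  if (fmt == "parquet") {
    if (!"EMG" %in% names(ann)) stop("missing mandatory column(s): EMG", call. = FALSE)
    emg_list <- lapply(seq_len(nrow(ann)), function(i) {
      v <- as.numeric(ann$EMG[[i]])
      if (length(v) %% 7L != 0L) {
        stop("unparsable EMG payload for ID ", ann$ID[i], call. = FALSE)
      }
      matrix(v, nrow = 7L)
    })
  } else {
    long <- utils::read.csv(file.path(path, "emg.csv"), stringsAsFactors = FALSE)
    long_by_id <- split(long$VALUE, factor(long$ID, levels = ann$ID))
    emg_list <- lapply(ann$ID, function(id) {
      v <- long_by_id[[id]]
      if (is.null(v) || length(v) %% 7L != 0L) {
        stop("unparsable EMG payload for ID ", id, call. = FALSE)
      }
      matrix(v, nrow = 7L)
    })
  }
  recs <- lapply(seq_len(nrow(ann)), function(i) {
    raw_recording(
      id = ann$ID[i], participant = ann$PARTICIPANT[i], task = ann$T[i],
      et = ann$ET[i], emg = emg_list[[i]],
      sampling_rate_hz = ann$SAMPLING_RATE_HZ[i], product_dh = ann$PRODUCT_DH[i],
      weight_g = ann$WEIGHT[i], span1_mm = ann$SPAN_1[i], span2_mm = ann$SPAN_2[i],
      grasp_dh = ann$GRASP_DH[i], action_dh = ann$ACTION_DH[i],
      task_height = ann$TASK_HEIGHT[i]
    )
  })
  profs <- lapply(seq_len(nrow(mvc)), function(i) {
    mvc_profile(mvc$PARTICIPANT[i], as.numeric(mvc[i, paste0("CH_", 1:7)]))
  })
  meta_path <- file.path(path, "meta.json")
  prov <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)$provenance else path
  dataset_bundle(recs, profs, provenance = prov)
}
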