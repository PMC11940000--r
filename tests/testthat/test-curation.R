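test_that("leading-null trimming removes all-channel zero prefixes and tags fully null recordings", {
  emg <- toy_emg(1200, seed = 3)
  emg[, 1:100] <- 0
  r <- toy_recording(emg = emg)
  tr <- trim_leading_nulls(r)
  expect_false(tr$rejected)
  expect_equal(tr$recording$datasize, 1100L)
  expect_identical(tr$recording$emg, emg[, 101:1200])

  z <- toy_recording(emg = matrix(0, 7, 500))
  tz <- trim_leading_nulls(z)
  expect_true(tz$rejected)
  expect_equal(tz$reason, "all_null")

  clean <- toy_recording(emg = toy_emg(300))
  expect_identical(trim_leading_nulls(clean)$recording, clean)
  # a single non-zero channel keeps the frame
  one <- toy_recording(emg = rbind(c(1, 1), matrix(0, 6, 2)))
  expect_equal(trim_leading_nulls(one)$recording$datasize, 2L)
})

test_that("sample selection applies the filters in order and logs every rejection", {
  recs <- list(
    toy_recording("a", 1L, toy_emg(800, 1), grasp = 1L, action = 1L),   # retained
    toy_recording("b", 1L, toy_emg(800, 2), grasp = 9L, action = 1L),   # free
    toy_recording("c", 1L, toy_emg(800, 3), grasp = 2L, action = 3L),   # non-reaching
    toy_recording("d", 1L, matrix(0, 7, 800), grasp = 1L, action = 1L), # all null
    toy_recording("e", 1L, toy_emg(500, 4), grasp = 3L, action = 1L)    # too short
  )
  sel <- select_samples(toy_bundle(recs), curation_config())
  expect_length(sel$retained, 1)
  expect_equal(sel$retained[[1]]$id, "a")
  expect_setequal(sel$rejections$ID, c("b", "c", "d", "e"))
  expect_equal(sel$rejections$reason[match(c("b", "c", "d", "e"), sel$rejections$ID)],
               c("free_grasp", "non_reaching", "all_null", "too_short"))
  # every input lands exactly once in retained or the log
  expect_equal(length(sel$retained) + nrow(sel$rejections), length(recs))

  none <- select_samples(toy_bundle(recs[3]), curation_config())
  expect_length(none$retained, 0)
  expect_equal(none$rejections$reason, "non_reaching")
})

test_that("selection rates on the generated default fixture match the config artifact rates", {
  b <- make_fixture("default")
  sel <- select_samples(b, curation_config())
  n <- length(b$recordings)
  counts <- table(sel$rejections$reason)
  expect_lt(abs(counts[["non_reaching"]] / n - 0.15), 0.02)
  # free grasps are counted after the reaching filter
  expect_lt(abs(counts[["free_grasp"]] / n - 0.08 * 0.85), 0.02)
  # retained class prevalence stays near the generator prevalence
  y <- vapply(sel$retained, function(r) as.integer(r$grasp_dh == 1L), integer(1))
  expect_lt(abs(mean(y) - 0.42), 0.03)
})

test_that("length_cdf equals a brute-force count and is monotone", {
  f <- length_cdf(c(100, 700, 800))
  expect_equal(f(700), 2 / 3)
  expect_equal(f(0), 1)
  expect_equal(f(801), 0)
  set.seed(20)
  lens <- sample(41:6337, 300, replace = TRUE)
  g <- length_cdf(lens)
  ts <- c(0, sort(sample(lens, 25)), 7000)
  brute <- vapply(ts, function(t) {
    k <- 0
    for (l in lens) if (l >= t) k <- k + 1
    k / length(lens)
  }, numeric(1))
  expect_equal(g(ts), brute)
  expect_true(all(diff(g(sort(ts))) <= 0))
  expect_error(length_cdf(numeric(0)), "empty")
})

test_that("length standardization keeps suffixes and left-pads with zeros, bit-exactly", {
  cfg <- curation_config()
  for (L in c(699, 700, 850, 1000, 1200)) {
    emg <- toy_emg(L, seed = L)
    st <- standardize_length(emg, cfg)
    if (L < 700) {
      expect_true(st$rejected)
      expect_equal(st$reason, "too_short")
    } else {
      expect_false(st$rejected)
      expect_equal(dim(st$emg), c(7L, 1000L))
      if (L > 1000) {
        expect_identical(st$emg, emg[, (L - 999):L])
      } else {
        expect_identical(st$emg[, (1000 - L + 1):1000], emg)
        if (L < 1000) expect_true(all(st$emg[, seq_len(1000 - L)] == 0))
      }
    }
  }
})

test_that("label binarization maps cylindrical to 1 and traps free grasps", {
  expect_equal(binarize_label(1L), 1L)
  expect_equal(binarize_label(4L), 0L)
  expect_equal(binarize_label(2:8), rep(0L, 7))
  expect_error(binarize_label(9L), "free")
})

test_that("the context scaler is an unclipped train-set min-max affine map", {
  mk <- function(w, s1 = 50, s2 = 0, th = 2L) {
    list(weight_g = w, span1_mm = s1, span2_mm = s2, task_height = th)
  }
  sc <- suppressWarnings(fit_context_scaler(list(mk(100), mk(500), mk(900))))
  expect_equal(sc$min[["WEIGHT"]], 100)
  expect_equal(sc$max[["WEIGHT"]], 900)
  enc <- encode_context(mk(500), sc)
  expect_equal(enc[["WEIGHT"]], 0.5)
  # out-of-range transform values extend affinely, no clipping
  expect_equal(encode_context(mk(1100), sc)[["WEIGHT"]], 1.25)
  # constant variable maps to 0 with a warning
  expect_warning(fit_context_scaler(list(mk(100), mk(500))), "SPAN_2")
  expect_equal(suppressWarnings(
    encode_context(mk(100), fit_context_scaler(list(mk(100), mk(500))))
  )[["SPAN_2"]], 0)
  expect_error(fit_context_scaler(list()), "empty")
})

test_that("context encoding has the documented order, one-hot block and subset behavior", {
  s <- list(weight_g = 300, span1_mm = 60, span2_mm = 20, task_height = 2L)
  sc <- fit_context_scaler(list(
    list(weight_g = 0, span1_mm = 0, span2_mm = 0, task_height = 1L),
    list(weight_g = 600, span1_mm = 120, span2_mm = 40, task_height = 3L)))
  full <- encode_context(s, sc)
  expect_equal(names(full), c("WEIGHT", "SPAN_1", "SPAN_2", "TH_1", "TH_2", "TH_3"))
  expect_equal(unname(full), c(0.5, 0.5, 0.5, 0, 1, 0))
  expect_equal(sum(full[c("TH_1", "TH_2", "TH_3")]), 1)
  expect_length(encode_context(s, sc, included = "WEIGHT"), 1)
  expect_equal(names(encode_context(s, sc, included = c("SPAN_1", "TASK_HEIGHT"))),
               c("SPAN_1", "TH_1", "TH_2", "TH_3"))
  expect_error(encode_context(s, sc, included = "COLOUR"), "unknown")
})

test_that("subject splits rank by ascending retained count with id tie-breaks", {
  # brute-force oracle over an explicit count table, including a tie
  participants <- rep(c(3L, 1L, 2L, 5L, 4L), times = c(4, 2, 2, 7, 6))
  cfg <- curation_config(n_test_subjects = 2L, n_val_subjects = 1L)
  sp <- split_by_subject(participants, cfg)
  # counts: s1=2, s2=2, s3=4, s4=6, s5=7; tie between 1 and 2 -> both to test
  expect_equal(sp$test_subjects, c(1L, 2L))
  expect_equal(sp$val_subjects, 3L)
  expect_equal(sp$train_subjects, c(4L, 5L))
  expect_length(intersect(sp$test_idx, c(sp$train_idx, sp$val_idx)), 0)
  expect_equal(sort(c(sp$train_idx, sp$val_idx, sp$test_idx)),
               seq_along(participants))

  expect_error(split_by_subject(rep(1:3, 5), curation_config()), "at least")
  # minimal 1/1/1 split is deterministic
  sp3 <- split_by_subject(rep(1:3, times = c(5, 3, 4)),
                          curation_config(n_test_subjects = 1, n_val_subjects = 1))
  expect_equal(sp3$test_subjects, 2L)
  expect_equal(sp3$val_subjects, 3L)
  expect_equal(sp3$train_subjects, 1L)
})

test_that("the default-fixture split matches a brute-force ranking oracle and the 16/4/10 layout", {
  b <- make_fixture("default")
  sel <- select_samples(b, curation_config())
  parts <- vapply(sel$retained, `[[`, integer(1), "participant")
  sp <- split_by_subject(parts, curation_config())
  expect_length(sp$train_subjects, 16)
  expect_length(sp$val_subjects, 4)
  expect_length(sp$test_subjects, 10)
  # brute-force oracle: order subjects by (count, id) with a stable sort
  cnt <- table(parts)
  oracle <- as.integer(names(cnt))[order(as.integer(cnt), as.integer(names(cnt)))]
  expect_setequal(sp$test_subjects, oracle[1:10])
  expect_setequal(sp$val_subjects, oracle[11:14])
  expect_setequal(sp$train_subjects, oracle[15:30])
})

test_that("curation is order-stable and partitions the bundle", {
  b <- small_trainable_bundle()
  cur <- suppressWarnings(curate_bundle(b, small_curation_config()))
  ids_in <- vapply(b$recordings, `[[`, character(1), "id")
  ids_ret <- vapply(cur$samples, `[[`, character(1), "id")
  expect_setequal(c(ids_ret, cur$rejections$ID), ids_in)
  expect_equal(length(ids_ret) + nrow(cur$rejections), length(ids_in))
  expect_true(all(vapply(cur$samples, function(s) dim(s$emg_fixed), integer(2)) ==
                    c(1000L, 7L)))
  expect_true(all(vapply(cur$samples, `[[`, integer(1), "label") %in% 0:1))

  set.seed(9)
  shuf <- b
  shuf$recordings <- b$recordings[sample(length(b$recordings))]
  cur2 <- suppressWarnings(curate_bundle(shuf, small_curation_config()))
  ids2 <- vapply(cur2$samples, `[[`, character(1), "id")
  expect_setequal(ids2, ids_ret)
  expect_setequal(cur2$rejections$ID, cur$rejections$ID)
  # per-sample results identical regardless of input order
  m1 <- cur$samples[[which(ids_ret == ids_ret[1])]]$emg_fixed
  m2 <- cur2$samples[[which(ids2 == ids_ret[1])]]$emg_fixed
  expect_identical(m1, m2)
  sp1 <- split_by_subject(vapply(cur$samples, `[[`, integer(1), "participant"),
                          small_curation_config())
  sp2 <- split_by_subject(vapply(cur2$samples, `[[`, integer(1), "participant"),
                          small_curation_config())
  expect_equal(sp1$test_subjects, sp2$test_subjects)
})
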