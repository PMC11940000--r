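ns <- asNamespace("emgrasp")

test_that("the cosine-decay schedule matches its closed form and is monotone", {
  cfg <- train_config(epochs = 300)
  expect_equal(lr_at(0, cfg), 0.001)
  expect_equal(lr_at(300, cfg), 1e-5)
  expect_equal(lr_at(150, cfg), 0.001 * (0.01 + (1 - 0.01) / 2))  # 0.000505
  trace <- lr_at(0:300, cfg)
  expect_true(all(diff(trace) <= 0))
  expect_true(all(trace >= 1e-5 - 1e-15 & trace <= 0.001 + 1e-15))
  expect_error(lr_at(301, cfg), "out of range")
  expect_error(lr_at(-1, cfg), "out of range")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr_alpha = 0), "lr_alpha")
})

# A deterministic M_CONTEXT stub: with all-ones branch weights, zero biases and
# a head reading the embedding into the class-1 logit, the network predicts 1
# exactly when its single input is positive (ties at 0 go to class 0).
threshold_stub <- function() {
  spec <- build_model("M_CONTEXT", context_input_dim = 1)
  params <- ns$.with_seed(1, nn_init(spec))
  params$fc1$W[] <- 1; params$fc1$b[] <- 0
  params$fc2$W[] <- 1 / 192; params$fc2$b[] <- 0
  params$head[[1]]$W[] <- 0
  params$head[[1]]$W[, 2] <- 1
  params$head[[1]]$b[] <- 0
  structure(list(spec = spec, params = params,
                 history = NULL, best_epoch = 1L, config = train_config()),
            class = "fitted_model")
}

test_that("evaluation reproduces confusion-matrix arithmetic on a constructed predictor", {
  stub <- threshold_stub()
  # realize confusion (TN=50, FP=10, FN=54, TP=86) on n=200
  y <- c(rep(0L, 50), rep(0L, 10), rep(1L, 54), rep(1L, 86))
  x <- c(rep(0, 50), rep(1, 10), rep(0, 54), rep(1, 86))
  rep_ <- evaluate(stub, list(Cx = matrix(x, ncol = 1), y = y), "toy")
  expect_equal(rep_$confusion_matrix["0", "0"], 50)
  expect_equal(rep_$confusion_matrix["0", "1"], 10)
  expect_equal(rep_$confusion_matrix["1", "0"], 54)
  expect_equal(rep_$confusion_matrix["1", "1"], 86)
  expect_equal(sum(rep_$confusion_matrix), rep_$n_samples)
  expect_equal(rep_$accuracy, 0.68)
  expect_equal(rep_$precision, 86 / 96)
  expect_equal(rep_$recall, 86 / 140)

  # perfect predictor: x encodes the label
  y2 <- rep(c(0L, 1L), 20)
  perf <- evaluate(stub, list(Cx = matrix(as.numeric(y2), ncol = 1), y = y2), "toy")
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$precision, 1)
  expect_equal(perf$recall, 1)
  expect_equal(perf$confusion_matrix["0", "1"] + perf$confusion_matrix["1", "0"], 0)

  # all-negative predictor on mixed labels: 0/0 convention gives 0 + flag
  neg <- evaluate(stub, list(Cx = matrix(0, 30, 1), y = rep(c(0L, 1L), 15)), "toy")
  expect_equal(neg$recall, 0)
  expect_equal(neg$precision, 0)
  expect_true(neg$degenerate)
  expect_error(evaluate(stub, list(Cx = matrix(0, 0, 1), y = integer(0))), "empty")
})

test_that("training keeps per-epoch books, follows the schedule, and is seed-deterministic", {
  b <- small_trainable_bundle()
  cur <- suppressWarnings(curate_bundle(b, small_curation_config()))
  inp <- suppressWarnings(prepare_model_inputs(cur))
  cfg <- train_config(epochs = 2, seed = 5)
  f <- train_model(build_model("M_CONTEXT", 6),
                   list(train = inp$train, val = inp$val), cfg)
  h <- f$history$table
  expect_equal(nrow(h), 2)
  expect_equal(h$lr, lr_at(0:1, cfg))
  expect_true(all(is.finite(unlist(h[, -1]))))
  expect_equal(f$best_epoch, which.max(h$val_accuracy))

  f2 <- train_model(build_model("M_CONTEXT", 6),
                    list(train = inp$train, val = inp$val), cfg)
  expect_equal(f2$history$table, h, tolerance = 1e-6)
  expect_equal(f2$params, f$params, tolerance = 1e-6)

  # checkpointing: evaluating the returned weights on the validation split
  # reproduces the recorded best validation accuracy
  ev <- evaluate(f, inp$val, "val")
  expect_equal(ev$accuracy, h$val_accuracy[f$best_epoch])

  expect_error(train_model(build_model("M_CONTEXT", 6),
                           list(train = inp$train,
                                val = list(Cx = inp$val$Cx[0, , drop = FALSE],
                                           y = integer(0)))),
               "empty")
  expect_error(train_model(build_model("M_CONTEXT", 4),
                           list(train = inp$train, val = inp$val)),
               "dimension mismatch")
})

test_that("a context model learns a separable context quickly", {
  b <- small_trainable_bundle()
  cur <- suppressWarnings(curate_bundle(b, small_curation_config()))
  inp <- suppressWarnings(prepare_model_inputs(cur))
  # make the context perfectly separable to isolate the optimizer
  inp$train$Cx[, 1] <- inp$train$y
  inp$val$Cx[, 1] <- inp$val$y
  f <- train_model(build_model("M_CONTEXT", 6),
                   list(train = inp$train, val = inp$val),
                   train_config(epochs = 30, batch_size = 8, seed = 2))
  expect_gte(max(f$history$table$val_accuracy), 0.99)
})

test_that("learning curves export to CSV that round-trips, with the 85% reference line", {
  b <- small_trainable_bundle()
  cur <- suppressWarnings(curate_bundle(b, small_curation_config()))
  inp <- suppressWarnings(prepare_model_inputs(cur))
  f <- train_model(build_model("M_CONTEXT", 6),
                   list(train = inp$train, val = inp$val),
                   train_config(epochs = 2, seed = 5))
  dir <- withr::local_tempdir()
  meta <- export_curves(f$history, dir)
  expect_equal(meta$reference_line, 0.85)
  expect_true(file.exists(meta$csv))
  expect_true(file.exists(meta$plot_file))
  back <- utils::read.csv(meta$csv)
  expect_equal(nrow(back), 2)
  expect_equal(back, f$history$table, tolerance = 1e-12)
})
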