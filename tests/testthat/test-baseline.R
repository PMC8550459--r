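test_that("retraining touches only the final fully connected layer", {
  w <- small_world()
  snap <- backbone_params(w$backbone)
  fit <- retrain_final_layer(w$backbone, w$split,
                             intensity_config(0.5, 5L, target = 1L),
                             short_cfg(seed = 41L))
  newp <- backbone_params(fit$model)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expect_identical(newp[[nm]], snap[[nm]])
  }
  expect_false(identical(newp$Wfc, snap$Wfc))
  # warm start: the retrained layer begins at the trained parameters
  expect_equal(dim(newp$Wfc), dim(snap$Wfc))
  # trainable-parameter footprint: (penultimate width + 1) x N for the
  # baseline vs F for the attention layer
  n_fc <- length(snap$Wfc) + length(snap$bfc)
  expect_equal(n_fc, (nrow(snap$Wfc) + 1L) * w$backbone$n_classes)
  expect_gt(n_fc, insertion_filters(w$backbone))
})

test_that("both methods consume identical epoch samples under one seed", {
  w <- small_world()
  cfg <- short_cfg(seed = 51L, max_epochs = 6L)
  intensity <- intensity_config(0.5, 5L, target = 2L)
  fit_a <- train_attention(modulated_classifier(w$backbone), w$split,
                           intensity, cfg)
  fit_r <- retrain_final_layer(w$backbone, w$split, intensity, cfg)
  n <- min(length(fit_a$epoch_ids), length(fit_r$epoch_ids))
  expect_gte(n, 1L)
  for (e in seq_len(n)) {
    expect_identical(fit_a$epoch_ids[[e]], fit_r$epoch_ids[[e]])
  }
})

test_that("complete focus raises the baseline's target training hit rate", {
  w <- small_world()
  cfg <- train_config(learning_rate = 0.01, max_epochs = 40L,
                      check_interval = 10L, seed = 61L)
  fit <- retrain_final_layer(w$backbone, w$split,
                             intensity_config(1, 5L, target = 3L), cfg)
  tr <- w$split$train
  hit0 <- mean(apply(predict(w$backbone, tr), 1, which.max)[tr$info$class == 3L] == 3L)
  hit1 <- mean(apply(predict(fit$model, tr), 1, which.max)[tr$info$class == 3L] == 3L)
  expect_gte(hit1, hit0)
})

make_sweep_stub <- function(d, crit, method = "attention") {
  alphas <- as.numeric(colnames(d))
  rows <- list()
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(ncol(d))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = i, alpha = alphas[j], method = method, testset = "standard",
        dprime = d[i, j], criterion = crit[i, j]
      )
    }
  }
  structure(list(metrics = dplyr::bind_rows(rows)), class = "sweep_result")
}

test_that("model comparison pairs cells and runs paired t tests", {
  d <- matrix(c(2, 2.5, 1.8, 2.2), 2, 2, dimnames = list(NULL, c("0.5", "1")))
  crit <- matrix(0, 2, 2, dimnames = list(NULL, c("0.5", "1")))
  a <- make_sweep_stub(d, crit)
  b <- make_sweep_stub(d, crit, method = "retrain")
  # identical sweeps: all differences zero, t undefined (zero variance)
  cmp0 <- compare_models(a, b)
  expect_true(all(cmp0$differences$delta_dprime == 0))
  expect_true(all(is.na(cmp0$tests$t_dprime)))
  # a uniform +0.5 shift in attention d-prime
  a2 <- make_sweep_stub(d + 0.5, crit)
  cmp <- compare_models(a2, b)
  expect_equal(cmp$differences$delta_dprime,
               rep(0.5, nrow(cmp$differences)), ignore_attr = TRUE)
  expect_equal(cmp$tests$mean_delta_dprime, c(0.5, 0.5))
  # non-degenerate paired differences give a positive finite t
  set.seed(3)
  a3 <- make_sweep_stub(d + 0.5 + matrix(rnorm(4, 0, 0.05), 2, 2), crit)
  cmp3 <- compare_models(a3, b)
  expect_true(all(is.finite(cmp3$tests$t_dprime)))
  expect_true(all(cmp3$tests$t_dprime > 0))
  # mismatched class lists are rejected
  b2 <- make_sweep_stub(d[1, , drop = FALSE], crit[1, , drop = FALSE],
                        method = "retrain")
  expect_error(compare_models(a, b2), "different target-class lists")
})

test_that("a single shared class leaves the t statistic flagged undefined", {
  d <- matrix(c(2, 2.5), 1, 2, dimnames = list(NULL, c("0.5", "1")))
  a <- make_sweep_stub(d + 0.3, d * 0)
  b <- make_sweep_stub(d, d * 0, method = "retrain")
  cmp <- compare_models(a, b)
  expect_true(all(is.na(cmp$tests$t_dprime)))
  expect_equal(cmp$tests$n_classes, c(1L, 1L))
})
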