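test_that("per-class splits have the right counts and are seed-stable", {
  ds <- generate_dataset(synthetic_spec(n_classes = 10L, images_per_class = 20L,
                                        image_size = 16L, seed = 2L))
  sp <- split_dataset(ds, train_fraction = 0.9, seed = 4L)
  tr_counts <- table(sp$train$info$class)
  va_counts <- table(sp$validation$info$class)
  expect_true(all(tr_counts == 18L))
  expect_true(all(va_counts == 2L))
  expect_equal(length(sp$test), 0L)
  # disjoint by id, reproducible
  expect_length(intersect(sp$train$info$id, sp$validation$info$id), 0)
  sp2 <- split_dataset(ds, train_fraction = 0.9, seed = 4L)
  expect_setequal(sp$train$info$id, sp2$train$info$id)
  # degenerate split rejected
  expect_error(split_dataset(ds, train_fraction = 1, seed = 1L), "validation")
  # undersized class named in the error
  tiny <- focalgain:::.img_subset(ds, c(1:2, 21:40))
  expect_error(split_dataset(tiny, 0.9, 1L), "1")
})

test_that("epoch samples keep all target images and correct non-targets", {
  ds <- generate_dataset(synthetic_spec(n_classes = 5L, images_per_class = 20L,
                                        image_size = 16L, seed = 3L))
  # only the train member matters to the sampler; use the full pool so every
  # class has exactly 20 training images
  sp <- list(train = ds)
  cfg <- intensity_config(0.5, 5L, target = 1L)
  es <- make_epoch_sample(sp, cfg, fraction = 0.1, seed = 6L)
  expect_equal(nrow(es), 20L + 4L * 2L)       # all targets + 2 of 20 per class
  expect_true(all(es$correction[es$class == 1L] == 1))
  expect_true(all(es$correction[es$class != 1L] == 10))
  # fraction 1 means no subsampling at all
  es_full <- make_epoch_sample(sp, cfg, fraction = 1, seed = 6L)
  expect_equal(nrow(es_full), 100L)
  expect_true(all(es_full$correction == 1))
  # the non-target subsample changes across seeds but not within one
  es_b <- make_epoch_sample(sp, cfg, fraction = 0.1, seed = 7L)
  expect_false(identical(sort(es$id), sort(es_b$id)))
  expect_identical(make_epoch_sample(sp, cfg, 0.1, seed = 6L)$id, es$id)
})

test_that("the one-image floor applies to tiny non-target classes", {
  ds <- generate_dataset(synthetic_spec(n_classes = 3L, images_per_class = 3L,
                                        image_size = 16L, seed = 8L))
  sp <- list(train = ds)
  cfg <- intensity_config(0.5, 3L, target = 1L)
  es <- make_epoch_sample(sp, cfg, fraction = 0.1, seed = 1L)
  nt <- es[es$class != 1L, ]
  expect_equal(nrow(nt), 2L)                   # max(1, round(0.3)) per class
  expect_true(all(nt$correction == 3))
})

test_that("the stopping rule needs two consecutive sub-threshold checks", {
  expect_true(should_stop(c(1.0, 0.9995, 0.99945), 0.001, 2L))
  expect_false(should_stop(c(1.0, 0.9, 0.8995), 0.001, 2L))
  expect_false(should_stop(1.0, 0.001, 2L))
  expect_false(should_stop(c(1.0, 0.9995), 0.001, 2L))  # one check short
  # a worsening loss counts as no improvement
  expect_true(should_stop(c(1.0, 1.01, 1.02), 0.001, 2L))
})

test_that("attention training is reproducible, feasible, and frozen-backbone", {
  w <- small_world()
  snap <- backbone_params(w$backbone)
  cfg <- short_cfg(seed = 21L)
  intensity <- intensity_config(0.6, 5L, target = 2L)
  fit1 <- train_attention(modulated_classifier(w$backbone), w$split,
                          intensity, cfg)
  fit2 <- train_attention(modulated_classifier(w$backbone), w$split,
                          intensity, cfg)
  expect_identical(fit1$weights$values, fit2$weights$values)
  expect_true(all(fit1$weights$values >= 0))
  expect_identical(backbone_params(w$backbone), snap)
  # the log records training loss each epoch and validation at checks
  expect_equal(nrow(fit1$log), fit1$epochs_run)
  expect_true(all(is.finite(fit1$log$train_loss)))
  checks <- fit1$log$epoch %% cfg$check_interval == 0
  expect_true(all(is.finite(fit1$log$val_loss[checks])))
  expect_true(all(is.na(fit1$log$val_loss[!checks])))
  # metadata travels with the weights
  expect_equal(fit1$weights$alpha, 0.6)
  expect_equal(fit1$weights$target, 2L)
  expect_identical(fit1$weights$backbone_id, w$backbone$id)
})

test_that("training requires an all-ones initialisation", {
  w <- small_world()
  g <- attention_weights(insertion_filters(w$backbone),
                         values = rep(0.5, insertion_filters(w$backbone)))
  expect_error(
    train_attention(modulated_classifier(w$backbone, g), w$split,
                    intensity_config(0.5, 5L, 1L), short_cfg()),
    "all ones"
  )
})

test_that("complete target focus raises target hits; control stays put", {
  w <- small_world()
  split <- w$split
  cfg <- train_config(learning_rate = 0.01, max_epochs = 80L,
                      check_interval = 10L, seed = 31L)
  # control: alpha = 1/N leaves behaviour within tolerance of the backbone
  fit_ctl <- train_attention(modulated_classifier(w$backbone), split,
                             intensity_config(1 / 5, 5L, target = 4L), cfg)
  ts <- assemble_standard_testset(split, 4L, seed = 1L)
  m_bb <- sdt_metrics(score_standard(decide(predict(w$backbone, ts)),
                                     ts$info$class, 4L))
  m_ctl <- sdt_metrics(score_standard(
    decide(predict(modulated_classifier(w$backbone, fit_ctl$weights), ts)),
    ts$info$class, 4L
  ))
  expect_lt(abs(m_ctl$dprime - m_bb$dprime), 0.75)
  # complete focus: training hit rate on the target does not drop
  fit1 <- train_attention(modulated_classifier(w$backbone), split,
                          intensity_config(1, 5L, target = 4L), cfg)
  tr <- split$train
  hit0 <- mean(apply(predict(w$backbone, tr), 1, which.max)[tr$info$class == 4L] == 4L)
  hit1 <- mean(apply(predict(modulated_classifier(w$backbone, fit1$weights), tr),
                     1, which.max)[tr$info$class == 4L] == 4L)
  expect_gte(hit1, hit0)
})
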