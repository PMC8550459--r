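test_that("per-image weights match exact arithmetic on the canonical grid", {
  # N = 1000 grid: alpha and the implied non-target weight (1-alpha)/(N-1)
  cases <- list(
    list(alpha = 0.001, nt = 0.999 / 999),   # = 0.001: no selective attention
    list(alpha = 0.002, nt = 0.998 / 999),
    list(alpha = 0.5,   nt = 0.5 / 999),
    list(alpha = 0.999, nt = 0.001 / 999),
    list(alpha = 1,     nt = 0)
  )
  for (cs in cases) {
    cfg <- intensity_config(cs$alpha, 1000L, target = 7L)
    expect_identical(per_image_weight(7L, cfg), cs$alpha)
    expect_equal(per_image_weight(8L, cfg), cs$nt, tolerance = 1e-12)
  }
  # at alpha = 1/N target and non-target weights coincide
  cfg <- intensity_config(1 / 1000, 1000L, target = 7L)
  expect_equal(per_image_weight(7L, cfg), per_image_weight(8L, cfg),
               tolerance = 1e-15)
})

test_that("intensities below uniform weighting are rejected", {
  expect_error(intensity_config(0.0005, 1000L, 1L), "outside")
  expect_error(intensity_config(0.05, 10L, 1L), "outside")
  expect_silent(intensity_config(0.1, 10L, 1L))
  expect_error(intensity_config(0.5, 10L, integer()), "non-empty")
  expect_error(intensity_config(0.5, 10L, 11L), "1..10")
})

test_that("cross-entropy matches the closed form -ln p", {
  expect_identical(cross_entropy(1), 0)
  expect_equal(cross_entropy(0.25), log(4), tolerance = 1e-12)
  expect_equal(cross_entropy(0.5), log(2), tolerance = 1e-12)
  expect_error(cross_entropy(1.5), "greater than 1")
  expect_warning(out <- cross_entropy(c(0.5, 0)), "clamped")
  expect_equal(out[2], -log(1e-12))
})

test_that("weighted batch loss sums weight x correction x CE", {
  cfg1 <- intensity_config(1, 10L, target = 2L)
  expect_equal(weighted_batch_loss(0.5, 2L, cfg1), log(2), tolerance = 1e-12)
  expect_equal(weighted_batch_loss(0.017, 5L, cfg1), 0) # non-target at alpha=1
  # at alpha = 1/N the batch loss is the plain CE sum scaled by 1/N
  cfgU <- intensity_config(0.1, 10L, target = 2L)
  p <- c(0.9, 0.4, 0.25, 0.6)
  lab <- c(2L, 5L, 7L, 2L)
  expect_equal(weighted_batch_loss(p, lab, cfgU),
               sum(-log(p)) / 10, tolerance = 1e-12)
  expect_error(weighted_batch_loss(c(0.5, 0.5), 2L, cfg1), "length mismatch")
})

test_that("subsample correction is the inverse sampling fraction", {
  expect_equal(subsample_correction(20, 2), 10)
  expect_equal(subsample_correction(15, 2), 7.5)
  expect_equal(subsample_correction(7, 7), 1)
  expect_error(subsample_correction(10, 0), "at least 1")
  expect_error(subsample_correction(10, 11), "exceed")
})

test_that("class mass is conserved and weights are monotone in alpha", {
  for (N in c(5L, 10L, 1000L)) {
    alphas <- sort(unique(c(alpha_grid(N), runif(20, 1 / N, 1))))
    prev_t <- -Inf; prev_nt <- Inf
    for (a in alphas) {
      cfg <- intensity_config(a, N, target = 1L)
      wt <- per_image_weight(1L, cfg)
      wn <- per_image_weight(2L, cfg)
      expect_equal(wt + (N - 1) * wn, 1, tolerance = 1e-12)
      expect_gte(wt, prev_t)
      expect_lte(wn, prev_nt)
      prev_t <- wt; prev_nt <- wn
    }
  }
})

test_that("at alpha = 1/N the gain gradient is the uniform-CE gradient / N", {
  w <- small_world()
  bb <- w$backbone
  imgs <- focalgain:::.img_subset(w$split$train, 1:8)
  acts <- insertion_activations(bb, imgs)
  tc <- focalgain:::.tail_cache(bb, acts)
  g <- focalgain:::.with_seed(4, runif(insertion_filters(bb), 0.5, 1.5))
  fw <- focalgain:::.tail_run(bb, tc, 1:8, g, keep = TRUE)
  lab <- imgs$info$class
  y <- matrix(0, bb$n_classes, 8); y[cbind(lab, 1:8)] <- 1
  resid <- fw$probs - y
  grad_w <- focalgain:::.tail_grad_gain(bb, tc, fw$cache, resid * (1 / 5), g)
  grad_u <- focalgain:::.tail_grad_gain(bb, tc, fw$cache, resid, g)
  nw <- grad_w / sqrt(sum(grad_w^2))
  nu <- grad_u / sqrt(sum(grad_u^2))
  expect_lt(max(abs(nw - nu)), 1e-5)
  expect_equal(grad_w, grad_u / 5, tolerance = 1e-12)
})

test_that("corrected subsampled loss is unbiased for the full-data loss", {
  # fixed tiny dataset: 5 classes x 20 images with fixed fake probabilities
  set.seed(42)
  labels <- rep(1:5, each = 20)
  probs <- runif(100, 0.05, 0.95)
  cfg <- intensity_config(0.5, 5L, target = 2L)
  full <- weighted_batch_loss(probs, labels, cfg)
  class_idx <- split(seq_along(labels), labels)
  n_rep <- 2000L
  draws <- vapply(seq_len(n_rep), function(r) {
    es <- focalgain:::.epoch_sample_idx(class_idx, 2L, 0.1, seed = r)
    weighted_batch_loss(probs[es$index], labels[es$index], cfg,
                        es$correction)
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(n_rep)
  expect_lt(abs(mean(draws) - full), 2 * se + 1e-12)
})
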