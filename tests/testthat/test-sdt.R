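test_that("the max decision rule picks top-k with index tie-breaking", {
  expect_identical(decide(c(0.1, 0.7, 0.2)), 2L)
  expect_identical(decide(c(0.4, 0.4, 0.2)), 1L)        # tie -> lowest index
  expect_identical(decide(c(0.5, 0.3, 0.2), k = 2), c(1L, 2L))
  expect_identical(sort(decide(c(0.2, 0.3, 0.5), k = 3)), 1:3)  # k = N
  expect_error(decide(c(0.5, 0.5), k = 3), "exceeds")
  expect_error(decide(c(0.5, 0.2)), "sum to 1")
  # matrix input: one row per image
  m <- rbind(c(0.1, 0.7, 0.2), c(0.4, 0.4, 0.2))
  expect_identical(decide(m), matrix(c(2L, 1L), 2, 1))
})

test_that("standard scoring implements target-detection semantics", {
  # perfect detector
  c1 <- score_standard(c(rep(1L, 10), rep(2L, 10)),
                       c(rep(1L, 10), rep(2L, 10)), target = 1L)
  expect_equal(unlist(c1[1:4], use.names = FALSE), c(10L, 0L, 0L, 10L))
  # always-yes detector
  c2 <- score_standard(rep(1L, 20), c(rep(1L, 10), rep(2L, 10)), target = 1L)
  expect_equal(unlist(c2[1:4], use.names = FALSE), c(10L, 0L, 10L, 0L))
  # toy enumeration: predictions equal labels on {target, other, other}
  c3 <- score_standard(c(1L, 2L, 3L), c(1L, 2L, 3L), target = 1L)
  expect_equal(unlist(c3[1:4], use.names = FALSE), c(1L, 0L, 0L, 2L))
  # count conservation
  expect_equal(c3$hits + c3$misses, 1L)
  expect_equal(c3$false_alarms + c3$correct_rejections, 2L)
  expect_error(score_standard(1L, c(1L, 2L), 1L), "length mismatch")
})

test_that("blended scoring treats either ground-truth label as presence", {
  pairs <- rbind(c(1L, 2L), c(3L, 1L), c(2L, 3L), c(4L, 5L))
  preds <- c(1L, 2L, 1L, 4L)
  cc <- score_blended(preds, pairs, target = 1L)
  # trial 1: present & predicted -> hit; trial 2: present, chose other -> miss
  # trial 3: absent & predicted target -> FA; trial 4: absent, other -> CR
  expect_equal(unlist(cc[1:4], use.names = FALSE), c(1L, 1L, 1L, 1L))
  expect_error(score_blended(1L, rbind(c(2L, 2L)), 1L), "distinct")
})

test_that("rates apply the 1/(2n) extreme-score correction", {
  r <- rates(confusion_counts(10, 0, 0, 10))
  expect_equal(unname(r), c(0.95, 0.05))
  expect_equal(unname(rates(confusion_counts(5, 5, 5, 5))), c(0.5, 0.5))
  expect_equal(unname(rates(confusion_counts(8, 2, 3, 7))), c(0.8, 0.3))
  expect_error(rates(confusion_counts(0, 0, 1, 1)), "at least one")
})

test_that("d-prime and criterion match the inverse-normal oracle", {
  # frozen oracle values: z(0.84) = 0.994458, z(0.16) = -0.994458,
  # z(0.9) = 1.281552
  expect_equal(dprime(0.84, 0.16), 1.988917, tolerance = 1e-4)
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(criterion_location(0.84, 0.16), 0, tolerance = 1e-12)
  expect_equal(criterion_location(0.9, 0.5), -0.640776, tolerance = 1e-4)
  expect_equal(criterion_location(0.5, 0.5), 0)
  expect_error(dprime(1, 0.5), "strictly inside")
  # antisymmetry
  for (i in 1:20) {
    hf <- focalgain:::.with_seed(i, runif(2, 0.01, 0.99))
    expect_equal(dprime(hf[1], hf[2]), -dprime(hf[2], hf[1]),
                 tolerance = 1e-12)
  }
})

test_that("d-prime is monotone in H and F; criterion decreasing in both", {
  grid <- seq(0.05, 0.95, by = 0.09)
  for (Fr in grid) {
    d <- vapply(grid, function(h) dprime(h, Fr), numeric(1))
    expect_true(all(diff(d) > 0))      # increasing in H at fixed F
    cc <- vapply(grid, function(h) criterion_location(h, Fr), numeric(1))
    expect_true(all(diff(cc) < 0))     # decreasing in H
  }
  for (H in grid) {
    d <- vapply(grid, function(f) dprime(H, f), numeric(1))
    expect_true(all(diff(d) < 0))      # decreasing in F at fixed H
    cc <- vapply(grid, function(f) criterion_location(H, f), numeric(1))
    expect_true(all(diff(cc) < 0))     # decreasing in F
  }
})

test_that("sweep statistics reproduce the expected degrees of freedom", {
  m <- matrix(focalgain:::.with_seed(1, rnorm(200 * 5, mean = 2)),
              200, 5, dimnames = list(NULL, letters[1:5]))
  s <- sweep_statistics(m)
  expect_equal(s$anova_df, c(4L, 995L))
  expect_equal(s$paired_df, 199L)
  expect_true(is.finite(s$anova_F))
  expect_true(is.finite(s$paired_t))
  # cross-check the ANOVA F against aov directly
  long <- data.frame(d = as.vector(m), g = factor(rep(letters[1:5], each = 200)))
  F_ref <- summary(stats::aov(d ~ g, data = long))[[1]]$`F value`[1]
  expect_equal(s$anova_F, F_ref, tolerance = 1e-10)
})

test_that("degenerate sweep matrices are flagged, not raised", {
  s0 <- sweep_statistics(matrix(1, 3, 3))
  expect_true(is.na(s0$anova_F))
  expect_true("anova_no_variance" %in% s0$flags)
  # aov warns on an essentially perfect fit; only the flagging matters here
  s1 <- suppressWarnings(sweep_statistics(matrix(c(1, 1, 2, 2), 2, 2)))
  expect_true(is.na(s1$paired_t))
  expect_true("paired_t_no_variance" %in% s1$flags)
  expect_error(sweep_statistics(matrix(1, 1, 5)), "at least 2")
})
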