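make_img <- function(val, label, id = paste0("i", label), size = 8L) {
  labeled_image(array(val, c(size, size, 3L)), label, id)
}

test_that("blending mixes pixels exactly and keeps both labels", {
  a <- make_img(0, 1L); b <- make_img(1, 2L)
  bl <- blend(a, b)
  expect_true(all(bl$pixels == 0.5))
  expect_equal(c(bl$label_a, bl$label_b), c(1L, 2L))
  # symmetry at mix 0.5
  expect_equal(blend(a, b)$pixels, blend(b, a)$pixels)
  # equal inputs blend to themselves
  x <- focalgain:::.with_seed(2, array(runif(8 * 8 * 3), c(8, 8, 3)))
  expect_equal(blend(labeled_image(x, 1L), labeled_image(x, 2L))$pixels, x)
  # general mix
  bl2 <- blend(a, b, mix = 0.25)
  expect_true(all(bl2$pixels == 0.75))
  # range invariant under random inputs
  y <- focalgain:::.with_seed(3, array(runif(8 * 8 * 3), c(8, 8, 3)))
  bl3 <- blend(labeled_image(x, 1L), labeled_image(y, 2L))
  expect_true(all(bl3$pixels >= 0 & bl3$pixels <= 1))
  expect_lte(mean(bl3$pixels), max(mean(x), mean(y)))
})

test_that("blend rejects mismatched dimensions and identical labels", {
  expect_error(blend(make_img(0, 1L), make_img(1, 2L, size = 4L)),
               "dimensions differ")
  expect_error(blend(make_img(0, 1L), make_img(1, 1L)), "distinct")
})

test_that("standard test sets are balanced and deterministic", {
  w <- small_world()
  ts <- assemble_standard_testset(w$split, target = 2L, seed = 7L)
  n_t <- sum(ts$info$class == 2L)
  expect_equal(n_t, sum(w$split$test$info$class == 2L))
  expect_equal(sum(ts$info$class != 2L), n_t)
  ts2 <- assemble_standard_testset(w$split, target = 2L, seed = 7L)
  expect_identical(ts$info$id, ts2$info$id)
  ts3 <- assemble_standard_testset(w$split, target = 2L, seed = 8L)
  expect_false(identical(ts$info$id, ts3$info$id))
})

test_that("standard test set refuses an infeasible balance", {
  w <- small_world()
  # target = 4 of the 5 classes: non-target pool too small to balance
  expect_error(assemble_standard_testset(w$split, target = 1:4, seed = 1L),
               "not enough non-target")
})

test_that("blended test sets are balanced, distinct-labelled, deterministic", {
  w <- small_world()
  bs <- assemble_blended_testset(w$split, target = 3L, n_per_side = 5L,
                                 seed = 11L)
  expect_equal(nrow(bs$info), 10L)
  present <- (bs$info$label_a == 3L) | (bs$info$label_b == 3L)
  expect_equal(sum(present), 5L)
  expect_identical(present, bs$info$target_present)
  expect_true(all(bs$info$label_a != bs$info$label_b))
  expect_true(all(bs$images >= 0 & bs$images <= 1))
  bs2 <- assemble_blended_testset(w$split, target = 3L, n_per_side = 5L,
                                  seed = 11L)
  expect_identical(bs$info, bs2$info)
  expect_identical(bs$images, bs2$images)
  expect_error(
    assemble_blended_testset(w$split, target = 3L, n_per_side = 1000L,
                             seed = 1L),
    "target test images"
  )
})

test_that("the challenge-set loader reads, maps, scales and skips", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "cats"))
  dir.create(file.path(root, "dogs"))
  dir.create(file.path(root, "unknown"))
  img <- focalgain:::.with_seed(5, array(runif(16 * 16 * 3), c(16, 16, 3)))
  for (i in 1:3) {
    png::writePNG(img, file.path(root, "cats", sprintf("c%d.png", i)))
    png::writePNG(img * 0.5, file.path(root, "dogs", sprintf("d%d.png", i)))
  }
  png::writePNG(img, file.path(root, "unknown", "u.png"))
  writeLines("not an image", file.path(root, "cats", "notes.txt"))
  expect_warning(
    expect_warning(
      cs <- load_challenge_set(root, c(cats = 1L, dogs = 2L)),
      "unmapped"
    ),
    "non-image"
  )
  expect_s3_class(cs, "image_set")
  expect_equal(length(cs), 6L)
  expect_equal(sort(unique(cs$info$class)), c(1L, 2L))
  expect_true(all(cs$images >= 0 & cs$images <= 1))
  # resampling to a backbone-compatible size
  cs8 <- suppressWarnings(load_challenge_set(root, c(cats = 1L, dogs = 2L),
                                             size = 8L))
  expect_equal(dim(cs8$images)[1:2], c(8L, 8L))
  expect_error(load_challenge_set(file.path(root, "missing"), c(cats = 1L)),
               "does not exist")
})
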