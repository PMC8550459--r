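# Shared fixtures, built lazily and memoised for the session so expensive
# objects (trained worlds, reference sweeps) are constructed at most once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A tiny untrained backbone for mechanical tests (shapes, gradients, I/O).
tiny_backbone <- function(n_classes = 5L, image_size = 16L, seed = 3L) {
  build_fixture_backbone(n_classes, image_size, filters = c(4L, 6L, 8L),
                         seed = seed)
}

# A tiny image set matching tiny_backbone's input contract.
tiny_images <- function(n = 6L, image_size = 16L, n_classes = 5L, seed = 9L) {
  imgs <- focalgain:::.with_seed(seed, {
    array(stats::runif(image_size * image_size * 3 * n),
          c(image_size, image_size, 3L, n))
  })
  new_image_set(imgs, tibble::tibble(
    id = sprintf("img%02d", seq_len(n)),
    class = rep_len(seq_len(n_classes), n),
    class_name = sprintf("c%d", rep_len(seq_len(n_classes), n))
  ))
}

# A small but real world: 5 classes, enough images to train on, cheap
# backbone. Used by trainer/baseline tests.
small_world <- function() {
  memo("small_world", {
    spec <- synthetic_spec(n_classes = 5L, images_per_class = 24L,
                           image_size = 16L, seed = 5L)
    ds <- generate_dataset(spec)
    split <- split_dataset(ds, train_fraction = 0.9, seed = 5L,
                           test_fraction = 0.25)
    bb <- build_fixture_backbone(5L, 16L, filters = c(6L, 10L, 12L), seed = 5L)
    bb <- train_backbone(bb, split$train, split$validation, epochs = 25L,
                         seed = 5L)
    list(spec = spec, split = split, backbone = bb)
  })
}

# Short attention-training configuration for mechanics tests.
short_cfg <- function(seed = 1L, max_epochs = 12L) {
  train_config(learning_rate = 0.01, max_epochs = max_epochs,
               check_interval = 2L, seed = seed)
}

# The full-scale fixture world and reference sweep used by the acceptance
# tests (the study conditions: K = 10 world, converged backbone,
# fixture-scale attention training regime).
reference_world <- function() {
  memo("reference_world", {
    prepare_fixture_world(synthetic_spec(), seed = 1L, backbone_epochs = 80L)
  })
}

reference_sweep <- function() {
  memo("reference_sweep", {
    run_reference_sweep(world = reference_world(), seed = 1L)
  })
}
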