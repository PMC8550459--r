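#' Run a full experiment from a configuration file
#'
#' Configuration-driven front end over the whole pipeline: build the fixture
#' world (or reuse a cached backbone), sweep attention models over the
#' intensity grid and target classes, optionally run the retrain-final-layer
#' baseline, and write a deterministic results tree:
#'
#' ```
#' out_dir/
#'   manifest.json            config hash, seed, dimensions
#'   config.yaml              the normalised configuration
#'   backbone.json            trained backbone checkpoint
#'   weights/t<k>_a<alpha>.json   attention weights per cell
#'   results/standard.csv     one row per (target, alpha)
#'   results/blended.csv
#'   analytics/weights.csv    variance and zeroed count per cell
#'   analytics/adjacent_rho.csv
#'   sweep_stats.json
#'   comparison.csv           (when the baseline is enabled)
#' ```
#'
#' Rerunning with the same configuration and seed reproduces identical
#' result files. With `resume = TRUE`, (target, alpha) cells whose weight
#' artifacts already exist are loaded instead of retrained.
#'
#' @param config Path to a YAML file, or an equivalent named list. Fields:
#'   `seed`; `fixture` (`n_classes`, `images_per_class`, `image_size`,
#'   `noise_sd`, `similarity`); optional `alphas` (all must be `>= 1/N`),
#'   `targets`, `backbone_epochs`, `train` (see [train_config()]), `eval`
#'   (`n_blend_per_side`, `top_k`), `baseline` (`enabled`, `alphas`).
#' @param out_dir Output directory (created if missing).
#' @param resume Reuse existing per-cell weight artifacts.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the attention `sweep`, optional
#'   `baseline` sweep and `comparison`, and the output paths.
#' @export
run_experiment <- function(config, out_dir, resume = FALSE, verbose = FALSE) {
  cfg <- .load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("weights", "results", "analytics")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  spec <- synthetic_spec(
    n_classes = cfg$fixture$n_classes,
    images_per_class = cfg$fixture$images_per_class,
    image_size = cfg$fixture$image_size,
    noise_sd = cfg$fixture$noise_sd,
    similarity = cfg$fixture$similarity,
    seed = cfg$seed
  )
  world <- prepare_fixture_world(spec, seed = cfg$seed,
                                 backbone_epochs = cfg$backbone_epochs,
                                 verbose = verbose)
  write_backbone(world$backbone, file.path(out_dir, "backbone.json"))

  tc <- do.call(train_config, cfg$train)
  sweep <- run_reference_sweep(
    world = world, alphas = cfg$alphas, targets = cfg$targets,
    seed = cfg$seed, method = "attention", train_cfg = tc,
    n_blend_per_side = cfg$eval$n_blend_per_side, top_k = cfg$eval$top_k,
    cache_dir = if (resume) file.path(out_dir, "weights") else NULL,
    verbose = verbose
  )
  for (key in names(sweep$weights)) {
    write_attention_weights(sweep$weights[[key]],
                            file.path(out_dir, "weights", paste0(key, ".json")))
  }
  std <- dplyr::filter(sweep$metrics, .data$testset == "standard")
  bld <- dplyr::filter(sweep$metrics, .data$testset == "blended")
  utils::write.csv(std, file.path(out_dir, "results", "standard.csv"),
                   row.names = FALSE)
  utils::write.csv(bld, file.path(out_dir, "results", "blended.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$weight_stats,
                   file.path(out_dir, "analytics", "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$adjacent_rho,
                   file.path(out_dir, "analytics", "adjacent_rho.csv"),
                   row.names = FALSE)
  stats_out <- list(
    standard = if (!is.null(sweep$stats)) unclass(sweep$stats),
    blended = if (!is.null(sweep$stats_blended)) unclass(sweep$stats_blended)
  )

  baseline <- NULL
  comparison <- NULL
  if (isTRUE(cfg$baseline$enabled)) {
    baseline <- run_reference_sweep(
      world = world, alphas = cfg$baseline$alphas, targets = cfg$targets,
      seed = cfg$seed, method = "retrain", train_cfg = tc,
      n_blend_per_side = cfg$eval$n_blend_per_side, top_k = cfg$eval$top_k,
      verbose = verbose
    )
    att_sub <- sweep
    att_sub$metrics <- dplyr::filter(sweep$metrics,
                                     .data$alpha %in% cfg$baseline$alphas)
    comparison <- compare_models(att_sub, baseline)
    utils::write.csv(comparison$differences,
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }

  jsonlite::write_json(stats_out, file.path(out_dir, "sweep_stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = cfg$seed,
         n_targets = length(sweep$targets), alphas = sweep$alphas,
         method = "attention", baseline = isTRUE(cfg$baseline$enabled)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(sweep = sweep, baseline = baseline,
                 comparison = comparison, out_dir = out_dir,
                 config_hash = cfg_hash))
}

# Validate and normalise a configuration, raising errors that name the field.
.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  need_num <- function(x, field, lo = -Inf, hi = Inf) {
    if (is.null(x) || !is.numeric(x) || any(x < lo) || any(x > hi)) {
      stop(sprintf("config field `%s` is missing or out of range", field))
    }
    x
  }
  cfg <- list()
  cfg$seed <- as.integer(need_num(config$seed %||% 1L, "seed", 0))
  fx <- config$fixture %||% list()
  cfg$fixture <- list(
    n_classes = as.integer(need_num(fx$n_classes %||% 10L, "fixture.n_classes", 2)),
    images_per_class = as.integer(need_num(fx$images_per_class %||% 60L,
                                           "fixture.images_per_class", 6)),
    image_size = as.integer(need_num(fx$image_size %||% 32L,
                                     "fixture.image_size", 8)),
    noise_sd = need_num(fx$noise_sd %||% 0.05, "fixture.noise_sd", 0),
    similarity = need_num(fx$similarity %||% 0, "fixture.similarity", 0, 1)
  )
  cfg$backbone_epochs <- as.integer(need_num(config$backbone_epochs %||% 80L,
                                             "backbone_epochs", 1))
  N <- cfg$fixture$n_classes
  cfg$alphas <- if (is.null(config$alphas)) alpha_grid(N) else {
    a <- need_num(config$alphas, "alphas", 0, 1)
    bad <- a[a < 1 / N - 1e-12]
    if (length(bad) > 0L) {
      stop(sprintf(
        "config field `alphas`: value(s) %s below 1/N = %g are not allowed (no anti-attention to the target)",
        paste(signif(bad, 4), collapse = ", "), 1 / N
      ))
    }
    a
  }
  cfg$targets <- if (is.null(config$targets)) seq_len(N) else {
    as.integer(need_num(config$targets, "targets", 1, N))
  }
  tr <- config$train %||% list()
  ok_train <- c("learning_rate", "batch_size", "max_epochs",
                "nontarget_fraction", "check_interval",
                "rel_improve_threshold", "consecutive_checks_to_stop",
                "train_fraction")
  extra <- setdiff(names(tr), ok_train)
  if (length(extra) > 0L) {
    stop("unknown config field(s) under `train`: ", paste(extra, collapse = ", "))
  }
  cfg$train <- tr
  ev <- config$eval %||% list()
  cfg$eval <- list(
    n_blend_per_side = as.integer(need_num(ev$n_blend_per_side %||% 10L,
                                           "eval.n_blend_per_side", 1)),
    top_k = as.integer(need_num(ev$top_k %||% 1L, "eval.top_k", 1, N))
  )
  bl <- config$baseline %||% list()
  cfg$baseline <- list(
    enabled = isTRUE(bl$enabled),
    alphas = if (is.null(bl$alphas)) 0.5 else need_num(bl$alphas,
                                                       "baseline.alphas",
                                                       1 / N, 1)
  )
  cfg
}
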