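# End-to-end pipeline: phantom generation -> training -> evaluation, with
# a YAML run configuration, JSON reports, logs and checkpoints in a run
# directory. Also the on-disk pair format: 16-bit TIFF source/target, PNG
# mask, JSON sidecar with the generating configuration.

#' Write / read an image pair on disk
#'
#' `write_pair()` stores `<prefix>_source.tiff` and `<prefix>_target.tiff`
#' (16-bit), `<prefix>_mask.png` when a rib mask is present, and a
#' `<prefix>_meta.json` sidecar recording the pixel range and any phantom
#' configuration.
#'
#' @param pair An [image_pair()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param config Optional [phantom_config()] recorded in the sidecar.
#' @return The prefix path, invisibly.
#' @export
write_pair <- function(pair, dir, prefix = "pair", config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p01 <- pair_normalize(pair, c(0, 1))
  base <- file.path(dir, prefix)
  write_image(p01$source, paste0(base, "_source.tiff"), bit_depth = 16L)
  write_image(p01$target, paste0(base, "_target.tiff"), bit_depth = 16L)
  if (!is.null(pair$rib_mask))
    png::writePNG(pair$rib_mask + 0, paste0(base, "_mask.png"))
  meta <- list(pixel_range = pair$pixel_range,
               has_mask = !is.null(pair$rib_mask))
  if (!is.null(config)) meta$phantom_config <- unclass(config)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_pair
#' @export
read_pair <- function(dir, prefix = "pair") {
  base <- file.path(dir, prefix)
  meta_path <- paste0(base, "_meta.json")
  if (!file.exists(meta_path))
    rc_abort(sprintf("pair sidecar not found: %s", meta_path), "ribclear_io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  src <- read_image(paste0(base, "_source.tiff"))
  tgt <- read_image(paste0(base, "_target.tiff"))
  msk <- if (isTRUE(meta$has_mask))
    png::readPNG(paste0(base, "_mask.png")) > 0.5
  pr <- image_pair(src, tgt, rib_mask = msk, pixel_range = c(0, 1))
  rng <- as.numeric(meta$pixel_range %||% c(0, 1))
  if (!isTRUE(all.equal(rng, c(0, 1)))) pr <- pair_normalize(pr, rng)
  pr
}

#' @rdname write_pair
#' @param pairs List of pairs to write (`pair_0001`, `pair_0002`, ...).
#' @export
write_pair_dataset <- function(pairs, dir, config = NULL) {
  for (i in seq_along(pairs))
    write_pair(pairs[[i]], dir, sprintf("pair_%04d", i), config = config)
  invisible(dir)
}

#' @rdname write_pair
#' @export
read_pair_dataset <- function(dir) {
  metas <- sort(list.files(dir, pattern = "_meta\\.json$", full.names = FALSE))
  if (length(metas) == 0L)
    rc_abort(sprintf("no image pairs found in %s", dir), "ribclear_io_error")
  lapply(sub("_meta\\.json$", "", metas), function(px) read_pair(dir, px))
}

#' Assemble a run configuration
#'
#' Bundles the sub-configurations of a full experiment. Validation checks
#' every sub-config and that referenced paths exist.
#'
#' @param phantom A [phantom_config()].
#' @param model A [model_spec()] (`cdae`, `unet` or `gan_generator`; the
#'   critic is derived automatically for the GAN).
#' @param train A [train_config()].
#' @param loss A loss name or [loss_config()].
#' @param n_pairs Number of phantom pairs to generate.
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param data_dir Optional directory of existing pairs (used instead of
#'   phantom generation; must exist at validation time).
#' @param n_test Held-out pairs for evaluation.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `ribclear_run_config`.
#' @export
run_config <- function(phantom = phantom_config(image_size = 32L),
                       model = model_spec("cdae", input_size = 32L, depth = 2L,
                                          base_filters = 4L),
                       train = train_config(epochs = 2L, batch_size = 4L),
                       loss = "L1", n_pairs = 12L, out_dir = tempfile("run_"),
                       data_dir = NULL, n_test = 4L, log_level = "info") {
  if (is.character(loss)) loss <- loss_config(loss)
  check_number(n_pairs, "n_pairs", min = 2, integerish = TRUE)
  check_number(n_test, "n_test", min = 1, integerish = TRUE)
  if (n_test >= n_pairs)
    rc_abort("`n_test` must be smaller than `n_pairs`", "ribclear_config_error")
  if (!is.null(data_dir) && !dir.exists(data_dir))
    rc_abort(sprintf("`data_dir` does not exist: %s", data_dir),
             "ribclear_config_error")
  if (model$family == "gan_critic")
    rc_abort("`model` must be a generator-side family", "ribclear_config_error")
  if (phantom$image_size != model$input_size)
    rc_abort("phantom image_size must equal model input_size",
             "ribclear_config_error")
  structure(list(phantom = phantom, model = model, train = train, loss = loss,
                 n_pairs = as.integer(n_pairs), out_dir = out_dir,
                 data_dir = data_dir, n_test = as.integer(n_test),
                 log_level = log_level),
            class = "ribclear_run_config")
}

.run_log <- function(con, level, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  writeLines(line, con)
  if (identical(level, "info")) message(line)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Generates (or loads) paired data, trains the configured model, applies
#' it to held-out pairs, and writes the run directory: `config.yaml`,
#' `log.txt`, `history.json`, `checkpoint.rds`, `metrics.json` and
#' `region_report.json`. Any stage failure raises a stage-tagged error
#' after logging it.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "ribclear_run_config"))
    rc_abort("`config` must be a run_config", "ribclear_config_error")
  if (!is.null(config$data_dir) && !dir.exists(config$data_dir))
    rc_abort(sprintf("`data_dir` vanished before the run started: %s",
                     config$data_dir), "ribclear_config_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "log.txt"), open = "wt")
  on.exit(close(logf), add = TRUE)
  lg <- function(stage, msg) .run_log(logf, config$log_level, stage, msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      lg(name, paste("FAILED:", conditionMessage(e)))
      rc_abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
               "ribclear_pipeline_error")
    })
  }
  lg("setup", sprintf("ribclear %s on R %s",
                      utils::packageVersion("ribclear"),
                      getRversion()))
  yaml::write_yaml(.config_to_list(config), file.path(config$out_dir, "config.yaml"))

  pairs <- stage("data", {
    if (is.null(config$data_dir)) {
      lg("data", sprintf("generating %d phantom pairs (size %d, seed %d)",
                         config$n_pairs, config$phantom$image_size,
                         config$phantom$seed))
      generate_dataset(config$phantom, config$n_pairs)
    } else {
      lg("data", sprintf("loading pairs from %s", config$data_dir))
      read_pair_dataset(config$data_dir)
    }
  })
  adversarial <- config$model$family == "gan_generator"
  if (adversarial) pairs <- lapply(pairs, pair_normalize, to = c(-1, 1))
  test_idx <- seq(length(pairs) - config$n_test + 1L, length(pairs))
  test_pairs <- pairs[test_idx]
  train_pairs <- pairs[-test_idx]

  fit <- stage("train", {
    if (adversarial) {
      critic <- build_critic(.critic_spec_from(config$model),
                             seed = config$train$seed + 1L)
      gen <- build_generator(config$model, seed = config$train$seed)
      w <- if (config$loss$kind == "adversarial") config$loss$weights
           else composite_weights()
      ex <- if (w$beta_perc > 0)
        make_random_extractor(in_ch = config$model$input_channels,
                              seed = config$train$seed + 2L)
      cfga <- config$train; cfga$normalization <- c(-1, 1)
      class(cfga) <- class(config$train)
      lg("train", sprintf("adversarial training, %d epochs, loss %s",
                          cfga$epochs, config$loss$name))
      train_adversarial(gen, critic, train_pairs, weights = w, cfg = cfga,
                        extractor = ex)
    } else {
      builder <- if (config$model$family == "cdae") build_cdae else build_unet
      model <- builder(config$model, seed = config$train$seed)
      lg("train", sprintf("supervised training, %d epochs, loss %s",
                          config$train$epochs, config$loss$name))
      train_supervised(model, train_pairs, loss = config$loss,
                       cfg = config$train)
    }
  })
  stage("report", {
    hist <- if (inherits(fit, "ribclear_gan_fit")) fit$history else fit$history
    jsonlite::write_json(hist, file.path(config$out_dir, "history.json"),
                         digits = NA)
    model <- if (adversarial) fit$gen else fit$model
    save_checkpoint(model, file.path(config$out_dir, "checkpoint.rds"),
                    history = hist)
    preds <- suppress_bones(model, test_pairs)
    rep01 <- metric_report(test_pairs, preds)
    jsonlite::write_json(.report_to_list(rep01),
                         file.path(config$out_dir, "metrics.json"),
                         digits = NA)
    t01 <- lapply(test_pairs, pair_normalize, to = c(0, 1))
    p01 <- lapply(seq_along(preds), function(i)
      normalize_range(preds[[i]], test_pairs[[i]]$pixel_range, c(0, 1)))
    rr <- region_analysis(t01[[1]]$source, t01[[1]]$target, p01[[1]])
    jsonlite::write_json(.region_to_list(rr),
                         file.path(config$out_dir, "region_report.json"),
                         digits = NA)
    lg("report", sprintf("held-out MS-SSIM %.4f, PSNR %s dB",
                         glance(rep01)$mean_ms_ssim,
                         .inf_str(glance(rep01)$mean_psnr_db)))
  })
  lg("done", config$out_dir)
  invisible(config$out_dir)
}

# swap a generator-side spec into its critic counterpart
.critic_spec_from <- function(spec) {
  s2 <- unclass(spec)
  s2$family <- "gan_critic"
  s2$output_activation <- "linear"
  s2$normalization <- "batch"
  s2$backbone <- NULL
  do.call(model_spec, s2)
}

.inf_str <- function(x) if (is.infinite(x)) "inf" else sprintf("%.3f", x)

.config_to_list <- function(config) {
  list(phantom = unclass(config$phantom),
       model = unclass(config$model)[!vapply(unclass(config$model), is.function, logical(1))],
       train = unclass(config$train),
       loss = list(name = config$loss$name, kind = config$loss$kind),
       n_pairs = config$n_pairs, n_test = config$n_test,
       data_dir = config$data_dir, out_dir = config$out_dir)
}

.report_to_list <- function(rep) {
  per <- rep$per_image
  per$psnr_db <- ifelse(is.infinite(per$psnr_db), "inf",
                        as.character(per$psnr_db))
  agg <- rep$aggregate
  agg$mean <- ifelse(is.infinite(agg$mean), "inf", as.character(agg$mean))
  list(per_image = per, aggregate = agg, n = rep$n)
}

.region_to_list <- function(rr) {
  list(mae_bone = rr$mae_bone, mae_nonbone = rr$mae_nonbone,
       mae_total = rr$mae_total, n_bone = rr$n_bone, n_nonbone = rr$n_nonbone,
       edge_error_bone = rr$edge_error_bone, threshold_used = rr$threshold_used,
       no_bone_signal = rr$no_bone_signal)
}

#' Plot an image pair
#' @param object An [image_pair()].
#' @param ... Unused.
#' @return A ggplot showing source, target and (if present) the rib mask.
#' @export
autoplot.ribclear_image_pair <- function(object, ...) {
  pnl <- function(m, what) tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m), panel = what)
  df <- dplyr::bind_rows(pnl(object$source, "source"),
                         pnl(object$target, "target"))
  if (!is.null(object$rib_mask))
    df <- dplyr::bind_rows(df, pnl(object$rib_mask + 0, "rib mask"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
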