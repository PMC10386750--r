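# Versioned JSON checkpoints for trained models. Numeric parameters are
# stored flat (column-major) alongside their dimensions, full precision.

CHECKPOINT_VERSION <- 1L

pack_array <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
  else list(dim = length(x), data = as.numeric(x))
}

unpack_array <- function(p) {
  d <- unlist(p$dim)
  x <- as.numeric(unlist(p$data))
  if (length(d) == 2) matrix(x, d[1], d[2]) else x
}

#' Save / load a trained model checkpoint
#'
#' Writes an `hr_corrector` or `rr_detector` to a versioned JSON file
#' (format: `type`, `version`, `config`, flattened numeric parameter arrays
#' with their dimensions, normalisation statistics and the training log).
#'
#' @param model An `hr_corrector` or `rr_detector`.
#' @param path Checkpoint path (`.json`).
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the
#'   reconstructed model.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "hr_corrector")) {
    obj <- list(type = "hr_corrector", version = CHECKPOINT_VERSION,
                config = unclass(model$config),
                params = lapply(model$params, pack_array),
                centers = as.list(model$centers),
                scales = as.list(model$scales),
                y_center = model$y_center, y_scale = model$y_scale,
                log = model$log)
  } else if (inherits(model, "rr_detector")) {
    obj <- list(type = "rr_detector", version = CHECKPOINT_VERSION,
                config = unclass(model$config),
                params = lapply(model$params, pack_array),
                bn = model$bn, global_mean = model$global_mean,
                global_sd = model$global_sd, log = model$log)
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$version) || obj$version != CHECKPOINT_VERSION) {
    stop(sprintf("unsupported checkpoint version in %s", path))
  }
  params <- lapply(obj$params, unpack_array)
  if (obj$type == "hr_corrector") {
    cfg <- obj$config
    structure(list(
      params = params,
      config = structure(list(
        layer_widths = unlist(cfg$layer_widths),
        dropout_rates = unlist(cfg$dropout_rates), eta = cfg$eta,
        eps = cfg$eps, epochs = cfg$epochs, batch_size = cfg$batch_size,
        prelu_init = cfg$prelu_init, seed = cfg$seed,
        input_dim = cfg$input_dim), class = "correction_net_config"),
      centers = unlist(obj$centers), scales = unlist(obj$scales),
      y_center = obj$y_center, y_scale = obj$y_scale,
      log = as.data.frame(do.call(rbind, lapply(obj$log, as.data.frame)))),
      class = "hr_corrector")
  } else if (obj$type == "rr_detector") {
    cfg <- obj$config
    structure(list(
      params = params,
      bn = lapply(obj$bn, function(v) as.numeric(unlist(v))),
      global_mean = obj$global_mean, global_sd = obj$global_sd,
      config = structure(list(
        window = cfg$window, conv_channels = unlist(cfg$conv_channels),
        kernel_sizes = unlist(cfg$kernel_sizes),
        pool_sizes = unlist(cfg$pool_sizes),
        fc_widths = unlist(cfg$fc_widths), fc_dropout = cfg$fc_dropout,
        alpha = cfg$alpha, beta1 = cfg$beta1, beta2 = cfg$beta2,
        eps = cfg$eps, epochs = cfg$epochs, batch_size = cfg$batch_size,
        decision_threshold = cfg$decision_threshold, seed = cfg$seed),
        class = "detector_net_config"),
      log = as.data.frame(do.call(rbind, lapply(obj$log, as.data.frame)))),
      class = "rr_detector")
  } else {
    stop(sprintf("unknown checkpoint type '%s'", obj$type))
  }
}
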