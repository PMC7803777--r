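# Pipeline configuration: nested sections mirroring the pipeline stages,
# every default the working value (binarization threshold 25, crop 300,
# half-window 10, resize 200, 1500/100 upsampling, lr 1e-4, 1000 epochs,
# cutoff 0.5, 60 fps).  Unknown keys are rejected so typos cannot
# silently fall back to defaults.

config_defaults <- function() {
  list(
    preprocess = list(threshold = 25, crop_px = 300, smooth = 0.5, min_pixels = 20),
    dataset = list(half_window = 10),
    model = list(input_px = 200, n_frames = 21, kernel = 3,
                 conv_filters = c(32, 32, 32), lstm_units = c(256, 256),
                 fc_widths = c(128, 128, 32, 8, 1),
                 lstm_relu = TRUE, dropout = 0.2),
    training = list(n_random = 1500, n_scratch = 100, epochs = 1000,
                    learning_rate = 1e-4, resize_px = 200, minibatch = 32,
                    clip = 0.5, seed = 1, augment_flip = TRUE, augment_rotate = TRUE),
    evaluation = list(cutoff = 0.5, fps = 60),
    synth = list(frame_px = 480, fps = 60, n_frames = 1800, intensity = 190,
                 bg = 10, noise_sd = 4, scratch_hz = 12, scratch_amp = 14,
                 groom_hz = 3, groom_amp = 8, ensure_scratch = TRUE)
  )
}

config_checks <- function() {
  between <- function(lo, hi) {
    list(ok = function(v) all(v >= lo & v <= hi),
         msg = sprintf("must be in [%s, %s]", lo, hi))
  }
  positive <- list(ok = function(v) all(v > 0), msg = "must be > 0")
  nonneg <- list(ok = function(v) all(v >= 0), msg = "must be >= 0")
  flag <- list(ok = function(v) is.logical(v), msg = "must be true/false")
  list(
    preprocess = list(threshold = between(0, 255), crop_px = positive,
                      smooth = between(1e-6, 1), min_pixels = nonneg),
    dataset = list(half_window = positive),
    model = list(input_px = positive, n_frames = positive, kernel = positive,
                 conv_filters = positive, lstm_units = positive,
                 fc_widths = positive, lstm_relu = flag, dropout = between(0, 0.999)),
    training = list(n_random = nonneg, n_scratch = nonneg, epochs = nonneg,
                    learning_rate = positive, resize_px = positive,
                    minibatch = positive, clip = nonneg, seed = nonneg,
                    augment_flip = flag, augment_rotate = flag),
    evaluation = list(cutoff = between(0, 1), fps = positive),
    synth = list(frame_px = positive, fps = positive, n_frames = positive,
                 intensity = between(0, 255), bg = between(0, 255),
                 noise_sd = nonneg, scratch_hz = positive, scratch_amp = nonneg,
                 groom_hz = positive, groom_amp = nonneg, ensure_scratch = flag)
  )
}

validate_config <- function(cfg) {
  defaults <- config_defaults()
  checks <- config_checks()
  for (sec in names(cfg)) {
    if (!sec %in% names(defaults))
      stop(sprintf("unknown config section '%s'", sec))
    for (key in names(cfg[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        stop(sprintf("unknown config key '%s.%s'", sec, key))
      chk <- checks[[sec]][[key]]
      val <- cfg[[sec]][[key]]
      if (is.logical(defaults[[sec]][[key]])) {
        if (!is.logical(val)) stop(sprintf("config key '%s.%s' must be true/false", sec, key))
      } else {
        if (!is.numeric(val)) stop(sprintf("config key '%s.%s' must be numeric", sec, key))
        cfg[[sec]][[key]] <- as.numeric(val)
      }
      if (!chk$ok(cfg[[sec]][[key]]))
        stop(sprintf("config key '%s.%s' %s", sec, key, chk$msg))
    }
  }
  cfg
}

#' Default pipeline configuration
#'
#' Nested sections (`preprocess`, `dataset`, `model`, `training`,
#' `evaluation`, `synth`) whose defaults are the working pipeline values.
#'
#' @return Object of class `pipeline_config` (a named nested list).
#' @export
pipeline_config <- function() {
  structure(config_defaults(), class = "pipeline_config")
}

#' Load a YAML pipeline configuration
#'
#' Reads a (possibly partial) YAML file and merges it over the defaults.
#' Unknown sections or keys, non-numeric values and out-of-range values
#' (e.g. an intensity threshold above 255) are rejected with an error
#' naming the key and the violated constraint.  An empty file yields all
#' defaults.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  user <- validate_config(user)
  cfg <- config_defaults()
  for (sec in names(user)) {
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  structure(validate_config(cfg), class = "pipeline_config")
}

#' Save a pipeline configuration as YAML
#'
#' A saved configuration loads back identical ([load_config()] round-trip).
#'
#' @param cfg A `pipeline_config`.
#' @param path Output YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Fingerprint of a pipeline configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in output manifests
#' so artifacts record the exact configuration that produced them.
#'
#' @param cfg A `pipeline_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# constructors from config sections
cfg_model_spec <- function(cfg) {
  m <- cfg$model
  crnn_spec(input_px = m$input_px, n_frames = m$n_frames, kernel = m$kernel,
            conv_filters = m$conv_filters, lstm_units = m$lstm_units,
            fc_widths = m$fc_widths, lstm_relu = m$lstm_relu, dropout = m$dropout)
}

cfg_train_control <- function(cfg, seed = NULL) {
  t <- cfg$training
  train_control(n_random = t$n_random, n_scratch = t$n_scratch, epochs = t$epochs,
                learning_rate = t$learning_rate, resize_px = t$resize_px,
                minibatch = t$minibatch, clip = t$clip,
                seed = if (is.null(seed)) t$seed else seed,
                augment = list(flip = t$augment_flip, rotate = t$augment_rotate))
}

cfg_synth_config <- function(cfg) {
  s <- cfg$synth
  synth_config(frame_px = s$frame_px, fps = s$fps, n_frames = s$n_frames,
               intensity = s$intensity, bg = s$bg, noise_sd = s$noise_sd,
               scratch_hz = s$scratch_hz, scratch_amp = s$scratch_amp,
               groom_hz = s$groom_hz, groom_amp = s$groom_amp,
               ensure_scratch = s$ensure_scratch)
}
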