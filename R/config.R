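# Run configuration: built-in defaults, overridden by a YAML config file,
# overridden by CLI flags (precedence: flag > file > default). Unknown keys
# are rejected; every run writes its resolved configuration next to its
# artifacts so results can be reproduced from the file alone.

run_config_defaults <- function() {
  list(
    variant = "baseline",
    num_classes = 4L,
    depth_multiple = 0.33,
    width_multiple = 0.50,
    input_size = 640L,
    conf_threshold = 0.25,
    nms_iou = 0.45,
    eval_iou = 0.5,
    epochs = 30L,
    batch_size = 2L,
    lr0 = 0.01,
    weight_decay = 5e-4,
    warmup_epochs = 3L,
    mosaic_prob = 0,
    n_scenes = 10L,
    scene_size = 256L,
    seed = 0L,
    out_dir = "seadetect_out",
    log_level = "info"
  )
}

#' Build a resolved run configuration
#'
#' @param file optional YAML config file.
#' @param overrides named list of overrides (highest precedence).
#' @return named list with class `seadetect_run_config`.
#' @export
run_config <- function(file = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    fromfile <- yaml::read_yaml(file)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(fromfile)] <- fromfile
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  # coerce numerics that may arrive as strings from the CLI
  for (k in c("num_classes", "input_size", "epochs", "batch_size",
              "warmup_epochs", "n_scenes", "scene_size", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("depth_multiple", "width_multiple", "conf_threshold", "nms_iou",
              "eval_iou", "lr0", "weight_decay", "mosaic_prob")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  structure(cfg, class = "seadetect_run_config")
}

write_resolved_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "run_config.yaml"))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}
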