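#' Default pipeline configuration
#'
#' The full pipeline is driven by one nested configuration with sections
#' `io`, `trim`, `model`, `synth` and `report`. Every value has a default;
#' a YAML file supplies overrides and unknown keys are rejected.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      io = list(image_width = 1920, image_height = 1080, fps = 30,
                aliases = list()),
      trim = list(likelihood_threshold = 0.6, baseline_window = 10,
                  rise_fraction = 0.05, confirm_frames = 3,
                  min_retained_frames = 20, onset_fallback = "error"),
      model = list(outer_folds = 5, inner_folds = 5,
                   num_trees = c(100, 300, 500), max_depth = c(0, 5, 10),
                   min_node = c(1, 3, 5), seed = 1,
                   grouping = "by_participant"),
      synth = unclass(synth_config()),
      report = list(n_boot = 2000, seed = 1)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads the file, checks every key against [default_config()] (unknown keys
#' are an error, so typos cannot silently fall back to defaults), and merges
#' the overrides.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merged <- merge_config(unclass(cfg), user, prefix = character())
  structure(merged, class = "pipeline_config")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    path_str <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base)) {
      abort(paste0("unknown config key: ", path_str))
    }
    if (is.list(base[[key]]) && !key %in% c("aliases", "severity_probs")) {
      if (!is.list(user[[key]])) {
        abort(paste0("config key ", path_str, " must be a section"))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

config_sections <- function(cfg, seed = NULL) {
  synth_args <- cfg$synth
  if (!is.null(seed)) {
    cfg$model$seed <- seed
    cfg$report$seed <- seed
    synth_args$seed <- seed
  }
  list(
    io = io_config(
      aliases = unlist(cfg$io$aliases) %||% character(),
      image_width = cfg$io$image_width,
      image_height = cfg$io$image_height, fps = cfg$io$fps),
    trim = do.call(trim_config, cfg$trim),
    model = do.call(model_config, cfg$model),
    synth = do.call(synth_config, synth_args),
    report = cfg$report
  )
}

write_manifest <- function(outdir, command, inputs, cfg, seed) {
  manifest <- list(
    command = command,
    inputs = inputs,
    config_hash = rlang::hash(cfg),
    seed = seed,
    package_version = as.character(utils::packageVersion("gaitarm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
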