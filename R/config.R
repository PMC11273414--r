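# Run configuration: a single flat key-value set spanning data, model,
# training and retrieval options. Every key has a default; YAML files and
# CLI flags override defaults, and unknown keys are rejected by name.

#' Default run configuration
#'
#' Training defaults mirror the reference recipe (50 epochs, Adam at 1e-4,
#' weight decay 1e-4, margin 0.5, gamma 1.5, lambda 1/3); model defaults are
#' a 32-bit code over 224x224 inputs; data defaults cover the synthetic
#' generator, the conventional 1.5 IQR fence, and the 8:2 split.
#'
#' @return named list of all run options.
#' @export
default_run_config <- function() {
  list(
    # training
    epochs = 50L, learning_rate = 1e-4, weight_decay = 1e-4,
    batch_size = 32L, margin = 0.5, gamma = 1.5, lambda = 1 / 3, beta = 1,
    seed = 1L, k_validate = 10L,
    # model
    hash_length = 32L, n_classes = 10L, side = 224L, backbone = "tiny",
    tap = "penultimate", d_linear1 = 128L, reduction = 4L,
    spatial_kernel = 7L, classifier_relu = FALSE,
    separate_quant_bias = FALSE, alpha_init = 1.1,
    # data
    split_ratio = 0.8, iqr_factor = 1.5, classes = 4L, per_class = 50L,
    noise_sd = 0.02,
    # retrieval
    k = 10L, map_normalize = "clamped")
}

coerce_like <- function(value, template) {
  if (is.logical(template)) return(as.logical(value))
  if (is.integer(template)) return(as.integer(value))
  if (is.numeric(template)) return(as.numeric(value))
  as.character(value)
}

#' Load a run configuration
#'
#' Starts from [default_run_config()], overlays a YAML file (if given), then
#' explicit overrides. Unknown keys in either source are an error naming the
#' offending key.
#'
#' @param path optional YAML config file.
#' @param overrides named list of final overrides (e.g. parsed CLI flags).
#' @return the merged configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  apply_over <- function(cfg, vals, origin) {
    for (nm in names(vals)) {
      if (!nm %in% names(cfg))
        stop("unknown configuration key '", nm, "' (from ", origin, ")")
      cfg[[nm]] <- coerce_like(vals[[nm]], cfg[[nm]])
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  apply_over(cfg, overrides, "command line")
}

model_config_from_run <- function(rc) {
  dafh_model_config(n_classes = rc$n_classes, hash_length = rc$hash_length,
                    side = rc$side, d_linear1 = rc$d_linear1,
                    reduction = rc$reduction,
                    spatial_kernel = rc$spatial_kernel,
                    classifier_relu = rc$classifier_relu,
                    separate_quant_bias = rc$separate_quant_bias,
                    alpha_init = rc$alpha_init, backbone = rc$backbone,
                    tap = rc$tap)
}

train_config_from_run <- function(rc) {
  train_config(epochs = rc$epochs, learning_rate = rc$learning_rate,
               weight_decay = rc$weight_decay, batch_size = rc$batch_size,
               weights = loss_weights(lam = rc$lambda, beta = rc$beta,
                                      gamma = rc$gamma, margin = rc$margin),
               seed = rc$seed, k_validate = rc$k_validate)
}

# 32-bit FNV-1a hash of a string (emulated in doubles), for stamps
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_stamp <- function(out_dir, rc) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config_hash = fnv1a(jsonlite::toJSON(rc, auto_unbox = TRUE)),
         seed = rc$seed,
         package_version = as.character(utils::packageVersion("dafh"))),
    file.path(out_dir, "run_stamp.json"), auto_unbox = TRUE, digits = NA)
}
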