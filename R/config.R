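# Run configuration: full-scale defaults encoding the published
# training recipe, a desk-scale preset, and YAML validation.

#' Full-scale default configuration
#'
#' Encodes the reference training recipe: 256x256 patches (640 source /
#' 896 target), 9-residual-block generators with 64 base channels,
#' synthesis for 150 epochs at learning rate 2e-4 (constant for the
#' first two thirds, then linear decay) with weights
#' `lambda1 = lambda2 = 1`, `lambda3 = 10`, batch size 1; depth-4 U-Net
#' trained 100 epochs at 1e-4, batch 8, dropout 0.4 with batch
#' normalization; patch-selection threshold 0.13; 80-pixel inference
#' tiles; end-to-end variant 150 joint epochs with `lambda4 = 1`.
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    preprocess = list(clahe_clip_limit = 2, clahe_tile_grid = c(8L, 8L),
                      gamma = 1.2, normalization_mode = "minmax",
                      invert_source = TRUE),
    size_match = list(th = 0.13),
    patch = list(size = 256L, n_source = 640L, n_target = 896L,
                 tile = 80L),
    synthesis = list(epochs = 150L, lr = 2e-4, lambda1 = 1, lambda2 = 1,
                     lambda3 = 10, n_res_blocks = 9L, base_channels = 64L,
                     disc_layers = 3L, buffer_size = 50L, beta1 = 0.5,
                     keep_checkpoints = FALSE),
    segmentation = list(epochs = 100L, lr = 1e-4, batch_size = 8L,
                        depth = 4L, base_channels = 64L, dropout = 0.4,
                        batchnorm = TRUE, threshold = 0.5),
    e2e = list(epochs = 150L, lr = 2e-4, lambda4 = 1),
    select_mode = "best_cosine",
    fixture = list(size = 584L, n_source = 40L, n_target = 140L))
}

#' Desk-scale preset
#'
#' Scales the pipeline to a single CPU: 64x64 fixtures and patches (20
#' per domain), 3-residual-block generators and a depth-3 U-Net with 8
#' base channels, 5 synthesis / 10 segmentation epochs, whole-image
#' tiles. Loss weights, the patch-selection threshold, and all
#' structural choices are unchanged from [default_config()]; the
#' segmentation learning rate is raised to 1e-3 since only a few dozen
#' optimizer steps are taken.
#'
#' @return a nested configuration list.
#' @export
tiny_config <- function() {
  cfg <- default_config()
  cfg$preprocess$clahe_tile_grid <- c(4L, 4L)
  cfg$patch$size <- 64L
  cfg$patch$n_source <- 20L
  cfg$patch$n_target <- 20L
  cfg$patch$tile <- 64L
  cfg$synthesis$epochs <- 5L
  cfg$synthesis$n_res_blocks <- 3L
  cfg$synthesis$base_channels <- 8L
  cfg$synthesis$disc_layers <- 2L
  cfg$synthesis$keep_checkpoints <- TRUE
  cfg$segmentation$epochs <- 10L
  cfg$segmentation$lr <- 1e-3
  cfg$segmentation$depth <- 3L
  cfg$segmentation$base_channels <- 8L
  cfg$e2e$epochs <- 5L
  cfg$fixture <- list(size = 64L, n_source = 12L, n_target = 12L)
  cfg
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a YAML run configuration
#'
#' Parses YAML text (or a file), overlays it on [default_config()] (or
#' the [tiny_config()] preset), rejects unknown keys, and checks value
#' ranges. An empty document yields the defaults unchanged.
#'
#' @param yaml_text YAML text, or a path to a YAML file.
#' @param base base configuration to overlay onto.
#' @return the validated configuration list.
#' @export
validate_config <- function(yaml_text = "", base = default_config()) {
  ov <- if (file.exists(yaml_text)) yaml::read_yaml(yaml_text)
        else yaml::yaml.load(yaml_text)
  cfg <- if (is.null(ov)) base else merge_config(base, ov)
  with(cfg, {
    stopifnot(
      "gamma must be > 0" = preprocess$gamma > 0,
      "th must be in (0,1)" = size_match$th > 0 && size_match$th < 1,
      "epochs must be >= 0" = synthesis$epochs >= 0 &&
        segmentation$epochs >= 0 && e2e$epochs >= 0,
      "learning rates must be > 0" = synthesis$lr > 0 && segmentation$lr > 0,
      "loss weights must be >= 0" =
        all(c(synthesis$lambda1, synthesis$lambda2, synthesis$lambda3,
              e2e$lambda4) >= 0),
      "dropout must be in [0,1)" = segmentation$dropout >= 0 &&
        segmentation$dropout < 1,
      "patch and tile sizes must be positive" =
        patch$size >= 1 && patch$tile >= 1)
  })
  cfg
}
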