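# Single-file model checkpoints: a serialized list holding a JSON
# architecture descriptor, the weights, the training scale factor and the
# sigma the model was trained for, so a checkpoint is self-describing.

model_descriptor <- function(model) {
  cfgl <- unclass(model$config)
  cfgl$class <- class(model$config)
  list(format = "mrdenoise-checkpoint-v1",
       kind = model$kind,
       config = cfgl,
       layers = lapply(model$params, function(p) {
         if (is.null(dim(p))) length(p) else dim(p)
       }))
}

descriptor_json <- function(model) {
  jsonlite::toJSON(model_descriptor(model), auto_unbox = TRUE, digits = NA)
}

config_from_descriptor <- function(desc) {
  cls <- desc$config$class
  cfg <- desc$config
  cfg$class <- NULL
  builder <- switch(cls,
                    sure_config = sure_config,
                    blindspot_config = blindspot_config,
                    stop("unknown config class in checkpoint", call. = FALSE))
  do.call(builder, cfg)
}

#' Save a denoiser checkpoint
#'
#' Writes a single file containing the JSON architecture descriptor, the
#' trained weights, the training scale factor and `sigma_trained`.
#'
#' @param model a `denoiser_model`.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "denoiser_model"))
  saveRDS(list(descriptor = as.character(descriptor_json(model)),
               params = model$params,
               train_scale = model$train_scale,
               sigma_trained = model$sigma_trained,
               train_mag = model$train_mag,
               trained = isTRUE(model$trained),
               history = model$history),
          path)
  invisible(path)
}

#' Load a denoiser checkpoint written by [save_denoiser()]
#'
#' The architecture is rebuilt from the JSON descriptor and the layer shapes
#' are verified against the stored weights.
#'
#' @param path checkpoint file path.
#' @return a `denoiser_model`.
#' @export
load_denoiser <- function(path) {
  ck <- readRDS(path)
  desc <- jsonlite::fromJSON(ck$descriptor, simplifyVector = TRUE)
  cfg <- config_from_descriptor(desc)
  model <- if (desc$kind == "sure_unet") build_sure_unet(cfg)
  else build_blindspot_net(cfg)
  if (!identical(sort(names(model$params)), sort(names(ck$params))))
    stop("checkpoint layers do not match the rebuilt architecture",
         call. = FALSE)
  for (nm in names(ck$params)) {
    if (!identical(dim(model$params[[nm]]), dim(ck$params[[nm]])) &&
        length(model$params[[nm]]) != length(ck$params[[nm]]))
      stop("checkpoint layer shape mismatch: ", nm, call. = FALSE)
  }
  model$params <- ck$params
  model$train_scale <- ck$train_scale
  model$sigma_trained <- ck$sigma_trained
  model$train_mag <- ck$train_mag
  model$trained <- ck$trained
  model$history <- ck$history
  model
}
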