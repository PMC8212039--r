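#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the data source, the noise
#' levels, the scale factor, the crop size, the methods to run and their
#' training configurations. Three presets mirror the standard protocols:
#'
#' * `"brain"` — simulated brain volumes: sigmas `c(50, 100, 200)`, scale
#'   `1/25000`, crop 192, full-size training (depth-5 networks, 300 epochs).
#' * `"knee"` — raw single-coil knee data: sigmas
#'   `c(8.2e-6, 1e-5, 2e-5)`, scale 500, crop 320.
#' * `"desk"` — a reduced, self-contained phantom study that runs on one
#'   CPU in minutes: 64 x 64 slices, 16 subjects (12 train / 4 test, two
#'   slices each), sigmas `c(50, 100, 200)` on intensities up to 2000,
#'   scale `1/2000`, depth-2 networks trained for 30 epochs.
#'
#' @param protocol `"desk"`, `"brain"`, `"knee"` or `"custom"`.
#' @param dataset `"phantom"` (generate in memory from `phantom`) or a
#'   directory written by [generate_dataset()].
#' @param sigmas noise standard deviations in raw data units (non-empty).
#' @param scale_factor multiplicative factor applied before training.
#' @param crop_size centre-crop side in pixels (`NULL` = no crop).
#' @param methods subset of `c("sure", "blindspot", "nlm")`.
#' @param phantom a [phantom_spec()] used when `dataset = "phantom"`.
#' @param sure,blindspot training configurations ([sure_config()],
#'   [blindspot_config()]); their `sigma` field is set per noise level by
#'   the driver.
#' @param nlm an [nlm_params()].
#' @param nlm_domain `"magnitude"` (default) runs the baseline on magnitude
#'   images — the domain in which traditional MRI denoisers operate —
#'   `"complex"` runs it channel-wise inside the complex pipeline.
#' @param seed integer seed for noise injection (training seeds live in the
#'   model configs and are independent).
#' @param output_dir optional directory for `metrics.csv`, panels and the
#'   manifest.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(protocol = c("desk", "brain", "knee", "custom"),
                              dataset = "phantom",
                              sigmas = NULL, scale_factor = NULL,
                              crop_size = NULL,
                              methods = c("sure", "blindspot", "nlm"),
                              phantom = NULL, sure = NULL, blindspot = NULL,
                              nlm = nlm_params(),
                              nlm_domain = c("magnitude", "complex"),
                              seed = 1L, output_dir = NULL) {
  nlm_domain <- match.arg(nlm_domain)
  protocol <- match.arg(protocol)
  preset <- switch(protocol,
    desk = list(sigmas = c(50, 100, 200), scale = 1 / 2000, crop = 64L,
                phantom = phantom_spec(size = 64L, n_slices = 2L,
                                       n_subjects = 16L, seed = seed),
                sure = sure_config(depth = 2L, base_features = 16L,
                                   batch_size = 2L, epochs = 30L,
                                   learning_rate = 1e-3, seed = seed),
                blindspot = blindspot_config(depth = 2L, base_features = 16L,
                                             batch_size = 1L, epochs = 30L,
                                             learning_rate = 5e-3,
                                             lr_patience = 5L, seed = seed)),
    brain = list(sigmas = c(50, 100, 200), scale = 1 / 25000, crop = 192L,
                 phantom = phantom_spec(size = 192L, seed = seed),
                 sure = sure_config(seed = seed),
                 blindspot = blindspot_config(seed = seed)),
    knee = list(sigmas = c(8.2e-6, 1e-5, 2e-5), scale = 500, crop = 320L,
                phantom = phantom_spec(size = 320L,
                                       intensity_range = c(3e-6, 2e-5),
                                       seed = seed),
                sure = sure_config(seed = seed),
                blindspot = blindspot_config(seed = seed)),
    custom = list(sigmas = NULL, scale = 1, crop = NULL, phantom = NULL,
                  sure = sure_config(seed = seed),
                  blindspot = blindspot_config(seed = seed)))
  sigmas <- if (is.null(sigmas)) preset$sigmas else sigmas
  if (is.null(sigmas) || length(sigmas) == 0L)
    stop("`sigmas` must be non-empty", call. = FALSE)
  methods <- if (length(methods))
    match.arg(methods, c("sure", "blindspot", "nlm"), several.ok = TRUE)
  else character(0)
  structure(list(protocol = protocol, dataset = dataset, sigmas = sigmas,
                 scale_factor = scale_factor %||% preset$scale,
                 crop_size = crop_size %||% preset$crop,
                 methods = methods,
                 phantom = phantom %||% preset$phantom,
                 sure = sure %||% preset$sure,
                 blindspot = blindspot %||% preset$blindspot,
                 nlm = nlm, nlm_domain = nlm_domain,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# load or generate the subject volumes and split them
experiment_data <- function(cfg) {
  if (identical(cfg$dataset, "phantom")) {
    spec <- cfg$phantom
    subjects <- lapply(seq_len(spec$n_subjects),
                       function(s) generate_phantom_volume(spec, s))
    n_train <- min(max(1L, round(0.75 * spec$n_subjects)),
                   spec$n_subjects - 1L)
    split <- list(train = seq_len(n_train),
                  test = seq.int(n_train + 1L, spec$n_subjects))
  } else {
    ds <- read_dataset(cfg$dataset)
    subjects <- ds$subjects
    split <- ds$split
  }
  if (!is.null(cfg$crop_size)) {
    subjects <- lapply(subjects, function(v)
      lapply(v, center_crop, size = cfg$crop_size))
  }
  list(subjects = subjects, split = split)
}

noise_seed <- function(cfg, si, slice_id) {
  as.integer((cfg$seed * 104729L + si * 9973L + slice_id * 389L) %%
               2147483647L)
}

train_models_for_sigma <- function(cfg, sigma, train_slices, si) {
  models <- list()
  scaled_noisy <- lapply(seq_along(train_slices), function(i) {
    noisy <- add_gaussian_noise(train_slices[[i]],
                                noise_model(sigma,
                                            noise_seed(cfg, si, 1000L + i)))
    apply_scale(noisy, cfg$scale_factor)
  })
  sigma_s <- sigma * cfg$scale_factor
  if ("sure" %in% cfg$methods) {
    scfg <- cfg$sure; scfg$sigma <- sigma_s
    models$sure <- train_sure(build_sure_unet(scfg), scaled_noisy, scfg)
  }
  if ("blindspot" %in% cfg$methods) {
    bcfg <- cfg$blindspot; bcfg$sigma <- sigma_s
    models$blindspot <- train_blindspot(build_blindspot_net(bcfg),
                                        scaled_noisy, bcfg)
  }
  models
}

#' Run the full denoising experiment
#'
#' Reproduces the evaluation protocol end to end: for every noise level a
#' noisy copy of each ground-truth test slice is created, every requested
#' method is applied (the networks are trained per noise level on noisy
#' training slices only — no clean targets), and MSE / PSNR / SSIM are
#' computed against the ground truth on magnitude images (`MAX` = maximum
#' ground-truth magnitude). A `noisy` row is always included; its
#' complex-space MSE equals `2 * sigma^2` in expectation, an internal
#' consistency anchor. With `output_dir` set, `metrics.csv`, a per-sigma
#' middle-slice panel and a manifest are written.
#'
#' @param cfg an [experiment_config()].
#' @param models optional pre-trained models: a list indexed by sigma name
#'   (`as.character(sigma)`) of lists with elements `sure` / `blindspot`.
#' @return list with `metrics` (data.frame: method, sigma, mse, psnr, ssim,
#'   mse_complex), `edge` (data.frame from [edge_preservation_report()] on
#'   the middle test slice), `models`, and `panels` (paths, if written).
#' @export
run_experiment <- function(cfg, models = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  dat <- experiment_data(cfg)
  train_slices <- unlist(lapply(dat$subjects[dat$split$train], identity),
                         recursive = FALSE)
  test_slices <- unlist(lapply(dat$subjects[dat$split$test], identity),
                        recursive = FALSE)
  max_val <- max(vapply(test_slices, function(s) max(Mod(s$data)), 1.0))
  out_dir <- cfg$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- NULL
  edge <- NULL
  panels <- character(0)
  trained <- models %||% list()
  for (si in seq_along(cfg$sigmas)) {
    sigma <- cfg$sigmas[si]
    key <- as.character(sigma)
    need_train <- length(intersect(cfg$methods, c("sure", "blindspot"))) > 0L
    if (need_train && is.null(trained[[key]]))
      trained[[key]] <- train_models_for_sigma(cfg, sigma, train_slices, si)
    mdl <- trained[[key]]
    for (meth in intersect(cfg$methods, c("sure", "blindspot"))) {
      if (is.null(mdl[[meth]]))
        stop(sprintf(paste0("no trained %s model for sigma %g; drop it from",
                            " `models` to train one here, or train it with ",
                            "train_%s()"), meth, sigma, meth), call. = FALSE)
    }
    outs_mid <- NULL
    acc <- list()
    mid <- (length(test_slices) + 1L) %/% 2L
    for (ti in seq_along(test_slices)) {
      truth <- test_slices[[ti]]
      noisy <- add_gaussian_noise(truth,
                                  noise_model(sigma, noise_seed(cfg, si, ti)))
      outs <- list(noisy = noisy)
      if ("sure" %in% cfg$methods)
        outs$sure <- denoise_sure(mdl$sure, noisy)
      if ("blindspot" %in% cfg$methods)
        outs$blindspot <- denoise_blindspot(mdl$blindspot, noisy, sigma)
      if ("nlm" %in% cfg$methods) {
        outs$nlm <- if (identical(cfg$nlm_domain, "complex"))
          nlm_denoise_complex(noisy, cfg$nlm, sigma)
        else nlm_denoise(magnitude(noisy), cfg$nlm, sigma)
      }
      tm <- magnitude(truth)
      for (m in names(outs)) {
        o <- outs[[m]]
        rec <- if (inherits(o, "complex_image"))
          metrics_record(m, sigma, tm, magnitude(o), max_val,
                         truth$data, o$data)
        else metrics_record(m, sigma, tm, o, max_val)
        acc[[m]] <- rbind(acc[[m]], rec)
      }
      if (ti == mid) outs_mid <- c(list(truth = truth), outs)
    }
    for (m in names(acc)) {
      agg <- acc[[m]]
      metrics <- rbind(metrics,
                       data.frame(method = m, sigma = sigma,
                                  mse = mean(agg$mse),
                                  psnr = mean(agg$psnr),
                                  ssim = mean(agg$ssim),
                                  mse_complex = mean(agg$mse_complex)))
    }
    er <- edge_preservation_report(outs_mid$truth, outs_mid[-1L])
    er$sigma <- sigma
    edge <- rbind(edge, er)
    if (!is.null(out_dir)) {
      pth <- file.path(out_dir, sprintf("panel_sigma%g.png", sigma))
      caps <- vapply(names(outs_mid), function(m) {
        if (m == "truth") "original" else
          sprintf("%s PSNR = %.3f", m,
                  psnr(magnitude(outs_mid$truth), magnitude(outs_mid[[m]]),
                       max_val))
      }, "")
      write_panel(pth, lapply(outs_mid, magnitude), caps)
      panels <- c(panels, pth)
    }
  }
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(list(protocol = cfg$protocol, sigmas = cfg$sigmas,
                              scale_factor = cfg$scale_factor,
                              crop_size = cfg$crop_size,
                              methods = cfg$methods, seed = cfg$seed),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, edge = edge, models = trained, panels = panels)
}

#' Denoise original data without adding noise (qualitative only)
#'
#' Applies the trained methods directly to the original (clean or
#' intrinsically noisy) test slices. No reference exists, so no metrics are
#' computed; panels are written when `output_dir` is set, in the order
#' original / SURE / blindspot / NLM.
#'
#' @param cfg an [experiment_config()].
#' @param models a per-method model list (e.g. one entry of
#'   `run_experiment()$models`).
#' @param sigma noise level assumed at inference (`"auto"` = background
#'   estimate per slice).
#' @return list of per-slice output lists, invisibly; panels written if
#'   requested.
#' @export
run_no_added_noise <- function(cfg, models, sigma = "auto") {
  stopifnot(inherits(cfg, "experiment_config"))
  dat <- experiment_data(cfg)
  test_slices <- unlist(lapply(dat$subjects[dat$split$test], identity),
                        recursive = FALSE)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_along(test_slices), function(ti) {
    y <- test_slices[[ti]]
    outs <- list(original = y)
    if ("sure" %in% cfg$methods) outs$sure <- denoise_sure(models$sure, y)
    if ("blindspot" %in% cfg$methods)
      outs$blindspot <- denoise_blindspot(models$blindspot, y, sigma)
    if ("nlm" %in% cfg$methods) {
      sg <- if (identical(sigma, "auto")) estimate_sigma_background(y)
      else sigma
      outs$nlm <- if (identical(cfg$nlm_domain, "complex"))
        nlm_denoise_complex(y, cfg$nlm, sg)
      else nlm_denoise(magnitude(y), cfg$nlm, sg)
    }
    if (!is.null(out_dir) && ti == (length(test_slices) + 1L) %/% 2L)
      write_panel(file.path(out_dir, "panel_no_added_noise.png"),
                  lapply(outs, magnitude), names(outs))
    outs
  })
  invisible(res)
}

grad_mag <- function(m) {
  gx <- m * 0; gy <- m * 0
  gx[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
  gy[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

dilate1 <- function(mask) {
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-nrow(mask), ]
  out[-nrow(mask), ] <- out[-nrow(mask), ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -ncol(mask)]
  out[, -ncol(mask)] <- out[, -ncol(mask)] | mask[, -1]
  out
}

#' Edge-preservation score per method
#'
#' Operationalises the qualitative edge/tissue comparison: the mean absolute
#' gradient magnitude of each output, restricted to a dilated mask of the
#' ground-truth tissue edges (top-5% gradient pixels of the truth). A method
#' that smooths edges away scores low; the truth itself is the reference.
#'
#' @param truth ground-truth [complex_image()] (or magnitude matrix).
#' @param outputs named list of per-method outputs ([complex_image()] or
#'   magnitude matrices).
#' @return data.frame with columns `method` and `edge_score` (the truth's
#'   own score is included as method `"truth"`).
#' @export
edge_preservation_report <- function(truth, outputs) {
  tm <- if (inherits(truth, "complex_image")) magnitude(truth) else truth
  g <- grad_mag(tm)
  pos <- g[g > 0]
  if (length(pos) == 0L) {
    sc <- c(truth = 0, vapply(outputs, function(o) 0, 1.0))
    return(data.frame(method = names(sc), edge_score = unname(sc)))
  }
  mask <- dilate1(g >= quantile(pos, 0.95))
  score <- function(m) {
    mm <- if (inherits(m, "complex_image")) magnitude(m) else m
    mean(grad_mag(mm)[mask])
  }
  sc <- c(truth = score(tm), vapply(outputs, score, 1.0))
  data.frame(method = names(sc), edge_score = unname(sc),
             row.names = NULL)
}

# simple grayscale panel writer with captions
write_panel <- function(path, mags, captions = names(mags)) {
  n <- length(mags)
  hi <- max(vapply(mags, max, 1.0), 1e-12)
  grDevices::png(path, width = 220L * n, height = 240L)
  op <- graphics::par(mfrow = c(1L, n), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (i in seq_len(n)) {
    m <- pmin(mags[[i]] / hi, 1)
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), zlim = c(0, 1),
                    col = grDevices::gray.colors(256L, 0, 1), axes = FALSE,
                    main = captions[i], cex.main = 0.9)
  }
  invisible(path)
}
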