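#' Specification of a synthetic anatomical phantom dataset
#'
#' Describes a reproducible stand-in for simulated brain / raw knee MRI
#' volumes: piecewise-smooth elliptical anatomy (randomised Shepp-Logan
#' style) with per-tissue intensities, a smooth non-constant phase field, and
#' an exactly-zero background outside the head ellipse. Phantoms are
#' noise-free, so they serve as ground truth for training and evaluating the
#' denoisers; noise of known sigma is added separately with
#' [add_gaussian_noise()].
#'
#' @param size slice side length in pixels (square), `>= 32`.
#' @param n_slices slices per subject volume.
#' @param n_subjects number of subject volumes.
#' @param tissue_count number of piecewise tissue regions (head included),
#'   `>= 2`.
#' @param intensity_range `c(min, max)` tissue intensity in arbitrary signal
#'   units. The default peak of 2000 makes per-channel noise sigma in
#'   \{50, 100, 200\} visibly low/medium/high corruption.
#' @param phase_smoothness low-pass cutoff of the phase field as a fraction
#'   of Nyquist; smaller is smoother.
#' @param background_margin fraction of the image guaranteed to be
#'   exactly-zero signal, in (0, 0.5).
#' @param seed integer seed; all slices are deterministic functions of
#'   `(seed, subject, slice)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 192L, n_slices = 4L, n_subjects = 16L,
                         tissue_count = 5L,
                         intensity_range = c(300, 2000),
                         phase_smoothness = 0.08,
                         background_margin = 0.2,
                         seed = 1L) {
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be >= 32", call. = FALSE)
  tissue_count <- as.integer(tissue_count)
  if (tissue_count < 2L) stop("`tissue_count` must be >= 2", call. = FALSE)
  if (background_margin <= 0 || background_margin >= 0.5)
    stop("`background_margin` must lie in (0, 0.5)", call. = FALSE)
  if (length(intensity_range) != 2L || diff(intensity_range) <= 0)
    stop("`intensity_range` must be c(min, max) with min < max", call. = FALSE)
  structure(list(size = size, n_slices = as.integer(n_slices),
                 n_subjects = as.integer(n_subjects),
                 tissue_count = tissue_count,
                 intensity_range = as.numeric(intensity_range),
                 phase_smoothness = phase_smoothness,
                 background_margin = background_margin,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic sub-stream seed, kept well below 2^31
phantom_seed <- function(spec, subject, slice = 0L) {
  as.integer((abs(spec$seed) * 2654435L + subject * 97561L + slice * 7919L) %%
               2147483647L)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# soft-boundary membership of an ellipse on [-1,1]^2 coordinates;
# exactly 0 well outside, exactly 1 well inside, smooth over `width` coords
ellipse_weight <- function(xg, yg, cx, cy, a, b, theta, width) {
  ct <- cos(theta); st <- sin(theta)
  u <- (xg - cx) * ct + (yg - cy) * st
  v <- -(xg - cx) * st + (yg - cy) * ct
  q <- sqrt((u / a)^2 + (v / b)^2)
  d <- (1 - q) * min(a, b)  # approximate signed distance, > 0 inside
  smoothstep(d / width + 0.5)
}

#' Generate one phantom slice
#'
#' Deterministic for fixed `(seed, subject, slice)`. The magnitude is a head
#' ellipse containing `tissue_count - 1` smooth-boundary tissue ellipses
#' whose through-plane size varies with the slice index; the phase is a
#' band-limited random field plus a mild linear ramp, so the data are
#' genuinely complex-valued. All pixels outside the head ellipse are exactly
#' zero.
#'
#' @param spec a [phantom_spec()].
#' @param subject subject index in `1:n_subjects`.
#' @param slice slice index in `1:n_slices`.
#' @param width optional number of columns to emit (defaults to `spec$size`);
#'   a smaller value produces a rectangular slice (centered columns), useful
#'   for exercising [zero_pad_square()].
#' @return a noise-free [complex_image()] in raw units (`scale_applied = 1`).
#' @export
generate_phantom_slice <- function(spec, subject, slice, width = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (subject < 1L || subject > spec$n_subjects)
    stop("`subject` out of range", call. = FALSE)
  if (slice < 1L || slice > spec$n_slices)
    stop("`slice` out of range", call. = FALSE)
  n <- spec$size
  px <- 2 / n                      # one pixel in [-1,1] coordinates
  g <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
  xg <- matrix(g, n, n)            # rows vary
  yg <- matrix(g, n, n, byrow = TRUE)
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]

  # subject-level anatomy (independent of slice index)
  anat <- with_seed(phantom_seed(spec, subject), {
    cap <- 4 * (1 - spec$background_margin) / pi
    a <- runif(1, 0.62, 0.80); b <- runif(1, 0.72, 0.90)
    if (a * b > cap) { s <- sqrt(cap / (a * b)); a <- a * s; b <- b * s }
    k <- spec$tissue_count - 1L
    list(head = list(cx = runif(1, -0.03, 0.03), cy = runif(1, -0.03, 0.03),
                     a = a, b = b, theta = runif(1, -0.15, 0.15)),
         head_int = lo + 0.35 * (hi - lo),
         tis = lapply(seq_len(k), function(i) {
           list(cx = runif(1, -0.45, 0.45) * a, cy = runif(1, -0.45, 0.45) * b,
                a = runif(1, 0.10, 0.42) * a, b = runif(1, 0.10, 0.42) * b,
                theta = runif(1, -pi / 2, pi / 2),
                int = runif(1, lo, hi))
         }))
  })

  # through-plane profile: tissues shrink towards the volume ends
  zrel <- if (spec$n_slices > 1L)
    (slice - (spec$n_slices + 1) / 2) / (spec$n_slices / 2) else 0
  zscale <- sqrt(pmax(1 - 0.4 * zrel^2, 0.2))

  ew <- 2.5 * px
  head_w <- ellipse_weight(xg, yg, anat$head$cx, anat$head$cy,
                           anat$head$a, anat$head$b, anat$head$theta, ew)
  mag <- matrix(anat$head_int, n, n)
  for (t in anat$tis) {
    wt <- ellipse_weight(xg, yg, t$cx, t$cy,
                         t$a * zscale, t$b * zscale, t$theta, ew)
    mag <- mag * (1 - wt) + t$int * wt
  }
  mag <- mag * head_w  # exactly zero outside the head

  # smooth random phase field, band-limited at phase_smoothness * Nyquist
  phase <- with_seed(phantom_seed(spec, subject, slice), {
    wn <- matrix(rnorm(n * n), n, n)
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n  # cycles/pixel
    fr <- sqrt(outer(f[1:n]^2, f[1:n]^2, "+"))
    H <- exp(-0.5 * (fr / (spec$phase_smoothness * 0.5))^2)
    s <- Re(stats::fft(stats::fft(wn) * H, inverse = TRUE)) / (n * n)
    s <- s / max(sd(s), 1e-12)
    0.8 * s + runif(1, -0.4, 0.4) * xg + runif(1, -0.4, 0.4) * yg
  })

  img <- complex_image(mag * exp(1i * phase))
  if (!is.null(width)) {
    width <- as.integer(width)
    c0 <- (n - width) %/% 2L
    img <- complex_image(img$data[, (c0 + 1L):(c0 + width), drop = FALSE])
  }
  img
}

# all slices of one subject, as a list of complex_image
generate_phantom_volume <- function(spec, subject) {
  lapply(seq_len(spec$n_slices),
         function(s) generate_phantom_slice(spec, subject, s))
}

#' Write a phantom dataset to disk
#'
#' Writes one two-channel (real/imaginary) NIfTI volume per subject plus a
#' JSON manifest recording the spec, the file list with MD5 hashes, and a
#' train/test subject split (by default 12 train / 4 test for the standard
#' 16-subject spec; otherwise roughly 3:1).
#'
#' @param spec a [phantom_spec()].
#' @param out_path writable directory (created if missing).
#' @param n_train number of training subjects; default `round(0.75 * n)`.
#' @param magnitude_nifti also write per-subject magnitude volumes
#'   (`subjectNN_mag.nii`).
#' @return (invisibly) the manifest as a list; also written as
#'   `manifest.json` in `out_path`.
#' @export
generate_dataset <- function(spec, out_path,
                             n_train = round(0.75 * spec$n_subjects),
                             magnitude_nifti = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  files <- character(spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    vol <- generate_phantom_volume(spec, s)
    arr <- array(0, dim = c(spec$size, spec$size, spec$n_slices, 2L))
    for (k in seq_along(vol)) {
      arr[, , k, 1L] <- Re(vol[[k]]$data)
      arr[, , k, 2L] <- Im(vol[[k]]$data)
    }
    f <- sprintf("subject%02d.nii", s)
    RNifti::writeNifti(RNifti::asNifti(arr), file.path(out_path, f))
    files[s] <- f
    if (magnitude_nifti) {
      mag <- array(sqrt(arr[, , , 1L]^2 + arr[, , , 2L]^2),
                   dim = c(spec$size, spec$size, spec$n_slices))
      RNifti::writeNifti(RNifti::asNifti(mag),
                         file.path(out_path,
                                   sprintf("subject%02d_mag.nii", s)))
    }
  }
  n_train <- min(max(1L, as.integer(n_train)), spec$n_subjects - 1L)
  manifest <- list(
    format = "mrdenoise-phantom-v1",
    spec = unclass(spec),
    files = files,
    md5 = unname(tools::md5sum(file.path(out_path, files))),
    split = list(train = seq_len(n_train),
                 test = seq.int(n_train + 1L, spec$n_subjects))
  )
  jsonlite::write_json(manifest, file.path(out_path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom dataset written by [generate_dataset()]
#'
#' @param path directory containing `manifest.json` and the subject volumes.
#' @return list with elements `spec`, `split`, and `subjects` (a list of
#'   per-subject lists of [complex_image()] slices).
#' @export
read_dataset <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(phantom_spec, manifest$spec[c(
    "size", "n_slices", "n_subjects", "tissue_count", "intensity_range",
    "phase_smoothness", "background_margin", "seed")])
  subjects <- lapply(manifest$files, function(f) {
    arr <- as.array(RNifti::readNifti(file.path(path, f)))
    lapply(seq_len(dim(arr)[3L]), function(k) {
      complex_image(matrix(complex(real = arr[, , k, 1L],
                                   imaginary = arr[, , k, 2L]),
                           dim(arr)[1L], dim(arr)[2L]))
    })
  })
  list(spec = spec, split = manifest$split, subjects = subjects)
}
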