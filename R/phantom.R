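# Seeded synthetic phantom generator. Emulates the three data regimes the
# network targets: multi-organ abdominal CT-like slices (8 organ classes +
# background), short-axis cardiac MRI-like slices (RV / myocardium / LV +
# background) and dermoscopic lesion-like images (binary). The difficulty
# axes are explicit knobs: `contrast` separates class intensities,
# `boundary_softness` blurs class edges (weak boundaries), `noise_sd` adds
# Gaussian noise, and blob boundaries are radially deformed (irregular
# shapes). Masks are always exact.

#' Phantom dataset specification
#'
#' @param regime `"multi_organ"` (9 classes), `"cardiac"` (4) or
#'   `"lesion"` (2).
#' @param img_size square image size in pixels.
#' @param contrast intensity separation between classes, in `(0, 1]`; at 1
#'   the class levels span the full intensity range.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units).
#' @param boundary_softness Gaussian blur sigma (pixels) applied to the
#'   image (never the mask) to soften class edges.
#' @param n_images number of images in the dataset.
#' @param seed integer seed; identical spec + seed reproduce the dataset
#'   bit for bit.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(regime = c("multi_organ", "cardiac", "lesion"),
                         img_size = 224L, contrast = 0.5, noise_sd = 0.05,
                         boundary_softness = 1.5, n_images = 100L, seed = 0L) {
  regime <- match.arg(regime)
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (boundary_softness < 0) stop("boundary_softness must be >= 0", call. = FALSE)
  structure(list(regime = regime,
                 num_classes = switch(regime, multi_organ = 9L, cardiac = 4L,
                                      lesion = 2L),
                 img_size = as.integer(img_size),
                 contrast = contrast, noise_sd = noise_sd,
                 boundary_softness = boundary_softness,
                 n_images = as.integer(n_images), seed = as.integer(seed)),
            class = "phantom_spec")
}

with_phantom_seed <- function(spec, index, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((spec$seed * 100003L + index * 7919L) %% 2147483647L)
  expr
}

# radially deformed ellipse membership on a pixel grid
rasterize_blob <- function(S, cx, cy, rx, ry, theta, deform) {
  xs <- matrix(rep(seq_len(S), each = S), S) # column index
  ys <- matrix(rep(seq_len(S), times = S), S) # row index
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  a <- stats::runif(3, 0, deform)
  psi <- stats::runif(3, 0, 2 * pi)
  rdef <- 1 + a[1] * cos(2 * phi + psi[1]) + a[2] * cos(3 * phi + psi[2]) +
    a[3] * cos(4 * phi + psi[3])
  rho <= rdef
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  S <- nrow(img)
  padded_idx <- pmin(pmax(seq(1 - r, S + r), 1L), S) # replicate edges
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    mp <- m[padded_idx, , drop = FALSE]
    for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(nrow(m)) + j - 1L, , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

class_levels <- function(num_classes, contrast) {
  0.5 + contrast * (seq_len(num_classes) - 1) / (num_classes - 1) - contrast / 2
}

place_organs <- function(S, n_organs, deform) {
  mask <- matrix(0L, S, S)
  bx <- S / 2; by <- S / 2
  body <- rasterize_blob(S, bx, by, 0.44 * S, 0.40 * S, 0, 0)
  for (cls in seq_len(n_organs)) {
    placed <- FALSE
    r0 <- stats::runif(1, 0.07, 0.13) * S
    for (try in seq_len(60)) {
      r <- r0 * (1 - 0.08 * (try %/% 10)) # shrink slowly if crowded
      cx <- stats::runif(1, 0.18 * S, 0.82 * S)
      cy <- stats::runif(1, 0.18 * S, 0.82 * S)
      blob <- rasterize_blob(S, cx, cy, r, r * stats::runif(1, 0.6, 1),
                             stats::runif(1, 0, pi), deform)
      blob <- blob & body
      if (sum(blob) < 9) next
      if (any(mask[blob] != 0L)) next
      mask[blob] <- cls
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("phantom placement infeasible for spec: regime=multi_organ, ",
           "img_size=", S, " (organ ", cls, ")", call. = FALSE)
    }
  }
  list(mask = mask, body = body)
}

make_mask <- function(spec) {
  S <- spec$img_size
  if (spec$regime == "multi_organ") {
    pl <- place_organs(S, 8L, deform = 0.15)
    list(mask = pl$mask, body = pl$body)
  } else if (spec$regime == "cardiac") {
    cx <- S / 2 + stats::runif(1, -0.05, 0.05) * S
    cy <- S / 2 + stats::runif(1, -0.05, 0.05) * S
    r_lv <- stats::runif(1, 0.10, 0.14) * S
    thick <- stats::runif(1, 0.05, 0.07) * S
    lv <- rasterize_blob(S, cx, cy, r_lv, r_lv, 0, 0.04)
    myo_out <- rasterize_blob(S, cx, cy, r_lv + thick, r_lv + thick, 0, 0.04)
    rv_cx <- cx - (r_lv + thick) * 1.05
    rv <- rasterize_blob(S, rv_cx, cy + stats::runif(1, -0.03, 0.03) * S,
                         (r_lv + thick) * 0.9, r_lv * 0.95,
                         stats::runif(1, -0.3, 0.3), 0.10)
    mask <- matrix(0L, S, S)
    mask[rv] <- 1L
    mask[myo_out] <- 2L
    mask[lv] <- 3L
    body <- rasterize_blob(S, S / 2, S / 2, 0.46 * S, 0.44 * S, 0, 0)
    list(mask = mask, body = body)
  } else {
    cx <- S / 2 + stats::runif(1, -0.1, 0.1) * S
    cy <- S / 2 + stats::runif(1, -0.1, 0.1) * S
    r <- stats::runif(1, 0.18, 0.30) * S
    lesion <- rasterize_blob(S, cx, cy, r, r * stats::runif(1, 0.7, 1),
                             stats::runif(1, 0, pi), 0.25)
    mask <- matrix(0L, S, S)
    mask[lesion] <- 1L
    list(mask = mask, body = NULL)
  }
}

#' Generate one phantom image/mask pair
#'
#' @param spec a [phantom_spec()].
#' @param index image index within the dataset (seeds are derived from
#'   `spec$seed` and `index`, so each pair is individually reproducible).
#' @return list with `image` (`S x S` matrix in `[0, 1]`) and `mask`
#'   (`S x S` integer matrix of class indices).
#' @export
generate_phantom <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_phantom_seed(spec, index, {
    mk <- make_mask(spec)
    lv <- class_levels(spec$num_classes, spec$contrast)
    img <- matrix(lv[1], spec$img_size, spec$img_size)
    img[] <- lv[mk$mask + 1L]
    if (!is.null(mk$body)) {
      # faint body silhouette so the background is not flat
      img[mk$body & mk$mask == 0L] <- lv[1] + 0.25 * spec$contrast /
        (spec$num_classes - 1)
    }
    img <- gaussian_blur(img, spec$boundary_softness)
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, mask = mk$mask)
  })
}

#' Jointly augment an image/mask pair
#'
#' Applies one geometric transform to both image and mask: horizontal or
#' vertical flip, rotation by a multiple of 90 degrees, or a small-angle
#' rotation (within +/- 20 degrees) resampled with nearest neighbours so
#' label values are preserved exactly.
#'
#' @param image numeric matrix.
#' @param mask integer matrix, same shape.
#' @param seed optional seed used to sample the transform.
#' @param transform optional explicit transform: `"none"`, `"hflip"`,
#'   `"vflip"`, `"rot90"`, `"rot180"`, `"rot270"`, or a small angle in
#'   degrees given as `list(angle = a)`.
#' @return list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, seed = NULL, transform = NULL) {
  stopifnot(all(dim(image) == dim(mask)))
  if (is.null(transform)) {
    if (!is.null(seed)) set.seed(seed)
    kind <- sample(c("none", "hflip", "vflip", "rot90", "rot180", "rot270",
                     "small"), 1)
    transform <- if (kind == "small") list(angle = stats::runif(1, -20, 20))
                 else kind
  }
  ap <- function(m) {
    if (is.character(transform)) {
      switch(transform,
             none = m,
             hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
             vflip = m[rev(seq_len(nrow(m))), , drop = FALSE],
             rot90 = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
             rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
             rot270 = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
             stop("unknown transform: ", transform, call. = FALSE))
    } else {
      a <- transform$angle * pi / 180
      S1 <- nrow(m); S2 <- ncol(m)
      ci <- (S1 + 1) / 2; cj <- (S2 + 1) / 2
      ii <- matrix(rep(seq_len(S1), times = S2), S1)
      jj <- matrix(rep(seq_len(S2), each = S1), S1)
      si <- round(ci + cos(a) * (ii - ci) - sin(a) * (jj - cj))
      sj <- round(cj + sin(a) * (ii - ci) + cos(a) * (jj - cj))
      ok <- si >= 1 & si <= S1 & sj >= 1 & sj <= S2
      out <- matrix(m[1] * 0, S1, S2)
      out[ok] <- m[cbind(si[ok], sj[ok])]
      out
    }
  }
  list(image = ap(image), mask = ap(mask))
}

#' Generate a dataset split on disk
#'
#' Writes PNG image/mask pairs into `train/`, `val/` and `test/`
#' subdirectories plus a JSON manifest recording the spec, seed and index
#' assignment, so a split is fully reproducible from its manifest.
#'
#' @param spec a [phantom_spec()].
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
generate_split <- function(spec, fractions = c(0.7, 0.1, 0.2), dir) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n <- spec$n_images
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  n_te <- n - n_tr - n_va
  idx <- with_phantom_seed(spec, 0L, sample.int(n))
  splits <- list(train = sort(idx[seq_len(n_tr)]),
                 val = sort(idx[n_tr + seq_len(n_va)]),
                 test = sort(idx[n_tr + n_va + seq_len(n_te)]))
  for (sp in names(splits)) {
    dir.create(file.path(dir, sp, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, sp, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in splits[[sp]]) {
      ph <- generate_phantom(spec, i)
      png::writePNG(ph$image, file.path(dir, sp, "images",
                                        sprintf("img_%04d.png", i)))
      png::writePNG(ph$mask / 255, file.path(dir, sp, "masks",
                                             sprintf("img_%04d.png", i)))
    }
  }
  manifest <- list(spec = unclass(spec), fractions = fractions,
                   splits = splits)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a phantom split from disk
#'
#' @param dir dataset directory written by [generate_split()].
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list with `images` and `masks` (lists of matrices).
#' @export
load_split <- function(dir, split = "train") {
  imgs <- sort(list.files(file.path(dir, split, "images"), full.names = TRUE))
  msks <- sort(list.files(file.path(dir, split, "masks"), full.names = TRUE))
  stopifnot(length(imgs) == length(msks))
  list(images = lapply(imgs, read_gray_png),
       masks = lapply(msks, function(f) {
         m <- round(read_gray_png(f) * 255)
         storage.mode(m) <- "integer"
         m
       }))
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Write phantom slices as a NIfTI volume
#'
#' Stacks the images (and masks) of the given indices along a third axis and
#' writes `<prefix>_image.nii.gz` / `<prefix>_mask.nii.gz`, mirroring the
#' volumetric layout used by the case-level evaluation path.
#'
#' @param spec a [phantom_spec()].
#' @param indices slice indices.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_phantom_volume <- function(spec, indices, prefix) {
  phs <- lapply(indices, function(i) generate_phantom(spec, i))
  S <- spec$img_size
  img <- array(unlist(lapply(phs, `[[`, "image")), c(S, S, length(phs)))
  msk <- array(unlist(lapply(phs, `[[`, "mask")), c(S, S, length(phs)))
  fi <- paste0(prefix, "_image.nii.gz")
  fm <- paste0(prefix, "_mask.nii.gz")
  RNifti::writeNifti(img, fi)
  RNifti::writeNifti(msk, fm)
  invisible(c(fi, fm))
}
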