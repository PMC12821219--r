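# Image stacks: containers, TIFF IO, resampling, smoothing.

#' 3D image stack with physical voxel spacing
#'
#' @param voxels 3D numeric array of intensities, dimensions (nx, ny, nz).
#' @param spacing voxel spacing `c(dx, dy, dz)` in micrometers.
#' @param origin physical position of the corner of voxel (1,1,1), micrometers.
#' @return an `image_stack` object.
#' @export
image_stack <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive and finite")
  if (any(!is.finite(voxels))) stop("intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack %d x %d x %d, spacing (%.4g, %.4g, %.4g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Binary vascular mask
#'
#' @param voxels 3D logical array.
#' @param spacing isotropic voxel spacing in micrometers (scalar or length 3).
#' @export
binary_mask <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(spacing > 0))
  structure(list(voxels = voxels, spacing = spacing),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask %d x %d x %d, spacing %.4g um, %d foreground voxels\n",
              d[1], d[2], d[3], x$spacing[1], sum(x$voxels)))
  invisible(x)
}

spacing_isotropic <- function(spacing, tol = 1e-6) {
  diff(range(spacing)) <= tol * max(spacing)
}

# Parse an ImageJ-style TIFF description string ("spacing=3.0\nunit=micron").
parse_ij_description <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (ln in strsplit(desc, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

#' Read a multi-page TIFF into an image stack
#'
#' Voxel spacing is taken from the TIFF metadata (x/y resolution tags plus an
#' ImageJ-style `spacing=` entry in the image description) or from the
#' `spacing` override. If neither source provides a full spacing, the read
#' fails: spacing is never silently defaulted.
#'
#' @param path path to a multi-page TIFF file.
#' @param channel 1-based channel index for multi-channel pages.
#' @param spacing optional spacing override `c(dx, dy, dz)` in micrometers.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel = 1L, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  take_channel <- function(pg) {
    if (length(dim(pg)) == 3L) {
      if (channel > dim(pg)[3]) stop("channel ", channel, " not present")
      pg[, , channel]
    } else {
      if (channel != 1L) stop("channel ", channel, " not present")
      pg
    }
  }
  mats <- lapply(pages, take_channel)
  ny <- nrow(mats[[1]]); nx <- ncol(mats[[1]]); nz <- length(mats)
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- t(mats[[k]])   # page rows are y
  meta <- NULL
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (is.null(spacing)) {
    info <- attr(pages[[1]], "info")
    if (is.null(info)) info <- list()
    ij <- parse_ij_description(info$description)
    xres <- suppressWarnings(as.numeric(info$x.resolution))
    dz <- suppressWarnings(as.numeric(ij$spacing))
    if (length(xres) == 1L && is.finite(xres) && xres > 0 &&
        length(dz) == 1L && is.finite(dz)) {
      spacing <- c(1 / xres, 1 / xres, dz)
    } else if (!is.null(meta$spacing)) {
      spacing <- as.numeric(meta$spacing)
    } else {
      stop("no voxel spacing in TIFF metadata and no `spacing` override given")
    }
  }
  if (!is.null(meta$scale))
    vox <- vox * as.numeric(meta$scale) + as.numeric(meta$offset)
  image_stack(vox, spacing)
}

#' Write an image stack (or mask) as a multi-page TIFF
#'
#' Intensities are written as 32-bit float pages (rescaled to [0, 1]); masks
#' as 8-bit 0/255. Voxel spacing and the intensity scale are recorded in a
#' JSON sidecar (`<path>.meta.json`) that [read_stack()] picks up, since the
#' available TIFF writer exposes no custom-tag interface.
#'
#' @param x an [image_stack()] or [binary_mask()].
#' @param path output path.
#' @export
write_stack <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  vox <- if (is_mask) array(as.numeric(x$voxels), dim(x$voxels)) else x$voxels
  lo <- min(vox); hi <- max(vox)
  scale <- max(hi - lo, .Machine$double.xmin)
  if (is_mask) { lo <- 0; scale <- 1 }
  nz <- dim(vox)[3]
  pages <- lapply(seq_len(nz), function(k) t((vox[, , k] - lo) / scale))
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (is_mask) 8L else 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(list(spacing = x$spacing, offset = lo, scale = scale),
                       paste0(path, ".meta.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Trilinear sampling of a 3D array at fractional voxel coordinates (1-based
# voxel-center coordinates); edge-clamped.
trilinear_sample <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(floor(xi), d[1]); x1 <- cl(x0 + 1, d[1])
  y0 <- cl(floor(yi), d[2]); y1 <- cl(y0 + 1, d[2])
  z0 <- cl(floor(zi), d[3]); z1 <- cl(z0 + 1, d[3])
  fx <- cl(xi, d[1]) - x0; fy <- cl(yi, d[2]) - y0; fz <- cl(zi, d[3]) - z0
  at <- function(ix, iy, iz) vol[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

#' Resample a stack to isotropic voxels
#'
#' The physical extent of each axis is preserved to within one target voxel;
#' the number of voxels per axis becomes `round(extent / target)`.
#'
#' @param stack an [image_stack()].
#' @param target target isotropic spacing in micrometers, or `"min-spacing"`
#'   (default) for the smallest input spacing component.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return an [image_stack()] with isotropic spacing.
#' @export
resample_isotropic <- function(stack, target = "min-spacing",
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(stack, "image_stack"))
  if (identical(target, "min-spacing")) target <- min(stack$spacing)
  target <- as.numeric(target)
  if (!is.finite(target) || target <= 0) stop("target spacing must be > 0")
  if (spacing_isotropic(stack$spacing) &&
      abs(stack$spacing[1] - target) <= 1e-9 * target)
    return(stack)
  d <- dim(stack$voxels)
  extent <- d * stack$spacing
  nd <- pmax(1L, as.integer(round(extent / target)))
  # output voxel-center positions mapped to input voxel-center coordinates
  ax <- function(n, sp_out, sp_in) ((seq_len(n) - 0.5) * sp_out) / sp_in + 0.5
  xi <- ax(nd[1], target, stack$spacing[1])
  yi <- ax(nd[2], target, stack$spacing[2])
  zi <- ax(nd[3], target, stack$spacing[3])
  if (interpolation == "nearest") {
    cl <- function(v, n) pmin(pmax(round(v), 1), n)
    out <- stack$voxels[cl(xi, d[1]), cl(yi, d[2]), cl(zi, d[3]), drop = FALSE]
  } else {
    g <- expand.grid(x = xi, y = yi, z = zi)
    out <- array(trilinear_sample(stack$voxels, g$x, g$y, g$z), nd)
  }
  image_stack(out, rep(target, 3), stack$origin)
}

# 1D normalized Gaussian kernel for a sigma expressed in voxels.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- dnorm(seq(-r, r), sd = sigma_vox)
  w / sum(w)
}

# Separable convolution along one axis with edge replication.
conv_axis <- function(vol, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  d <- dim(vol)
  n <- d[axis]
  out <- array(0, d)
  for (t in seq_along(w)) {
    off <- t - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      vol[idx, , , drop = FALSE],
                      vol[, idx, , drop = FALSE],
                      vol[, , idx, drop = FALSE])
    out <- out + w[t] * shifted
  }
  out
}

#' Gaussian smoothing in physical units
#'
#' `sigma` is given in micrometers and converted per axis to voxels via the
#' stack spacing, so anisotropic stacks are smoothed isotropically in
#' physical space. `sigma = 0` is the identity.
#'
#' @param stack an [image_stack()].
#' @param sigma Gaussian standard deviation in micrometers.
#' @export
gaussian_smooth <- function(stack, sigma) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(stack)
  vox <- stack$voxels
  for (a in 1:3) {
    sv <- sigma / stack$spacing[a]
    if (sv > 1e-8) vox <- conv_axis(vox, gauss_kernel(sv), a)
  }
  image_stack(vox, stack$spacing, stack$origin)
}

# Box mean filter (separable running mean via cumulative sums, truncated at
# the edges), used by adaptive thresholding.
box_mean <- function(vol, window) {
  d <- dim(vol)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  for (a in 1:3) {
    n <- d[a]
    if (n <= 1L) next
    cs <- vol
    for (i in 2:n) {
      if (a == 1) cs[i, , ] <- cs[i - 1L, , ] + cs[i, , ]
      else if (a == 2) cs[, i, ] <- cs[, i - 1L, ] + cs[, i, ]
      else cs[, , i] <- cs[, , i - 1L] + cs[, , i]
    }
    hi <- pmin(seq_len(n) + h2, n)
    lo <- pmax(seq_len(n) - h1, 1L)
    cnt <- hi - lo + 1L
    pick <- function(idx) switch(a, cs[idx, , , drop = FALSE],
                                 cs[, idx, , drop = FALSE],
                                 cs[, , idx, drop = FALSE])
    upper <- pick(hi)
    lower <- array(0, dim(upper))
    has_lo <- lo > 1L
    if (any(has_lo)) {
      lower_part <- pick(lo[has_lo] - 1L)
      if (a == 1) lower[has_lo, , ] <- lower_part
      else if (a == 2) lower[, has_lo, ] <- lower_part
      else lower[, , has_lo] <- lower_part
    }
    sums <- upper - lower
    cntarr <- switch(a, array(cnt, d), array(rep(cnt, each = d[1]), d),
                     array(rep(cnt, each = d[1] * d[2]), d))
    vol <- sums / cntarr
  }
  vol
}

#' Binarize an image stack
#'
#' `"global"` thresholds at a user-specified intensity (the manual path used
#' when contrast varies between acquisitions); `"adaptive"` compares each
#' voxel against the local mean intensity in a cubic window plus an offset.
#' The applied parameters are recorded in the `provenance` attribute.
#'
#' @param stack an [image_stack()].
#' @param method `"adaptive"` or `"global"`.
#' @param threshold global intensity threshold (required for `"global"`).
#' @param window adaptive window size in voxels (default 32).
#' @param offset adaptive offset added to the local mean (default 0).
#' @return a [binary_mask()] with a `provenance` attribute.
#' @export
binarize <- function(stack, method = c("adaptive", "global"),
                     threshold = NULL, window = 32L, offset = 0) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  if (method == "global") {
    if (is.null(threshold)) stop("global method requires `threshold`")
    mask <- stack$voxels > threshold
    prov <- list(method = "global", threshold = threshold)
  } else {
    window <- as.integer(window)
    if (window < 3L) stop("adaptive window must be at least 3 voxels")
    local_mean <- box_mean(stack$voxels, window)
    mask <- stack$voxels > local_mean + offset
    prov <- list(method = "adaptive", window = window, offset = offset)
  }
  if (!any(mask)) warning("binarize produced an empty mask")
  out <- binary_mask(mask, stack$spacing)
  attr(out, "provenance") <- prov
  out
}

#' Fill cavities and drop small components
#'
#' Fully enclosed background cavities (6-connectivity) are filled, then
#' foreground connected components (26-connectivity) with fewer than
#' `min_voxels` voxels are removed; a component of exactly `min_voxels`
#' voxels is kept.
#'
#' @param mask a [binary_mask()].
#' @param min_voxels minimum component size kept (default 500).
#' @export
clean_mask <- function(mask, min_voxels = 500L) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$voxels)
  filled <- .fill_holes(as.logical(mask$voxels), d)
  lab <- .cc_label(filled, d, 26L)
  nl <- attr(lab, "n_components")
  if (nl > 0L) {
    sizes <- tabulate(lab, nbins = nl)
    keep <- sizes >= min_voxels
    filled <- filled & keep[pmax(lab, 1L)] & lab > 0L
  }
  out <- binary_mask(array(filled, d), mask$spacing)
  attr(out, "provenance") <- c(attr(mask, "provenance"),
                               list(min_voxels = min_voxels))
  out
}

#' Count connected components of a mask
#'
#' @param mask a [binary_mask()] or logical array.
#' @param connectivity 26 (default) or 6.
#' @export
count_components <- function(mask, connectivity = 26L) {
  vox <- if (inherits(mask, "binary_mask")) mask$voxels else mask
  lab <- .cc_label(as.logical(vox), dim(vox), as.integer(connectivity))
  attr(lab, "n_components")
}

#' Dice overlap coefficient between two masks
#' @param a,b binary masks or logical arrays of equal dimension.
#' @export
dice_coefficient <- function(a, b) {
  va <- if (inherits(a, "binary_mask")) a$voxels else a
  vb <- if (inherits(b, "binary_mask")) b$voxels else b
  stopifnot(identical(dim(va), dim(vb)))
  2 * sum(va & vb) / (sum(va) + sum(vb))
}
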