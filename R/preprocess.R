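# Preprocessing of raw serial-section acquisitions into registration-ready
# volumes: acquisition accounting, per-section maximum intensity projection,
# anti-aliased in-plane downsampling, depth padding/cropping, and per-section
# recentering used to initialize registration.

#' Acquisition geometry
#'
#' @param mosaic_rows,mosaic_cols mosaic tiling of each section scan.
#' @param sections physical sections.
#' @param planes optical planes per section.
#' @param channels emission channels (acquired simultaneously per tile scan).
#' @param lateral_um,axial_um nominal resolutions (um/pixel, um).
#' @export
acquisition_geometry <- function(mosaic_rows, mosaic_cols, sections, planes,
                                 channels, lateral_um = 0.875, axial_um = 20) {
  g <- list(mosaic_rows = as.integer(mosaic_rows),
            mosaic_cols = as.integer(mosaic_cols),
            sections = as.integer(sections), planes = as.integer(planes),
            channels = as.integer(channels),
            lateral_um = lateral_um, axial_um = axial_um)
  if (any(unlist(g[1:5]) < 1)) stop("all acquisition counts must be >= 1")
  class(g) <- "AcquisitionGeometry"
  g
}

#' Tile and stitched-image accounting
#'
#' Number of raw image tiles (mosaic positions x sections x optical planes;
#' emission channels are collected simultaneously per tile scan) and of
#' stitched 2D section images (one per section, plane and channel).
#'
#' @param g an [acquisition_geometry()].
#' @return list with `n_tiles` and `n_stitched`.
#' @export
acquisition_accounting <- function(g) {
  stopifnot(inherits(g, "AcquisitionGeometry"))
  list(n_tiles = g$mosaic_rows * g$mosaic_cols * g$sections * g$planes,
       n_stitched = g$sections * g$planes * g$channels)
}

#' Maximum intensity projection across optical planes
#'
#' @param planes list of 2D matrices (or a 3D array, planes along dim 1) of
#'   identical shape.
#' @return single 2D matrix, the voxelwise maximum.
#' @export
mip_project <- function(planes) {
  if (is.array(planes) && length(dim(planes)) == 3L)
    planes <- lapply(seq_len(dim(planes)[1]), function(i) planes[i, , ])
  stopifnot(length(planes) >= 1)
  d1 <- dim(planes[[1]])
  for (p in planes) if (!identical(dim(p), d1)) stop("plane shape mismatch")
  Reduce(pmax, planes)
}

# 1D area-weighted (anti-aliased) resampling matrix: rows = output pixels,
# each row averages the input interval it covers; mean-preserving.
area_weights <- function(n_in, src, target) {
  r <- target / src
  n_out <- floor(n_in / r)
  if (n_out < 1) stop("target spacing coarser than the full image extent")
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * r; b <- i * r
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) W[i, j] <- ov / r
    }
  }
  W
}

#' Anti-aliased in-plane downsampling
#'
#' Area-weighted resampling of each section to a coarser in-plane pixel size;
#' mean intensity is preserved (each output pixel is the area-weighted mean of
#' the input pixels it covers).
#'
#' @param image 2D matrix or `ImageVolume`.
#' @param target_um_per_px target in-plane pixel size (um).
#' @param src_um_per_px source pixel size; taken from the volume metadata
#'   when `image` is an `ImageVolume`.
#' @export
downsample_xy <- function(image, target_um_per_px, src_um_per_px = NULL) {
  is_vol <- inherits(image, "ImageVolume")
  src <- src_um_per_px %||% (if (is_vol) voxel_size(image)[2] else
    stop("src_um_per_px required for plain matrices"))
  if (target_um_per_px < src) stop("target pixel size must be >= source")
  if (target_um_per_px == src) return(image)
  if (is_vol) {
    d <- dim(image)
    Wy <- area_weights(d[2], src, target_um_per_px)
    Wx <- area_weights(d[3], src, target_um_per_px)
    out <- array(0, c(d[1], nrow(Wy), nrow(Wx)))
    for (z in seq_len(d[1])) out[z, , ] <- Wy %*% image[z, , ] %*% t(Wx)
    image_volume(out, c(voxel_size(image)[1], target_um_per_px, target_um_per_px),
                 attr(image, "channel"))
  } else {
    Wy <- area_weights(nrow(image), src, target_um_per_px)
    Wx <- area_weights(ncol(image), src, target_um_per_px)
    Wy %*% image %*% t(Wx)
  }
}

#' Pad or crop a volume to a fixed section count
#'
#' Padding appends blank (zero) sections at the caudal end; cropping removes
#' caudal excess. Retained sections are untouched.
#'
#' @param volume an `ImageVolume`.
#' @param target_sections target depth (default 200 sections).
#' @export
pad_or_crop_depth <- function(volume, target_sections = 200L) {
  stopifnot(target_sections >= 1)
  d <- dim(volume)
  if (d[1] == target_sections) return(volume)
  out <- array(0, c(target_sections, d[2], d[3]))
  keep <- seq_len(min(d[1], target_sections))
  out[keep, , ] <- as_plain_array(volume)[keep, , ]
  as_volume_like(out, volume)
}

# Otsu threshold on a vector of intensities
otsu_threshold <- function(v, nbins = 128L) {
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(Inf)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = nbins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[length(cm)]
  for (k in seq_len(nbins - 1)) {
    w0 <- cw[k]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- cm[k] / w0; m1 <- (mt - cm[k]) / w1
    vb <- w0 * w1 * (m0 - m1)^2
    if (vb > best) { best <- vb; thr <- h$breaks[k + 1] }
  }
  thr
}

#' Recenter sections on their tissue centroid
#'
#' For each section, the tissue is segmented by an Otsu threshold on the
#' nonzero intensities, the largest 4-connected component is taken, and the
#' section is shifted by an integer number of pixels so that the component
#' centroid lands on the image centre. Blank sections are untouched. Used to
#' initialize registration, so shifts are integer (no resampling blur).
#'
#' @param volume an `ImageVolume` (autofluorescence channel).
#' @return list with `volume` (recentered) and `shifts` (sections x 2 matrix
#'   of applied (dy, dx) shifts).
#' @export
recenter_sections <- function(volume) {
  d <- dim(volume)
  out <- as_plain_array(volume)
  shifts <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  center <- c((d[2] + 1) / 2, (d[3] + 1) / 2)
  for (z in seq_len(d[1])) {
    sec <- out[z, , ]
    nz <- sec[sec > 0]
    if (length(nz) < 16) next
    thr <- otsu_threshold(nz)
    mask <- sec > thr
    if (!any(mask)) next
    lab <- cpp_label2d(mask)
    tab <- tabulate(lab[lab > 0])
    comp <- lab == which.max(tab)
    cy <- mean(row(sec)[comp]); cx <- mean(col(sec)[comp])
    sh <- as.integer(round(center - c(cy, cx)))
    if (any(sh != 0L)) out[z, , ] <- shift_section(sec, sh[1], sh[2])
    shifts[z, ] <- sh
  }
  list(volume = as_volume_like(out, volume), shifts = shifts)
}

#' Apply integer per-section shifts
#'
#' Applies shifts (e.g. from [recenter_sections()] on the autofluorescence
#' channel) to another channel of the same sample.
#'
#' @param volume an `ImageVolume`.
#' @param shifts sections x 2 integer matrix of (dy, dx).
#' @export
apply_section_shifts <- function(volume, shifts) {
  d <- dim(volume)
  stopifnot(nrow(shifts) == d[1])
  out <- as_plain_array(volume)
  for (z in seq_len(d[1]))
    if (any(shifts[z, ] != 0L))
      out[z, , ] <- shift_section(out[z, , ], shifts[z, 1], shifts[z, 2])
  as_volume_like(out, volume)
}

# integer 2D shift with zero fill
shift_section <- function(sec, dy, dx) {
  ny <- nrow(sec); nx <- ncol(sec)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[which(oky), which(okx)] <- sec[ys[oky], xs[okx]]
  out
}
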