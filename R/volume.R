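#' Image volume container
#'
#' A thin container for a 3D intensity grid: a numeric array with dimensions
#' `c(z, y, x)` (sections x rows x columns, rostral to caudal along z)
#' carrying its voxel sizes in micrometres and the channel role. Intensities
#' are kept as doubles on a 16-bit-like 0-65535 scale.
#'
#' @param data numeric 3D array, dim `c(nz, ny, nx)`.
#' @param voxel_size numeric length-3, micrometres per voxel along (z, y, x).
#' @param channel channel role, e.g. `"autofluorescence"` or `"signal"`.
#' @return An `ImageVolume` (array subclass).
#' @export
image_volume <- function(data, voxel_size = c(40, 10, 10), channel = "autofluorescence") {
  if (length(dim(data)) == 2L) dim(data) <- c(1L, dim(data))
  stopifnot(length(dim(data)) == 3L, length(voxel_size) == 3L, all(voxel_size > 0))
  structure(as.array(data * 1.0),
            voxel_size = as.numeric(voxel_size),
            channel = channel,
            class = c("ImageVolume", "array"))
}

#' Voxel sizes of a volume
#' @param x an `ImageVolume` or `AnnotationVolume`.
#' @return numeric length-3 (z, y, x) in micrometres.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) stop("object carries no voxel_size attribute")
  vs
}

#' @export
print.ImageVolume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("ImageVolume [%s channel] %d x %d x %d voxels (z,y,x), %s um\n",
              attr(x, "channel") %||% "?", d[1], d[2], d[3],
              paste(signif(voxel_size(x), 4), collapse = " x ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild an ImageVolume around new data, inheriting metadata from `like`
as_volume_like <- function(data, like, voxel_size = NULL) {
  image_volume(data,
               voxel_size = voxel_size %||% attr(like, "voxel_size") %||% c(40, 10, 10),
               channel = attr(like, "channel") %||% "autofluorescence")
}

# strip to a plain array (drops class/attrs except dim)
as_plain_array <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}

# physical (z,y,x) coordinates in um of 1-based voxel indices; origin at voxel 1 = 0
voxel_to_phys <- function(idx, vs) {
  sweep(idx - 1, 2, vs, `*`)
}

phys_to_voxel0 <- function(pts, vs) {
  sweep(pts, 2, vs, `/`)
}

# all voxel physical coordinates of a z-slab (rows vary z fastest, matching
# R array linearization of arr[zsel, , ])
slab_phys_coords <- function(dimv, vs, zsel) {
  nz <- length(zsel); ny <- dimv[2]; nx <- dimv[3]
  z <- rep.int(zsel, times = ny * nx)
  y <- rep.int(rep(seq_len(ny), each = nz), times = nx)
  x <- rep(seq_len(nx), each = nz * ny)
  cbind((z - 1) * vs[1], (y - 1) * vs[2], (x - 1) * vs[3])
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian blur with reflected boundaries.
#'
#' @param vol `ImageVolume` or 3D array.
#' @param sigma standard deviation in voxels, length 1 (in-plane only) or 3
#'   (z, y, x); non-positive entries skip that axis.
#' @return blurred object of the same kind.
#' @export
gauss_smooth <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- c(0, sigma, sigma)
  d <- dim(vol)
  out <- cpp_gauss_sep(as.numeric(vol), as.integer(d), as.numeric(sigma))
  dim(out) <- d
  if (inherits(vol, "ImageVolume")) out <- as_volume_like(out, vol)
  out
}
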