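# Parametric spatial transforms and transform chains.
#
# Convention (resampling form): a transform maps physical
# coordinates (z, y, x in micrometres) of the FIXED space to coordinates in
# the MOVING space. apply_transform() resamples the moving volume on the
# fixed grid by pulling intensities back through the chain. Transforms in a
# chain are applied sequentially in list order.

#' Build an affine-type transform
#'
#' @param A 3x3 matrix acting on (z, y, x) physical coordinates (um).
#' @param b length-3 translation (um).
#' @param type one of `"rigid"`, `"affine"`, `"landmark_affine"`.
#' @param params optional named parameter vector kept for reporting.
#' @return a transform object (list).
#' @export
affine_transform <- function(A = diag(3), b = c(0, 0, 0), type = "affine",
                             params = NULL) {
  A <- matrix(as.numeric(A), 3, 3)
  if (det(A) <= 0) stop("affine transform must have positive Jacobian determinant")
  structure(list(type = type, A = A, b = as.numeric(b), params = params),
            class = "cq_transform")
}

#' Build a rigid transform from angles and translation
#'
#' Rotations are applied about the given centre in the order z, y, x
#' (a z-rotation rotates the in-plane (y, x) axes).
#'
#' @param angles length-3 rotation angles (radians) about the z, y, x axes.
#' @param translation length-3 translation (um, z/y/x order).
#' @param center rotation centre in physical um (z, y, x).
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  az <- angles[1]; ay <- angles[2]; ax <- angles[3]
  # coordinate order (z, y, x)
  Rz <- rbind(c(1, 0, 0),
              c(0, cos(az), -sin(az)),
              c(0, sin(az), cos(az)))
  Ry <- rbind(c(cos(ay), 0, -sin(ay)),
              c(0, 1, 0),
              c(sin(ay), 0, cos(ay)))
  Rx <- rbind(c(cos(ax), -sin(ax), 0),
              c(sin(ax), cos(ax), 0),
              c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  b <- as.numeric(center - R %*% center + translation)
  affine_transform(R, b, type = "rigid",
                   params = c(angle_z = az, angle_y = ay, angle_x = ax,
                              tz = translation[1], ty = translation[2],
                              tx = translation[3]))
}

#' Build a cubic b-spline free-form deformation transform
#'
#' @param coef control-point displacement matrix `(prod(ncp)) x 3` in um
#'   (z index fastest), or `NULL` for an all-zero field.
#' @param origin physical position (um) of the first control point.
#' @param spacing control grid spacing (um per axis, z/y/x).
#' @param ncp number of control points per axis.
#' @export
bspline_transform <- function(coef = NULL, origin, spacing, ncp) {
  ncp <- as.integer(ncp)
  if (any(ncp < 4)) stop("b-spline grid needs at least 4 control points per axis")
  if (is.null(coef)) coef <- matrix(0, prod(ncp), 3)
  stopifnot(nrow(coef) == prod(ncp), ncol(coef) == 3)
  structure(list(type = "bspline", origin = as.numeric(origin),
                 spacing = as.numeric(spacing), ncp = ncp,
                 coef = unname(as.matrix(coef))),
            class = "cq_transform")
}

# control grid covering a physical extent (um) with margin
bspline_grid_for <- function(extent_lo, extent_hi, spacing) {
  origin <- extent_lo - spacing
  ncp <- pmax(4L, as.integer(ceiling((extent_hi - extent_lo) / spacing)) + 3L)
  list(origin = origin, ncp = ncp)
}

# sparse basis-weight matrix (N x prod(ncp)) for fixed evaluation points,
# used during optimization where coefficients change but points do not
bspline_weight_matrix <- function(tf, pts) {
  n <- nrow(pts)
  ncp <- tf$ncp
  u <- sweep(sweep(pts, 2, tf$origin, `-`), 2, tf$spacing, `/`)
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(ncp - 4L, each = n), n, 3))
  t <- u - i0
  bw <- function(t) cbind((1 - 3 * t + 3 * t^2 - t^3) / 6,
                          (4 - 6 * t^2 + 3 * t^3) / 6,
                          (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6,
                          t^3 / 6)
  wz <- bw(t[, 1]); wy <- bw(t[, 2]); wx <- bw(t[, 3])
  ii <- integer(n * 64); jj <- integer(n * 64); xx <- numeric(n * 64)
  k <- 1L
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
    idx <- seq.int(k, by = 64L, length.out = n)
    ii[idx] <- seq_len(n)
    jj[idx] <- (i0[, 1] + a) + ncp[1] * ((i0[, 2] + b) + ncp[2] * (i0[, 3] + cc)) + 1
    xx[idx] <- wz[, a + 1] * wy[, b + 1] * wx[, cc + 1]
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, prod(ncp)))
}

# apply a single transform to an N x 3 matrix of physical points
transform_points <- function(tf, pts) {
  if (tf$type == "bspline") {
    pts + cpp_bspline_disp(pts, tf$origin, tf$spacing, tf$ncp, tf$coef)
  } else {
    sweep(pts %*% t(tf$A), 2, tf$b, `+`)
  }
}

#' Assemble a transform chain
#'
#' @param ... transforms, applied in the given order (each maps fixed-space
#'   physical coordinates one step closer to the moving space).
#' @param fixed_geometry list with `dim` (z, y, x voxel counts) and
#'   `voxel_size` (um) of the fixed (output) grid.
#' @export
transform_chain <- function(..., fixed_geometry) {
  tfs <- list(...)
  if (length(tfs) == 1L && is.list(tfs[[1]]) && !inherits(tfs[[1]], "cq_transform"))
    tfs <- tfs[[1]]
  stopifnot(all(vapply(tfs, inherits, TRUE, "cq_transform")),
            !is.null(fixed_geometry$dim), !is.null(fixed_geometry$voxel_size))
  structure(list(transforms = tfs, fixed_geometry = fixed_geometry),
            class = "TransformChain")
}

#' Map physical points through a transform chain
#'
#' @param chain a `TransformChain`.
#' @param pts N x 3 matrix of fixed-space physical coordinates (um, z/y/x).
#' @return N x 3 matrix of moving-space physical coordinates.
#' @export
chain_map <- function(chain, pts) {
  for (tf in chain$transforms) pts <- transform_points(tf, pts)
  pts
}

#' Resample a volume through a transform chain
#'
#' Pulls the moving volume back onto the fixed grid declared in the chain.
#' Linear interpolation is used for intensity and probability images, nearest
#' neighbour for label volumes; voxels mapping outside the source get 0.
#'
#' @param volume moving `ImageVolume` (or labelled `AnnotationVolume`).
#' @param chain a `TransformChain` whose fixed geometry defines the output.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return resampled volume on the fixed grid.
#' @export
apply_transform <- function(volume, chain, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  fg <- chain$fixed_geometry
  dimf <- as.integer(fg$dim)
  vsf <- as.numeric(fg$voxel_size)
  vsm <- voxel_size(volume)
  mode <- if (interpolation == "nearest") 1L else 0L
  out <- array(0, dimf)
  vol_num <- as.numeric(volume)
  dim_m <- as.integer(dim(volume))
  # process in z-slabs to bound the coordinate matrices
  slab <- max(1L, as.integer(ceiling(4e5 / (dimf[2] * dimf[3]))))
  z0 <- 1L
  while (z0 <= dimf[1]) {
    zsel <- z0:min(dimf[1], z0 + slab - 1L)
    pts <- slab_phys_coords(dimf, vsf, zsel)
    pts <- chain_map(chain, pts)
    vals <- cpp_sample_points(vol_num, dim_m, phys_to_voxel0(pts, vsm), mode, 0)
    out[zsel, , ] <- vals
    z0 <- z0 + slab
  }
  if (inherits(volume, "AnnotationVolume")) {
    annotation_volume(array(as.integer(round(out)), dimf), voxel_size = vsf,
                      ontology = attr(volume, "ontology"),
                      midline_x = attr(volume, "midline_x"))
  } else {
    image_volume(out, voxel_size = vsf, channel = attr(volume, "channel") %||% "signal")
  }
}

# compose all leading affine-type transforms of a chain into (A, b)
compose_affines <- function(tfs) {
  A <- diag(3); b <- c(0, 0, 0)
  for (tf in tfs) {
    stopifnot(tf$type != "bspline")
    # existing map p -> A p + b, then tf: q -> tf$A q + tf$b
    A <- tf$A %*% A
    b <- as.numeric(tf$A %*% b) + tf$b
  }
  list(A = A, b = b)
}

#' Serialize a transform chain to JSON
#' @param chain a `TransformChain`.
#' @param path output file.
#' @export
write_transform_chain <- function(chain, path) {
  enc <- list(
    fixed_geometry = chain$fixed_geometry,
    transforms = lapply(chain$transforms, function(tf) {
      if (tf$type == "bspline")
        list(type = "bspline", origin = tf$origin, spacing = tf$spacing,
             ncp = tf$ncp, coef = tf$coef)
      else
        list(type = tf$type, A = tf$A, b = tf$b, params = tf$params)
    })
  )
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a transform chain from JSON
#' @param path JSON file written by [write_transform_chain()].
#' @export
read_transform_chain <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tfs <- lapply(seq_len(if (is.data.frame(enc$transforms)) nrow(enc$transforms)
                        else length(enc$transforms)), function(i) {
    tf <- if (is.data.frame(enc$transforms)) lapply(enc$transforms, `[[`, i)
          else enc$transforms[[i]]
    if (tf$type == "bspline")
      bspline_transform(matrix(unlist(tf$coef), ncol = 3), unlist(tf$origin),
                        unlist(tf$spacing), unlist(tf$ncp))
    else
      affine_transform(matrix(unlist(tf$A), 3, 3), unlist(tf$b), type = tf$type,
                       params = if (!is.null(tf$params)) unlist(tf$params))
  })
  transform_chain(tfs, fixed_geometry = list(
    dim = as.integer(unlist(enc$fixed_geometry$dim)),
    voxel_size = as.numeric(unlist(enc$fixed_geometry$voxel_size))))
}
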