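# Multistep intensity-based registration: rigid, then affine, then cubic
# b-spline free-form refinement, each optimized on a multiresolution pyramid
# with a mutual-information metric estimated from randomly sampled fixed
# voxels (joint histogram with first-order Parzen windowing). A landmark
# (fiducial) affine solved in closed form can be prepended for poorly
# initialized samples. Transforms map fixed-space physical coordinates to
# moving-space coordinates (resampling convention).

#' Registration configuration
#'
#' @param pyramid_levels multiresolution levels (default 6; level spacing
#'   halves each level, capped so no axis drops below 8 voxels).
#' @param bins histogram bins for the mutual-information metric.
#' @param iterations optimizer iteration budget per level (Nelder-Mead).
#' @param sample_fraction fraction of fixed voxels sampled per level.
#' @param max_samples cap on metric samples per level.
#' @param stages registration components, in order.
#' @param bspline_spacing final b-spline control grid spacing in um
#'   (default 1 x 1 x 1 mm).
#' @param bspline_iterations L-BFGS-B iterations for the b-spline stage.
#' @param bspline_samples metric samples for the b-spline stage.
#' @param seed RNG seed for metric sampling (required; all stochastic
#'   sampling derives from it).
#' @export
registration_config <- function(pyramid_levels = 6L, bins = 32L,
                                iterations = 300L, sample_fraction = 0.1,
                                max_samples = 10000L,
                                stages = c("rigid", "affine", "bspline"),
                                bspline_spacing = c(1000, 1000, 1000),
                                bspline_iterations = 20L,
                                bspline_samples = 4000L,
                                seed = 1L) {
  stopifnot(pyramid_levels >= 1, all(bspline_spacing > 0), !is.null(seed))
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 bins = as.integer(bins), iterations = as.integer(iterations),
                 sample_fraction = sample_fraction,
                 max_samples = as.integer(max_samples),
                 stages = stages, bspline_spacing = as.numeric(bspline_spacing),
                 bspline_iterations = as.integer(bspline_iterations),
                 bspline_samples = as.integer(bspline_samples),
                 seed = as.integer(seed)),
            class = "RegistrationConfig")
}

# Gaussian-smoothed, decimated pyramid; level L is full resolution.
build_pyramid <- function(vol, levels, min_dim = 8L) {
  d <- dim(vol); vs <- voxel_size(vol)
  arr <- as_plain_array(vol)
  lapply(seq_len(levels), function(l) {
    f <- pmax(1L, pmin(2L^(levels - l), d %/% min_dim))
    if (all(f == 1L)) return(list(arr = arr, dim = d, vs = vs))
    sm <- cpp_gauss_sep(arr, d, f / 2)
    dim(sm) <- d
    sub <- sm[seq(1, d[1], by = f[1]), seq(1, d[2], by = f[2]),
              seq(1, d[3], by = f[3]), drop = FALSE]
    list(arr = sub, dim = dim(sub), vs = vs * f)
  })
}

# random fixed-voxel metric samples at one pyramid level
metric_samples <- function(pyr, n, seed) {
  nvox <- prod(pyr$dim)
  n <- min(n, nvox)
  idx <- with_seed(seed, sample.int(nvox, n))
  pts <- (arrayInd(idx, pyr$dim) - 1) * matrix(pyr$vs, n, 3, byrow = TRUE)
  list(pts = pts, vals = as.numeric(pyr$arr[idx]),
       fmin = min(pyr$arr), fmax = max(pyr$arr))
}

mi_of_points <- function(smp, mov, pts_m, bins) {
  cpp_mi_points(smp$vals, as.numeric(mov$arr), as.integer(mov$dim),
                sweep(pts_m, 2, mov$vs, `/`), bins, smp$fmin, smp$fmax)
}

#' Mutual information between two volumes under a transform chain
#'
#' Deterministic (strided) sampling of the fixed grid; used to report and
#' test the stagewise metric-improvement property.
#'
#' @param fixed,moving `ImageVolume`s.
#' @param chain optional `TransformChain` mapping fixed to moving space
#'   (identity when `NULL`).
#' @param bins histogram bins.
#' @param n_samples approximate number of fixed samples.
#' @export
mutual_information <- function(fixed, moving, chain = NULL, bins = 32L,
                               n_samples = 30000L) {
  d <- dim(fixed); vsf <- voxel_size(fixed)
  stride <- max(1L, floor(prod(d) / n_samples))
  idx <- seq(1L, prod(d), by = stride)
  pts <- (arrayInd(idx, d) - 1) * matrix(vsf, length(idx), 3, byrow = TRUE)
  if (!is.null(chain)) pts <- chain_map(chain, pts)
  arrf <- as_plain_array(fixed)
  cpp_mi_points(as.numeric(arrf[idx]), as.numeric(as_plain_array(moving)),
                as.integer(dim(moving)), sweep(pts, 2, voxel_size(moving), `/`),
                as.integer(bins), min(arrf), max(arrf))
}

# physical center of mass of a volume (um)
center_of_mass <- function(vol) {
  arr <- as_plain_array(vol)
  arr <- pmax(arr, 0)
  tot <- sum(arr)
  if (tot <= 0) return((dim(vol) - 1) / 2 * voxel_size(vol))
  d <- dim(vol)
  sz <- apply(arr, 1, sum); sy <- apply(arr, 2, sum); sx <- apply(arr, 3, sum)
  c(sum(sz * (seq_len(d[1]) - 1)), sum(sy * (seq_len(d[2]) - 1)),
    sum(sx * (seq_len(d[3]) - 1))) / tot * voxel_size(vol)
}

#' Multistep registration of a sample to a template
#'
#' Rigid, then affine, then b-spline free-form registration, each optimized
#' over a multiresolution pyramid with a sampled mutual-information metric.
#' Initialization aligns intensity centroids. A stage is kept only if it does
#' not decrease the metric evaluated on a held-out deterministic sample, so
#' the returned chain never underperforms its predecessor stages.
#'
#' @param moving sample `ImageVolume` (e.g. recentered autofluorescence).
#' @param fixed template `ImageVolume`.
#' @param cfg a [registration_config()].
#' @param fiducials optional list with `sample` and `atlas` N x 3 matrices of
#'   corresponding physical points (um); when given, the closed-form landmark
#'   affine is prepended as an additional stage before optimization
#'   (`landmark_mode = "augment"`), or replaces the automated rigid/affine
#'   stages (`"replace"`).
#' @param landmark_mode see `fiducials`.
#' @return a `TransformChain` ([rigid, affine, bspline] in order, plus a
#'   leading landmark affine when requested) with per-stage metric values in
#'   `attr(, "diagnostics")`.
#' @export
register_multistep <- function(moving, fixed, cfg = registration_config(),
                               fiducials = NULL,
                               landmark_mode = c("augment", "replace")) {
  landmark_mode <- match.arg(landmark_mode)
  stopifnot(inherits(moving, "ImageVolume"), inherits(fixed, "ImageVolume"))
  if (diff(range(moving)) == 0 || diff(range(fixed)) == 0)
    stop("registration metric undefined: a volume has no intensity content ",
         "(no overlapping structure to align)")
  L <- cfg$pyramid_levels
  pyr_f <- build_pyramid(fixed, L)
  pyr_m <- build_pyramid(moving, L)
  fg <- list(dim = dim(fixed), voxel_size = voxel_size(fixed))
  base <- list()  # transforms preceding the optimized stages
  diagnostics <- list()

  if (!is.null(fiducials)) {
    lm <- landmark_affine(fiducials$sample, fiducials$atlas)
    base <- c(base, list(lm$transform))
    com_f <- center_of_mass(fixed)
    t_init <- c(0, 0, 0)
  } else {
    com_f <- center_of_mass(fixed)
    t_init <- center_of_mass(moving) - com_f
  }

  # held-out evaluation sample (finest level) for stage acceptance
  eval_smp <- metric_samples(pyr_f[[L]], cfg$max_samples,
                             derive_seed(cfg$seed, "eval"))
  eval_mi <- function(tfs) {
    pts <- eval_smp$pts
    for (tf in tfs) pts <- transform_points(tf, pts)
    mi_of_points(eval_smp, pyr_m[[L]], pts, cfg$bins)
  }
  mi0 <- eval_mi(base)
  if (is.na(mi0))
    stop("registration metric undefined: fixed and moving content do not overlap")
  diagnostics$initial_mi <- mi0

  stage_pts <- function(tfs, smp) {
    pts <- smp$pts
    for (tf in tfs) pts <- transform_points(tf, pts)
    pts
  }

  chain_tfs <- base
  do_stage <- function(stage) {
    if (stage == "rigid" && is.null(fiducials)) {
      p <- c(0, 0, 0, t_init)
      for (l in seq_len(L)) {
        smp <- metric_samples(pyr_f[[l]],
                              max(2000L, min(cfg$max_samples,
                                             ceiling(cfg$sample_fraction * prod(pyr_f[[l]]$dim)))),
                              derive_seed(cfg$seed, paste0("rigid", l)))
        pts0 <- stage_pts(chain_tfs, smp)
        fn <- function(p) {
          tf <- rigid_transform(p[1:3], p[4:6], com_f)
          mi <- mi_of_points(smp, pyr_m[[l]],
                             sweep(pts0 %*% t(tf$A), 2, tf$b, `+`), cfg$bins)
          if (is.na(mi)) 10 else -mi
        }
        ps <- c(rep(0.02, 3), rep(2 * mean(pyr_m[[l]]$vs), 3))
        nstart <- if (l >= L - 1) 2L else 1L  # simplex restart at fine levels
        for (r in seq_len(nstart))
          p <- optim(p, fn, method = "Nelder-Mead",
                     control = list(maxit = cfg$iterations, parscale = ps,
                                    reltol = 1e-8))$par
      }
      rigid_transform(p[1:3], p[4:6], com_f)
    } else if (stage == "rigid") {
      # landmark affine already initializes; identity rigid placeholder
      rigid_transform(c(0, 0, 0), c(0, 0, 0), com_f)
    } else if (stage == "affine") {
      p <- rep(0, 12)
      for (l in seq_len(L)) {
        smp <- metric_samples(pyr_f[[l]],
                              max(2000L, min(cfg$max_samples,
                                             ceiling(cfg$sample_fraction * prod(pyr_f[[l]]$dim)))),
                              derive_seed(cfg$seed, paste0("affine", l)))
        pts0 <- stage_pts(chain_tfs, smp)
        fn <- function(p) {
          A <- diag(3) + matrix(p[1:9], 3, 3)
          if (det(A) < 0.05) return(10)
          b <- as.numeric((diag(3) - A) %*% com_f) + p[10:12]
          mi <- mi_of_points(smp, pyr_m[[l]],
                             sweep(pts0 %*% t(A), 2, b, `+`), cfg$bins)
          if (is.na(mi)) 10 else -mi
        }
        ps <- c(rep(0.02, 9), rep(2 * mean(pyr_m[[l]]$vs), 3))
        nstart <- if (l >= L - 1) 2L else 1L
        for (r in seq_len(nstart))
          p <- optim(p, fn, method = "Nelder-Mead",
                     control = list(maxit = cfg$iterations, parscale = ps,
                                    reltol = 1e-8))$par
      }
      A <- diag(3) + matrix(p[1:9], 3, 3)
      affine_transform(A, as.numeric((diag(3) - A) %*% com_f) + p[10:12],
                       type = "affine")
    } else if (stage == "bspline") {
      # single (finest) level; control grid covers the moving extent
      smp <- metric_samples(pyr_f[[L]], cfg$bspline_samples,
                            derive_seed(cfg$seed, "bspline"))
      pts0 <- stage_pts(chain_tfs, smp)
      ext_hi <- (dim(moving) - 1) * voxel_size(moving)
      grid <- bspline_grid_for(c(0, 0, 0) - 0.1 * ext_hi, 1.1 * ext_hi,
                               cfg$bspline_spacing)
      tf0 <- bspline_transform(NULL, grid$origin, cfg$bspline_spacing, grid$ncp)
      W <- bspline_weight_matrix(tf0, pts0)
      ncp_tot <- prod(grid$ncp)
      fn <- function(cf) {
        D <- as.matrix(W %*% matrix(cf, ncp_tot, 3))
        mi <- mi_of_points(smp, pyr_m[[L]], pts0 + D, cfg$bins)
        if (is.na(mi)) 10 else -mi
      }
      res <- optim(rep(0, ncp_tot * 3), fn, method = "L-BFGS-B",
                   lower = -3 * max(cfg$bspline_spacing),
                   upper = 3 * max(cfg$bspline_spacing),
                   control = list(maxit = cfg$bspline_iterations,
                                  ndeps = rep(1.0, ncp_tot * 3), factr = 1e10))
      bspline_transform(matrix(res$par, ncp_tot, 3), grid$origin,
                        cfg$bspline_spacing, grid$ncp)
    } else stop("unknown registration stage: ", stage)
  }

  stages <- cfg$stages
  if (!is.null(fiducials) && landmark_mode == "replace")
    stages <- setdiff(stages, c("rigid", "affine"))
  mi_prev <- mi0
  for (stage in stages) {
    cand <- do_stage(stage)
    mi_new <- eval_mi(c(chain_tfs, list(cand)))
    if (!is.na(mi_new) && mi_new >= mi_prev - 1e-9) {
      chain_tfs <- c(chain_tfs, list(cand))
      mi_prev <- mi_new
    } else {
      # keep an identity placeholder so the chain structure is stable
      ident <- if (stage == "bspline")
        bspline_transform(NULL, c(0, 0, 0) - voxel_size(moving),
                          cfg$bspline_spacing,
                          pmax(4L, as.integer(ceiling((dim(moving) - 1) *
                                                        voxel_size(moving) /
                                                        cfg$bspline_spacing)) + 3L))
      else affine_transform(diag(3), c(0, 0, 0), type = stage)
      chain_tfs <- c(chain_tfs, list(ident))
    }
    diagnostics[[paste0("mi_", stage)]] <- mi_prev
  }
  chain <- transform_chain(chain_tfs, fixed_geometry = fg)
  attr(chain, "diagnostics") <- diagnostics
  chain
}

#' Closed-form landmark affine from fiducial pairs
#'
#' Least-squares affine minimizing the sum of squared Euclidean distances
#' between mapped atlas points and their corresponding sample points
#' (resampling convention: maps atlas/fixed coordinates to sample/moving
#' coordinates).
#'
#' @param sample_points,atlas_points N x 3 matrices of corresponding physical
#'   coordinates (um, z/y/x); N >= 4, non-coplanar.
#' @return list with `transform` (`landmark_affine` transform), `residual_rms`
#'   and `n_points`.
#' @export
landmark_affine <- function(sample_points, atlas_points) {
  sample_points <- as.matrix(sample_points)
  atlas_points <- as.matrix(atlas_points)
  stopifnot(ncol(sample_points) == 3, ncol(atlas_points) == 3,
            nrow(sample_points) == nrow(atlas_points))
  n <- nrow(atlas_points)
  if (n < 4) stop("at least 4 fiducial pairs are required")
  X <- cbind(atlas_points, 1)
  qrx <- qr(X)
  if (qrx$rank < 4)
    stop("degenerate fiducial configuration (coplanar or collinear points)")
  coef <- qr.coef(qrx, sample_points)
  A <- t(coef[1:3, , drop = FALSE])
  b <- as.numeric(coef[4, ])
  resid <- X %*% coef - sample_points
  rms <- sqrt(mean(resid^2))  # per-coordinate RMS (12 dof absorbed)
  list(transform = affine_transform(A, b, type = "landmark_affine"),
       residual_rms = rms, n_points = n)
}

#' Write fiducial pairs to CSV
#'
#' Columns `point_index`, `space` (sample|atlas), `z`, `y`, `x` in 0-based
#' voxel units.
#'
#' @param sample_vox,atlas_vox N x 3 matrices of 1-based voxel coordinates.
#' @param path output CSV.
#' @export
write_fiducials <- function(sample_vox, atlas_vox, path) {
  n <- nrow(sample_vox)
  df <- rbind(
    data.frame(point_index = seq_len(n) - 1L, space = "sample",
               z = sample_vox[, 1] - 1, y = sample_vox[, 2] - 1,
               x = sample_vox[, 3] - 1),
    data.frame(point_index = seq_len(n) - 1L, space = "atlas",
               z = atlas_vox[, 1] - 1, y = atlas_vox[, 2] - 1,
               x = atlas_vox[, 3] - 1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fiducial pairs from CSV
#' @param path CSV written by [write_fiducials()].
#' @return list with `sample` and `atlas` N x 3 matrices (1-based voxels).
#' @export
read_fiducials <- function(path) {
  df <- read.csv(path)
  s <- df[df$space == "sample", ]; a <- df[df$space == "atlas", ]
  s <- s[order(s$point_index), ]; a <- a[order(a$point_index), ]
  stopifnot(identical(s$point_index, a$point_index))
  list(sample = as.matrix(s[, c("z", "y", "x")]) + 1,
       atlas = as.matrix(a[, c("z", "y", "x")]) + 1)
}
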