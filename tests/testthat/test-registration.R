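# Landmark affine, transform application, and light registration checks
# (the full-size rigid/affine recovery runs live in test-acceptance.R).

test_that("landmark affine recovers known mappings in closed form", {
  set.seed(5)
  atlas <- matrix(runif(60 * 3, 0, 2000), 60, 3)
  fit0 <- landmark_affine(atlas, atlas)
  expect_equal(fit0$transform$A, diag(3), tolerance = 1e-12)
  expect_equal(fit0$transform$b, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit0$residual_rms, 0, tolerance = 1e-9)

  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  b <- c(30, -12, 55)
  sample_pts <- sweep(atlas %*% t(A), 2, b, `+`)
  fit <- landmark_affine(sample_pts, atlas)
  expect_lt(max(abs(fit$transform$A - A)), 1e-6)
  expect_lt(max(abs(fit$transform$b - b)), 1e-6)
  expect_lt(fit$residual_rms, 1e-8)

  # residual under isotropic target noise tracks sigma (12 dof absorbed)
  sigma <- 2
  rms <- vapply(1:20, function(i) {
    noisy <- sample_pts + matrix(rnorm(180, 0, sigma), 60, 3)
    landmark_affine(noisy, atlas)$residual_rms
  }, 0)
  expect_lt(mean(rms), 1.2 * sigma)
  expect_gt(mean(rms), 0.8 * sigma)

  expect_error(landmark_affine(sample_pts[1:3, ], atlas[1:3, ]), "4 fiducial")
  coplanar <- cbind(atlas[, 1:2], 5)
  expect_error(landmark_affine(coplanar, coplanar), "degenerate")
})

test_that("transform application respects interpolation and direction", {
  tpl <- tiny_phantom()
  vol <- tpl$autofluorescence
  d <- dim(vol); vs <- voxel_size(vol)
  fg <- list(dim = d, voxel_size = vs)
  ident <- transform_chain(affine_transform(diag(3)), fixed_geometry = fg)
  expect_identical(unclass(apply_transform(vol, ident, "nearest")), unclass(vol))
  expect_lt(max(abs(apply_transform(vol, ident, "linear") - vol)), 1)

  tr <- affine_transform(diag(3), c(0, 30, -40))
  inv <- affine_transform(diag(3), c(0, -30, 40))
  fwd <- apply_transform(vol, transform_chain(tr, fixed_geometry = fg), "linear")
  back <- apply_transform(fwd, transform_chain(inv, fixed_geometry = fg), "linear")
  interior <- unclass(vol)[, 11:62, 11:62]
  expect_lt(max(abs(unclass(back)[, 11:62, 11:62] - interior)), 2)

  ann <- tpl$annotation
  wann <- apply_transform(ann, transform_chain(tr, fixed_geometry = fg), "nearest")
  expect_true(all(unique(as.vector(wann)) %in% unique(as.vector(ann))))
  expect_error(apply_transform(vol, ident, "cubic"), "arg")

  # direction: resampling pulls intensities, so a +x translation in the chain
  # moves image content toward -x
  imp <- array(0, c(1, 21, 21)); imp[1, 11, 15] <- 100
  iv <- image_volume(imp, c(40, 10, 10))
  ch <- transform_chain(affine_transform(diag(3), c(0, 0, 4 * 10)),
                        fixed_geometry = list(dim = dim(iv), voxel_size = voxel_size(iv)))
  mv <- apply_transform(iv, ch, "nearest")
  expect_equal(mv[1, 11, 11], 100)
})

test_that("transform chains serialize to JSON and back", {
  grid <- bspline_grid_for(c(0, 0, 0), c(400, 700, 700), c(300, 300, 300))
  set.seed(3)
  bs <- bspline_transform(matrix(rnorm(prod(grid$ncp) * 3, 0, 5), ncol = 3),
                          grid$origin, c(300, 300, 300), grid$ncp)
  chain <- transform_chain(
    rigid_transform(c(0.1, 0, 0), c(5, -3, 2), c(200, 350, 350)),
    affine_transform(diag(c(1, 0.95, 1.05)), c(0, 1, -1)), bs,
    fixed_geometry = list(dim = c(10L, 64L, 64L), voxel_size = c(40, 10, 10)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_chain(chain, path)
  back <- read_transform_chain(path)
  pts <- matrix(runif(30, 0, 600), 10, 3)
  expect_equal(chain_map(back, pts), chain_map(chain, pts), tolerance = 1e-12)
  expect_identical(back$fixed_geometry$dim, chain$fixed_geometry$dim)
})

test_that("fiducial CSV round-trips with the 0-based interchange convention", {
  s <- matrix(sample.int(50, 30), 10, 3)
  a <- matrix(sample.int(50, 30), 10, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiducials(s, a, path)
  raw <- read.csv(path)
  expect_equal(min(raw$point_index), 0)  # 0-based on disk
  expect_equal(raw$z[raw$space == "sample"], s[, 1] - 1)
  back <- read_fiducials(path)
  expect_equal(back$sample, unname(s), ignore_attr = TRUE)
  expect_equal(back$atlas, unname(a), ignore_attr = TRUE)
})

test_that("registration of small deformations improves mutual information stagewise", {
  tpl <- tiny_phantom()
  fixed <- tpl$autofluorescence
  def <- deform_sample(list(a = fixed), magnitude = list(
    translate = 4, translate_z = 0, rotate = 3, scale = 0.03,
    elastic_amp = 8, elastic_spacing = 300), seed = 4)
  moving <- def$volumes$a
  cfg <- registration_config(pyramid_levels = 3L, iterations = 150L,
                             bspline_spacing = c(300, 300, 300),
                             bspline_iterations = 10L, seed = 2)
  chain <- register_multistep(moving, fixed, cfg)
  di <- attr(chain, "diagnostics")
  expect_gte(di$mi_rigid, di$initial_mi - 1e-3)
  expect_gte(di$mi_affine, di$mi_rigid - 1e-3)
  expect_gte(di$mi_bspline, di$mi_affine - 1e-3)
  expect_identical(vapply(chain$transforms, `[[`, "", "type"),
                   c("rigid", "affine", "bspline"))
  # warped moving should be closer to fixed than the unregistered moving
  warped <- apply_transform(moving, chain, "linear")
  expect_lt(mean((warped - fixed)^2), mean((moving - fixed)^2))

  # non-overlapping content errors with a diagnostic
  blank <- image_volume(array(0, dim(fixed)), voxel_size(fixed))
  off <- image_volume(array(c(rep(0, prod(dim(fixed)) - 10), rep(1, 10)), dim(fixed)),
                      voxel_size(fixed))
  expect_error(register_multistep(blank, fixed,
                                  registration_config(pyramid_levels = 2L, seed = 1)),
               "overlap|undefined")
})
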