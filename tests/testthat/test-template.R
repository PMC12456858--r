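# Symmetric template construction: mirroring, aspect adjustment, masking
# with an artificial border, and iterative averaging.

test_that("mirroring makes volumes exactly reflection-invariant", {
  tpl <- tiny_phantom()
  auto <- tpl$autofluorescence
  sym0 <- symmetrize_mirror(auto)
  # already nearly symmetric input stays put
  expect_lt(max(abs(sym0 - auto)), 1e-9)

  set.seed(2)
  noisy <- image_volume(array(runif(12 * 72 * 72), c(12, 72, 72)))
  sym <- symmetrize_mirror(noisy)
  expect_identical(plain_arr(sym), flip_x(plain_arr(sym)))  # defining property, exact

  # impulse response: a spike right of the midline appears at midline +/- k
  imp <- array(0, c(3, 20, 20)); imp[2, 10, 14] <- 7
  mi <- symmetrize_mirror(image_volume(imp), midline_x = 10.5)
  expect_equal(mi[2, 10, 14], 7)
  expect_equal(mi[2, 10, 7], 7)   # 2*10.5 - 14
  expect_equal(sum(mi), 14)
  expect_error(symmetrize_mirror(image_volume(imp), midline_x = 99), "bounds")
})

test_that("aspect adjustment rescales in-plane geometry about the centre", {
  disk <- array(0, c(2, 101, 101))
  yy <- matrix(seq_len(101), 101, 101); xx <- t(yy)
  disk[1, , ] <- ((yy - 51)^2 + (xx - 51)^2 <= 40^2) * 100
  disk[2, , ] <- disk[1, , ]
  dv <- image_volume(disk, c(40, 10, 10))
  expect_identical(adjust_aspect(dv, 1, 1), dv)

  half <- adjust_aspect(dv, 0.5, 0.5)
  mask <- half[1, , ] > 50
  rad_x <- (diff(range(col(mask)[mask])) + 1) / 2
  rad_y <- (diff(range(row(mask)[mask])) + 1) / 2
  expect_equal(rad_x, 20, tolerance = 0.08)
  expect_equal(rad_y, 20, tolerance = 0.08)

  sq <- adjust_aspect(dv, 0.93, 0.95)
  m2 <- sq[1, , ] > 50
  w <- diff(range(col(m2)[m2])) + 1
  h <- diff(range(row(m2)[m2])) + 1
  expect_equal(w, 0.93 * 81, tolerance = 2 / 81)
  expect_equal(h, 0.95 * 81, tolerance = 2 / 81)
})

test_that("masking zeroes outside the annotation and the rim brightens the border", {
  tpl <- tiny_phantom()
  auto <- tpl$autofluorescence; ann <- tpl$annotation
  cfg0 <- template_build_config(border_width = 0)
  masked <- mask_and_border(auto, ann, cfg0)
  expect_equal(sum(masked[unclass(ann) == 0L]), 0)
  expect_identical(unclass(mask_and_border(masked, ann, cfg0)), unclass(masked))

  flat <- image_volume(array(100, dim(ann)), voxel_size(ann))
  cfg <- template_build_config(border_width = 3, border_gain = 1.8)
  rimmed <- mask_and_border(flat, ann, cfg)
  mask <- unclass(ann) > 0L
  er <- mask
  for (k in 1:3) er <- cordquant:::erode_inplane(er)
  rim_band <- mask & !er
  expect_gt(mean(rimmed[rim_band]), mean(rimmed[er]))
  empty <- annotation_volume(array(0L, dim(ann)), voxel_size(ann),
                             attr(ann, "ontology"))
  expect_error(mask_and_border(flat, empty, cfg), "empty annotation")
})

test_that("averaging identical samples reproduces the sample", {
  tpl <- tiny_phantom()
  auto <- tpl$autofluorescence
  cfg <- template_build_config(iterations = 1L,
                               registration = registration_config(
                                 pyramid_levels = 3L,
                                 stages = c("rigid", "affine"),
                                 iterations = 100L, seed = 1))
  out <- iterative_average_template(list(auto, auto, auto), cfg)
  # registration of a volume to itself settles within a fraction of a voxel,
  # so the template matches the sample up to subvoxel resampling at edges
  ca <- cordquant:::compose_affines(
    register_multistep(auto, auto, cfg$registration)$transforms)
  expect_lt(max(abs(ca$b)) / min(voxel_size(auto)), 0.5)   # < 0.5 voxel
  expect_lt(max(abs(ca$A - diag(3))), 0.005)               # < 0.3 degree / 0.5% scale
  expect_lt(mean((out - auto)^2) / stats::var(as.vector(auto)), 0.05)
  expect_lt(median(abs(out - auto)), 1)
  rep <- attr(out, "report")
  expect_equal(rep$mean_pairwise_mse[1], 0)
})
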