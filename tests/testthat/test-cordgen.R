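# Phantom generator: determinism, symmetry, contrast, deposit ground truth,
# deformation, and cohort effects.

test_that("phantom generation is a pure function of config and seed", {
  cfg <- tiny_config(noise_sd = 3, shot_scale = 0.02)
  a <- generate_template_phantom(cfg, seed = 7)
  b <- generate_template_phantom(cfg, seed = 7)
  expect_identical(unclass(a$autofluorescence), unclass(b$autofluorescence))
  expect_identical(unclass(a$annotation), unclass(b$annotation))
  c2 <- generate_template_phantom(cfg, seed = 8)
  expect_false(identical(unclass(a$autofluorescence), unclass(c2$autofluorescence)))
})

test_that("noise-free phantom is mirror-symmetric with the configured contrast", {
  tpl <- tiny_phantom()
  auto <- tpl$autofluorescence
  expect_lt(max(abs(auto - flip_x(auto))), 1e-9)
  ann <- tpl$annotation
  ont <- tpl$ontology
  gray <- array(ann %in% ont$regions$id[ont$regions$tissue_class == "gray"], dim(ann))
  white <- array(ann %in% ont$regions$id[ont$regions$tissue_class == "white"], dim(ann))
  mg <- mean(auto[gray]); mw <- mean(auto[white])
  expect_gt(mg, mw)
  cfg <- tiny_config()
  expect_equal(mg / mw, cfg$gray_intensity / cfg$white_intensity, tolerance = 0.1)
  expect_error(generate_template_phantom(phantom_config(dim = c(5, 16, 16))),
               "too small")
})

test_that("deposited truth sums are exact mask sums and zero densities give zero", {
  tpl <- clean_phantom()
  ann <- tpl$annotation
  ont <- tpl$ontology
  cfg <- phantom_config(noise_sd = 0, shot_scale = 0, axon_tract = FALSE)

  zero_dens <- setNames(rep(0, nrow(ont$regions)), ont$regions$id)
  dep0 <- deposit_signal(ann, cfg, seed = 3, density = zero_dens)
  expect_true(all(dep0$truth$region_sums == 0))
  expect_equal(sum(dep0$signal), 0)

  rid <- ont$regions$id[ont$regions$name == "C4 lamina 7 left"]
  dens <- zero_dens; dens[as.character(rid)] <- 5
  dep <- deposit_signal(ann, cfg, seed = 3, density = dens)
  sig <- unclass(dep$signal)
  # truth oracle: direct mask accumulation of the pre-noise signal
  expect_equal(unname(dep$truth$region_sums[as.character(rid)]),
               sum(sig[unclass(ann) == rid]))
  # conservation over all regions
  expect_equal(sum(dep$truth$region_sums), sum(sig[unclass(ann) > 0]))
  # most signal stays inside the target region's mask (tails leak to neighbours)
  expect_gt(dep$truth$region_sums[as.character(rid)] / sum(sig), 0.9)
  expect_error(deposit_signal(ann, cfg, seed = 1, density = c("99999" = 1)),
               "unknown region")
})

test_that("doubling a region's density doubles its expected truth sum", {
  tpl <- tiny_phantom()
  ont <- tpl$ontology
  rid <- as.character(ontology_select(ont, level = "C5", lamina = "5",
                                      hemicord = "left"))
  cfg <- tiny_config()
  # high rates so 20 seeds give a few hundred puncta per arm (truth sums are
  # exactly linear in deposited intensity, so only Poisson noise remains)
  dens <- setNames(rep(0, nrow(ont$regions)), ont$regions$id)
  dens[rid] <- 500
  dens2 <- dens; dens2[rid] <- 1000
  s1 <- s2 <- 0
  for (seed in 1:20) {
    s1 <- s1 + sum(deposit_signal(tpl$annotation, cfg, seed = seed,
                                  density = dens)$truth$region_sums)
    s2 <- s2 + sum(deposit_signal(tpl$annotation, cfg, seed = 100 + seed,
                                  density = dens2)$truth$region_sums)
  }
  expect_equal(unname(s2 / s1), 2, tolerance = 0.1)
})

test_that("deformation returns the exact transform used and handles edge cases", {
  tpl <- tiny_phantom()
  vols <- list(auto = tpl$autofluorescence)
  ident <- deform_sample(vols, magnitude = 0, seed = 1)
  expect_identical(ident$volumes$auto, vols$auto)

  d1 <- deform_sample(vols, magnitude = 0.5, seed = 9)
  d2 <- deform_sample(vols, magnitude = 0.5, seed = 9)
  p1 <- d1$chain$transforms[[1]]
  expect_identical(p1$params, d2$chain$transforms[[1]]$params)
  expect_identical(unclass(d1$volumes$auto), unclass(d2$volumes$auto))

  # a pure in-plane translation is recovered by the cross-correlation peak
  vs <- voxel_size(vols$auto)
  tr <- affine_transform(diag(3), c(0, 5 * vs[2], 7 * vs[3]))
  chain <- transform_chain(tr, fixed_geometry = list(dim = dim(vols$auto),
                                                     voxel_size = vs))
  moved <- apply_transform(vols$auto, chain, "linear")
  sec0 <- vols$auto[6, , ]; sec1 <- moved[6, , ]
  cc <- Re(stats::fft(stats::fft(sec1) * Conj(stats::fft(sec0)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1
  ny <- nrow(sec0); nx <- ncol(sec0)
  off <- c(ifelse(pk[1] > ny / 2, pk[1] - ny, pk[1]),
           ifelse(pk[2] > nx / 2, pk[2] - nx, pk[2]))
  # the moved image content shifts by -5, -7 (resampling pulls from +5, +7)
  expect_equal(unname(off), c(-5, -7))

  big <- list(translate = 40, translate_z = 0, rotate = 0, scale = 0,
              elastic_amp = 0)
  expect_error(deform_sample(vols, magnitude = big, seed = 2), "out of frame")
})

test_that("cohort group effects scale the target regions' truth", {
  cfg <- tiny_config()
  expect_error(generate_cohort(0, list(a = NULL), config = cfg), "n_per_group")
  expect_error(generate_cohort(1, list(a = NULL, b = NULL), groups = "a",
                               config = cfg), "unknown group")

  # dense uniform deposition keeps the per-group Poisson noise small
  ont0 <- tiny_phantom()$ontology
  cfg <- tiny_config(puncta_density = setNames(rep(30, nrow(ont0$regions)),
                                               ont0$regions$id))
  target <- list(lamina = "5", hemicord = "left", factor = 10)
  r_null <- r_eff <- numeric(0)
  for (seed in 1:10) {
    co <- generate_cohort(5, list(g1 = NULL, g2 = list(lamina = "5",
                                                       hemicord = "left",
                                                       factor = 1)),
                          seed = seed, config = cfg, volumes = FALSE)
    co10 <- generate_cohort(5, list(g1 = NULL, g2 = target), seed = 1000 + seed,
                            config = cfg, volumes = FALSE)
    ids <- as.character(ontology_select(co$template$ontology, lamina = "5",
                                        hemicord = "left"))
    sums <- function(cohort) vapply(cohort$samples, function(s)
      sum(s$truth$region_sums[ids]), 0)
    grp <- function(cohort) vapply(cohort$samples, `[[`, "", "group")
    s0 <- sums(co); g0 <- grp(co)
    r_null <- c(r_null, mean(s0[g0 == "g2"]) / mean(s0[g0 == "g1"]))
    s1 <- sums(co10); g1 <- grp(co10)
    r_eff <- c(r_eff, mean(s1[g1 == "g2"]) / mean(s1[g1 == "g1"]))
  }
  expect_equal(mean(r_null), 1, tolerance = 0.15)
  expect_gt(mean(r_eff), 7)
  expect_lt(mean(r_eff), 13)
})
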