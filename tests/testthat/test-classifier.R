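# Feature bank, random-forest training/prediction, probability-map
# normalization, and threshold denoising.

test_that("feature bank has the documented structure and analytic responses", {
  const <- matrix(3, 24, 24)
  fs <- extract_features(const, scales = c(1, 2))
  expect_identical(dim(fs)[3], 2L * 7L + 1L)  # 7 features per scale + raw
  for (nm in grep("gradmag|log_", dimnames(fs)[[3]], value = TRUE))
    expect_equal(max(abs(fs[, , nm])), 0, tolerance = 1e-9)

  # Gaussian response of an isolated bright pixel = sampled normalized kernel
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  s <- 2
  fi <- extract_features(imp, scales = s)
  r <- ceiling(4 * s)
  k <- exp(-0.5 * ((-r:r) / s)^2); k <- k / sum(k)
  oracle <- outer(k, k)
  got <- fi[17 + (-r:r), 17 + (-r:r), sprintf("gauss_s%.1f", s)]
  expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(extract_features(const, scales = numeric(0)), "scales")
  # multi-channel stacking
  fs2 <- extract_features(list(const, const), scales = 1)
  expect_identical(dim(fs2)[3], 2L * 8L)
})

make_separable_sections <- function(n, seed) {
  # two intensity-separable classes: dim background vs bright plateau; brush
  # labels avoid the plateau boundary, as sparse annotations do in practice
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(32 * 32, 20, 0.5), 32, 32)
    m[9:24, 9:24] <- rnorm(256, 200, 0.5)
    cls <- matrix("background", 32, 32)
    cls[9:24, 9:24] <- "bright"
    confident <- matrix(TRUE, 32, 32)
    confident[6:27, 6:27] <- FALSE
    confident[12:21, 12:21] <- TRUE
    pick <- sample(which(confident), 120)
    list(section = m,
         labels = data.frame(y = ((pick - 1) %% 32) + 1,
                             x = ((pick - 1) %/% 32) + 1,
                             class = cls[pick]),
         truth = cls)
  }))
}

test_that("training is deterministic and separable classes are learned perfectly", {
  scheme <- class_scheme(c("bright", "background"))
  secs <- make_separable_sections(4, seed = 3)
  model <- train_classifier(secs[1:3], scheme, seed = 7, scales = c(1, 2),
                            num_trees = 50)
  expect_gte(model$training_accuracy, 0.999)
  held <- predict_probability_maps(model, list(secs[[4]]$section))
  pred <- ifelse(held$maps$bright[1, , ] >= held$maps$background[1, , ],
                 "bright", "background")
  # away from the 1-px class boundary (where multi-scale features straddle
  # classes by construction) the held-out call is perfect
  away <- matrix(TRUE, 32, 32); away[7:26, 7:26] <- FALSE; away[11:22, 11:22] <- TRUE
  expect_equal(mean(pred[away] == secs[[4]]$truth[away]), 1)
  expect_gte(mean(pred == secs[[4]]$truth), 0.99)  # all pixels

  model2 <- train_classifier(secs[1:3], scheme, seed = 7, scales = c(1, 2),
                             num_trees = 50)
  held2 <- predict_probability_maps(model2, list(secs[[4]]$section))
  expect_identical(held$maps, held2$maps)

  solo <- secs[[1]]
  solo$labels$class <- "bright"
  expect_error(train_classifier(list(solo), scheme, seed = 1, scales = 1),
               "no training labels")
})

test_that("probability maps are 8-bit with near-unit per-voxel class sums", {
  scheme <- class_scheme(c("bright", "background"))
  secs <- make_separable_sections(3, seed = 5)
  # a vote fraction of 250/255 needs better than 98% tree consensus,
  # so use a forest large enough for one dissenting tree to be harmless
  model <- train_classifier(secs[1:2], scheme, seed = 2, scales = c(1, 2),
                            num_trees = 150)
  maps <- predict_probability_maps(model, list(secs[[3]]$section))
  tot <- maps$maps$bright + maps$maps$background
  expect_true(all(tot >= 254 & tot <= 255))  # floor(p*255), 2 classes
  expect_true(all(vapply(maps$maps, max, 0L) <= 255L))

  bg_only <- matrix(20, 32, 32)
  m2 <- predict_probability_maps(model, list(bg_only))
  expect_gte(mean(m2$maps$background[1, , ] >= 250), 0.99)

  expect_error(predict_probability_maps(model, list(secs[[3]]$section,
                                                    matrix(0, 10, 10))),
               "shape mismatch")
})

test_that("threshold denoising zeroes below tau and preserves values above", {
  m <- array(c(10L, 85L, 86L, 200L, 0L, 255L), c(1, 2, 3))
  expect_identical(threshold_probability(m, 0), m)
  thr <- threshold_probability(m, 86)
  expect_identical(as.vector(thr), c(0L, 0L, 86L, 200L, 0L, 255L))
  u <- array(255L, c(2, 3, 3))
  expect_identical(threshold_probability(u, 86), u)
  expect_error(threshold_probability(m, 300), "\\[0, 255\\]")

  # monotone: raising tau never increases any voxel or downstream region sum
  set.seed(8)
  r <- array(sample.int(256, 200, replace = TRUE) - 1L, c(2, 10, 10))
  taus <- c(0, 40, 86, 150, 255)
  sums <- vapply(taus, function(t) sum(threshold_probability(r, t)), 0)
  expect_true(all(diff(sums) <= 0))
  for (i in seq_len(length(taus) - 1)) {
    a <- threshold_probability(r, taus[i]); b <- threshold_probability(r, taus[i + 1])
    expect_true(all(b <= a))
  }
})
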