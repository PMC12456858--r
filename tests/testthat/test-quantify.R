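# Region quantification: brute-force oracle agreement, conservation,
# normalization and aggregation views.

make_mapset <- function(maps, tau = 86L) {
  classes <- names(maps)
  scheme <- class_scheme(c(classes, "gray_matter", "white_matter", "background"))
  full <- c(maps, list(gray_matter = maps[[1]] * 0L,
                       white_matter = maps[[1]] * 0L,
                       background = maps[[1]] * 0L))
  names(full) <- c(classes, "gray_matter", "white_matter", "background")
  structure(list(maps = full, scheme = scheme, tau = tau),
            class = "ProbabilityMapSet")
}

test_that("region sums equal exhaustive per-voxel accumulation", {
  ann <- random_annotation(dim = c(32, 32, 32), seed = 4)
  set.seed(9)
  m <- array(sample.int(256, prod(dim(ann)), replace = TRUE) - 1L, dim(ann))
  qm <- quantify_regions(make_mapset(list(presynaptic_terminal = m)), ann,
                         sample = "s1")
  # brute-force voxel loop oracle
  oracle <- setNames(numeric(nrow(attr(ann, "ontology")$regions)),
                     attr(ann, "ontology")$regions$id)
  d <- dim(ann)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    lab <- ann[z, y, x]
    if (lab > 0L) oracle[as.character(lab)] <- oracle[as.character(lab)] + m[z, y, x]
  }
  expect_equal(qm$value[match(as.integer(names(oracle)), qm$region_id)],
               unname(oracle))
  # conservation: sum over regions equals total masked intensity
  expect_equal(sum(qm$value), sum(m[unclass(ann) > 0L]))

  zeroq <- quantify_regions(make_mapset(list(presynaptic_terminal = m * 0L)), ann)
  expect_true(all(zeroq$value == 0))

  single <- m * 0L
  rid <- attr(ann, "ontology")$regions$id[5]
  vox <- which(unclass(ann) == rid)[1]
  single[vox] <- 200L
  sq <- quantify_regions(make_mapset(list(presynaptic_terminal = single)), ann)
  expect_equal(sq$value[sq$region_id == rid], 200)
  expect_equal(sum(sq$value), 200)

  small <- make_mapset(list(presynaptic_terminal = m[1:10, , ]))
  expect_error(quantify_regions(small, ann), "grid mismatch")
})

test_that("gray/white/background classes are excluded from quantification", {
  ann <- random_annotation(dim = c(6, 10, 10), seed = 2)
  m <- array(100L, dim(ann))
  qm <- quantify_regions(make_mapset(list(presynaptic_terminal = m, axon = m)), ann)
  expect_setequal(unique(qm$class), c("presynaptic_terminal", "axon"))
})

test_that("normalization modes behave and fail loudly on zero denominators", {
  ann <- random_annotation(dim = c(6, 12, 12), seed = 11)
  set.seed(3)
  m1 <- array(sample.int(200, prod(dim(ann)), TRUE), dim(ann))
  q1 <- quantify_regions(make_mapset(list(presynaptic_terminal = m1, axon = m1)),
                         ann, sample = "s1", group = "g1")
  q2 <- quantify_regions(make_mapset(list(presynaptic_terminal = m1 * 2L,
                                          axon = m1 * 2L)),
                         ann, sample = "s2", group = "g1")
  qm <- bind_quant(list(q1, q2))

  none <- normalize_quant(qm, "none")
  expect_equal(none$normalized_value, none$value)

  tot <- normalize_quant(qm, "total_signal")
  sums <- tapply(tot$normalized_value, tot$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # scale invariance: s2 is s1 scaled by 2
  expect_equal(tot$normalized_value[tot$sample == "s1"],
               tot$normalized_value[tot$sample == "s2"], tolerance = 1e-9)

  ax <- normalize_quant(qm, "axon_reference")
  expect_equal(attr(ax, "normalization"), "axon_reference")
  expect_equal(ax$normalized_value[ax$sample == "s1"],
               ax$normalized_value[ax$sample == "s2"], tolerance = 1e-9)

  qz <- quantify_regions(make_mapset(list(presynaptic_terminal = m1 * 0L,
                                          axon = m1 * 0L)),
                         ann, sample = "sz")
  expect_error(normalize_quant(qz, "total_signal"), "sz")
})

test_that("aggregation conserves totals and percentage strata sum to 100", {
  study_free <- {
    tpl <- tiny_phantom()
    # dense uniform deposit so every (level, hemicord) stratum carries signal
    dens <- setNames(rep(30, nrow(tpl$ontology$regions)), tpl$ontology$regions$id)
    dep <- deposit_signal(tpl$annotation, tiny_config(), seed = 6,
                          density = dens)
    m <- array(as.integer(pmin(round(unclass(dep$signal)), 255)), dim(tpl$annotation))
    quantify_regions(make_mapset(list(presynaptic_terminal = m)),
                     tpl$annotation, sample = "s1", group = "g")
  }
  agg <- aggregate_quant(study_free, by = "level")
  expect_equal(sum(agg$value),
               sum(study_free$value[study_free$tissue_class == "gray"]))

  pct <- aggregate_quant(study_free, by = "lamina",
                         percent_within = c("level", "hemicord"))
  tots <- tapply(pct$percent, interaction(pct$level, pct$hemicord, drop = TRUE), sum)
  expect_true(all(abs(tots - 100) < 1e-9))

  # ipsi/contra framing from injection side
  lat <- aggregate_quant(study_free, by = "level",
                         injection_side = c(s1 = "right"))
  expect_setequal(unique(lat$laterality), c("ipsilateral", "contralateral"))
  one <- study_free[study_free$region_id == study_free$region_id[1], ]
  attr(one, "ontology") <- attr(study_free, "ontology")
  a1 <- aggregate_quant(one, by = "level")
  expect_equal(nrow(a1), 1)
  expect_equal(a1$value, one$value[1])
})
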