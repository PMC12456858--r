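# Synthetic phantom-cord generator.
#
# Emulates the anatomy the pipeline is built for: a cervical cord whose
# elliptical outline and butterfly-shaped gray matter vary smoothly along z,
# an autofluorescence channel with gray/white contrast and a bright tissue
# border, and a signal channel carrying punctate presynaptic-terminal-like
# blobs and a curvilinear axon-like tract, deposited at known per-region
# densities so that ground truth is available for every downstream stage.

#' Phantom configuration
#'
#' Defaults are desk-scale: 50 sections of 256 x 256 pixels at 10 um in-plane
#' and 40 um axially, so that registration and classification run in minutes.
#'
#' @param dim grid size (z sections, y rows, x columns).
#' @param voxel_size um per voxel (z, y, x).
#' @param levels cervical levels spanned rostro-caudally.
#' @param motor_pools motor pool names carved out of lamina 9.
#' @param gray_intensity,white_intensity autofluorescence plateau intensities.
#' @param border_gain multiplicative brightness of the tissue border rim
#'   relative to white matter (1 = no rim).
#' @param border_width rim width in pixels.
#' @param smooth_sigma in-plane smoothing (px) applied to the clean anatomy.
#' @param noise_sd additive Gaussian noise sd; 0 for a noise-free phantom.
#' @param shot_scale Poisson-like shot-noise variance per intensity unit.
#' @param puncta_density named per-region puncta rates (expected puncta per
#'   1000 voxels, names = region ids); `NULL` uses a lamina-based default.
#' @param puncta_sigma puncta radius (Gaussian sigma) range in voxels.
#' @param puncta_amp puncta peak amplitude.
#' @param axon_tract deposit a curvilinear axon-like structure in the dorsal
#'   white matter.
#' @param axon_amp,axon_sigma axon tube amplitude and cross-section sigma.
#' @param soma_density expected soma-like blobs per 1000 voxels in the soma
#'   regions (0 = none).
#' @param soma_regions region ids receiving somas (`NULL` = lamina 9 + pools).
#' @param soma_sigma,soma_amp soma blob sigma range (voxels) and amplitude.
#' @param deform default deformation magnitudes used by [generate_cohort()]:
#'   in-plane translation (voxels), z translation (sections), rotation about
#'   z (degrees), anisotropic scale, elastic amplitude (um) and elastic
#'   control-grid spacing (um).
#' @return a `PhantomConfig` list.
#' @export
phantom_config <- function(dim = c(50, 256, 256),
                           voxel_size = c(40, 10, 10),
                           levels = paste0("C", 1:8),
                           motor_pools = c("trapezius", "phrenic", "biceps",
                                           "forearm flexor", "forearm extensor",
                                           "axial"),
                           gray_intensity = 180, white_intensity = 120,
                           border_gain = 1.5, border_width = 3,
                           smooth_sigma = 0.8,
                           noise_sd = 4, shot_scale = 0.02,
                           puncta_density = NULL,
                           puncta_sigma = c(0.7, 1.1), puncta_amp = 150,
                           axon_tract = TRUE, axon_amp = 120, axon_sigma = 1,
                           soma_density = 0, soma_regions = NULL,
                           soma_sigma = c(1.0, 1.6), soma_amp = 220,
                           deform = list(translate = 8, translate_z = 0.5,
                                         rotate = 4, scale = 0.04,
                                         elastic_amp = 15, elastic_spacing = 600)) {
  cfg <- list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
              levels = levels, motor_pools = motor_pools,
              n_sections = as.integer(dim[1]),
              gray_intensity = gray_intensity, white_intensity = white_intensity,
              border_gain = border_gain, border_width = border_width,
              smooth_sigma = smooth_sigma,
              noise_sd = noise_sd, shot_scale = shot_scale,
              puncta_density = puncta_density,
              puncta_sigma = puncta_sigma, puncta_amp = puncta_amp,
              axon_tract = axon_tract, axon_amp = axon_amp, axon_sigma = axon_sigma,
              soma_density = soma_density, soma_regions = soma_regions,
              soma_sigma = soma_sigma, soma_amp = soma_amp,
              deform = deform)
  stopifnot(cfg$n_sections >= 1, all(cfg$dim >= 1),
            is.null(puncta_density) || all(puncta_density >= 0),
            soma_density >= 0)
  class(cfg) <- "PhantomConfig"
  cfg
}

# smoothly varying cross-section geometry at section z (1-based)
cord_geometry <- function(z, dim) {
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  tau <- if (nz > 1) (z - 1) / (nz - 1) else 0.5
  list(
    cx = (nx + 1) / 2,
    cy = (ny + 1) / 2,
    Rx = 0.40 * nx * (0.92 + 0.08 * cos(2 * pi * tau)),
    Ry = 0.30 * ny * (0.94 + 0.06 * sin(2 * pi * tau + 1)),
    ventral_scale = 1 + 0.18 * tau  # enlarged ventral horns caudally
  )
}

#' Generate the template phantom
#'
#' Builds a noise-free (or noisy, per config) autofluorescence volume and the
#' matching annotation volume. The anatomy is mirror-symmetric about the
#' midline by construction; gray matter is brighter than white matter by the
#' configured contrast and a bright rim marks the tissue border.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed (only noise is stochastic).
#' @return list with `autofluorescence` (`ImageVolume`), `annotation`
#'   (`AnnotationVolume`) and `ontology`.
#' @export
generate_template_phantom <- function(config = phantom_config(), seed = 1L) {
  d <- config$dim
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny < 32 || nx < 32) stop("grid too small to contain a cord cross-section")
  ontology <- build_region_ontology(
    levels = config$levels, motor_pools = config$motor_pools,
    white_tracts = "white matter")
  id_of <- setNames(ontology$regions$id,
                    paste(ontology$regions$level, ontology$regions$lamina,
                          ontology$regions$hemicord))
  pool_levels <- unique(ontology$regions$level[ontology$regions$region_type == "pool"])
  nlev <- length(config$levels)
  labels <- array(0L, d)
  auto <- array(0, d)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  yy <- matrix(seq_len(ny), ny, nx)
  midline_x <- (nx + 1) / 2
  for (z in seq_len(nz)) {
    g <- cord_geometry(z, d)
    lv <- config$levels[pmin(nlev, 1L + ((z - 1L) * nlev) %/% nz)]
    s <- abs(xx - g$cx)
    ey <- yy - g$cy
    outline <- (s / g$Rx)^2 + (ey / g$Ry)^2 <= 1
    inner <- (s / (0.85 * g$Rx))^2 + (ey / (0.85 * g$Ry))^2 <= 1
    dorsal <- ((s - 0.42 * g$Rx) / (0.22 * g$Rx))^2 +
      ((ey + 0.45 * g$Ry) / (0.38 * g$Ry))^2 <= 1
    ventral <- ((s - 0.33 * g$Rx) / (0.30 * g$Rx * g$ventral_scale))^2 +
      ((ey - 0.40 * g$Ry) / (0.42 * g$Ry * g$ventral_scale))^2 <= 1
    commissure <- abs(ey) <= 0.15 * g$Ry & s <= 0.45 * g$Rx
    gray <- (dorsal | ventral | commissure) & inner
    canal <- s^2 + ey^2 <= (0.06 * g$Ry)^2
    white <- outline & !gray & !canal
    sec <- matrix(0L, ny, nx)
    for (h in c("left", "right")) {
      side <- if (h == "left") xx > midline_x else xx < midline_x
      wid <- id_of[paste(lv, "white matter", h)]
      sec[white & side] <- wid
      gs <- gray & side
      if (!any(gs)) next
      ygr <- range(yy[gs])
      t01 <- pmin(pmax((yy - ygr[1]) / max(1e-9, diff(ygr)), 0), 1)
      # dorsoventral lamina bands; lamina 9 (motoneuron territory) is widest
      bw <- c(0.9, 0.9, 1, 1, 1, 1, 1, 1.3, 2)
      cuts <- cumsum(bw) / sum(bw)
      band <- matrix(findInterval(t01, cuts[1:8]) + 1L, nrow(t01), ncol(t01))
      if (lv %in% NO_LAMINA6_LEVELS) band[band == 6L] <- 5L
      for (l in sort(unique(band[gs]))) {
        rid <- id_of[paste(lv, l, h)]
        sel <- gs & band == l
        sec[sel] <- rid
      }
      # lamina 10 around the central canal
      near_canal <- s^2 + ey^2 <= (0.14 * g$Ry)^2
      sec[gs & near_canal] <- id_of[paste(lv, 10, h)]
      # motor pools: disks carved out of the lamina-9 band of the ventral horn
      if (lv %in% pool_levels && length(config$motor_pools)) {
        l9 <- gs & band == 9L & ventral
        if (any(l9)) {
          sr <- range(s[l9])
          K <- length(config$motor_pools)
          rad <- 0.35 * diff(sr) / K + 1
          for (k in seq_len(K)) {
            sk <- sr[1] + (k - 0.5) / K * diff(sr)
            ysel <- yy[l9 & abs(s - sk) <= rad]
            if (!length(ysel)) next
            yk <- mean(range(ysel))
            pool_sel <- l9 & ((s - sk)^2 + (yy - yk)^2 <= rad^2)
            sec[pool_sel] <- id_of[paste(lv, config$motor_pools[k], h)]
          }
        }
      }
    }
    img <- matrix(0, ny, nx)
    img[white] <- config$white_intensity
    img[sec > 0 & !white] <- config$gray_intensity
    if (config$border_gain > 1 && config$border_width > 0) {
      w <- config$border_width / max(g$Rx, g$Ry)
      rim <- outline & ((s / ((1 - w) * g$Rx))^2 + (ey / ((1 - w) * g$Ry))^2 > 1)
      img[rim] <- config$white_intensity * config$border_gain
    }
    auto[z, , ] <- img
    labels[z, , ] <- sec
  }
  if (config$smooth_sigma > 0)
    auto <- cpp_gauss_sep(auto, d, c(0.5, config$smooth_sigma, config$smooth_sigma))
  dim(auto) <- d
  auto <- add_noise(auto, config$noise_sd, config$shot_scale, seed)
  list(autofluorescence = image_volume(auto, config$voxel_size, "autofluorescence"),
       annotation = annotation_volume(labels, config$voxel_size, ontology,
                                      midline_x = midline_x),
       ontology = ontology)
}

# additive Gaussian + Poisson-like shot noise, clipped at 0
add_noise <- function(arr, noise_sd, shot_scale, seed) {
  if (noise_sd <= 0 && shot_scale <= 0) return(arr)
  with_seed(seed, {
    n <- length(arr)
    out <- arr + rnorm(n, 0, noise_sd) +
      rnorm(n, 0, sqrt(pmax(shot_scale * arr, 0)))
    pmax(out, 0)
  })
}

#' Default per-region puncta densities
#'
#' Lamina-weighted rates (expected puncta per 1000 voxels) emulating a
#' corticospinal presynaptic-terminal distribution concentrated in the
#' intermediate laminae; white matter carries none. Rates are set so that
#' even small regions carry puncta counts in the tens, as real terminal
#' counts per region do.
#'
#' @param ontology a `RegionOntology`.
#' @export
default_puncta_density <- function(ontology) {
  prof <- c("1" = 0.8, "2" = 1.2, "3" = 2.5, "4" = 3, "5" = 3, "6" = 2.5,
            "7" = 3, "8" = 1.5, "9" = 1.2, "10" = 0.5)
  r <- ontology$regions
  dens <- numeric(nrow(r))
  dens[r$region_type == "lamina"] <- prof[r$lamina[r$region_type == "lamina"]]
  dens[r$region_type == "pool"] <- 1.2
  dens[r$region_type == "white"] <- 0
  setNames(dens, r$id)
}

#' Deposit synthetic signal into an annotated phantom
#'
#' Places Gaussian puncta with per-region expected counts proportional to the
#' configured densities, an optional curvilinear axon-like tube in the dorsal
#' white matter, and optional soma-like blobs, then records exact pre-noise
#' per-region signal sums and per-voxel class labels as ground truth.
#'
#' @param annotation an `AnnotationVolume` (template space).
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @param density optional named per-region density override (per 1000 voxels).
#' @return list with `signal` (`ImageVolume`, noise added per config) and
#'   `truth` (`PhantomTruth`: `region_sums`, `class_region_sums`, `labels`,
#'   `somas`, `seed`).
#' @export
deposit_signal <- function(annotation, config = phantom_config(), seed = 1L,
                           density = NULL) {
  ontology <- attr(annotation, "ontology")
  d <- dim(annotation)
  vs <- voxel_size(annotation)
  zaspect <- vs[1] / vs[2]
  dens <- density %||% config$puncta_density %||% default_puncta_density(ontology)
  unknown <- setdiff(names(dens), as.character(ontology$regions$id))
  if (length(unknown))
    stop("density map references unknown region id(s): ",
         paste(unknown, collapse = ", "))
  lab_vec <- as.vector(as_plain_array(annotation))
  vox_by_region <- split(which(lab_vec > 0L), lab_vec[lab_vec > 0L])
  comp <- list()  # per-class pre-noise components
  with_seed(seed, {
    # puncta
    centers <- sig <- amp <- NULL
    for (rid in names(dens)) {
      vox <- vox_by_region[[rid]]
      if (is.null(vox) || dens[[rid]] <= 0) next
      n <- rpois(1, dens[[rid]] * length(vox) / 1000)
      if (n == 0) next
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      zyx <- arrayInd(pick, d) - 1 + matrix(runif(3 * n, -0.5, 0.5), n, 3)
      centers <- rbind(centers, zyx)
      sig <- c(sig, runif(n, config$puncta_sigma[1], config$puncta_sigma[2]))
      amp <- c(amp, runif(n, 0.85, 1.15) * config$puncta_amp)
    }
    zero <- array(0, d)
    comp$presynaptic_terminal <-
      if (is.null(centers)) zero
      else cpp_add_blobs(zero, d, centers, sig, amp, zaspect, 3.0)
    # axon: smooth curve along z through the dorsal white matter
    if (isTRUE(config$axon_tract)) {
      nz <- d[1]
      zc <- seq(1, nz, length.out = max(4, min(7, nz)))
      gs <- lapply(zc, cord_geometry, dim = d)
      ycp <- vapply(gs, function(g) g$cy - 0.90 * g$Ry, 0) + rnorm(length(zc), 0, 1)
      xcp <- vapply(gs, function(g) g$cx, 0) + rnorm(length(zc), 0, 1.5)
      zf <- seq(1, nz, by = 0.25)
      yf <- stats::spline(zc, ycp, xout = zf)$y
      xf <- stats::spline(zc, xcp, xout = zf)$y
      ax_centers <- cbind(zf, yf, xf) - 1
      n_ax <- nrow(ax_centers)
      comp$axon <- cpp_add_blobs(array(0, d), d, ax_centers,
                                 rep(config$axon_sigma, n_ax),
                                 rep(config$axon_amp * 0.45, n_ax), zaspect, 3.0)
    } else comp$axon <- array(0, d)
    # soma-like blobs
    somas <- NULL
    if (config$soma_density > 0) {
      soma_ids <- config$soma_regions %||%
        ontology_select(ontology, lamina = c("9", ontology$regions$lamina[
          ontology$regions$region_type == "pool"]))
      # a motoneuron territory is defined by the cells it contains: place
      # centers so the cell body fits inside, i.e. with an in-plane margin
      # of about one soma radius from the territory boundary
      margin <- ceiling(config$soma_sigma[2])
      er <- array(lab_vec %in% as.integer(soma_ids), d)
      for (k in seq_len(margin + 1)) er <- erode_inplane(er)
      er_idx <- which(er)
      sc <- ss <- sa <- NULL
      srec <- list()
      for (rid in as.character(soma_ids)) {
        vox <- intersect(vox_by_region[[rid]], er_idx)
        if (!length(vox)) next
        n <- rpois(1, config$soma_density * length(vox) / 1000)
        if (n == 0) next
        pick <- vox[sample.int(length(vox), n, replace = TRUE)]
        zyx <- arrayInd(pick, d) - 1 + matrix(runif(3 * n, -0.5, 0.5), n, 3)
        sgm <- runif(n, config$soma_sigma[1], config$soma_sigma[2])
        sc <- rbind(sc, zyx); ss <- c(ss, sgm)
        sa <- c(sa, runif(n, 0.85, 1.15) * config$soma_amp)
        srec[[rid]] <- data.frame(region_id = as.integer(rid),
                                  z = zyx[, 1] + 1, y = zyx[, 2] + 1,
                                  x = zyx[, 3] + 1, radius = sgm)
      }
      comp$soma <- if (is.null(sc)) array(0, d)
                   else cpp_add_blobs(array(0, d), d, sc, ss, sa, zaspect, 3.0)
      somas <- if (length(srec)) do.call(rbind, c(srec, make.row.names = FALSE))
    } else comp$soma <- array(0, d)
  })
  for (nm in names(comp)) dim(comp[[nm]]) <- d
  signal_clean <- comp$presynaptic_terminal + comp$axon + comp$soma
  # ground truth: exact pre-noise sums within each region mask
  ids <- ontology$regions$id
  sum_by_region <- function(v) {
    rs <- rowsum(v[lab_vec > 0L], lab_vec[lab_vec > 0L])
    out <- setNames(numeric(length(ids)), ids)
    out[rownames(rs)] <- rs[, 1]
    out
  }
  region_sums <- sum_by_region(as.vector(signal_clean))
  class_region_sums <- do.call(rbind, lapply(names(comp), function(cl) {
    data.frame(class = cl, region_id = ids,
               truth_sum = unname(sum_by_region(as.vector(comp[[cl]]))),
               stringsAsFactors = FALSE)
  }))
  # per-voxel class labels (priority: soma > puncta > axon > tissue)
  class_names <- c("background", "gray_matter", "white_matter",
                   "presynaptic_terminal", "axon", "soma")
  lab_cls <- integer(length(lab_vec))  # 0 = background
  tc <- ontology$regions$tissue_class[match(lab_vec, ontology$regions$id)]
  lab_cls[!is.na(tc) & tc == "gray"] <- 1L
  lab_cls[!is.na(tc) & tc == "white"] <- 2L
  lab_cls[as.vector(comp$axon) > 0.12 * config$axon_amp] <- 4L
  lab_cls[as.vector(comp$presynaptic_terminal) > 0.12 * config$puncta_amp] <- 3L
  lab_cls[as.vector(comp$soma) > 0.12 * config$soma_amp] <- 5L
  labels <- array(lab_cls, d)
  attr(labels, "class_names") <- class_names
  signal <- add_noise(signal_clean, config$noise_sd / 2, config$shot_scale,
                      derive_seed(seed, "signal-noise"))
  truth <- structure(list(region_sums = region_sums,
                          class_region_sums = class_region_sums,
                          labels = labels, somas = somas, seed = seed),
                     class = "PhantomTruth")
  list(signal = image_volume(signal, vs, "signal"), truth = truth)
}

#' Apply a known smooth deformation to a sample
#'
#' Draws a rigid + anisotropic-scale affine + elastic (b-spline) deformation
#' of the requested magnitude, applies it to every supplied volume (linear
#' interpolation for intensities, nearest neighbour for integer label
#' volumes), and returns the exact transform chain used.
#'
#' @param volumes named list of `ImageVolume`s (and/or integer label arrays
#'   wrapped as volumes) sharing one grid.
#' @param magnitude either a single non-negative scalar multiplying the
#'   default magnitudes of [phantom_config()]`$deform`, or a list with fields
#'   `translate` (voxels), `translate_z` (sections), `rotate` (degrees),
#'   `scale`, `elastic_amp` (um), `elastic_spacing` (um).
#' @param seed RNG seed.
#' @return list with `volumes` (moved) and `chain` (the true
#'   `TransformChain`, mapping moved-space coordinates to original space).
#' @export
deform_sample <- function(volumes, magnitude = 1, seed = 1L) {
  stopifnot(length(volumes) >= 1)
  v1 <- volumes[[1]]
  d <- dim(v1); vs <- voxel_size(v1)
  defaults <- phantom_config(dim = d, voxel_size = vs)$deform
  mag <- if (is.numeric(magnitude) && length(magnitude) == 1L)
    lapply(defaults, `*`, magnitude) else modifyList(defaults, magnitude)
  if (all(unlist(mag[c("translate", "translate_z", "rotate", "scale",
                       "elastic_amp")]) == 0)) {
    ident <- transform_chain(affine_transform(diag(3), c(0, 0, 0), type = "rigid"),
                             fixed_geometry = list(dim = d, voxel_size = vs))
    return(list(volumes = volumes, chain = ident))
  }
  center <- (d - 1) / 2 * vs
  with_seed(seed, {
    theta <- runif(1, -1, 1) * mag$rotate * pi / 180
    tr <- c(runif(1, -1, 1) * mag$translate_z * vs[1],
            runif(1, -1, 1) * mag$translate * vs[2],
            runif(1, -1, 1) * mag$translate * vs[3])
    rigid <- rigid_transform(c(theta, 0, 0), tr, center)
    sc <- diag(c(1, 1 + runif(1, -1, 1) * mag$scale,
                 1 + runif(1, -1, 1) * mag$scale))
    aff <- affine_transform(sc, as.numeric((diag(3) - sc) %*% center),
                            type = "affine")
    tfs <- list(rigid, aff)
    if (mag$elastic_amp > 0) {
      ext <- (d - 1) * vs
      grid <- bspline_grid_for(c(0, 0, 0), ext, rep(mag$elastic_spacing, 3))
      coef <- matrix(rnorm(prod(grid$ncp) * 3, 0,
                           mag$elastic_amp * c(0.3, 1, 1)), prod(grid$ncp), 3,
                     byrow = TRUE)
      tfs <- c(tfs, list(bspline_transform(coef, grid$origin,
                                           rep(mag$elastic_spacing, 3), grid$ncp)))
    }
  })
  chain <- transform_chain(tfs, fixed_geometry = list(dim = d, voxel_size = vs))
  moved <- lapply(volumes, function(v) {
    nearest <- inherits(v, "AnnotationVolume") ||
      is.integer(as_plain_array(v)) || isTRUE(attr(v, "labels"))
    apply_transform(v, chain, if (nearest) "nearest" else "linear")
  })
  names(moved) <- names(volumes)
  # guard against gross escapes from the field of view: warp the binarized
  # tissue mask (nearest neighbour, so no interpolation loss) and compare
  # voxel counts; small scale factors and boundary-section effects pass
  ref <- as_plain_array(v1)
  thr <- 0.2 * max(ref)
  mask <- image_volume((ref > thr) * 1.0, vs)
  moved_mask <- apply_transform(mask, chain, "nearest")
  frac <- sum(moved_mask) / max(sum(ref > thr), 1e-12)
  if (frac < 0.85)
    stop("deformation pushed the cord partially out of frame (retained mass ",
         signif(frac, 3), ")")
  list(volumes = moved, chain = chain)
}

#' Generate a phantom cohort with group effects
#'
#' Builds one template phantom, then per sample applies the group's region
#' density multipliers, deposits signal (recording ground truth in template
#' space), and applies an independent random deformation plus acquisition
#' noise. Emulates a multi-group (e.g. sham vs post-stroke) experimental
#' design with a known injected effect.
#'
#' @param n_per_group samples per group (>= 1).
#' @param group_effects named list, one entry per group: `NULL` for no effect
#'   or a list of selectors `list(level=, lamina=, hemicord=, factor=)`
#'   multiplying the base densities of the matching regions.
#' @param seed master seed.
#' @param config a [phantom_config()].
#' @param groups group names; defaults to `names(group_effects)`. Effects
#'   naming a group not listed here are an error.
#' @param volumes if `FALSE`, skip deformation/noise/volume synthesis and
#'   return ground-truth sums only (fast Monte-Carlo path).
#' @param deform_magnitude passed to [deform_sample()].
#' @return list with `template` (phantom + annotation + ontology), `samples`
#'   (per sample: volumes, truth, group, true chain) and `manifest`.
#' @export
generate_cohort <- function(n_per_group, group_effects, seed = 1L,
                            config = phantom_config(),
                            groups = names(group_effects),
                            volumes = TRUE, deform_magnitude = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.null(groups) || !length(groups)) stop("no groups declared")
  unknown <- setdiff(names(group_effects), groups)
  if (length(unknown))
    stop("unknown group name in effects: ", paste(unknown, collapse = ", "))
  tpl <- generate_template_phantom(config, seed = derive_seed(seed, "template"))
  ontology <- tpl$ontology
  base_dens <- config$puncta_density %||% default_puncta_density(ontology)
  dens_of_group <- function(g) {
    dens <- base_dens
    eff <- group_effects[[g]]
    if (is.null(eff)) return(dens)
    if (!is.list(eff[[1]])) eff <- list(eff)
    for (sel in eff) {
      ids <- ontology_select(ontology, level = sel$level, lamina = sel$lamina,
                             hemicord = sel$hemicord)
      if (!length(ids)) stop("group effect selector matches no region")
      dens[as.character(ids)] <- dens[as.character(ids)] * sel$factor
    }
    dens
  }
  samples <- list()
  manifest <- list()
  for (g in groups) {
    dens <- dens_of_group(g)
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      s_seed <- derive_seed(seed, paste0("sample-", sid))
      dep <- deposit_signal(tpl$annotation, config, seed = s_seed, density = dens)
      smp <- list(id = sid, group = g, truth = dep$truth, seed = s_seed)
      if (volumes) {
        auto_i <- image_volume(
          add_noise(as_plain_array(tpl$autofluorescence), config$noise_sd,
                    config$shot_scale, derive_seed(s_seed, "auto-noise")),
          config$voxel_size, "autofluorescence")
        lab_img <- image_volume(dep$truth$labels * 1.0, config$voxel_size, "labels")
        attr(lab_img, "labels") <- TRUE
        def <- deform_sample(list(autofluorescence = auto_i, signal = dep$signal,
                                  labels = lab_img),
                             magnitude = deform_magnitude,
                             seed = derive_seed(s_seed, "deform"))
        moved_labels <- array(as.integer(round(as_plain_array(def$volumes$labels))),
                              dim(def$volumes$labels))
        attr(moved_labels, "class_names") <- attr(dep$truth$labels, "class_names")
        smp$autofluorescence <- def$volumes$autofluorescence
        smp$signal <- def$volumes$signal
        smp$labels <- moved_labels
        smp$chain_true <- def$chain
      }
      samples[[sid]] <- smp
      manifest[[sid]] <- data.frame(sample = sid, group = g, seed = s_seed,
                                    stringsAsFactors = FALSE)
    }
  }
  list(template = tpl, samples = samples,
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)))
}
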