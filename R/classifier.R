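# Random-forest pixel classification of MIP sections into signal classes,
# exported as 8-bit probability maps (0 = 0%, 255 = 100%), with the
# fixed-threshold intensity-preserving denoising step applied before
# region quantification.

#' Class scheme
#'
#' @param classes ordered class names; two presets mirror typical training
#'   schemes: `"terminals"` = presynaptic_terminal, axon, gray_matter,
#'   white_matter, background; `"somas"` = soma, process, gray_matter,
#'   white_matter, background. Gray/white/background are carried for
#'   visualization only and are excluded from quantification.
#' @export
class_scheme <- function(classes = c("presynaptic_terminal", "axon",
                                     "gray_matter", "white_matter",
                                     "background")) {
  if (is.character(classes) && length(classes) == 1L)
    classes <- switch(classes,
                      terminals = c("presynaptic_terminal", "axon", "gray_matter",
                                    "white_matter", "background"),
                      somas = c("soma", "process", "gray_matter",
                                "white_matter", "background"),
                      stop("unknown class scheme preset: ", classes))
  if (length(classes) < 2 || anyDuplicated(classes))
    stop("a class scheme needs >= 2 unique class names")
  structure(list(classes = classes,
                 signal = setdiff(classes, c("gray_matter", "white_matter",
                                             "background"))),
            class = "ClassScheme")
}

default_feature_scales <- c(0.7, 1.0, 1.6, 3.5, 5.0)

# shift a matrix by (dy, dx) with edge replication (for finite differences)
shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[pmin(pmax(seq_len(ny) - dy, 1), ny), pmin(pmax(seq_len(nx) - dx, 1), nx)]
}

gauss2d <- function(m, sigma) {
  d <- dim(m)
  out <- cpp_gauss_sep(as.numeric(m), c(1L, d[1], d[2]), c(0, sigma, sigma))
  matrix(out, d[1], d[2])
}

#' Per-pixel feature stack for classification
#'
#' For each scale: Gaussian smoothing, gradient magnitude,
#' Laplacian-of-Gaussian, the two Hessian eigenvalues and the two
#' structure-tensor eigenvalues of the smoothed image, plus the raw image
#' once. Multi-channel sections (list of matrices) get the full bank per
#' channel.
#'
#' @param section 2D matrix, or list of matrices (channels).
#' @param scales Gaussian scales in pixels (all > 0).
#' @return 3D array (y, x, features) with named feature planes.
#' @export
extract_features <- function(section, scales = default_feature_scales) {
  if (!length(scales) || any(scales <= 0)) stop("scales must be a non-empty positive vector")
  if (is.list(section)) {
    feats <- lapply(seq_along(section), function(i) {
      f <- extract_features(section[[i]], scales)
      dimnames(f)[[3]] <- paste0("ch", i, "_", dimnames(f)[[3]])
      f
    })
    out <- array(unlist(feats), c(dim(feats[[1]])[1:2],
                                  sum(vapply(feats, function(f) dim(f)[3], 0L))))
    dimnames(out)[[3]] <- unlist(lapply(feats, function(f) dimnames(f)[[3]]))
    return(out)
  }
  m <- as.matrix(section)
  planes <- list(raw = m)
  for (s in scales) {
    g <- gauss2d(m, s)
    gy <- (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) / 2
    gx <- (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) / 2
    hyy <- shift_mat(g, -1, 0) + shift_mat(g, 1, 0) - 2 * g
    hxx <- shift_mat(g, 0, -1) + shift_mat(g, 0, 1) - 2 * g
    hxy <- (shift_mat(g, -1, -1) + shift_mat(g, 1, 1) -
              shift_mat(g, -1, 1) - shift_mat(g, 1, -1)) / 4
    disc <- sqrt(pmax((hyy - hxx)^2 + 4 * hxy^2, 0))
    # structure tensor smoothed at the same scale
    jyy <- gauss2d(gy * gy, s); jxx <- gauss2d(gx * gx, s); jxy <- gauss2d(gx * gy, s)
    jdisc <- sqrt(pmax((jyy - jxx)^2 + 4 * jxy^2, 0))
    tag <- sprintf("s%.1f", s)
    planes[[paste0("gauss_", tag)]] <- g
    planes[[paste0("gradmag_", tag)]] <- sqrt(gy^2 + gx^2)
    planes[[paste0("log_", tag)]] <- hyy + hxx
    planes[[paste0("hess1_", tag)]] <- (hyy + hxx + disc) / 2
    planes[[paste0("hess2_", tag)]] <- (hyy + hxx - disc) / 2
    planes[[paste0("st1_", tag)]] <- (jyy + jxx + jdisc) / 2
    planes[[paste0("st2_", tag)]] <- (jyy + jxx - jdisc) / 2
  }
  out <- array(unlist(planes), c(dim(m), length(planes)))
  dimnames(out)[[3]] <- names(planes)
  out
}

# features at given (y, x) pixels, as a plain matrix
features_at <- function(fs, y, x) {
  d <- dim(fs)
  idx <- cbind(rep(y, d[3]), rep(x, d[3]), rep(seq_len(d[3]), each = length(y)))
  matrix(fs[idx], length(y), d[3], dimnames = list(NULL, dimnames(fs)[[3]]))
}

#' Train a random-forest pixel classifier
#'
#' One model per cohort: sparse brush labels from up to a few representative
#' sections per sample train a random forest over the feature bank; every
#' section of every sample in the cohort is then classified with this single
#' model.
#'
#' @param samples list of `list(section = matrix-or-channel-list,
#'   labels = data.frame(y, x, class))` training items; `class` is a class
#'   name or 1-based index into the scheme.
#' @param scheme a [class_scheme()]; every class must receive >= 1 label.
#' @param seed RNG seed (forest construction is deterministic given it).
#' @param scales feature scales (px).
#' @param num_trees forest size (default 100).
#' @return a `pixel_classifier` with the fitted forest, the scheme, scales
#'   and the training accuracy on the labelled pixels.
#' @export
train_classifier <- function(samples, scheme = class_scheme(), seed = 1L,
                             scales = default_feature_scales, num_trees = 100L) {
  stopifnot(length(samples) >= 1)
  Xs <- list(); ys <- list()
  for (s in samples) {
    lab <- s$labels
    cls <- if (is.numeric(lab$class)) scheme$classes[lab$class] else as.character(lab$class)
    if (!all(cls %in% scheme$classes))
      stop("labels reference classes outside the scheme")
    fs <- extract_features(s$section, scales)
    if (any(lab$y < 1 | lab$y > dim(fs)[1] | lab$x < 1 | lab$x > dim(fs)[2]))
      stop("label coordinates out of bounds")
    Xs[[length(Xs) + 1]] <- features_at(fs, lab$y, lab$x)
    ys[[length(ys) + 1]] <- cls
  }
  X <- do.call(rbind, Xs)
  y <- factor(unlist(ys), levels = scheme$classes)
  missing <- setdiff(scheme$classes, levels(droplevels(y)))
  if (length(missing))
    stop("no training labels for class(es): ", paste(missing, collapse = ", "))
  df <- data.frame(X, check.names = TRUE)
  df$.class <- y
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  pred <- ranger::predictions(predict(fit, df, num.threads = 1, seed = seed))
  train_acc <- mean(scheme$classes[max.col(pred, ties.method = "first")] ==
                      as.character(y))
  structure(list(forest = fit, scheme = scheme, scales = scales,
                 num_trees = num_trees, seed = seed,
                 feature_names = colnames(df)[-ncol(df)],
                 n_channels = if (is.list(samples[[1]]$section))
                   length(samples[[1]]$section) else 1L,
                 training_accuracy = train_acc),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: %d classes (%s), %d trees, %d features, training accuracy %.1f%%\n",
              length(x$scheme$classes), paste(x$scheme$classes, collapse = ", "),
              x$num_trees, length(x$feature_names), 100 * x$training_accuracy))
  invisible(x)
}

#' Predict per-class 8-bit probability maps
#'
#' Per-pixel random-forest vote fractions scaled to 0-255 (floor), so the
#' per-voxel sum over classes lies in [255 - n_classes + 1, 255].
#'
#' @param model a trained `pixel_classifier`.
#' @param sections list of sections (matrices or channel lists, one per
#'   physical section), or an `ImageVolume` (sections along z), or a list of
#'   `ImageVolume` channels.
#' @param tau denoising threshold stored with the maps (default 86).
#' @param tissue_bbox when `TRUE`, predict only inside a dilated bounding box
#'   of the tissue (Otsu on the first channel) and fill the outside with a
#'   certain background call (background = 255); per-voxel class sums are
#'   unaffected. Saves most of the prediction time on sparse fields of view.
#' @return a `ProbabilityMapSet`: named list of integer (z, y, x) volumes in
#'   `$maps`, plus `$scheme` and `$tau`.
#' @export
predict_probability_maps <- function(model, sections, tau = 86L,
                                     tissue_bbox = FALSE) {
  sections <- as_section_list(sections)
  d2 <- dim(if (is.list(sections[[1]])) sections[[1]][[1]] else sections[[1]])
  nz <- length(sections)
  classes <- model$scheme$classes
  bg <- match("background", classes)
  maps <- lapply(classes, function(cl) array(0L, c(nz, d2[1], d2[2])))
  names(maps) <- classes
  for (z in seq_len(nz)) {
    sec <- sections[[z]]
    dd <- dim(if (is.list(sec)) sec[[1]] else sec)
    if (!identical(dd, d2)) stop("section shape mismatch")
    ysel <- seq_len(d2[1]); xsel <- seq_len(d2[2])
    if (isTRUE(tissue_bbox) && !is.na(bg)) {
      ref <- if (is.list(sec)) sec[[1]] else sec
      m <- ref > otsu_threshold(ref[ref > 0])
      if (any(m)) {
        yr <- range(row(ref)[m]); xr <- range(col(ref)[m])
        ysel <- max(1, yr[1] - 8):min(d2[1], yr[2] + 8)
        xsel <- max(1, xr[1] - 8):min(d2[2], xr[2] + 8)
      } else { ysel <- integer(0); xsel <- integer(0) }
      maps[[bg]][z, , ] <- 255L
    }
    if (!length(ysel)) next
    sub <- if (is.list(sec)) lapply(sec, function(ch) ch[ysel, xsel, drop = FALSE])
           else sec[ysel, xsel, drop = FALSE]
    fs <- extract_features(sub, model$scales)
    X <- matrix(fs, length(ysel) * length(xsel), dim(fs)[3])
    colnames(X) <- model$feature_names
    pr <- ranger::predictions(predict(model$forest, data.frame(X, check.names = TRUE),
                                      num.threads = 1, seed = model$seed))
    for (k in seq_along(classes)) {
      page <- maps[[k]][z, , ]
      page[ysel, xsel] <- matrix(as.integer(floor(pr[, classes[k]] * 255)),
                                 length(ysel), length(xsel))
      maps[[k]][z, , ] <- page
    }
  }
  structure(list(maps = maps, scheme = model$scheme, tau = as.integer(tau)),
            class = "ProbabilityMapSet")
}

as_section_list <- function(sections) {
  if (inherits(sections, "ImageVolume")) {
    d <- dim(sections)
    return(lapply(seq_len(d[1]), function(z) sections[z, , ]))
  }
  if (is.list(sections) && length(sections) &&
      inherits(sections[[1]], "ImageVolume")) {
    # list of channel volumes -> per-section channel lists
    d <- dim(sections[[1]])
    return(lapply(seq_len(d[1]), function(z)
      lapply(sections, function(v) v[z, , ])))
  }
  sections
}

#' Threshold probability maps (intensity-preserving denoise)
#'
#' Voxels below the threshold are zeroed; voxels at or above keep their
#' original value, because downstream quantification sums the denoised map
#' intensities. Applied to the quantified signal classes of a map set
#' (gray/white/background maps are for visualization only), or to a single
#' map array.
#'
#' @param x a `ProbabilityMapSet` or a numeric/integer array.
#' @param tau threshold in 0-255 (default 86).
#' @param classes which classes to threshold when `x` is a map set
#'   (default: the scheme's signal classes).
#' @export
threshold_probability <- function(x, tau = 86L, classes = NULL) {
  if (tau < 0 || tau > 255) stop("threshold must lie in [0, 255]")
  if (inherits(x, "ProbabilityMapSet")) {
    classes <- classes %||% x$scheme$signal
    for (cl in classes) {
      m <- x$maps[[cl]]
      m[m < tau] <- 0L
      x$maps[[cl]] <- m
    }
    x$tau <- as.integer(tau)
    x
  } else {
    x[x < tau] <- 0L
    x
  }
}
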