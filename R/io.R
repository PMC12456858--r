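# Readers and writers for the pipeline's interchange formats: multi-page
# 16-bit TIFF volumes (sections along z), per-section TIFF trees, NIfTI
# templates, and JSON metadata sidecars.

#' Write a volume as a multi-page 16-bit TIFF
#'
#' One page per section (z); intensities are stored relative to `scale`
#' (default 65535, i.e. raw 16-bit units). Voxel sizes go to a JSON sidecar.
#'
#' @param volume an `ImageVolume`.
#' @param path output `.tif`.
#' @param scale full-scale intensity.
#' @export
write_volume_tiff <- function(volume, path, scale = 65535) {
  d <- dim(volume)
  pages <- lapply(seq_len(d[1]), function(z)
    pmin(pmax(volume[z, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size = voxel_size(volume),
                            channel = attr(volume, "channel"), scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume
#' @param path `.tif` written by [write_volume_tiff()] (JSON sidecar expected;
#'   missing sidecar falls back to the supplied defaults).
#' @param voxel_size,channel,scale defaults when no sidecar is present.
#' @export
read_volume_tiff <- function(path, voxel_size = c(40, 10, 10),
                             channel = "autofluorescence", scale = 65535) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxel_size <- meta$voxel_size; channel <- meta$channel; scale <- meta$scale
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  image_volume(arr, voxel_size, channel)
}

#' Write per-section TIFF files
#'
#' Layout `{dir}/{sample}/{section:04d}_{plane}_{channel}.tif`, one image per
#' section per optical plane per channel.
#'
#' @param channels named list of `ImageVolume`s (one per channel); each may be
#'   a list of per-plane volumes for multi-plane acquisitions.
#' @param dir,sample output tree.
#' @param scale full-scale intensity.
#' @export
write_section_tiffs <- function(channels, dir, sample, scale = 65535) {
  root <- file.path(dir, sample)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(channels)) {
    vols <- channels[[ch]]
    if (inherits(vols, "ImageVolume")) vols <- list(vols)
    for (p in seq_along(vols)) {
      v <- vols[[p]]
      for (z in seq_len(dim(v)[1]))
        tiff::writeTIFF(pmin(pmax(v[z, , ] / scale, 0), 1),
                        file.path(root, sprintf("%04d_%d_%s.tif", z, p, ch)),
                        bits.per.sample = 16L)
    }
  }
  invisible(root)
}

#' Read a per-section TIFF tree into MIP volumes
#'
#' Collects `{section:04d}_{plane}_{channel}.tif` files and returns, per
#' channel, the per-section maximum intensity projection over optical planes.
#'
#' @param dir,sample tree written by [write_section_tiffs()].
#' @param voxel_size voxel sizes of the assembled volume.
#' @param scale full-scale intensity.
#' @export
read_section_tiffs <- function(dir, sample, voxel_size = c(40, 10, 10),
                               scale = 65535) {
  root <- file.path(dir, sample)
  files <- list.files(root, pattern = "^\\d{4}_\\d+_.+\\.tif$")
  if (!length(files)) stop("no section TIFFs found under ", root)
  parts <- regmatches(files, regexec("^(\\d{4})_(\\d+)_(.+)\\.tif$", files))
  info <- data.frame(file = files,
                     section = as.integer(vapply(parts, `[`, "", 2)),
                     plane = as.integer(vapply(parts, `[`, "", 3)),
                     channel = vapply(parts, `[`, "", 4),
                     stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(info$channel)) {
    sub <- info[info$channel == ch, ]
    secs <- sort(unique(sub$section))
    first <- tiff::readTIFF(file.path(root, sub$file[1]))
    arr <- array(0, c(length(secs), nrow(first), ncol(first)))
    for (i in seq_along(secs)) {
      planes <- lapply(sub$file[sub$section == secs[i]], function(f)
        tiff::readTIFF(file.path(root, f)) * scale)
      arr[i, , ] <- mip_project(planes)
    }
    out[[ch]] <- image_volume(arr, voxel_size, ch)
  }
  out
}

#' Write an intensity template as NIfTI
#' @param volume an `ImageVolume`.
#' @param path output `.nii`/`.nii.gz`.
#' @export
write_template_nifti <- function(volume, path) {
  arr <- as_plain_array(volume)
  attr(arr, "pixdim") <- voxel_size(volume) / 1000
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read an intensity template from NIfTI
#' @param path NIfTI written by [write_template_nifti()].
#' @param channel channel role to attach.
#' @export
read_template_nifti <- function(path, channel = "autofluorescence") {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)),
               signif(RNifti::pixdim(img) * 1000, 7), channel)
}

#' Write probability maps (one multi-page 8-bit TIFF per class)
#' @param maps a `ProbabilityMapSet`.
#' @param dir output directory; files are `probmap_<class>.tif`.
#' @export
write_probability_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(maps$maps)) {
    m <- maps$maps[[cl]]
    pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ] / 255)
    tiff::writeTIFF(pages, file.path(dir, paste0("probmap_", gsub("\\W+", "_", cl), ".tif")),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(list(classes = maps$scheme$classes, tau = maps$tau),
                       file.path(dir, "probmaps.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read probability maps written by [write_probability_maps()]
#' @param dir directory containing `probmap_*.tif` and `probmaps.json`.
#' @export
read_probability_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "probmaps.json"), simplifyVector = TRUE)
  scheme <- class_scheme(meta$classes)
  maps <- lapply(meta$classes, function(cl) {
    pages <- tiff::readTIFF(file.path(dir, paste0("probmap_", gsub("\\W+", "_", cl), ".tif")),
                            all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- as.integer(round(pages[[z]] * 255))
    arr
  })
  names(maps) <- meta$classes
  structure(list(maps = maps, scheme = scheme, tau = as.integer(meta$tau)),
            class = "ProbabilityMapSet")
}

# metadata sidecar shared by CLI stages
write_stage_metadata <- function(path, config, seed, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  meta <- c(list(config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
                 config_md5 = unname(tools::md5sum(tmp)), seed = seed,
                 package_version = as.character(utils::packageVersion("cordquant")),
                 r_version = R.version.string),
            extra)
  unlink(tmp)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
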