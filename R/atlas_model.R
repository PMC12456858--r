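# Region ontology and annotation-volume data model.
#
# Gray-matter regions are identified by cervical level (C1-C8), Rexed lamina
# (1-10) or a named motor pool (a subregion of lamina 9), and hemicord
# (left/right). Lamina 6 does not exist at levels C1-C3. White matter is
# carried as one tract region per level and hemicord. Region id 0 is
# reserved for background.

CERVICAL_LEVELS <- paste0("C", 1:8)
NO_LAMINA6_LEVELS <- c("C1", "C2", "C3")

#' Build a region ontology
#'
#' Enumerates gray-matter regions as level x lamina x hemicord (dropping
#' lamina 6 at C1-C3), optionally adds named motor pools (subregions of
#' lamina 9) and white-matter tract regions per level and hemicord. Region
#' ids are assigned deterministically in enumeration order, starting at 1.
#'
#' @param levels cervical levels, subset of C1-C8.
#' @param laminae_per_level either an integer vector of laminae applied to
#'   every level (lamina 6 silently dropped at C1-C3, the anatomical rule),
#'   or a named list giving the laminae of each level explicitly (requesting
#'   lamina 6 at C1-C3 is then an error).
#' @param motor_pools character vector of motor pool names (may be empty).
#' @param pool_levels levels at which the pools are defined (default C2-C8,
#'   intersected with `levels`).
#' @param white_tracts character vector of white-matter tract names to add
#'   per level and hemicord (default none).
#' @param version free-text version tag.
#' @return A `RegionOntology`: list with a `regions` data frame
#'   (id, name, level, lamina, hemicord, tissue_class, region_type) and
#'   `version`.
#' @export
build_region_ontology <- function(levels = CERVICAL_LEVELS,
                                  laminae_per_level = 1:10,
                                  motor_pools = character(),
                                  pool_levels = intersect(paste0("C", 2:8), levels),
                                  white_tracts = character(),
                                  version = "cordquant-ontology-1") {
  stopifnot(all(levels %in% CERVICAL_LEVELS), !anyDuplicated(levels))
  if (is.list(laminae_per_level)) {
    if (!setequal(names(laminae_per_level), levels))
      stop("laminae_per_level list must name every requested level")
    for (lv in intersect(names(laminae_per_level), NO_LAMINA6_LEVELS))
      if (6 %in% laminae_per_level[[lv]])
        stop("lamina 6 does not exist at levels C1-C3 (requested at ", lv, ")")
    lam_of <- laminae_per_level
  } else {
    lam <- as.integer(laminae_per_level)
    stopifnot(all(lam %in% 1:10))
    lam_of <- lapply(levels, function(lv)
      if (lv %in% NO_LAMINA6_LEVELS) setdiff(lam, 6L) else lam)
    names(lam_of) <- levels
  }
  hemis <- c("left", "right")
  rows <- list()
  for (lv in levels) for (h in hemis) for (l in lam_of[[lv]]) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("%s lamina %d %s", lv, l, h), level = lv,
      lamina = as.character(l), hemicord = h,
      tissue_class = "gray", region_type = "lamina",
      stringsAsFactors = FALSE)
  }
  if (length(motor_pools)) {
    if (anyDuplicated(motor_pools)) stop("duplicate motor pool names")
    for (lv in pool_levels) for (h in hemis) for (p in motor_pools) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s %s pool %s", lv, p, h), level = lv,
        lamina = p, hemicord = h,
        tissue_class = "gray", region_type = "pool",
        stringsAsFactors = FALSE)
    }
  }
  for (lv in levels) for (h in hemis) for (w in white_tracts) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("%s %s %s", lv, w, h), level = lv,
      lamina = w, hemicord = h,
      tissue_class = "white", region_type = "white",
      stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, rows)
  if (anyDuplicated(regions$name)) stop("duplicate region names in ontology")
  regions <- cbind(id = seq_len(nrow(regions)), regions)
  structure(list(regions = regions, version = version), class = "RegionOntology")
}

#' @export
print.RegionOntology <- function(x, ...) {
  cat(sprintf("RegionOntology '%s': %d regions (%d gray, %d white)\n",
              x$version, nrow(x$regions), sum(x$regions$tissue_class == "gray"),
              sum(x$regions$tissue_class == "white")))
  invisible(x)
}

#' Select region ids from an ontology
#'
#' @param ontology a `RegionOntology`.
#' @param level,lamina,hemicord,region_type optional filters (vectors allowed;
#'   `lamina` matches the lamina/pool/tract label as character).
#' @return integer vector of region ids.
#' @export
ontology_select <- function(ontology, level = NULL, lamina = NULL,
                            hemicord = NULL, region_type = NULL) {
  r <- ontology$regions
  keep <- rep(TRUE, nrow(r))
  if (!is.null(level)) keep <- keep & r$level %in% level
  if (!is.null(lamina)) keep <- keep & r$lamina %in% as.character(lamina)
  if (!is.null(hemicord)) keep <- keep & r$hemicord %in% hemicord
  if (!is.null(region_type)) keep <- keep & r$region_type %in% region_type
  r$id[keep]
}

#' Annotation volume container
#'
#' @param labels integer 3D array (z, y, x) of region ids; 0 = background.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param ontology the `RegionOntology` the labels refer to.
#' @param midline_x declared midline x-position (may be half-integer; voxels
#'   with x-index > midline are the left hemicord).
#' @export
annotation_volume <- function(labels, voxel_size = c(40, 10, 10), ontology,
                              midline_x = (dim(labels)[3] + 1) / 2) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  bad <- setdiff(ids, c(0L, ontology$regions$id))
  if (length(bad)) stop("labels contain ids absent from the ontology: ",
                        paste(bad, collapse = ", "))
  structure(labels, voxel_size = as.numeric(voxel_size), ontology = ontology,
            midline_x = as.numeric(midline_x),
            class = c("AnnotationVolume", "array"))
}

#' @export
print.AnnotationVolume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("AnnotationVolume %d x %d x %d voxels, %d labelled (%d regions), midline x = %s\n",
              d[1], d[2], d[3], sum(x != 0L),
              length(setdiff(unique(as.vector(x)), 0L)),
              format(attr(x, "midline_x"))))
  invisible(x)
}

#' Look up the region at a voxel
#'
#' @param annotation an `AnnotationVolume`.
#' @param voxel integer length-3 (z, y, x), 1-based.
#' @return the matching region record (one-row data frame), or `NULL` for
#'   background (label 0).
#' @export
region_lookup <- function(annotation, voxel) {
  d <- dim(annotation)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d))
    stop("voxel index out of bounds")
  id <- annotation[voxel[1], voxel[2], voxel[3]]
  if (id == 0L) return(NULL)
  ont <- attr(annotation, "ontology")
  ont$regions[ont$regions$id == id, , drop = FALSE]
}

#' Write an ontology to JSON
#' @param ontology a `RegionOntology`.
#' @param path output file.
#' @export
write_ontology_json <- function(ontology, path) {
  jsonlite::write_json(list(version = ontology$version, regions = ontology$regions),
                       path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read an ontology from JSON
#' @param path file written by [write_ontology_json()].
#' @export
read_ontology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- as.data.frame(x$regions, stringsAsFactors = FALSE)
  regions$id <- as.integer(regions$id)
  structure(list(regions = regions, version = x$version), class = "RegionOntology")
}

#' Write an annotation volume as NIfTI
#'
#' Integer labels, voxel sizes in the header (stored in millimetres as NIfTI
#' convention dictates; this package's axis order z,y,x is recorded by
#' writing the array as-is with z fastest).
#' @param annotation an `AnnotationVolume`.
#' @param path output `.nii`/`.nii.gz` file.
#' @export
write_annotation_nifti <- function(annotation, path) {
  arr <- as_plain_array(annotation)
  attr(arr, "pixdim") <- voxel_size(annotation) / 1000
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), path)
  invisible(path)
}

#' Read an annotation volume from NIfTI
#' @param path NIfTI file written by [write_annotation_nifti()].
#' @param ontology the `RegionOntology` the labels refer to.
#' @param midline_x declared midline x-position.
#' @export
read_annotation_nifti <- function(path, ontology, midline_x = NULL) {
  img <- RNifti::readNifti(path)
  vs <- signif(RNifti::pixdim(img) * 1000, 7)  # undo float32 header rounding
  arr <- array(as.integer(img), dim(img))
  annotation_volume(arr, voxel_size = vs, ontology = ontology,
                    midline_x = midline_x %||% ((dim(arr)[3] + 1) / 2))
}
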