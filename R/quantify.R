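# Region-specific accumulation of warped, thresholded probability-map signal
# into a sample x class x region matrix, with normalization and aggregation
# views (level / lamina / hemicord / motor pool, ipsi/contra framing).

#' Quantify probability maps over atlas regions
#'
#' Sums the denoised probability-map intensity of each signal class within
#' every annotated region. Background voxels (label 0) are excluded;
#' gray/white/background classes are not quantified. The per-class sum over
#' all regions equals the total map intensity within the annotated mask.
#'
#' @param maps a `ProbabilityMapSet` in template space (already thresholded).
#' @param annotation the `AnnotationVolume` on the same grid.
#' @param sample,group optional metadata attached to the rows.
#' @return a tidy `QuantMatrix` data frame: sample, group, class, region_id,
#'   region_name, level, lamina, hemicord, tissue_class, value.
#' @export
quantify_regions <- function(maps, annotation, sample = "sample1", group = NA) {
  stopifnot(inherits(maps, "ProbabilityMapSet"))
  ontology <- attr(annotation, "ontology")
  d <- dim(annotation)
  classes <- maps$scheme$signal
  lab <- as.vector(as_plain_array(annotation))
  sel <- lab > 0L
  labs <- lab[sel]
  r <- ontology$regions
  out <- list()
  for (cl in classes) {
    m <- maps$maps[[cl]]
    if (!identical(dim(m), d))
      stop(sprintf("grid mismatch: map '%s' is %s but annotation is %s",
                   cl, paste(dim(m), collapse = "x"), paste(d, collapse = "x")))
    rs <- rowsum(as.numeric(m)[sel], labs)
    value <- setNames(numeric(nrow(r)), r$id)
    value[rownames(rs)] <- rs[, 1]
    out[[cl]] <- data.frame(sample = sample, group = group, class = cl,
                            region_id = r$id, region_name = r$name,
                            level = r$level, lamina = r$lamina,
                            hemicord = r$hemicord, tissue_class = r$tissue_class,
                            value = unname(value), stringsAsFactors = FALSE)
  }
  qm <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(qm, ontology = ontology, normalization = "none",
            class = c("QuantMatrix", "data.frame"))
}

#' Combine per-sample quantifications into one matrix
#' @param qms list of `QuantMatrix` data frames.
#' @export
bind_quant <- function(qms) {
  out <- do.call(rbind, c(lapply(qms, as.data.frame), make.row.names = FALSE))
  structure(out, ontology = attr(qms[[1]], "ontology"),
            normalization = attr(qms[[1]], "normalization"),
            class = c("QuantMatrix", "data.frame"))
}

#' Normalize a quantification matrix
#'
#' `total_signal` divides each sample's entries by that sample's grand total
#' over all quantified classes and regions; `axon_reference` divides by the
#' sample's axon-class signal within white-matter regions (a proxy for viral
#' labelling strength); `none` copies the raw values. The mode is recorded on
#' the object.
#'
#' @param qm a `QuantMatrix`.
#' @param mode `"none"`, `"total_signal"` or `"axon_reference"`.
#' @param reference_class class used by `axon_reference` (default "axon").
#' @return the matrix with a `normalized_value` column.
#' @export
normalize_quant <- function(qm, mode = c("total_signal", "none", "axon_reference"),
                            reference_class = "axon") {
  mode <- match.arg(mode)
  qm <- as.data.frame(qm)
  denom <- switch(mode,
    none = setNames(rep(1, length(unique(qm$sample))), unique(qm$sample)),
    total_signal = tapply(qm$value, qm$sample, sum),
    axon_reference = {
      sel <- qm$class == reference_class & qm$tissue_class == "white"
      if (!any(sel)) stop("no ", reference_class, " signal in white-matter regions")
      tapply(qm$value[sel], qm$sample[sel], sum)[unique(qm$sample)]
    })
  zero <- names(denom)[!is.finite(denom) | denom == 0]
  if (length(zero))
    stop("zero normalization denominator for sample(s): ",
         paste(zero, collapse = ", "))
  qm$normalized_value <- qm$value / as.numeric(denom[qm$sample])
  structure(qm, ontology = attr(qm, "ontology"), normalization = mode,
            class = c("QuantMatrix", "data.frame"))
}

#' Aggregate a quantification matrix
#'
#' Sums entries within a grouping (level, lamina, hemicord or pool), per
#' sample and class. Percentage views normalize each declared stratum to 100.
#' Ipsi/contralateral framing is derived at aggregation time from the
#' hemicord and the per-sample injection side.
#'
#' @param qm a `QuantMatrix`.
#' @param by grouping key: `"level"`, `"lamina"`, `"hemicord"` or `"pool"`.
#' @param value column to aggregate (`"value"` or `"normalized_value"`).
#' @param percent_within optional character vector of columns defining strata
#'   within which values are rescaled to sum to 100 (e.g. c("level",
#'   "hemicord")).
#' @param injection_side optional named vector (sample -> "left"/"right");
#'   adds a `laterality` column (ipsilateral/contralateral).
#' @param gray_only restrict to gray-matter regions (default TRUE).
#' @export
aggregate_quant <- function(qm, by = c("level", "lamina", "hemicord", "pool"),
                            value = "value", percent_within = NULL,
                            injection_side = NULL, gray_only = TRUE) {
  by <- match.arg(by)
  df <- as.data.frame(qm)
  if (!value %in% names(df)) stop("no '", value, "' column; run normalize_quant()?")
  if (gray_only) df <- df[df$tissue_class == "gray", ]
  ont <- attr(qm, "ontology")
  if (by == "pool") {
    pools <- ont$regions$lamina[ont$regions$region_type == "pool"]
    df <- df[df$lamina %in% pools, ]
    df$key <- df$lamina
  } else df$key <- df[[by]]
  if (!is.null(injection_side)) {
    side <- injection_side[df$sample]
    df$laterality <- ifelse(df$hemicord == side, "ipsilateral", "contralateral")
  }
  grp_cols <- c("sample", "group", "class", "key",
                if (!is.null(injection_side)) "laterality",
                setdiff(percent_within, c("sample", "group", "class", "key")))
  agg <- stats::aggregate(df[[value]], df[grp_cols], sum)
  names(agg)[names(agg) == "x"] <- "value"
  names(agg)[names(agg) == "key"] <- by
  if (!is.null(percent_within)) {
    strat <- interaction(agg[c("sample", "class", percent_within)], drop = TRUE)
    tot <- tapply(agg$value, strat, sum)
    agg$percent <- 100 * agg$value / as.numeric(tot[strat])
  }
  agg
}

#' Write a quantification matrix to CSV (+ JSON metadata)
#' @param qm a `QuantMatrix`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @param meta extra metadata fields.
#' @export
write_quant_csv <- function(qm, path, meta = list()) {
  write.csv(as.data.frame(qm), path, row.names = FALSE)
  meta$normalization <- attr(qm, "normalization") %||% "none"
  meta$ontology_version <- attr(qm, "ontology")$version
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
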