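# Group statistics mirroring the pipeline's analysis conventions: log10
# scaling with a pseudocount, log10 fold changes of group means,
# Kruskal-Wallis with Dunn's post hoc test and Benjamini-Hochberg FDR
# correction across the full region x pair family, hierarchical clustering of
# laminar profiles, and subtraction heatmaps.

#' log10 fold change of group means
#'
#' `log10((mean(A) + eps) / (mean(B) + eps))`; the pseudocount guards the
#' zeros that occur in sparse regions.
#'
#' @param values_a,values_b non-negative group values.
#' @param eps pseudocount (> 0), default 1 intensity unit.
#' @export
log10_fold_change <- function(values_a, values_b, eps = 1) {
  if (!length(values_a) || !length(values_b)) stop("empty group")
  stopifnot(eps > 0, all(values_a >= 0), all(values_b >= 0))
  log10((mean(values_a) + eps) / (mean(values_b) + eps))
}

# midranks with tie bookkeeping
rank_with_ties <- function(v) {
  r <- rank(v)
  t <- table(v)
  list(ranks = r, tie_sizes = as.numeric(t[t > 1]))
}

#' Kruskal-Wallis with Dunn's post hoc test and FDR correction
#'
#' Tie-corrected Kruskal-Wallis H; Dunn pairwise z statistics from the pooled
#' tie-corrected rank variance; two-sided normal p values adjusted by
#' Benjamini-Hochberg within this call (adjust across a wider family by
#' collecting raw p values with [compare_groups()]). If every value is
#' identical the rank variance is zero and the defined result is p = 1.
#'
#' @param groups named list (>= 2) of numeric vectors (each >= 1 value).
#' @param p_adjust adjustment method for the pairwise p values.
#' @return list with `H`, `df`, `p_value` and a `dunn` data frame
#'   (group1, group2, z, p, p_adj).
#' @export
kruskal_dunn_fdr <- function(groups, p_adjust = "BH") {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(v)
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  if (length(unique(v)) == 1L) {
    dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                       z = 0, p = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(list(H = 0, df = k - 1, p_value = 1, dunn = dunn))
  }
  rt <- rank_with_ties(v)
  r <- rt$ranks
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_term <- sum(rt$tie_sizes^3 - rt$tie_sizes)
  H <- (12 / (N * (N + 1))) * sum(n * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_term / (N^3 - N)
  H <- H / C
  p_kw <- pchisq(H, df = k - 1, lower.tail = FALSE)
  # Dunn: pooled rank variance with tie correction
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(s2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  p <- 2 * pnorm(-abs(z))
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = as.numeric(z), p = as.numeric(p),
                     p_adj = p.adjust(as.numeric(p), method = p_adjust),
                     stringsAsFactors = FALSE)
  list(H = as.numeric(H), df = k - 1, p_value = as.numeric(p_kw), dunn = dunn)
}

#' Per-region group comparison of a quantification matrix
#'
#' For one signal class: per-region group means on a log10 scale
#' (`log10(mean + eps)`), pairwise log10 fold changes, Kruskal-Wallis H/p and
#' Dunn pairwise z/p, with Benjamini-Hochberg correction across the full
#' declared family (all regions x all pairwise comparisons).
#'
#' @param qm a `QuantMatrix` (normalized or not).
#' @param class signal class to compare.
#' @param value column to use. The default is the raw summed intensity
#'   (`"value"`), on whose scale the default pseudocount of 1 intensity unit
#'   is meaningful; when comparing normalized values pass
#'   `value = "normalized_value"` together with a commensurate `eps`.
#' @param eps pseudocount for the log scale (units of `value`).
#' @return list with `regions` (per-region table) and `dunn` (region x pair
#'   table with `p_adj` over the full family).
#' @export
compare_groups <- function(qm, class = NULL, value = NULL, eps = 1) {
  df <- as.data.frame(qm)
  class <- class %||% df$class[1]
  df <- df[df$class == class, ]
  value <- value %||% "value"
  if (length(unique(df$group[!is.na(df$group)])) < 2)
    stop("need >= 2 groups for comparison")
  groups <- sort(unique(df$group))
  region_rows <- list(); dunn_rows <- list()
  for (rid in unique(df$region_id)) {
    sub <- df[df$region_id == rid, ]
    gl <- split(sub[[value]], sub$group)[groups]
    kd <- kruskal_dunn_fdr(gl)
    means <- vapply(gl, mean, 0)
    row <- data.frame(region_id = rid, region_name = sub$region_name[1],
                      level = sub$level[1], lamina = sub$lamina[1],
                      hemicord = sub$hemicord[1],
                      H = kd$H, p_kw = kd$p_value, stringsAsFactors = FALSE)
    for (g in groups) row[[paste0("log10_mean_", g)]] <- log10(means[[g]] + eps)
    pairs <- utils::combn(groups, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      row[[paste0("log10FC_", a, "_vs_", b)]] <-
        log10_fold_change(gl[[a]], gl[[b]], eps)
    }
    region_rows[[length(region_rows) + 1]] <- row
    kd$dunn$region_id <- rid
    dunn_rows[[length(dunn_rows) + 1]] <- kd$dunn[c("region_id", "group1",
                                                    "group2", "z", "p")]
  }
  dunn <- do.call(rbind, c(dunn_rows, make.row.names = FALSE))
  dunn$p_adj <- p.adjust(dunn$p, method = "BH")  # family: all regions x pairs
  list(regions = do.call(rbind, c(region_rows, make.row.names = FALSE)),
       dunn = dunn, class = class, value = value, eps = eps)
}

#' Hierarchical clustering of laminar profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage (the
#' conventions of the heatmap package this mirrors). Leaf order is the
#' deterministic `hclust` order; with fewer than 2 rows the identity order is
#' returned.
#'
#' @param mat numeric matrix (rows = laminae, cols = levels), finite.
#' @return list with `order` (row indices), `labels`, `hclust` and a Newick
#'   string of the dendrogram (`newick`, NULL when degenerate).
#' @export
cluster_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("matrix must be finite")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  if (nrow(mat) < 2)
    return(list(order = seq_len(nrow(mat)), labels = rownames(mat),
                hclust = NULL, newick = NULL))
  hc <- hclust(dist(mat, method = "euclidean"), method = "complete")
  phy <- ape::as.phylo(hc)
  list(order = hc$order, labels = rownames(mat)[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}

#' Subtraction heatmap matrix
#'
#' Elementwise difference of two aligned group-mean matrices (e.g. post-stroke
#' minus sham normalized means).
#'
#' @param means_a,means_b matrices with identical dimnames.
#' @export
subtraction_heatmap <- function(means_a, means_b) {
  means_a <- as.matrix(means_a); means_b <- as.matrix(means_b)
  if (!identical(dim(means_a), dim(means_b)) ||
      !identical(dimnames(means_a), dimnames(means_b)))
    stop("region sets of the two groups do not match")
  means_a - means_b
}

#' Lamina x level group-mean matrix for heatmaps
#'
#' @param qm a `QuantMatrix`.
#' @param class signal class.
#' @param group group to average over (NULL = all samples).
#' @param hemicord restrict to one hemicord (optional).
#' @param value value column; default normalized when available.
#' @param eps pseudocount; result is log10(mean + eps).
#' @export
lamina_level_matrix <- function(qm, class = NULL, group = NULL, hemicord = NULL,
                                value = NULL, eps = 1) {
  df <- as.data.frame(qm)
  class <- class %||% df$class[1]
  df <- df[df$class == class & df$tissue_class == "gray" &
             df$lamina %in% as.character(1:10), ]
  if (!is.null(group)) df <- df[df$group %in% group, ]
  if (!is.null(hemicord)) df <- df[df$hemicord == hemicord, ]
  value <- value %||% (if ("normalized_value" %in% names(df)) "normalized_value"
                       else "value")
  agg <- stats::aggregate(df[[value]], df[c("lamina", "level")], mean)
  laminae <- as.character(sort(as.integer(unique(agg$lamina))))
  levels_ <- unique(df$level)[order(match(unique(df$level), CERVICAL_LEVELS))]
  m <- matrix(NA_real_, length(laminae), length(levels_),
              dimnames = list(laminae, levels_))
  m[cbind(match(agg$lamina, laminae), match(agg$level, levels_))] <- log10(agg$x + eps)
  m
}
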