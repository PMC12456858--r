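# Nonparametric group statistics: log10 fold change, Kruskal-Wallis + Dunn
# against an exhaustive-rank oracle, BH monotonicity, clustering, subtraction.

# independent oracle: ranks by explicit sorting, H and Dunn z from first principles
oracle_kw_dunn <- function(groups) {
  v <- unlist(groups); g <- rep(names(groups), lengths(groups))
  N <- length(v)
  sorted <- sort(v)
  r <- vapply(v, function(x) mean(which(sorted == x)), 0)
  rbar <- vapply(names(groups), function(k) mean(r[g == k]), 0)
  n <- vapply(names(groups), function(k) sum(g == k), 0)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(v); t <- as.numeric(ties[ties > 1])
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H <- H / C
  s2 <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  pr <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pr)), function(j)
    (rbar[pr[1, j]] - rbar[pr[2, j]]) /
      sqrt(s2 * (1 / n[pr[1, j]] + 1 / n[pr[2, j]])), 0)
  list(H = H, z = z)
}

test_that("log10 fold change handles identity, decades and errors", {
  expect_equal(log10_fold_change(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(log10_fold_change(rep(1e6, 3), rep(1e5, 3), eps = 1e-9), 1,
               tolerance = 1e-6)
  expect_error(log10_fold_change(numeric(0), 1), "empty")
  expect_error(log10_fold_change(1, 1, eps = 0), "eps > 0")
})

test_that("Kruskal-Wallis and Dunn agree with the exhaustive-rank oracle", {
  set.seed(21)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    groups <- setNames(lapply(seq_len(k), function(i)
      round(rnorm(sample(3:8, 1), mean = i), sample(0:1, 1))), letters[1:k])
    got <- kruskal_dunn_fdr(groups)
    ora <- oracle_kw_dunn(groups)
    expect_equal(got$H, ora$H, tolerance = 1e-10)
    expect_equal(got$dunn$z, unname(ora$z), tolerance = 1e-10)
    # cross-check H/p against the reference implementation
    kt <- kruskal.test(unlist(groups), factor(rep(names(groups), lengths(groups))))
    expect_equal(got$H, unname(kt$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, kt$p.value, tolerance = 1e-10)
  }
})

test_that("two-group Kruskal-Wallis matches the Wilcoxon normal approximation", {
  set.seed(33)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(7, 0.5)
    got <- kruskal_dunn_fdr(list(a = a, b = b))
    # normal-approximation rank-sum p (no continuity correction, no ties)
    r <- rank(c(a, b)); W <- sum(r[1:6])
    mu <- 6 * (6 + 7 + 1) / 2; sd_w <- sqrt(6 * 7 * (6 + 7 + 1) / 12)
    p_w <- 2 * pnorm(-abs((W - mu) / sd_w))
    expect_equal(got$p_value, p_w, tolerance = 1e-9)
    expect_equal(got$dunn$p, p_w, tolerance = 1e-9)
  }
})

test_that("degenerate all-identical input yields the defined p = 1", {
  got <- kruskal_dunn_fdr(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(got$H, 0)
  expect_equal(got$p_value, 1)
  expect_true(all(got$dunn$p == 1))
})

test_that("BH adjustment is monotone over the declared family", {
  set.seed(44)
  p <- runif(40)^2
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p - 1e-15))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_lte(max(adj), 1)

  # compare_groups adjusts across all regions x pairs
  qm <- data.frame(sample = rep(paste0("s", 1:6), each = 4),
                   group = rep(c("g1", "g2"), each = 12),
                   class = "presynaptic_terminal",
                   region_id = rep(1:4, 6),
                   region_name = paste0("r", rep(1:4, 6)),
                   level = "C4", lamina = "5", hemicord = "left",
                   tissue_class = "gray",
                   value = rpois(24, 40) + rep(c(0, 0, 0, 60), 6) *
                     rep(c(0, 1), each = 12))
  cmp <- compare_groups(structure(qm, class = c("QuantMatrix", "data.frame")))
  expect_equal(nrow(cmp$dunn), 4)  # 4 regions x 1 pair
  expect_true(all(cmp$dunn$p_adj >= cmp$dunn$p - 1e-15))
  expect_true("log10FC_g1_vs_g2" %in% names(cmp$regions))
})

test_that("row clustering is deterministic with sensible structure", {
  m <- rbind(a = c(0, 0, 0), b = c(0.01, 0, 0), c = c(5, 5, 5), d = c(5.1, 5, 5))
  cl <- cluster_rows(m)
  ord <- cl$order
  # the two blocks stay contiguous in leaf order
  blocks <- c(a = 1, b = 1, c = 2, d = 2)[rownames(m)[ord]]
  expect_true(all(diff(blocks) >= 0) || all(diff(blocks) <= 0))
  # identical rows merge first at distance zero
  m2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9), d = c(4, 0))
  cl2 <- cluster_rows(m2)
  expect_equal(cl2$hclust$height[1], 0)
  expect_setequal(rownames(m2)[-cl2$hclust$merge[1, ]], c("a", "b"))
  # permutation invariance of the dendrogram topology (cophenetic distances)
  set.seed(9)
  m3 <- matrix(rnorm(28), 7, 4, dimnames = list(letters[1:7], NULL))
  perm <- sample(7)
  d1 <- as.matrix(stats::cophenetic(cluster_rows(m3)$hclust))
  d2 <- as.matrix(stats::cophenetic(cluster_rows(m3[perm, ])$hclust))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  # degenerate input
  expect_equal(cluster_rows(m3[1, , drop = FALSE])$order, 1)
  expect_true(grepl("^\\(", cluster_rows(m3)$newick))
})

test_that("subtraction heatmaps are exact elementwise differences", {
  a <- matrix(rnorm(12), 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_true(all(subtraction_heatmap(a, a) == 0))
  b <- a; b["b", "C"] <- b["b", "C"] - 2.5
  d <- subtraction_heatmap(a, b)
  expect_equal(d["b", "C"], 2.5)
  expect_equal(sum(d != 0), 1)
  set.seed(2)
  x <- matrix(rnorm(12), 3, 4, dimnames = dimnames(a))
  y <- matrix(rnorm(12), 3, 4, dimnames = dimnames(a))
  oracle <- x
  for (i in 1:3) for (j in 1:4) oracle[i, j] <- x[i, j] - y[i, j]
  expect_equal(subtraction_heatmap(x, y), oracle)
  expect_error(subtraction_heatmap(a, a[, 1:3]), "match")
})
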