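# Diversity and group-comparison statistics for region and infection
# contrasts.  All routines are implemented directly (base R arithmetic plus
# the standard distribution functions); stochastic routines take an explicit
# seed and record it in their result.

#' Alpha diversity of one sample
#'
#' Richness counts non-zero features; Shannon is -sum(p log p) with the
#' natural logarithm; Simpson is the Gini-Simpson index 1 - sum(p^2).
#'
#' @param x non-negative abundance vector, not all zero.
#' @param index one of `"richness"`, `"shannon"`, `"simpson"`.
#' @return Scalar diversity value.
#' @export
alpha_diversity <- function(x, index = c("richness", "shannon", "simpson")) {
  index <- match.arg(index)
  if (any(x < 0)) vp_stop("abundances must be non-negative")
  if (all(x == 0)) vp_stop("all-zero sample has no diversity")
  p <- x[x > 0] / sum(x)
  switch(index,
         richness = sum(x > 0),
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2))
}

#' Alpha diversity for every sample of a matrix
#' @param mat samples x features non-negative matrix.
#' @param indices subset of the three index names.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(mat,
                                  indices = c("richness", "shannon", "simpson")) {
  out <- data.frame(sample_id = rownames(mat), stringsAsFactors = FALSE)
  for (idx in indices) {
    out[[idx]] <- apply(mat, 1L, alpha_diversity, index = idx)
  }
  out
}

#' Bray-Curtis dissimilarity between two samples
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in \[0, 1\]: `sum(|x - y|) / sum(x + y)`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) vp_stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) vp_stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) vp_stop("both samples are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param mat samples x features non-negative matrix.
#' @return A symmetric `dist_matrix` (zero diagonal) with sample dimnames.
#' @export
bray_curtis_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(mat[i, ], mat[j, ])
    }
  }
  dist_matrix(d)
}

#' Distance matrix container
#' @param d symmetric non-negative matrix with zero diagonal.
#' @return Matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) vp_stop("distances must be square")
  if (max(abs(d - t(d))) > 1e-9) vp_stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) vp_stop("distance diagonal must be zero")
  if (any(d < 0)) vp_stop("distances must be non-negative")
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.
#' Axes are ordered by eigenvalue; only positive eigenvalues (above a
#' small tolerance) contribute coordinates, and negative eigenvalues are
#' excluded from the explained-variance denominator.
#'
#' @param d a [dist_matrix()].
#' @param n_axes number of axes requested.
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `explained_fraction` (per retained axis).
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  a <- -0.5 * unclass(d)^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  g <- (g + t(g)) / 2
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- which(eig$values > tol)
  if (length(pos) == 0L) {
    warning("all eigenvalues are zero: identical points")
    return(structure(list(
      coordinates = matrix(0, n, 0, dimnames = list(rownames(d), NULL)),
      eigenvalues = eig$values, explained_fraction = numeric(0)),
      class = "pcoa_result"))
  }
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive axes available", length(pos)))
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), n_axes)
  dimnames(coords) <- list(rownames(d), paste0("PCoA", seq_len(n_axes)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values,
    explained_fraction = eig$values[keep] / sum(eig$values[pos])),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes; explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}

permanova_ss <- function(d2, groups) {
  n <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' PERMANOVA (one-way, permutation test on a distance matrix)
#'
#' Partitions the squared distances into between- and within-group sums of
#' squares (SS_total = sum over pairs of d^2 / n; SS_within analogously per
#' group), forms the pseudo-F statistic
#' `(SS_between / (k - 1)) / (SS_within / (n - k))`, and obtains the p-value
#' by permuting the group labels with the `+1` convention:
#' `p = (1 + #permuted F >= observed F) / (1 + n_permutations)`.
#'
#' @param d a [dist_matrix()].
#' @param groups group label per sample (character or factor).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutation generator (required).
#' @return Object of class `permanova_result` with `r_squared`, `pseudo_F`,
#'   `p_value`, `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 1000, seed) {
  stopifnot(inherits(d, "dist_matrix"))
  if (missing(seed)) vp_stop("permanova requires an explicit seed")
  groups <- as.character(groups)
  n <- length(groups)
  if (n != nrow(d)) vp_stop("groups length must match distance matrix")
  k <- length(unique(groups))
  if (k < 2L) vp_stop("need at least two groups")
  if (k >= n) vp_stop("no residual degrees of freedom (k = n)")
  d2 <- unclass(d)^2
  obs <- permanova_ss(d2, groups)
  f_stat <- (obs["between"] / (k - 1)) / (obs["within"] / (n - k))
  r2 <- obs["between"] / obs["total"]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(groups)
    ss <- permanova_ss(d2, perm)
    f_b <- (ss["between"] / (k - 1)) / (ss["within"] / (n - k))
    if (f_b >= f_stat) exceed <- exceed + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(r_squared = unname(r2), pseudo_F = unname(f_stat),
                 p_value = (1 + exceed) / (1 + n_permutations),
                 df = c(between = k - 1L, within = n - k),
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations, seed %s)\n",
    x$r_squared, x$pseudo_F, x$p_value, x$n_permutations, format(x$seed)))
  invisible(x)
}

#' Pairwise PERMANOVA with BH-FDR across group pairs
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `r_squared`, `pseudo_F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 1000, seed) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    idx <- which(groups %in% c(g1, g2))
    res <- permanova(dist_matrix(unclass(d)[idx, idx]), groups[idx],
                     n_permutations, seed = seed + i)
    data.frame(group1 = g1, group2 = g2, r_squared = res$r_squared,
               pseudo_F = res$pseudo_F, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test.  In `"exact"` mode (automatic when the smaller
#' sample has at most 8 observations and there are no ties) the p-value is
#' obtained by complete enumeration of rank assignments; otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return Object of class `vp_test` with `statistic` (the Mann-Whitney U
#'   for `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) vp_stop("empty sample")
  combined <- c(x, y)
  r <- rank(combined)
  ties <- anyDuplicated(combined) > 0L
  w <- sum(r[seq_len(nx)])            # rank sum of x
  u <- w - nx * (nx + 1) / 2          # Mann-Whitney U
  if (mode == "exact" || (mode == "auto" && min(nx, ny) <= 8L && !ties)) {
    if (ties) vp_stop("exact mode is undefined with ties; use mode = 'normal'")
    # Exact null distribution of the x rank sum: count subsets of size nx
    # from ranks 1..n by their sum (dynamic programming over elements).
    n <- nx + ny
    max_sum <- sum(seq.int(n - nx + 1L, n))
    counts <- matrix(0, nx + 1L, max_sum + 1L)  # [k+1, s+1]
    counts[1L, 1L] <- 1
    for (elem in seq_len(n)) {
      kmax <- min(elem, nx)
      for (k in seq.int(kmax, 1L)) {
        s_idx <- seq.int(elem + 1L, max_sum + 1L)
        counts[k + 1L, s_idx] <- counts[k + 1L, s_idx] +
          counts[k, s_idx - elem]
      }
    }
    tail_counts <- counts[nx + 1L, ]
    total <- sum(tail_counts)
    p_le <- sum(tail_counts[seq_len(w + 1L)]) / total
    p_ge <- sum(tail_counts[seq.int(w + 1L, max_sum + 1L)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "wilcoxon exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "wilcoxon normal approximation"
  }
  structure(list(statistic = unname(u), p_value = p, effect_size = NULL,
                 method = method), class = "vp_test")
}

#' @export
print.vp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value,
              if (is.null(x$effect_size)) "" else
                sprintf(", effect size = %.3f", x$effect_size)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity; adjusted values never
#' fall below the raw p-value and are capped at 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) vp_stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq.int(m, 1L)))
  adj[order(ord)]
}

#' Fisher's method for combining p-values
#'
#' `X2 = -2 sum(log p)` referred to a chi-square distribution with `2k`
#' degrees of freedom.  Zero p-values are clamped to `floor` with a
#' warning.
#'
#' @param p p-values in (0, 1\].
#' @param floor clamp for zero p-values.
#' @return Object of class `vp_test` with the chi-square `statistic`,
#'   combined `p_value` and degrees of freedom in `method`.
#' @export
fishers_method <- function(p, floor = 1e-300) {
  if (any(p < 0 | p > 1)) vp_stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning(sprintf("zero p-value(s) clamped to %g", floor))
    p[p == 0] <- floor
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  structure(list(statistic = x2,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE),
                 effect_size = NULL,
                 method = sprintf("Fisher's method (df = %d)", df)),
            class = "vp_test")
}

#' Cohen's d
#'
#' Standardized mean difference with the pooled standard deviation
#' (`n_x + n_y - 2` denominator).
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return Scalar effect size (positive when `mean(x) > mean(y)`).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) vp_stop("need at least 2 observations per group")
  s2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (s2 == 0) {
    if (mean(x) == mean(y)) return(0)
    vp_stop("zero pooled variance with unequal means")
  }
  (mean(x) - mean(y)) / sqrt(s2)
}

#' Group comparison of a feature table
#'
#' Runs Wilcoxon rank-sum tests per feature for every pair of groups, with
#' BH-FDR adjustment across all tests, and reports the direction of change
#' and Cohen's d.
#'
#' @param mat samples x features matrix.
#' @param groups group label per sample.
#' @return data.frame with `feature`, `group1`, `group2`, `statistic`,
#'   `p_value`, `p_adjusted`, `cohens_d`, `direction` (sign of the
#'   group1 - group2 median difference).
#' @export
compare_groups <- function(mat, groups) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2L)
  rows <- list()
  for (feat in colnames(mat)) {
    for (i in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
      x <- mat[groups == g1, feat]; y <- mat[groups == g2, feat]
      tst <- wilcoxon_rank_sum(x, y)
      dval <- if (length(x) >= 2L && length(y) >= 2L &&
                  (stats::var(x) > 0 || stats::var(y) > 0)) {
        cohens_d(x, y)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, group1 = g1, group2 = g2,
        statistic = tst$statistic, p_value = tst$p_value,
        cohens_d = dval,
        direction = sign(stats::median(x) - stats::median(y)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out[, c("feature", "group1", "group2", "statistic", "p_value",
          "p_adjusted", "cohens_d", "direction")]
}
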