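# Compositional statistics: Bray-Curtis dissimilarity, within/between-group
# distance summaries, classical PCoA, and one-way permutation PERMANOVA on
# a distance matrix.

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `d(x, y) = 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, computed on
#' relative abundances. A pair of empty (all-zero) samples has an undefined
#' 0/0 dissimilarity; it is defined here as 0 with a warning.
#'
#' @param table an [abundance_table] (counts are converted per sample).
#' @return a [stats::dist] object labelled with sample IDs.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- to_relative(table)$values
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  tots <- rowSums(v)
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- tots[i] + tots[j]
      if (denom == 0) {
        if (!warned) {
          warning("Bray-Curtis between two empty samples is undefined; set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(v[i, ], v[j, ])) / denom
      }
    }
  }
  stats::as.dist(d)
}

#' Within- and between-arm distance distributions for one sample type
#'
#' Splits a distance matrix into three distributions for a sample type:
#' all unordered pairs within the PMA-free arm, all pairs within the
#' PMA-treated arm, and the distances between paired samples across arms
#' (matched on replicate and spike status).
#'
#' @param dm a [stats::dist] or symmetric matrix labelled with sample IDs.
#' @param meta sample metadata data.frame.
#' @param sample_type which type to summarise.
#' @return list with numeric vectors `within_free`, `within_pma`,
#'   `between`.
#' @export
group_distance_summary <- function(dm, meta, sample_type) {
  m <- as.matrix(dm)
  msub <- meta[meta$sample_type == sample_type &
                 meta$sample_id %in% rownames(m), , drop = FALSE]
  free <- msub[!msub$pma_treated, , drop = FALSE]
  pma <- msub[msub$pma_treated, , drop = FALSE]
  if (nrow(free) == 0 || nrow(pma) == 0)
    stop("sample type '", sample_type, "' needs both PMA arms")
  pairs_within <- function(ids) {
    if (length(ids) < 2) return(numeric(0))
    sub <- m[ids, ids, drop = FALSE]
    sub[lower.tri(sub)]
  }
  between <- numeric(0)
  for (i in seq_len(nrow(free))) {
    j <- which(pma$replicate == free$replicate[i] & pma$spiked == free$spiked[i])
    if (length(j) >= 1)
      between <- c(between, m[free$sample_id[i], pma$sample_id[j]])
  }
  list(within_free = unname(pairs_within(free$sample_id)),
       within_pma = unname(pairs_within(pma$sample_id)),
       between = unname(between))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates
#' `eigenvectors %*% diag(sqrt(eigenvalues))` on the positive-eigenvalue
#' axes. Negative eigenvalues (from non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the `proportion_explained`
#' denominator.
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @param n_axes number of axes to keep (default: all positive axes).
#' @return a `pcoa_ordination`: list with `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing) and `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = NULL) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2) stop("need at least two samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (length(pos) == 0) stop("no positive eigenvalues; degenerate distances")
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]),
                                                    length(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = ev[keep] / sum(ev[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("pcoa_ordination: %d samples, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- utils::head(x$proportion_explained, 3)
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * pe), collapse = ", "),
      if (length(x$proportion_explained) > 3) "..." else "", "\n")
  invisible(x)
}

#' @param x a `pcoa_ordination`.
#' @param axes which two axes to draw.
#' @param col point colours (e.g. by group).
#' @param ... passed to [graphics::plot()].
#' @rdname pcoa
#' @export
plot.pcoa_ordination <- function(x, axes = c(1, 2), col = 1, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) stop("fewer than two axes available")
  pe <- 100 * x$proportion_explained[axes]
  graphics::plot(co[, axes[1]], co[, axes[2]], col = col,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1], pe[1]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2], pe[2]), ...)
  invisible(x)
}

.permanova_stats <- function(d2, groups) {
  n <- length(groups)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(groups))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(r2 = ss_between / ss_total, f = f)
}

# all distinct two-group label assignments (for exact enumeration)
.two_group_assignments <- function(groups) {
  lv <- unique(groups)
  n <- length(groups)
  n1 <- sum(groups == lv[1])
  sets <- utils::combn(n, n1)
  lapply(seq_len(ncol(sets)), function(k) {
    g <- rep(lv[2], n)
    g[sets[, k]] <- lv[1]
    g
  })
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-way PERMANOVA: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within`
#' summed per group, pseudo-F = `(SS_between/(a-1)) / (SS_within/(n-a))`,
#' and `p = (1 + #{permuted F >= observed F}) / (1 + n_permutations)` under
#' random relabelling with a fixed seed. With `exact = TRUE` (two groups
#' only) all distinct label assignments are enumerated instead and
#' `p = #{F >= observed} / #assignments` (the observed assignment counts
#' itself).
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @param groups group label per sample (same order as the matrix).
#' @param n_permutations number of random permutations (>= 99).
#' @param seed integer seed making the p-value bit-reproducible.
#' @param factor_name label stored in the result.
#' @param exact enumerate all distinct assignments (two groups).
#' @return a `permanova_result`: list with `factor`, `r_squared`,
#'   `pseudo_f`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 9999, seed = 1,
                      factor_name = "group", exact = FALSE) {
  d <- as.matrix(dm)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("each group needs at least two samples")
  d2 <- d^2
  obs <- .permanova_stats(d2, groups)
  eps <- sqrt(.Machine$double.eps)
  if (exact) {
    if (length(tab) != 2) stop("exact enumeration implemented for two groups only")
    fs <- vapply(.two_group_assignments(groups),
                 function(g) .permanova_stats(d2, g)$f, numeric(1))
    p <- mean(fs >= obs$f - eps)
    n_perm <- length(fs)
  } else {
    if (n_permutations < 99) stop("n_permutations must be >= 99")
    set.seed(seed)
    count <- 0L
    for (k in seq_len(n_permutations)) {
      fp <- .permanova_stats(d2, sample(groups))$f
      if (fp >= obs$f - eps) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(factor = factor_name, r_squared = obs$r2, pseudo_f = obs$f,
                 p_value = p, n_permutations = n_perm, seed = seed,
                 exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA [%s]: R2 = %.3f (%.1f%% of variation), pseudo-F = %.3f, p = %.4g (%s%d permutations)\n",
    x$factor, x$r_squared, 100 * x$r_squared, x$pseudo_f, x$p_value,
    if (x$exact) "exact, " else "", x$n_permutations))
  invisible(x)
}

#' Marginal PERMANOVA over several metadata factors
#'
#' Runs a one-way [permanova()] per factor and adjusts the p-values across
#' factors by Benjamini-Hochberg FDR.
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @param meta sample metadata data.frame; rows are matched to the matrix
#'   labels via `sample_id`.
#' @param factors metadata column names to test.
#' @param n_permutations,seed passed to [permanova()].
#' @return data.frame with one row per factor: `factor`, `r_squared`,
#'   `pseudo_f`, `p_value`, `p_adjusted`.
#' @export
permanova_factors <- function(dm, meta, factors, n_permutations = 9999,
                              seed = 1) {
  m <- as.matrix(dm)
  idx <- match(rownames(m), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for sample(s): ",
                       paste(rownames(m)[is.na(idx)], collapse = ", "))
  msub <- meta[idx, , drop = FALSE]
  res <- lapply(factors, function(f) {
    r <- permanova(m, msub[[f]], n_permutations = n_permutations,
                   seed = seed, factor_name = f)
    data.frame(factor = f, r_squared = r$r_squared, pseudo_f = r$pseudo_f,
               p_value = r$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
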