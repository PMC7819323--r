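# Independent brute-force PERMANOVA: enumerates every two-group label
# assignment directly from the squared-distance sums, with no code shared
# with the package implementation.
oracle_permanova_exact <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- length(groups)
  stat <- function(g) {
    sst <- sum(d2[lower.tri(d2)]) / n
    ssw <- 0
    for (lv in unique(g)) {
      i <- which(g == lv)
      if (length(i) > 1) {
        s <- d2[i, i, drop = FALSE]
        ssw <- ssw + sum(s[lower.tri(s)]) / length(i)
      }
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- stat(groups)
  lv <- unique(groups)
  picks <- utils::combn(n, sum(groups == lv[1]))
  fs <- apply(picks, 2, function(ix) {
    g <- rep(lv[2], n)
    g[ix] <- lv[1]
    stat(g)
  })
  list(f = f_obs, p = mean(fs >= f_obs - sqrt(.Machine$double.eps)))
}
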