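test_that("Bray-Curtis matches hand arithmetic and vegan", {
  taxa <- c("a", "b", "c")
  tab <- rel_table_from(list(s1 = c(a = 0.5, b = 0.5),
                             s2 = c(a = 1),
                             s3 = c(c = 1),
                             s4 = c(a = 0.5, b = 0.5)), taxa)
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s1", "s4"], 0)       # identical rows
  expect_equal(d["s1", "s3"], 1)       # disjoint supports
  expect_equal(d["s1", "s2"], 0.5)     # 1 - 2*0.5/2
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rexp(60), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  m <- m / rowSums(m)
  tab2 <- abundance_table(m, mode = "relative")
  expect_equal(as.matrix(bray_curtis(tab2)),
               as.matrix(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a pair of empty samples gets dissimilarity 0 with a warning", {
  m <- rbind(s1 = c(a = 0, b = 0), s2 = c(a = 0, b = 0), s3 = c(a = 1, b = 0))
  tab <- abundance_table(m, mode = "relative")
  expect_warning(d <- bray_curtis(tab), "empty samples")
  expect_equal(as.matrix(d)["s1", "s2"], 0)
})

test_that("group distance summaries pair replicates across arms", {
  n <- 4
  meta <- paired_meta("screen", n)
  set.seed(8)
  m <- matrix(rexp(8 * 5), nrow = 8, dimnames = list(meta$sample_id, paste0("t", 1:5)))
  m <- m / rowSums(m)
  d <- bray_curtis(abundance_table(m, mode = "relative"))
  gs <- group_distance_summary(d, meta, "screen")
  expect_length(gs$within_free, choose(n, 2))  # 6
  expect_length(gs$within_pma, choose(n, 2))
  expect_length(gs$between, n)                 # replicate-matched pairs only

  # identical arms: between distances all zero
  m2 <- rbind(m[1:4, ], m[1:4, ])
  rownames(m2) <- meta$sample_id
  gs2 <- group_distance_summary(bray_curtis(abundance_table(m2, mode = "relative")),
                                meta, "screen")
  expect_true(all(gs2$between == 0))

  # single replicate per arm: no within pairs, one between pair
  meta1 <- paired_meta("solo", 1)
  m3 <- m[1:2, ]
  rownames(m3) <- meta1$sample_id
  gs3 <- group_distance_summary(bray_curtis(abundance_table(m3, mode = "relative")),
                                meta1, "solo")
  expect_length(gs3$within_free, 0)
  expect_length(gs3$between, 1)
})

test_that("classical PCoA reproduces simplex geometry and Euclidean input", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa(d3)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # Euclidean distances round-trip through the ordination
  set.seed(21)
  pts <- matrix(rnorm(7 * 3), nrow = 7)
  rownames(pts) <- paste0("s", 1:7)
  d <- as.matrix(dist(pts))
  ord2 <- pcoa(d)
  expect_equal(as.matrix(dist(ord2$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(ord2$proportion_explained), 1, tolerance = 1e-9)
  # axes ordered by eigenvalue
  expect_true(all(diff(ord2$eigenvalues) <= 1e-9))

  # agreement with base R classical scaling up to axis sign
  cs <- stats::cmdscale(d, k = 3)
  expect_equal(abs(ord2$coordinates[, 1:3]), abs(cs), tolerance = 1e-9,
               ignore_attr = TRUE)

  # duplicated sample lands on coincident coordinates
  d8 <- as.matrix(dist(pts[c(1:7, 1), ]))
  dimnames(d8) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord3 <- pcoa(d8)
  expect_equal(ord3$coordinates[1, ], ord3$coordinates[8, ], tolerance = 1e-9)
})

test_that("PERMANOVA matches vegan and its exact mode matches enumeration", {
  set.seed(33)
  groups <- rep(c("g1", "g2"), each = 3)
  m <- matrix(rexp(6 * 8), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  m[groups == "g2", 1:4] <- m[groups == "g2", 1:4] * 3
  m <- m / rowSums(m)
  d <- bray_curtis(abundance_table(m, mode = "relative"))

  res <- permanova(d, groups, n_permutations = 999, seed = 4)
  skip_if_not_installed("vegan")
  df <- data.frame(g = groups)
  ad <- vegan::adonis2(d ~ g, data = df, permutations = 999)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)

  # exact enumeration over all 6!/(3!3!) label splits equals brute force
  exact <- permanova(d, groups, exact = TRUE)
  oracle <- oracle_permanova_exact(d, groups)
  expect_equal(exact$pseudo_f, oracle$f, tolerance = 1e-12)
  expect_equal(exact$p_value, oracle$p)
  expect_equal(exact$n_permutations, choose(6, 3))
})

test_that("maximal separation yields R2 = 1 at the smallest attainable p", {
  ids <- paste0("s", 1:6)
  d <- matrix(1, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  groups <- rep(c("g1", "g2"), each = 3)
  res <- permanova(d, groups, exact = TRUE)
  expect_equal(res$r_squared, 1)
  # only the observed split and its mirror reach the observed statistic
  expect_equal(res$p_value, 2 / choose(6, 3))
})

test_that("PERMANOVA p-values are seed-reproducible and invariant to label names", {
  set.seed(99)
  m <- matrix(rexp(8 * 6), nrow = 8,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:6)))
  m <- m / rowSums(m)
  d <- bray_curtis(abundance_table(m, mode = "relative"))
  g <- rep(c("a", "b"), each = 4)
  r1 <- permanova(d, g, n_permutations = 199, seed = 7)
  r2 <- permanova(d, g, n_permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  g2 <- rep(c("first", "second"), each = 4)
  r3 <- permanova(d, g2, n_permutations = 199, seed = 7)
  expect_equal(r3$r_squared, r1$r_squared, tolerance = 1e-12)

  expect_error(permanova(d, rep("a", 8)), "two groups")
  expect_error(permanova(d, c(rep("a", 7), "b")), "at least two samples")
})

test_that("marginal multi-factor tests report BH-adjusted p-values", {
  meta <- rbind(paired_meta("screen", 3), paired_meta("soil", 3))
  set.seed(12)
  m <- matrix(rexp(12 * 10), nrow = 12,
              dimnames = list(meta$sample_id, paste0("t", 1:10)))
  m[meta$sample_type == "soil", 1:5] <- m[meta$sample_type == "soil", 1:5] * 5
  m <- m / rowSums(m)
  d <- bray_curtis(abundance_table(m, mode = "relative"))
  res <- permanova_factors(d, meta, c("sample_type", "pma_treated"),
                           n_permutations = 199, seed = 2)
  expect_identical(res$factor, c("sample_type", "pma_treated"))
  expect_equal(res$p_adjusted, stats::p.adjust(res$p_value, "BH"))
  expect_gt(res$r_squared[1], res$r_squared[2])
})
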