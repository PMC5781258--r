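test_that("rarefaction drops shallow samples and hits the exact depth", {
  counts <- cbind(s1 = c(20000, 5000), s2 = c(10000, 9000), s3 = c(6000, 4000))
  rownames(counts) <- c("OTU_0001", "OTU_0002")
  tab <- make_table(counts)
  expect_message(r <- rarefy(tab, depth = 19000, seed = 1), "dropping 1")
  expect_equal(ncol(r$counts), 2)
  expect_true(all(colSums(r$counts) == 19000))
  ## sample exactly at depth is untouched
  expect_identical(r$counts[, "s2"], counts[, "s2"])
  expect_error(rarefy(tab, depth = 1e6), "fewer than")
})

test_that("rarefaction matches the hypergeometric mean", {
  counts <- matrix(c(600, 300, 100), 3, 1,
                   dimnames = list(paste0("OTU_", 1:3), "s1"))
  tab <- make_table(counts)
  depth <- 200
  draws <- sapply(1:500, function(s) rarefy(tab, depth, seed = s)$counts[, 1])
  expected <- depth * counts[, 1] / sum(counts)   # E[hypergeometric]
  N <- sum(counts)
  se <- sqrt(depth * (counts[, 1] / N) * (1 - counts[, 1] / N) *
               (N - depth) / (N - 1) / 500)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se))
})

test_that("Shannon index matches hand-computed values and the filter rule", {
  expect_equal(shannon_index(rep(0.25, 4), min_frac = 0), log(4))
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.3, 0.2), min_frac = 0),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)))
  ## boundary: fraction equal to min_frac is dropped, remainder renormalized
  x <- c(9999, 1, 90000)   # OTU 2 at 1e-5 <= 1e-4 -> dropped
  expect_equal(shannon_index(x, min_frac = 1e-4),
               shannon_index(c(9999, 90000), min_frac = 0))
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Shannon is stable under deep rarefaction", {
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(n_otus = 40, seed = 500 + s,
                                       depth_range = c(20000, 60000)))
    r <- rarefy(sim$table, depth = 10000, seed = s)
    h_full <- shannon_table(sim$table)$H
    h_rare <- shannon_table(r)$H
    expect_lt(max(abs(h_full - h_rare)), 0.05)
  }
})

test_that("weighted UniFrac reproduces hand-computed branch sums", {
  ## two tips, both branch lengths 1, samples on opposite tips
  tree <- ape::read.tree(text = "(A:1,B:1);")
  counts <- cbind(s1 = c(10, 0), s2 = c(0, 10))
  rownames(counts) <- c("A", "B")
  tab <- make_table(counts)
  raw <- as.matrix(weighted_unifrac(tab, tree))
  expect_equal(raw["s1", "s2"], 2.0)
  norm <- as.matrix(weighted_unifrac(tab, tree, normalized = TRUE))
  expect_equal(norm["s1", "s2"], 1.0)
  ## identical samples at distance zero
  same <- make_table(cbind(s1 = c(5, 5), s2 = c(5, 5)) |>
                       (\(m) {rownames(m) <- c("A", "B"); m})())
  expect_equal(as.matrix(weighted_unifrac(same, tree))["s1", "s2"], 0)
  ## missing tip errors with the OTU named
  bad <- make_table(matrix(1:4, 2, dimnames = list(c("A", "X"), c("s1", "s2"))))
  expect_error(weighted_unifrac(bad, tree), "X")
})

test_that("weighted UniFrac equals the exhaustive per-branch oracle", {
  for (s in 1:50) {
    set.seed(s)
    n_tip <- sample(3:8, 1)
    tree <- simulate_tree(sprintf("OTU_%02d", seq_len(n_tip)), seed = s)
    counts <- matrix(rpois(n_tip * 4, 20) + 1, n_tip, 4,
                     dimnames = list(tree$tip.label, paste0("s", 1:4)))
    tab <- make_table(counts)
    for (normalized in c(FALSE, TRUE)) {
      got <- as.matrix(weighted_unifrac(tab, tree, normalized = normalized))
      want <- unifrac_oracle(counts, tree, normalized = normalized)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("weighted UniFrac agrees with phyloseq on a simulated community", {
  skip_if_not_installed("phyloseq")
  sim <- simulate_dataset(sim_config(n_otus = 25, seed = 13))
  got <- as.matrix(weighted_unifrac(sim$table, sim$tree, normalized = TRUE))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(sim$table$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(sim$tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_lt(max(abs(got - ref[rownames(got), colnames(got)])), 1e-10)
})

test_that("raw weighted UniFrac is symmetric and satisfies the triangle inequality", {
  sim <- simulate_dataset(sim_config(n_otus = 30, seed = 21))
  D <- as.matrix(weighted_unifrac(sim$table, sim$tree))
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  ## max over all triples (i, j, k) of d(i,j) - d(i,k) - d(k,j)
  violation <- max(sapply(seq_len(nrow(D)), function(k)
    max(D - outer(D[, k], D[k, ], "+"))))
  expect_lte(violation, 1e-12)
})

test_that("PCoA reproduces hand eigen-decompositions", {
  ## two samples at distance 2: one axis, coordinates +/-1, eigenvalue 2
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(stats::as.dist(d), n_axes = 1)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-1, 1))
  expect_equal(max(ord$eigenvalues), 2)
  ## three collinear points recover the line up to sign/translation
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  ord3 <- pcoa(stats::as.dist(d3), n_axes = 2)
  ax1 <- ord3$coordinates[, 1]
  expect_equal(unname(abs(diff(sort(ax1)))), c(1, 1))
  ## Euclidean distances of full-rank coordinates reproduce the input
  set.seed(2)
  pts <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  dm <- dist(pts)
  expect_warning(full <- pcoa(dm, n_axes = 5), "clipped")
  expect_equal(as.matrix(dist(full$coordinates)), as.matrix(dm), tolerance = 1e-8)
  ## degenerate all-zero matrix: all coordinates zero (cmdscale warns that
  ## no eigenvalue is positive)
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(suppressWarnings(pcoa(stats::as.dist(z), n_axes = 2))$coordinates == 0))
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  sim <- simulate_dataset(sim_config(n_otus = 30, seed = 31))
  dm <- weighted_unifrac(sim$table, sim$tree)
  grp <- setNames(sim$table$metadata$treatment, sim$table$metadata$sample)
  ours <- permanova(dm, grp, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dm ~ g, data = data.frame(g = grp[attr(dm, "Labels")]),
                        permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA detects separated clusters at the permutation floor", {
  ## groups big enough that no random permutation recreates the true split,
  ## so the observed F is strictly the permutation maximum
  set.seed(4)
  pts <- rbind(matrix(rnorm(32, 0, 0.05), 16), matrix(rnorm(32, 10, 0.05), 16))
  rownames(pts) <- paste0("s", 1:32)
  dm <- dist(pts)
  res <- permanova(dm, rep(c("a", "b"), each = 16), n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_error(permanova(dm, rep("a", 32)), "two groups")
})

test_that("PERMANOVA is invariant to relabeling samples within groups", {
  sim <- simulate_dataset(sim_config(n_otus = 25, seed = 8))
  dm <- weighted_unifrac(sim$table, sim$tree)
  grp <- setNames(sim$table$metadata$treatment, sim$table$metadata$sample)
  f1 <- permanova(dm, grp, n_perm = 9, seed = 1)$pseudo_F
  perm <- unlist(lapply(split(names(grp), grp), sample))  # shuffle within groups
  grp2 <- setNames(grp[perm], perm)
  f2 <- permanova(dm, grp2, n_perm = 9, seed = 1)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("within/between test is asymmetric and finds gross separation", {
  ## toy 2+2: hand-checkable asymmetry of the two within-sets
  pts <- rbind(a1 = 0, a2 = 0.2, b1 = 5, b2 = 9)
  dm <- dist(pts)
  ab <- within_between_test(dm, c("a1", "a2"), c("b1", "b2"), n_perm = 99, seed = 1)
  ba <- within_between_test(dm, c("b1", "b2"), c("a1", "a2"), n_perm = 99, seed = 1)
  expect_false(isTRUE(all.equal(ab$t_stat, ba$t_stat)))
  ## displaced group: all between-distances exceed within -> permutation floor
  ## (groups big enough that no permutation recreates the original assignment)
  set.seed(9)
  far <- rbind(matrix(rnorm(16, 0, 0.1), 8), matrix(rnorm(16, 50, 0.1), 8))
  rownames(far) <- paste0("s", 1:16)
  res <- within_between_test(dist(far), paste0("s", 1:8), paste0("s", 9:16),
                             n_perm = 999, seed = 2)
  ## the mirror assignment (swapping the two groups wholesale) is itself an
  ## extreme permutation, so the attainable floor is at most two ties in 999
  expect_lte(res$p_value, 2 / 1000)
  expect_error(within_between_test(dm, c("a1", "a2"), c("a2", "b1")), "disjoint")
})
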