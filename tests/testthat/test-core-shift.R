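test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  set.seed(1)
  for (i in 1:1000) {
    m <- sample(1:30, 1)
    p <- round(runif(m), 3)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) >= 0))   # step-up is monotone in p order
    expect_true(all(q >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical groups give t = 0, p = 1, not significant", {
  counts <- matrix(rep(c(10, 20, 30), 8), 3, 8,
                   dimnames = list(paste0("OTU_", 1:3), paste0("s", 1:8)))
  tab <- make_table(counts, treatments = rep(c("control", "copper"), each = 4))
  d <- differential_otus(tab, "copper")
  expect_true(all(d$p_raw == 1))
  expect_true(all(d$direction == 0))
  expect_false(any(d$significant))
})

test_that("vectorized Student t matches stats::t.test row by row", {
  set.seed(6)
  sim <- simulate_dataset(sim_config(n_otus = 25, seed = 6))
  d <- differential_otus(sim$table, "drought")
  R <- relative_abundance(sim$table)
  ctrl <- treatment_samples(sim$table, "control")
  drt <- treatment_samples(sim$table, "drought")
  for (i in sample(nrow(R), 5)) {
    ref <- t.test(R[i, drt], R[i, ctrl], var.equal = TRUE)
    row <- d[d$otu == rownames(R)[i], ]
    expect_equal(row$p_raw, ref$p.value, tolerance = 1e-12)
    expect_equal(row$mean_treatment - row$mean_control,
                 unname(diff(rev(ref$estimate))), tolerance = 1e-12)
  }
})

test_that("planted core OTUs are recovered with the right direction", {
  ## strong effect, 8 per group: each core OTU called with its true sign in
  ## the vast majority of seeds
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(n_otus = 30, n_core_up = 3, n_core_down = 3,
                                       effect_log2 = 2, seed = 7000 + s))
    d <- differential_otus(sim$table, "copper")
    up <- d[match(sim$truth$core_up, d$otu), ]
    dn <- d[match(sim$truth$core_down, d$otu), ]
    hits <- hits + sum(up$significant & up$direction == 1) +
      sum(dn$significant & dn$direction == -1)
    total <- total + nrow(up) + nrow(dn)
  }
  expect_gte(hits / total, 0.9)
})

test_that("cross-treatment consistency tally matches hand enumeration", {
  ## pattern per OTU across three treatments: A (+,+,+), B (+,.,+),
  ## C (+,.,-), D (.,.,+), E (.,.,.)
  mk <- function(sig, dir) {
    data.frame(otu = LETTERS[1:5], mean_control = 0.1, mean_treatment = 0.1,
               direction = dir, p_raw = ifelse(sig, 0.01, 0.9),
               q_bh = ifelse(sig, 0.05, 0.9), significant = sig,
               treatment = "x", stringsAsFactors = FALSE)
  }
  res <- list(
    copper  = mk(c(TRUE, TRUE, TRUE, FALSE, FALSE),  c(1, 1, 1, 0, 0)),
    drought = mk(c(TRUE, FALSE, FALSE, FALSE, FALSE), c(1, 0, 0, 0, 0)),
    shade   = mk(c(TRUE, TRUE, TRUE, TRUE, FALSE),   c(1, 1, -1, 1, 0)))
  cc <- core_consistency(res)
  expect_equal(cc$n_significant_any, 4)
  expect_equal(cc$n_multi_treatment, 3)
  expect_equal(cc$n_consistent_multi, 2)   # A and B; C flips sign
  expect_equal(cc$per_otu$consistent_direction[1:3], c(TRUE, TRUE, FALSE))
  expect_setequal(core_otus(cc), LETTERS[1:4])
  expect_setequal(core_otus(cc, min_treatments = 2), LETTERS[1:3])

  none <- lapply(res, function(r) { r$significant <- FALSE; r })
  cc0 <- core_consistency(none)
  expect_equal(cc0$n_significant_any + cc0$n_multi_treatment +
                 cc0$n_consistent_multi, 0)
  bad <- res
  bad$shade$otu[1] <- "Z"
  expect_error(core_consistency(bad), "OTU universe")
})

test_that("multi-treatment calls on synthetic data are direction-consistent", {
  consistent <- 0L; multi <- 0L
  for (s in 1:10) {
    sim <- simulate_dataset(sim_config(seed = 8000 + s))
    diff <- lapply(c("copper", "drought", "shade"), function(tr)
      differential_otus(sim$table, tr))
    names(diff) <- c("copper", "drought", "shade")
    cc <- core_consistency(diff)
    multi <- multi + cc$n_multi_treatment
    consistent <- consistent + cc$n_consistent_multi
  }
  expect_gte(consistent / multi, 0.95)
})

test_that("responsive summary sums abundance within sharedness classes", {
  ## 2 OTUs at 5% and 3% significant in all three treatments
  counts <- rbind(OTU_A = 50, OTU_B = 30, OTU_C = 920)
  counts <- counts[, rep(1, 16)]
  colnames(counts) <- paste0("s", 1:16)
  tab <- make_table(counts, treatments = rep(c("control", "copper", "drought", "shade"),
                                             each = 4))
  mk <- function(tr) data.frame(
    otu = c("OTU_A", "OTU_B", "OTU_C"), mean_control = 0.1, mean_treatment = 0.1,
    direction = c(1, 1, 0), p_raw = c(0.01, 0.01, 0.9), q_bh = c(0.05, 0.05, 0.9),
    significant = c(TRUE, TRUE, FALSE), treatment = tr, stringsAsFactors = FALSE)
  res <- list(copper = mk("copper"), drought = mk("drought"), shade = mk("shade"))
  cc <- core_consistency(res)
  s <- responsive_summary(cc, res, tab)
  three <- s[s$class == "3/3", ]
  expect_equal(three$abundance_pct, rep(8, 3))
  expect_equal(three$n_otus, rep(2L, 3))
  expect_true(all(s[s$class != "3/3", "n_otus"] == 0))
  ## partition: class counts sum to the treatment's significant total
  agg <- tapply(s$n_otus, s$treatment, sum)
  expect_true(all(agg == 2))
})

test_that("response-profile clustering separates blocks and ignores row order", {
  up <- matrix(2 + rnorm(30, 0, 0.05), 10, 3)
  dn <- matrix(-2 + rnorm(30, 0, 0.05), 10, 3)
  m <- rbind(up, dn)
  rownames(m) <- paste0("OTU_", 1:20)
  labs <- cluster_response_profiles(m, min_cluster = 3)
  expect_equal(length(unique(labs)), 2)
  expect_equal(length(unique(labs[1:10])), 1)
  expect_equal(length(unique(labs[11:20])), 1)
  ## permuted rows give the same partition up to label renaming
  set.seed(3)
  perm <- sample(20)
  labs2 <- cluster_response_profiles(m[perm, ], min_cluster = 3)[rownames(m)]
  expect_equal(length(unique(paste(labs, labs2))), length(unique(labs)))
  ## identical rows collapse to one cluster
  same <- matrix(1, 6, 3, dimnames = list(paste0("o", 1:6), NULL))
  expect_equal(unique(cluster_response_profiles(same)), 1L)
  expect_error(cluster_response_profiles(matrix(c(1, NA), 2, 1)), "finite")
})
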