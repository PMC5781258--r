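test_that("simulated tables honor the configured design", {
  cfg <- sim_config(n_otus = 50, samples_per_group = 8, seed = 5)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$table$counts), c(50, 32))
  depths <- colSums(sim$table$counts)
  expect_true(all(depths >= 19000 & depths <= 60000))
  expect_equal(unname(table(sim$table$metadata$treatment)[cfg$treatments]),
               rep(8L, 4), ignore_attr = TRUE)
  ## truth record: sets disjoint, ids exist
  ids <- rownames(sim$table$counts)
  planted <- c(sim$truth$core_up, sim$truth$core_down,
               unlist(lapply(sim$truth$specific, names)))
  expect_equal(anyDuplicated(planted), 0)
  expect_true(all(planted %in% ids))
  expect_true(all(unlist(sim$truth$corr_pairs[, 1:2]) %in% ids))
  ## tree covers the OTUs
  expect_setequal(sim$tree$tip.label, ids)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(sim_config(corr_strength = 1), "corr_strength")
  expect_error(sim_config(n_otus = 5, n_core_up = 3, n_core_down = 3,
                          n_specific_per_treatment = 0), "n_otus")
  expect_error(sim_config(depth_range = c(100, 50)), "depth_range")
  expect_error(sim_config(samples_per_group = 0), "samples_per_group")
})

test_that("planted basis correlation is recovered empirically at large n", {
  ## 600 samples from the basis model: the empirical correlation of a planted
  ## pair's latent log abundances sits within 0.1 of the configured strength
  cfg <- sim_config(n_otus = 30, samples_per_group = 150,
                    treatments = c("control", "copper", "drought", "shade"),
                    effect_log2 = 0, n_core_up = 0, n_core_down = 0,
                    n_specific_per_treatment = 0, n_corr_pairs = 2,
                    corr_strength = 0.7, depth_range = c(8000, 12000), seed = 9)
  sim <- simulate_dataset(cfg)
  for (k in 1:2) {
    pair <- sim$truth$corr_pairs[k, ]
    r <- cor(sim$basis[pair$otu_i, ], sim$basis[pair$otu_j, ])
    expect_lt(abs(r - 0.7), 0.1)
  }
  ## and the clr of the realized counts still reflects it, if attenuated
  z <- clr_transform(sim$table)
  pair <- sim$truth$corr_pairs[1, ]
  expect_gt(cor(z[pair$otu_i, ], z[pair$otu_j, ]), 0.4)
})

test_that("core-up OTUs exceed control in stress samples (sign test, 50 seeds)", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- sim_config(n_otus = 30, n_core_up = 2, n_core_down = 2,
                      n_specific_per_treatment = 1, effect_log2 = 1,
                      depth_range = c(5000, 8000), seed = 1000 + s)
    sim <- simulate_dataset(cfg)
    R <- relative_abundance(sim$table)
    stress <- sim$table$metadata$sample[sim$table$metadata$treatment != "control"]
    ctrl <- sim$table$metadata$sample[sim$table$metadata$treatment == "control"]
    up <- sim$truth$core_up[1]
    if (mean(R[up, stress]) > mean(R[up, ctrl])) hits <- hits + 1L
  }
  ## one-sided sign test: P(hits >= 40 | p = 0.5) < 1e-4, so 40/50 passes at 0.99
  expect_gte(hits, 40)
})

test_that("null simulation yields false-positive rate near the raw threshold", {
  ## no planted effects: the differential caller's raw-p rate should match
  ## its nominal threshold within binomial tolerance (200 replicates pooled)
  n_sig <- 0L; n_tot <- 0L
  for (s in 1:200) {
    cfg <- sim_config(n_otus = 20, samples_per_group = 6,
                      treatments = c("control", "copper"),
                      effect_log2 = 0, n_core_up = 0, n_core_down = 0,
                      n_specific_per_treatment = 0, n_corr_pairs = 0,
                      depth_range = c(2000, 3000), seed = 3000 + s)
    sim <- simulate_dataset(cfg)
    d <- differential_otus(sim$table, "copper", fdr_alpha = 1)  # raw p only
    n_sig <- n_sig + sum(d$p_raw < 0.05)
    n_tot <- n_tot + nrow(d)
  }
  rate <- n_sig / n_tot
  se <- sqrt(0.05 * 0.95 / n_tot)
  ## tests within a replicate are correlated through the composition, so
  ## allow 5 nominal-binomial standard errors around 0.05
  expect_lt(abs(rate - 0.05), 5 * se + 0.01)
})

test_that("trees are rooted, bifurcating, with positive branch lengths", {
  tr <- simulate_tree(sprintf("OTU_%02d", 1:2), seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)
  for (n in c(5, 11)) {
    tr <- simulate_tree(sprintf("OTU_%02d", seq_len(n)), seed = n)
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.binary(tr))
    expect_equal(tr$Nnode, n - 1)   # rooted bifurcating: n - 1 internal nodes
    expect_true(all(tr$edge.length > 0))
  }
  expect_error(simulate_tree("OTU_1"), "at least 2")
  expect_identical(ape::write.tree(simulate_tree(letters[1:6], seed = 2)),
                   ape::write.tree(simulate_tree(letters[1:6], seed = 2)))
})

test_that("linked omics features track the planted slope and sign", {
  sim <- simulate_dataset(sim_config(n_otus = 25, seed = 4))
  links <- data.frame(feature = c(1, 2), otu = rownames(sim$table$counts)[1:2],
                      slope = c(1, -2))
  noiseless <- simulate_linked_omics(sim$table, n_features = 5, links = links,
                                     noise_sd = 0, seed = 8)
  z <- clr_transform(sim$table)
  expect_equal(cor(noiseless$features[1, ], z[links$otu[1], ]), 1.0)
  noisy <- simulate_linked_omics(sim$table, n_features = 5, links = links,
                                 noise_sd = 0.1, seed = 8)
  expect_lt(cor(noisy$features[2, ], z[links$otu[2], ]), 0)
  expect_error(simulate_linked_omics(sim$table, 5,
                                     data.frame(feature = 1, otu = "nope", slope = 1)),
               "unknown OTU")
})

test_that("simulation artifacts round-trip through their on-disk formats", {
  sim <- simulate_dataset(sim_config(n_otus = 25, seed = 33))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("otu_table.tsv", "metadata.tsv", "tree.nwk", "truth.json"))
  back <- read_otu_table(file.path(dir, "otu_table.tsv"),
                         metadata = file.path(dir, "metadata.tsv"))
  expect_identical(back$counts, sim$table$counts)
  expect_identical(back$metadata$treatment, sim$table$metadata$treatment)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, rownames(sim$table$counts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$core_up, sim$truth$core_up)
  expect_equal(truth$corr_pairs$rho_true, sim$truth$corr_pairs$rho_true)
})
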