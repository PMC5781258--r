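## Synthetic community generator.
##
## The generator emulates the study design the analysis assumes: four
## treatments (control + three stresses) with eight plants each, library
## depths at or above the 19,000-read rarefaction depth, a "core" set of OTUs
## shifted in the SAME direction in every stress treatment, treatment-specific
## OTUs shifted in exactly one, planted inter-OTU basis correlations, and
## omics features linearly linked to chosen OTUs.  Latent ("basis")
## abundances are log-normal with effects applied on the log scale BEFORE
## closure, and reads are drawn multinomially per sample — the standard
## compositional benchmark, matching the assumptions SparCC is framed on.

TAXONOMY_POOL <- c(
  "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhizobiales; g__Bradyrhizobium",
  "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Burkholderiales; g__Burkholderia",
  "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Xanthomonadales; g__Dyella",
  "k__Bacteria; p__Proteobacteria; c__Deltaproteobacteria; o__Myxococcales; g__U",
  "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; g__Aeromicrobium",
  "k__Bacteria; p__Bacteroidetes; c__Cytophagia; o__Cytophagales; g__Spirosoma",
  "k__Bacteria; p__Bacteroidetes; c__Sphingobacteriia; o__Sphingobacteriales; g__Niabella",
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; g__Paenibacillus",
  "k__Bacteria; p__Verrucomicrobia; c__Verrucomicrobiae; o__Verrucomicrobiales; g__Luteolibacter",
  "k__Bacteria; p__Acidobacteria; c__Acidobacteriia; o__Acidobacteriales; g__U"
)

#' Configuration for the synthetic community generator
#'
#' Defaults mirror the emulated study design: eight plants per treatment,
#' four treatments (control plus copper, drought and shade), library depths
#' from the 19,000-read rarefaction floor up to 60,000 reads, a balanced core
#' of up- and down-shifted OTUs present in all three stresses, and a few
#' treatment-specific responders.
#'
#' @param n_otus number of OTUs.
#' @param samples_per_group plants per treatment (default 8).
#' @param treatments ordered treatment labels; the first is the control.
#' @param depth_range inclusive bounds for per-sample library size, drawn
#'   uniformly per sample so rarefaction is exercised.
#' @param n_core_up,n_core_down OTUs shifted up/down in ALL stress treatments.
#' @param n_specific_per_treatment OTUs shifted in exactly one stress treatment.
#' @param effect_log2 planted log2 fold-change magnitude on basis abundances.
#' @param n_corr_pairs number of planted correlated basis pairs.
#' @param corr_strength basis correlation of each planted pair, in (-1, 1).
#' @param basis_log_mean_sd spread (natural-log scale) of per-OTU mean basis
#'   abundances; sets how uneven the community is.
#' @param basis_log_sd per-sample log-normal noise sd around each OTU's mean.
#' @param seed root integer seed; all draws descend from named substreams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_otus = 50, samples_per_group = 8,
                       treatments = c("control", "copper", "drought", "shade"),
                       depth_range = c(19000, 60000),
                       n_core_up = 5, n_core_down = 5,
                       n_specific_per_treatment = 3,
                       effect_log2 = 1.5, n_corr_pairs = 3, corr_strength = 0.7,
                       basis_log_mean_sd = 1.5, basis_log_sd = 0.5,
                       seed = 1) {
  cfg <- list(n_otus = n_otus, samples_per_group = samples_per_group,
              treatments = treatments, depth_range = depth_range,
              n_core_up = n_core_up, n_core_down = n_core_down,
              n_specific_per_treatment = n_specific_per_treatment,
              effect_log2 = effect_log2, n_corr_pairs = n_corr_pairs,
              corr_strength = corr_strength,
              basis_log_mean_sd = basis_log_mean_sd, basis_log_sd = basis_log_sd,
              seed = seed)
  pos <- c("n_otus", "samples_per_group", "basis_log_mean_sd", "basis_log_sd")
  for (f in pos) if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
    stop("sim_config: `", f, "` must be a positive number")
  nonneg <- c("n_core_up", "n_core_down", "n_specific_per_treatment",
              "n_corr_pairs", "effect_log2")
  for (f in nonneg) if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
    stop("sim_config: `", f, "` must be non-negative")
  if (length(treatments) < 2 || anyDuplicated(treatments))
    stop("sim_config: `treatments` must be >=2 unique labels")
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] || depth_range[1] < 1)
    stop("sim_config: `depth_range` must be an increasing pair of positive bounds")
  if (abs(corr_strength) >= 1)
    stop("sim_config: `corr_strength` must be strictly inside (-1, 1)")
  n_stress <- length(treatments) - 1
  if (n_core_up + n_core_down + n_stress * n_specific_per_treatment > n_otus)
    stop("sim_config: `n_otus` too small for the requested effect sets")
  if (n_core_up + n_core_down + n_stress * n_specific_per_treatment +
        2 * n_corr_pairs > n_otus)
    stop("sim_config: `n_corr_pairs` needs ", 2 * n_corr_pairs,
         " OTUs outside the effect sets; increase `n_otus`")
  structure(cfg, class = "sim_config")
}

#' Simulate an OTU table, tree and ground-truth record
#'
#' Draws per-OTU mean log basis abundances, embeds the planted pairwise
#' correlations in a block-diagonal correlation matrix, applies the planted
#' log2 effects to treatment groups, exponentiates to basis abundances,
#' closes to per-sample composition and draws multinomial reads at a
#' per-sample uniform depth. The returned truth record lists every planted
#' effect for parameter-recovery testing.
#'
#' @param config a [sim_config].
#' @return List with elements `table` ([otu_table]), `tree` ([ape::phylo]),
#'   `truth` (class `synthetic_truth`), and `basis` (the latent log basis
#'   abundance matrix, OTUs x samples, kept so generator properties can be
#'   verified directly).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  D <- config$n_otus
  m <- config$samples_per_group
  treatments <- config$treatments
  control <- treatments[1]
  stresses <- treatments[-1]
  otu_ids <- sprintf("OTU_%04d", seq_len(D))

  ## -- planted effect sets (disjoint) and correlated pairs ------------------
  set.seed(derive_seed(config$seed, "assign"))
  n_spec_total <- length(stresses) * config$n_specific_per_treatment
  picked <- sample(otu_ids, config$n_core_up + config$n_core_down + n_spec_total)
  core_up <- picked[seq_len(config$n_core_up)]
  core_down <- picked[config$n_core_up + seq_len(config$n_core_down)]
  spec_pool <- picked[config$n_core_up + config$n_core_down + seq_len(n_spec_total)]
  specific <- list()
  for (k in seq_along(stresses)) {
    ids <- spec_pool[(k - 1) * config$n_specific_per_treatment +
                       seq_len(config$n_specific_per_treatment)]
    dirs <- if (length(ids)) sample(c(-1, 1), length(ids), replace = TRUE) else numeric(0)
    specific[[stresses[k]]] <- setNames(dirs, ids)
  }
  free <- setdiff(otu_ids, picked)
  corr_pairs <- NULL
  if (config$n_corr_pairs > 0) {
    if (length(free) < 2 * config$n_corr_pairs)
      stop("sim_config: `n_corr_pairs` too large for the unplanted OTU pool")
    pair_ids <- sample(free, 2 * config$n_corr_pairs)
    corr_pairs <- data.frame(
      otu_i = pair_ids[seq(1, length(pair_ids), by = 2)],
      otu_j = pair_ids[seq(2, length(pair_ids), by = 2)],
      rho_true = config$corr_strength, stringsAsFactors = FALSE)
  }

  ## -- basis log-abundance model -------------------------------------------
  set.seed(derive_seed(config$seed, "basis_means"))
  mu <- rnorm(D, 0, config$basis_log_mean_sd)
  names(mu) <- otu_ids
  Sigma <- diag(D)
  dimnames(Sigma) <- list(otu_ids, otu_ids)
  if (!is.null(corr_pairs)) for (r in seq_len(nrow(corr_pairs))) {
    i <- corr_pairs$otu_i[r]; j <- corr_pairs$otu_j[r]
    Sigma[i, j] <- Sigma[j, i] <- config$corr_strength
  }
  Sigma <- Sigma * config$basis_log_sd^2

  eff <- log(2) * config$effect_log2
  delta <- matrix(0, D, length(treatments), dimnames = list(otu_ids, treatments))
  delta[core_up, stresses] <- eff
  delta[core_down, stresses] <- -eff
  for (tr in stresses) {
    s <- specific[[tr]]
    if (length(s)) delta[names(s), tr] <- delta[names(s), tr] + s * eff
  }

  sample_ids <- as.vector(vapply(treatments, function(tr)
    sprintf("%s_%02d", tr, seq_len(m)), character(m)))
  sample_treat <- rep(treatments, each = m)

  logA <- matrix(NA_real_, D, length(sample_ids), dimnames = list(otu_ids, sample_ids))
  for (tr in treatments) {
    set.seed(derive_seed(config$seed, "lognormal", tr))
    draw <- MASS::mvrnorm(m, mu = mu + delta[, tr], Sigma = Sigma)
    logA[, sample_treat == tr] <- t(draw)
  }

  ## -- multinomial read sampling at heterogeneous depth ---------------------
  set.seed(derive_seed(config$seed, "depths"))
  depths <- sample(seq(config$depth_range[1], config$depth_range[2]),
                   length(sample_ids), replace = TRUE)
  counts <- matrix(0, D, length(sample_ids), dimnames = list(otu_ids, sample_ids))
  for (s in seq_along(sample_ids)) {
    set.seed(derive_seed(config$seed, "multinomial", sample_ids[s]))
    p <- exp(logA[, s] - max(logA[, s]))
    counts[, s] <- rmultinom(1, depths[s], p / sum(p))
  }

  taxonomy <- setNames(rep_len(TAXONOMY_POOL, D), otu_ids)
  metadata <- data.frame(sample = sample_ids, treatment = sample_treat,
                         compartment = "root", stringsAsFactors = FALSE)
  table <- otu_table(counts, taxonomy = taxonomy, metadata = metadata)
  tree <- simulate_tree(otu_ids, seed = derive_seed(config$seed, "tree"))

  truth <- structure(list(core_up = core_up, core_down = core_down,
                          specific = specific, corr_pairs = corr_pairs,
                          omics_links = NULL, effect_log2 = config$effect_log2,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(table = table, tree = tree, truth = truth, basis = logA)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:\n")
  cat(sprintf("  core up: %d, core down: %d\n", length(x$core_up), length(x$core_down)))
  cat(sprintf("  treatment-specific: %s\n",
              paste(sprintf("%s (%d)", names(x$specific),
                            lengths(x$specific)), collapse = ", ")))
  cat(sprintf("  correlated pairs: %d\n",
              if (is.null(x$corr_pairs)) 0L else nrow(x$corr_pairs)))
  invisible(x)
}

#' Simulate a rooted bifurcating tree over OTU ids
#'
#' Random topology with exponential branch lengths; tips are the given ids.
#'
#' @param otu_ids at least two unique tip labels.
#' @param seed integer seed.
#' @return An [ape::phylo] rooted binary tree.
#' @export
simulate_tree <- function(otu_ids, seed = 1) {
  if (length(otu_ids) < 2) stop("need at least 2 OTU ids for a tree")
  if (anyDuplicated(otu_ids)) stop("OTU ids must be unique")
  set.seed(derive_seed(seed, "topology"))
  tree <- ape::rtree(length(otu_ids), rooted = TRUE, br = rexp)
  tree$tip.label <- otu_ids[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

#' Simulate omics features linearly linked to OTUs
#'
#' Each linked feature is `slope * clr(OTU) + N(0, noise_sd)` where `clr` is
#' the centered log-ratio of the OTU's relative abundance (0.5 pseudocount);
#' unlinked features are pure standard normal noise.
#'
#' @param table an [otu_table] supplying the OTU abundances.
#' @param n_features number of feature rows to generate.
#' @param links data.frame with columns `feature`, `otu`, `slope`; `feature`
#'   indices must lie in `1:n_features` and `otu` ids must exist in `table`.
#' @param noise_sd Gaussian noise sd added to linked features.
#' @param seed integer seed.
#' @return List with `features` (matrix, features x samples) and `links`
#'   (the realized link truth with feature ids).
#' @export
simulate_linked_omics <- function(table, n_features, links = NULL,
                                  noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(table, "cs_otu_table"))
  feat_ids <- sprintf("feat_%03d", seq_len(n_features))
  samples <- colnames(table$counts)
  if (!is.null(links)) {
    bad <- setdiff(links$otu, rownames(table$counts))
    if (length(bad)) stop("unknown OTU ids in links: ", paste(bad, collapse = ", "))
    if (any(links$feature < 1 | links$feature > n_features))
      stop("link feature indices must lie in 1..n_features")
  }
  Z <- clr_transform(table)
  set.seed(derive_seed(seed, "omics_noise"))
  X <- matrix(rnorm(n_features * length(samples)), n_features,
              dimnames = list(feat_ids, samples))
  truth <- NULL
  if (!is.null(links)) {
    for (r in seq_len(nrow(links))) {
      f <- links$feature[r]
      X[f, ] <- links$slope[r] * Z[links$otu[r], ] +
        if (noise_sd > 0) rnorm(length(samples), 0, noise_sd) else 0
    }
    truth <- data.frame(feature = feat_ids[links$feature], otu = links$otu,
                        slope = links$slope, stringsAsFactors = FALSE)
  }
  list(features = X, links = truth)
}

#' Centered log-ratio transform of an OTU table
#'
#' @param table an [otu_table].
#' @param pseudocount added to counts before closure (default 0.5).
#' @return Matrix of clr values, OTUs x samples.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "cs_otu_table"))
  a <- table$counts + pseudocount
  f <- sweep(a, 2, colSums(a), "/")
  lf <- log(f)
  sweep(lf, 2, colMeans(lf), "-")
}

#' Write all artifacts of a simulated dataset to a directory
#'
#' Emits the OTU-table TSV, metadata TSV, newick tree and a JSON truth record.
#'
#' @param sim result of [simulate_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_otu_table(sim$table, file.path(dir, "otu_table.tsv")),
    write_metadata(sim$table$metadata, file.path(dir, "metadata.tsv")),
    write_newick(sim$tree, file.path(dir, "tree.nwk")))
  truth <- sim$truth
  truth$corr_pairs <- if (!is.null(truth$corr_pairs)) truth$corr_pairs
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, file.path(dir, "truth.json")))
}
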