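#' Run the full stress-microbiome pipeline on an OTU table
#'
#' Chains the whole analysis: organelle filtering, rarefaction, filtered
#' Shannon diversity, weighted UniFrac with PCoA, PERMANOVA plus all pairwise
#' within/between permutation tests, per-treatment differential OTU calling
#' with cross-treatment direction-consistency tallies and the
#' sharedness-class abundance summary, response-profile clustering, the
#' Gaussian naive Bayes leave-one-out classification, per-treatment SparCC
#' networks with hub extraction and merging, and (optionally) OTU-omics
#' correlation links. All artifacts are written as TSV under `out_dir`.
#'
#' @param table an [otu_table] with metadata and taxonomy.
#' @param tree rooted [ape::phylo] over the OTUs.
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param control control treatment label (default `"control"`).
#' @param depth rarefaction depth (default 19000).
#' @param min_frac Shannon low-abundance filter (default 1e-4).
#' @param p_thresh,fdr_alpha differential-calling thresholds (0.05, 0.10).
#' @param min_prevalence prevalence filter for classifier and networks (0.80).
#' @param n_perm permutations for PERMANOVA and pairwise tests (default 999).
#' @param sparcc_inner,sparcc_boot SparCC iterations and bootstrap resamples
#'   (defaults 20 and 100).
#' @param edge_p,top_k,hub_top_n network thresholds (0.1, 10000, 20).
#' @param omics optional features x samples matrix to link against core OTUs.
#' @param seed integer root seed.
#' @return List of class `coreshift_pipeline` with every intermediate result.
#' @export
run_pipeline <- function(table, tree, out_dir = NULL, control = "control",
                         depth = 19000, min_frac = 1e-4,
                         p_thresh = 0.05, fdr_alpha = 0.10,
                         min_prevalence = 0.80, n_perm = 999,
                         sparcc_inner = 20, sparcc_boot = 100,
                         edge_p = 0.1, top_k = 10000, hub_top_n = 20,
                         omics = NULL, seed = 1) {
  stopifnot(inherits(table, "cs_otu_table"))
  if (is.null(table$metadata)) stop("pipeline needs sample metadata")
  treatments <- unique(table$metadata$treatment)
  stresses <- setdiff(treatments, control)
  if (!control %in% treatments) stop("control label '", control, "' not in metadata")

  if (!is.null(table$taxonomy)) table <- filter_organelle_otus(table)
  rare <- rarefy(table, depth = depth, seed = derive_seed(seed, "rarefy"))

  shannon <- shannon_table(rare, min_frac = min_frac)
  dm <- weighted_unifrac(rare, tree)
  ord <- pcoa(dm, n_axes = 2)
  perm <- permanova(dm, setNames(rare$metadata$treatment, rare$metadata$sample),
                    n_perm = n_perm, seed = derive_seed(seed, "permanova"))
  pairwise <- pairwise_within_between(dm, rare$metadata, n_perm = n_perm,
                                      seed = derive_seed(seed, "pairwise"))

  diff <- lapply(stresses, function(tr)
    differential_otus(rare, tr, control = control,
                      p_thresh = p_thresh, fdr_alpha = fdr_alpha))
  names(diff) <- stresses
  consistency <- core_consistency(diff)
  summary_tab <- responsive_summary(consistency, diff, rare)
  core <- core_otus(consistency)
  clusters <- if (length(core) >= 2)
    cluster_response_profiles(log_ratio_matrix(diff, core)) else NULL

  features <- prevalence_filter(rare, min_prevalence = min_prevalence)
  loo <- loo_evaluate(features, rare$metadata$treatment, control_label = control)

  networks <- list()
  subnets <- list()
  for (tr in treatments) {
    sub <- subset_otu_table(rare, samples = treatment_samples(rare, tr))
    prev <- rowMeans(sub$counts > 0)
    sub <- subset_otu_table(sub, otus = rownames(sub$counts)[prev >= min_prevalence])
    fit <- sparcc_correlations(sub, n_inner = sparcc_inner,
                               seed = derive_seed(seed, "sparcc", tr))
    fit <- sparcc_pvalues(sub, fit, n_boot = sparcc_boot,
                          seed = derive_seed(seed, "sparcc_boot", tr))
    edges <- select_edges(fit, p_thresh = edge_p, top_k = top_k)
    networks[[tr]] <- list(fit = fit, edges = edges)
    subnets[[tr]] <- hub_subnetwork(build_network(edges, taxonomy = rare$taxonomy,
                                                  treatment = tr),
                                    top_n = hub_top_n)
  }
  merged <- merge_subnetworks(subnets)
  core_comp <- if (sum(merged$membership$class == "core") > 0)
    taxonomy_composition(merged$membership$otu[merged$membership$class == "core"],
                         rare$taxonomy) else NULL

  links <- if (!is.null(omics) && length(core))
    otu_omics_links(rare, omics, otus = core, p_thresh = p_thresh) else NULL

  res <- structure(list(
    table = rare, shannon = shannon, unifrac = dm, pcoa = ord,
    permanova = perm, pairwise = pairwise,
    differential = diff, consistency = consistency,
    responsive_summary = summary_tab, core_otus = core, clusters = clusters,
    classifier = loo, networks = networks, merged = merged,
    core_taxonomy = core_comp, omics_links = links, seed = seed),
    class = "coreshift_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.coreshift_pipeline <- function(x, ...) {
  cat("core stress microbiome pipeline\n")
  cat(sprintf("  %d OTUs x %d samples after rarefaction\n",
              nrow(x$table$counts), ncol(x$table$counts)))
  cat(sprintf("  PERMANOVA (treatment): pseudo-F = %.3g, P = %.3g\n",
              x$permanova$pseudo_F, x$permanova$p_value))
  cat(sprintf("  stress-responsive OTUs (>=1 treatment): %d; multi-treatment: %d; direction-consistent: %d\n",
              x$consistency$n_significant_any, x$consistency$n_multi_treatment,
              x$consistency$n_consistent_multi))
  cat(sprintf("  classifier LOO accuracy: %.2f (stress-vs-control %.2f)\n",
              x$classifier$accuracy, x$classifier$collapsed_accuracy))
  cat(sprintf("  merged network: %d OTUs, core subnetwork: %d\n",
              nrow(x$merged$membership),
              sum(x$merged$membership$class == "core")))
  invisible(x)
}

## write every pipeline artifact as TSV
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) write.table(df, file.path(out_dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  write_otu_table(res$table, file.path(out_dir, "otu_table_rarefied.tsv"))
  write_metadata(res$table$metadata, file.path(out_dir, "metadata.tsv"))
  wt(res$shannon, "shannon.tsv")
  write_distance_matrix(res$unifrac, file.path(out_dir, "weighted_unifrac.tsv"))
  wt(cbind(sample = rownames(res$pcoa$coordinates),
           as.data.frame(res$pcoa$coordinates)), "pcoa.tsv")
  wt(data.frame(test = "PERMANOVA", pseudo_F = res$permanova$pseudo_F,
                p_value = res$permanova$p_value, n_perm = res$permanova$n_perm),
     "permanova.tsv")
  wt(res$pairwise, "pairwise_within_between.tsv")
  wt(do.call(rbind, res$differential), "differential_otus.tsv")
  wt(res$consistency$per_otu, "core_consistency.tsv")
  wt(res$responsive_summary, "responsive_summary.tsv")
  writeLines(res$core_otus, file.path(out_dir, "core_otus.txt"))
  if (!is.null(res$clusters))
    wt(data.frame(otu = names(res$clusters), cluster = res$clusters),
       "response_clusters.tsv")
  wt(res$classifier$predictions, "classifier_loo.tsv")
  for (tr in names(res$networks))
    write_edge_list(res$networks[[tr]]$edges,
                    file.path(out_dir, sprintf("edges_%s.tsv", tr)))
  wt(res$merged$membership, "network_membership.tsv")
  wt(res$merged$edges, "merged_edges.tsv")
  if (!is.null(res$core_taxonomy))
    wt(data.frame(taxon = names(res$core_taxonomy),
                  fraction = as.numeric(res$core_taxonomy)),
       "core_taxonomy.tsv")
  if (!is.null(res$omics_links)) wt(res$omics_links, "omics_links.tsv")
  invisible(out_dir)
}
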