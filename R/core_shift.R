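#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to
#' input order (delegated to [stats::p.adjust]).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

## vectorized equal-variance (Student) two-sample t-test over matrix rows
row_student_t <- function(X, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, idx2, drop = FALSE])
  v1 <- apply(X[, idx1, drop = FALSE], 1, var)
  v2 <- apply(X[, idx2, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(t), df)
  ## degenerate rows: zero pooled variance
  flat <- se == 0
  t[flat] <- 0
  p[flat & (m1 == m2)] <- 1
  p[flat & (m1 != m2)] <- 0   # perfectly separated constant groups
  t[flat & (m1 != m2)] <- sign(m1 - m2)[flat & (m1 != m2)] * Inf
  list(t = t, p = p, mean1 = m1, mean2 = m2)
}

#' Call stress-responsive OTUs for one treatment
#'
#' Per OTU, an equal-variance two-sample Student t-test on per-sample
#' relative abundances (treatment vs control), Benjamini-Hochberg adjustment
#' across all tested OTUs within the treatment, and a dual significance rule:
#' raw `p < p_thresh` AND BH `q <= fdr_alpha`. Direction is the sign of the
#' mean difference.
#'
#' @param table an [otu_table] (rarefied) with metadata.
#' @param treatment,control treatment labels to compare.
#' @param p_thresh raw p-value threshold (default 0.05).
#' @param fdr_alpha BH q-value ceiling (default 0.10).
#' @return data.frame of class `otu_diff` with one row per OTU: `otu`,
#'   `mean_control`, `mean_treatment`, `direction`, `p_raw`, `q_bh`,
#'   `significant`, `treatment`.
#' @export
differential_otus <- function(table, treatment, control = "control",
                              p_thresh = 0.05, fdr_alpha = 0.10) {
  stopifnot(inherits(table, "cs_otu_table"))
  R <- relative_abundance(table)
  idx_t <- which(colnames(R) %in% treatment_samples(table, treatment))
  idx_c <- which(colnames(R) %in% treatment_samples(table, control))
  if (length(idx_t) < 2 || length(idx_c) < 2)
    stop("both groups need at least 2 samples")
  tt <- row_student_t(R, idx_t, idx_c)
  q <- bh_fdr(tt$p)
  direction <- sign(tt$mean1 - tt$mean2)
  direction[tt$p == 1 & tt$t == 0] <- 0
  res <- data.frame(otu = rownames(R), mean_control = tt$mean2,
                    mean_treatment = tt$mean1, direction = direction,
                    p_raw = tt$p, q_bh = q,
                    significant = tt$p < p_thresh & q <= fdr_alpha,
                    treatment = treatment,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("otu_diff", "data.frame")
  res
}

#' Cross-treatment consistency of stress-responsive OTUs
#'
#' Tallies, per OTU, the number of stress treatments in which it was called
#' significant and whether all of those calls share one direction — the
#' defining property of a "core stress" OTU.
#'
#' @param results named list of [differential_otus] results, one per stress
#'   treatment, over the same OTU universe.
#' @return Object of class `core_stress`: per-OTU data.frame (`otu`,
#'   `n_significant_treatments`, `consistent_direction`, per-treatment
#'   direction columns) plus the headline totals `n_significant_any`,
#'   `n_multi_treatment`, `n_consistent_multi`.
#' @export
core_consistency <- function(results) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("`results` must be a named list (one entry per stress treatment)")
  otus <- results[[1]]$otu
  for (r in results) if (!identical(sort(r$otu), sort(otus)))
    stop("differential results do not share one OTU universe")
  sig <- sapply(results, function(r) r$significant[match(otus, r$otu)])
  dirs <- sapply(results, function(r) r$direction[match(otus, r$otu)])
  n_sig <- rowSums(sig)
  consistent <- vapply(seq_along(otus), function(i) {
    d <- dirs[i, sig[i, ]]
    length(d) > 0 && (all(d > 0) || all(d < 0))
  }, logical(1))
  per_otu <- data.frame(otu = otus, n_significant_treatments = n_sig,
                        consistent_direction = consistent,
                        stringsAsFactors = FALSE, row.names = NULL)
  dir_cols <- as.data.frame(dirs * sig)   # 0 where not significant
  names(dir_cols) <- paste0("dir_", names(results))
  per_otu <- cbind(per_otu, dir_cols)
  structure(list(per_otu = per_otu,
                 n_treatments = length(results),
                 n_significant_any = sum(n_sig >= 1),
                 n_multi_treatment = sum(n_sig > 1),
                 n_consistent_multi = sum(n_sig > 1 & consistent)),
            class = "core_stress")
}

#' @export
print.core_stress <- function(x, ...) {
  cat("core stress OTU tally:\n")
  cat(sprintf("  significant in >=1 of %d stress treatments: %d\n",
              x$n_treatments, x$n_significant_any))
  cat(sprintf("  significant in  >1 treatment: %d\n", x$n_multi_treatment))
  cat(sprintf("  direction-consistent among those: %d\n", x$n_consistent_multi))
  invisible(x)
}

#' Core stress OTU ids
#'
#' @param consistency a [core_consistency] result.
#' @param min_treatments minimum number of treatments with a significant call
#'   (default 1: "significant in at least one treatment").
#' @return Character vector of OTU ids.
#' @export
core_otus <- function(consistency, min_treatments = 1) {
  stopifnot(inherits(consistency, "core_stress"))
  p <- consistency$per_otu
  p$otu[p$n_significant_treatments >= min_treatments]
}

#' Responsive-OTU abundance summary by sharedness class
#'
#' For each stress treatment, OTUs significant in exactly k of the stress
#' treatments (with that treatment among them) are grouped into class
#' `k/total`; the summary reports the group's summed mean relative abundance
#' in that treatment's samples (as % of the community) and the group size.
#'
#' @param consistency a [core_consistency] result.
#' @param results the list of [differential_otus] results it was built from.
#' @param table the (rarefied) [otu_table].
#' @return data.frame with `treatment`, `class` (e.g. `"3/3"`),
#'   `abundance_pct`, `n_otus`.
#' @export
responsive_summary <- function(consistency, results, table) {
  stopifnot(inherits(consistency, "core_stress"), inherits(table, "cs_otu_table"))
  R <- relative_abundance(table)
  total <- consistency$n_treatments
  per <- consistency$per_otu
  out <- list()
  for (tr in names(results)) {
    sig_here <- results[[tr]]$otu[results[[tr]]$significant]
    cols <- colnames(R) %in% treatment_samples(table, tr)
    for (k in seq(total, 1)) {
      grp <- intersect(sig_here, per$otu[per$n_significant_treatments == k])
      ab <- if (length(grp))
        100 * sum(rowMeans(R[grp, cols, drop = FALSE])) else 0
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, class = sprintf("%d/%d", k, total),
        abundance_pct = ab, n_otus = length(grp), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Log2 response-profile matrix of significant OTUs
#'
#' `log2((mean_treatment + eps) / (mean_control + eps))` per OTU and stress
#' treatment, with `eps` = half the smallest nonzero mean relative abundance
#' (guards zeros without dominating real signal).
#'
#' @param results named list of [differential_otus] results.
#' @param otus OTU ids to include (default: all significant in >= 1 treatment).
#' @return Matrix OTUs x treatments of log2 ratios.
#' @export
log_ratio_matrix <- function(results, otus = NULL) {
  if (is.null(otus)) {
    sig <- unique(unlist(lapply(results, function(r) r$otu[r$significant])))
    otus <- sig
  }
  if (!length(otus)) stop("no OTUs to profile")
  means <- unlist(lapply(results, function(r) c(r$mean_control, r$mean_treatment)))
  eps <- min(means[means > 0]) / 2
  out <- sapply(results, function(r) {
    i <- match(otus, r$otu)
    log2((r$mean_treatment[i] + eps) / (r$mean_control[i] + eps))
  })
  rownames(out) <- otus
  out
}

#' Cluster OTU response profiles
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' response profiles. The cut height is scanned over the gaps between
#' successive merge heights: among cuts whose clusters all keep at least
#' `min_cluster` members, the one at the widest height gap is taken (a
#' height-scan stand-in for dynamic tree cutting). Degenerate trees with no
#' positive gap, or fewer rows than `min_cluster`, collapse to one cluster.
#'
#' @param profiles numeric matrix, OTUs x treatments (e.g. [log_ratio_matrix]).
#' @param min_cluster minimum cluster size (default 3).
#' @return Named integer vector of cluster labels.
#' @export
cluster_response_profiles <- function(profiles, min_cluster = 3) {
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  n <- nrow(profiles)
  one <- setNames(rep(1L, n), rownames(profiles))
  if (n < 2 * min_cluster) return(one)
  hc <- hclust(dist(profiles), method = "average")
  h <- hc$height                       # ascending merge heights
  gaps <- diff(h)                      # cutting inside gap i gives n - i clusters
  best <- one
  best_gap <- 0
  for (i in seq_along(gaps)) {
    if (gaps[i] <= best_gap) next
    labs <- cutree(hc, k = n - i)
    if (min(table(labs)) >= min_cluster) {
      best <- labs
      best_gap <- gaps[i]
    }
  }
  best
}
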