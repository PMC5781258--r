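#' Rarefy an OTU table to even depth
#'
#' Samples with fewer total reads than `depth` are dropped (with a message);
#' every surviving sample is subsampled uniformly without replacement to
#' exactly `depth` reads. Each sample uses its own substream seed derived
#' from the root seed, so single columns can be reproduced in isolation.
#'
#' @param table an [otu_table].
#' @param depth target reads per sample (the study design rarefies to 19,000).
#' @param seed integer seed.
#' @return The rarefied [otu_table]; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = 19000, seed = 1) {
  stopifnot(inherits(table, "cs_otu_table"))
  if (depth <= 0) stop("`depth` must be positive")
  tot <- colSums(table$counts)
  drop <- colnames(table$counts)[tot < depth]
  if (length(drop) == ncol(table$counts))
    stop("all samples have fewer than ", depth, " reads")
  if (length(drop))
    message("dropping ", length(drop), " sample(s) below depth ", depth, ": ",
            paste(drop, collapse = ", "))
  keep <- setdiff(colnames(table$counts), drop)
  out <- table$counts[, keep, drop = FALSE]
  for (s in keep) {
    if (sum(out[, s]) == depth) next
    set.seed(derive_seed(seed, "rarefy", s))
    reads <- sample(rep.int(seq_len(nrow(out)), out[, s]), depth)
    out[, s] <- tabulate(reads, nbins = nrow(out))
  }
  md <- table$metadata
  if (!is.null(md)) md <- md[md$sample %in% keep, , drop = FALSE]
  otu_table(out, taxonomy = table$taxonomy, metadata = md)
}

#' Shannon diversity with a low-abundance filter
#'
#' OTUs at relative abundance `<= min_frac` are dropped before the index is
#' computed (the remaining fractions are renormalized), reducing noise from
#' low-abundance taxa. `H = -sum(p_i * ln p_i)` with the natural log.
#'
#' @param abundances non-negative vector of counts or relative abundances for
#'   one sample.
#' @param min_frac retain OTUs with fraction strictly above this (default
#'   `1e-4`, i.e. > 0.01%).
#' @return Shannon index H (>= 0).
#' @export
shannon_index <- function(abundances, min_frac = 1e-4) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  tot <- sum(abundances)
  if (tot == 0) stop("all-zero abundance vector")
  p <- abundances / tot
  p <- p[p > min_frac]
  if (!length(p)) stop("no OTUs above min_frac = ", min_frac)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of an OTU table
#'
#' @param table an [otu_table].
#' @inheritParams shannon_index
#' @return data.frame with `sample`, `treatment` (if metadata present), `H`.
#' @export
shannon_table <- function(table, min_frac = 1e-4) {
  stopifnot(inherits(table, "cs_otu_table"))
  H <- apply(table$counts, 2, shannon_index, min_frac = min_frac)
  out <- data.frame(sample = colnames(table$counts), H = unname(H),
                    stringsAsFactors = FALSE)
  if (!is.null(table$metadata))
    out$treatment <- table$metadata$treatment[match(out$sample, table$metadata$sample)]
  out
}

#' Weighted UniFrac distances between samples
#'
#' For each branch of the rooted tree, each sample's read fraction descending
#' through the branch is accumulated; the raw distance between samples A and
#' B is `sum_b len_b * |p_A(b) - p_B(b)|`. The normalized variant divides by
#' `sum_b len_b * (p_A(b) + p_B(b))`, bounding distances by 1. The raw
#' (unnormalized) variant is the default.
#'
#' @param table an [otu_table]; columns are converted to relative abundance
#'   internally.
#' @param tree a rooted [ape::phylo] whose tips cover every OTU with nonzero
#'   counts.
#' @param normalized if `TRUE` return the normalized variant.
#' @return A [stats::dist] over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  stopifnot(inherits(table, "cs_otu_table"), inherits(tree, "phylo"))
  present <- rownames(table$counts)[rowSums(table$counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "))
  R <- relative_abundance(table)
  n <- ncol(R)
  n_node <- max(tree$edge)
  ## accumulate, per node, the fraction of each sample's reads at descendant tips
  F <- matrix(0, n_node, n)
  idx <- match(tree$tip.label, rownames(R))
  has <- !is.na(idx)
  F[seq_along(tree$tip.label)[has], ] <- R[idx[has], , drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    F[po$edge[e, 1], ] <- F[po$edge[e, 1], ] + F[po$edge[e, 2], ]
  }
  len <- po$edge.length
  B <- F[po$edge[, 2], , drop = FALSE] * len   # branch-weighted fractions
  d <- dist(t(B), method = "manhattan")
  if (normalized) {
    s <- colSums(B)
    denom <- as.dist(outer(s, s, "+"))
    d <- d / denom
    d[denom == 0] <- 0
  }
  attr(d, "Labels") <- colnames(R)
  attr(d, "method") <- if (normalized) "weighted UniFrac (normalized)" else "weighted UniFrac"
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling of the double-centered squared-distance matrix via
#' [stats::cmdscale]. Axes are ordered by eigenvalue; axes with negative
#' eigenvalues are reported but excluded from the coordinates.
#'
#' @param dm a [stats::dist] or square symmetric matrix.
#' @param n_axes number of axes to return (clipped to n - 1 with a warning).
#' @return List of class `pcoa_ordination`: `coordinates` (samples x axes,
#'   column-centered), `eigenvalues` (all, nonincreasing), and
#'   `prop_explained` over the positive eigenvalues.
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  if (n_axes > n - 1) {
    warning("n_axes clipped to ", n - 1)
    n_axes <- n - 1
  }
  fit <- cmdscale(dm, k = n_axes, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  k <- min(n_axes, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  if (k < n_axes)   # degenerate input: pad with zero axes so shape is stable
    coords <- cbind(coords, matrix(0, n, n_axes - k))
  rownames(coords) <- attr(dm, "Labels")
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig,
                 prop_explained = if (pos) eig[seq_len(k)] / sum(eig[eig > 0]) else rep(0, n_axes),
                 n_negative = sum(fit$eig < 0)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes", nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$prop_explained))
    cat(sprintf(" (axis 1: %.1f%% explained)", 100 * x$prop_explained[1]))
  cat("\n")
  if (x$n_negative) cat(x$n_negative, "negative eigenvalues excluded\n")
  invisible(x)
}

## distance-based SS partition shared by permanova(); labels as integer codes
pseudo_f <- function(D2, codes, n_groups) {
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in seq_len(n_groups)) {
    idx <- which(codes == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (n_groups - 1)) / (ss_within / (n - n_groups))
}

#' PERMANOVA (one-way Adonis) on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and tests the pseudo-F statistic by random
#' permutation of sample labels. P-values use the add-one convention, so the
#' smallest achievable value is `1/(n_perm + 1)`.
#'
#' @param dm a [stats::dist] or square symmetric matrix over samples.
#' @param labels group label per sample, in `dm` label order (or named by
#'   sample id).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return List of class `permanova`: `pseudo_F`, `p_value`, `df`, `n_perm`.
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = 1) {
  D2 <- as.matrix(dm)^2
  n <- nrow(D2)
  if (!is.null(names(labels)) && !is.null(rownames(D2)))
    labels <- labels[rownames(D2)]
  if (length(labels) != n) stop("`labels` must cover every sample in `dm`")
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least two groups")
  if (any(table(f) < 2)) stop("every group needs at least two samples")
  codes <- as.integer(f)
  F_obs <- pseudo_f(D2, codes, nlevels(f))
  set.seed(derive_seed(seed, "permanova"))
  F_perm <- vapply(seq_len(n_perm), function(i)
    pseudo_f(D2, sample(codes), nlevels(f)), numeric(1))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  structure(list(pseudo_F = F_obs, p_value = p,
                 df = c(between = nlevels(f) - 1L, within = n - nlevels(f)),
                 n_perm = n_perm),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), P = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_perm))
  invisible(x)
}

#' Within- vs between-group distance permutation test
#'
#' Compares the distances *within* `group_a` against the distances *between*
#' `group_a` and `group_b` with a two-sample (equal-variance) t statistic;
#' significance by Monte Carlo permutation of the sample-to-group assignment
#' within the union, two-sided on |t|. The test is asymmetric: swapping the
#' arguments compares the within-`group_b` distances instead, giving the
#' second value of each pairwise comparison.
#'
#' @param dm a [stats::dist] or square matrix over samples.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param n_perm Monte Carlo permutations (default 999).
#' @param seed integer seed.
#' @return List of class `within_between`: `t_stat`, `p_value`, `n_perm`.
#' @export
within_between_test <- function(dm, group_a, group_b, n_perm = 999, seed = 1) {
  D <- as.matrix(dm)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two samples")
  bad <- setdiff(c(group_a, group_b), rownames(D))
  if (length(bad)) stop("samples absent from dm: ", paste(bad, collapse = ", "))

  tstat <- function(a, b) {
    wi <- D[a, a][upper.tri(diag(length(a)))]
    bw <- as.vector(D[a, b])
    n1 <- length(wi); n2 <- length(bw)
    ## a group of 2 contributes a single within-distance: its (n-1)-weighted
    ## variance term is 0, not NA
    v1 <- if (n1 > 1) var(wi) else 0
    v2 <- if (n2 > 1) var(bw) else 0
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) return(0)
    (mean(wi) - mean(bw)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t_obs <- tstat(group_a, group_b)
  pool <- c(group_a, group_b)
  na <- length(group_a)
  set.seed(derive_seed(seed, "within_between"))
  t_perm <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(pool)
    tstat(perm[seq_len(na)], perm[-seq_len(na)])
  }, numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm)
  structure(list(t_stat = t_obs, p_value = p, n_perm = n_perm),
            class = "within_between")
}

#' @export
print.within_between <- function(x, ...) {
  cat(sprintf("within/between test: t = %.4g, P = %.4g (%d permutations)\n",
              x$t_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' All pairwise within/between tests for a treatment design
#'
#' Runs [within_between_test] for every ordered pair of treatments, matching
#' the two values reported per cell of a pairwise-comparison table: within
#' the first treatment vs between, then within the second vs between.
#'
#' @param dm distance matrix over samples.
#' @param metadata data.frame with `sample` and `treatment`.
#' @inheritParams within_between_test
#' @return data.frame with columns `treatment_a`, `treatment_b`, `t_stat`, `p_value`.
#' @export
pairwise_within_between <- function(dm, metadata, n_perm = 999, seed = 1) {
  treatments <- unique(metadata$treatment)
  grp <- split(metadata$sample, metadata$treatment)
  out <- list()
  for (i in seq_along(treatments)) for (j in seq_along(treatments)) {
    if (i == j) next
    a <- treatments[i]; b <- treatments[j]
    r <- within_between_test(dm, grp[[a]], grp[[b]], n_perm = n_perm,
                             seed = derive_seed(seed, "pair", a, b))
    out[[length(out) + 1L]] <- data.frame(treatment_a = a, treatment_b = b,
                                          t_stat = r$t_stat, p_value = r$p_value,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
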