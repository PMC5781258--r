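## SparCC-style basis correlation estimation for compositional OTU counts.
##
## Sequencing counts carry only relative information, so Pearson correlations
## on fractions are spurious.  The estimator works on log-ratio variances
## t_ij = Var(log f_i / f_j), which are invariant to the closure, and assumes
## the underlying ("basis") correlation matrix is sparse.  Under sparsity,
## basis variances omega satisfy the linear system
##     M %*% omega = rowSums(T),  M = (D-1) on the diagonal, 1 off-diagonal,
## and the basis correlation follows from
##     rho_ij = (omega_i + omega_j - t_ij) / (2 * sqrt(omega_i * omega_j)).
## Strongly correlated pairs violate the sparsity assumption, so the single
## strongest pair above a threshold is iteratively excluded from the system
## (its t_ij dropped from the row sums, both diagonal entries decremented)
## and the variances re-solved.  Sampling noise in the fractions is averaged
## out by repeating the whole procedure over posterior draws of the
## compositions (Dirichlet with add-one concentration) and averaging the
## correlation matrices.

## one inner estimate from a fraction matrix (OTUs x samples)
##
## Excluding a strong pair (i, j) removes t_ij from both row sums; since
## E[t_ij] carries one omega_i and one omega_j, the system update zeroes
## M[i, j] and M[j, i] and decrements both diagonals — dropping only the
## diagonals would leave phantom omega_j mass in row i and inflate the
## solved variances.
sparcc_from_fractions <- function(fr, exclusion_thresh, max_exclusions) {
  D <- nrow(fr)
  lf <- log(fr)
  V <- apply(lf, 1, var)
  C <- cov(t(lf))
  T_mat <- outer(V, V, "+") - 2 * C          # t_ij = Var(log f_i/f_j)
  diag(T_mat) <- 0
  excl <- matrix(FALSE, D, D)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  clip_count <- 0L
  exclusion_log <- list()
  rho <- NULL
  repeat {
    omega <- tryCatch(solve(M, rowSums(T_mat * !excl)),
                      error = function(e) NULL)
    if (is.null(omega)) break                # singular system: keep last rho
    bad <- omega <= 0
    omega[bad] <- NA_real_
    rho <- (outer(omega, omega, "+") - T_mat) / (2 * sqrt(outer(omega, omega)))
    if (any(bad))
      warning(sum(bad), " OTU(s) with nonpositive solved basis variance; ",
              "their correlations are undefined")
    clip_count <- clip_count + sum(abs(rho) > 1, na.rm = TRUE) / 2
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (length(exclusion_log) >= max_exclusions) break
    cand <- abs(rho)
    cand[excl | row(cand) == col(cand)] <- NA
    strongest <- suppressWarnings(max(cand, na.rm = TRUE))
    if (!is.finite(strongest) || strongest <= exclusion_thresh) break
    at <- which(cand == strongest, arr.ind = TRUE)[1, ]   # deterministic first hit
    i <- at[1]; j <- at[2]
    if (M[i, i] <= 1 || M[j, j] <= 1) break  # exclusion would exhaust an OTU
    excl[i, j] <- excl[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    exclusion_log[[length(exclusion_log) + 1L]] <- c(i, j)
  }
  if (is.null(rho)) {
    rho <- matrix(NA_real_, D, D)
    diag(rho) <- 1
  }
  list(rho = rho, clip_count = clip_count, exclusions = exclusion_log)
}

## Dirichlet posterior fraction draw, seeded per OTU (keyed by OTU id) so the
## estimator is exactly equivariant under OTU reordering
draw_fractions <- function(counts, seed, iter) {
  g <- counts
  for (i in seq_len(nrow(counts))) {
    set.seed(derive_seed(seed, "dirichlet", iter, rownames(counts)[i]))
    g[i, ] <- rgamma(ncol(counts), shape = counts[i, ] + 1)
  }
  sweep(g, 2, colSums(g), "/")
}

#' SparCC basis correlations for an OTU table
#'
#' Estimates the correlation matrix of latent basis abundances from
#' compositional counts (see the algorithm sketch in the package vignette).
#' Each of `n_inner` iterations resamples per-sample compositions from a
#' Dirichlet posterior with add-one concentration, runs the log-ratio
#' variance estimator with iterative strong-pair exclusion, and the final
#' correlation is the element-wise mean. `deterministic = TRUE` replaces the
#' posterior draws by the posterior mean (one iteration, bit-reproducible
#' without a seed).
#'
#' @param table an [otu_table] (or counts matrix), ideally prevalence-filtered
#'   upstream; needs >= 4 OTUs and >= 4 samples.
#' @param n_inner posterior-resampling iterations averaged (default 20).
#' @param exclusion_thresh |rho| above which the strongest pair is excluded
#'   from the sparsity system (default 0.1).
#' @param max_exclusions cap on excluded pairs per iteration (default 10).
#' @param seed integer seed.
#' @param deterministic use posterior-mean fractions in a single pass.
#' @return Object of class `sparcc`: `rho` (symmetric, unit diagonal, clipped
#'   to `[-1, 1]`), `n_inner`, `clip_count`, `exclusion_log`, `pvals` (NULL
#'   until [sparcc_pvalues] fills it), and the call parameters.
#' @export
sparcc_correlations <- function(table, n_inner = 20, exclusion_thresh = 0.1,
                                max_exclusions = 10, seed = 1,
                                deterministic = FALSE) {
  counts <- if (inherits(table, "cs_otu_table")) table$counts else as.matrix(table)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  if (nrow(counts) < 4) stop("SparCC needs at least 4 OTUs")
  if (ncol(counts) < 4) stop("SparCC needs at least 4 samples")
  ## canonical OTU-id order internally: together with id-keyed substreams
  ## this makes the estimate independent of the input row order
  input_ids <- rownames(counts)
  counts <- counts[sort(input_ids), , drop = FALSE]
  D <- nrow(counts)
  if (deterministic) n_inner <- 1L
  rho_sum <- matrix(0, D, D)
  rho_n <- matrix(0L, D, D)
  clip_count <- 0L
  exclusion_log <- vector("list", n_inner)
  for (k in seq_len(n_inner)) {
    fr <- if (deterministic) {
      sweep(counts + 1, 2, colSums(counts + 1), "/")
    } else draw_fractions(counts, seed, k)
    est <- sparcc_from_fractions(fr, exclusion_thresh, max_exclusions)
    ok <- !is.na(est$rho)
    rho_sum[ok] <- rho_sum[ok] + est$rho[ok]
    rho_n <- rho_n + ok
    clip_count <- clip_count + est$clip_count
    exclusion_log[[k]] <- est$exclusions
  }
  rho <- rho_sum / rho_n
  rho[rho_n == 0] <- NA_real_
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  rho <- rho[input_ids, input_ids]
  structure(list(rho = rho, pvals = NULL, n_inner = n_inner,
                 clip_count = clip_count, exclusion_log = exclusion_log,
                 exclusion_thresh = exclusion_thresh,
                 max_exclusions = max_exclusions, seed = seed,
                 deterministic = deterministic),
            class = "sparcc")
}

#' @export
print.sparcc <- function(x, ...) {
  D <- nrow(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("SparCC: %d OTUs, %d inner iteration(s)\n", D, x$n_inner))
  cat(sprintf("  |rho| range: %.3f-%.3f; clipped values: %d\n",
              min(abs(off), na.rm = TRUE), max(abs(off), na.rm = TRUE),
              as.integer(x$clip_count)))
  if (!is.null(x$pvals))
    cat(sprintf("  pseudo-p-values present (floor %.4g)\n", min(x$pvals)))
  invisible(x)
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' Each of `n_boot` null datasets permutes every OTU's counts across samples
#' independently (destroying inter-OTU association while preserving
#' marginals); the full estimator is re-run and a two-sided pseudo-p-value
#' `p_ij = (1 + #{|rho_null| >= |rho_obs|}) / (1 + n_boot)` is attached, so
#' the smallest achievable value is `1/(n_boot + 1)`.
#'
#' @param table the [otu_table] (or counts matrix) `result` was computed on.
#' @param result a [sparcc_correlations] result.
#' @param n_boot number of resampled null datasets (default 100).
#' @param seed integer seed.
#' @return `result` with its `pvals` matrix filled in.
#' @export
sparcc_pvalues <- function(table, result, n_boot = 100, seed = 1) {
  stopifnot(inherits(result, "sparcc"))
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  counts <- if (inherits(table, "cs_otu_table")) table$counts else as.matrix(table)
  if (is.null(rownames(counts))) rownames(counts) <- rownames(result$rho)
  abs_obs <- abs(result$rho)
  exceed <- matrix(0L, nrow(counts), nrow(counts))
  n_def <- matrix(0L, nrow(counts), nrow(counts))
  for (b in seq_len(n_boot)) {
    null_counts <- counts
    for (i in seq_len(nrow(counts))) {
      set.seed(derive_seed(seed, "boot_perm", b, rownames(counts)[i]))
      null_counts[i, ] <- counts[i, sample(ncol(counts))]
    }
    null_fit <- sparcc_correlations(
      null_counts, n_inner = result$n_inner,
      exclusion_thresh = result$exclusion_thresh,
      max_exclusions = result$max_exclusions,
      seed = derive_seed(seed, "boot_fit", b),
      deterministic = result$deterministic)
    cmp <- abs(null_fit$rho) >= abs_obs
    ok <- !is.na(cmp)
    exceed[ok] <- exceed[ok] + cmp[ok]
    n_def <- n_def + ok
  }
  ## pairs whose null estimate was degenerate in some resamples use the
  ## resamples that were defined; a pair with no defined resample gets p = 1
  p <- (1 + exceed) / (1 + n_def)
  p[n_def == 0] <- 1
  diag(p) <- 1
  dimnames(p) <- dimnames(result$rho)
  result$pvals <- p
  result$n_boot <- n_boot
  result
}

#' Select significant network edges from a SparCC result
#'
#' Keeps OTU pairs with pseudo-p below `p_thresh`, ranks them by descending
#' correlation score and truncates to the strongest `top_k`. Ranking is by
#' the signed coefficient by default; `ranking = "absolute"` ranks by |rho|.
#' Boundary ties break lexicographically by OTU-id pair.
#'
#' @param result a [sparcc_pvalues]-completed `sparcc` object.
#' @param p_thresh pseudo-p cutoff (default 0.1).
#' @param top_k maximum edges retained (default 10000).
#' @param ranking `"signed"` or `"absolute"`.
#' @return data.frame with `otu_a`, `otu_b` (`otu_a < otu_b`), `rho`, `p`.
#' @export
select_edges <- function(result, p_thresh = 0.1, top_k = 10000,
                         ranking = c("signed", "absolute")) {
  stopifnot(inherits(result, "sparcc"))
  ranking <- match.arg(ranking)
  if (is.null(result$pvals)) stop("run sparcc_pvalues() first")
  ids <- rownames(result$rho)
  ut <- which(upper.tri(result$rho), arr.ind = TRUE)
  edges <- data.frame(otu_a = ids[ut[, 1]], otu_b = ids[ut[, 2]],
                      rho = result$rho[ut], p = result$pvals[ut],
                      stringsAsFactors = FALSE)
  swap <- edges$otu_a > edges$otu_b
  tmp <- edges$otu_a[swap]; edges$otu_a[swap] <- edges$otu_b[swap]; edges$otu_b[swap] <- tmp
  edges <- edges[!is.na(edges$rho) & !is.na(edges$p) & edges$p < p_thresh, , drop = FALSE]
  score <- if (ranking == "signed") edges$rho else abs(edges$rho)
  edges <- edges[order(-score, edges$otu_a, edges$otu_b), , drop = FALSE]
  edges <- head(edges, top_k)
  rownames(edges) <- NULL
  edges
}

#' Edge-count and node-rank stability across correlation cutoffs
#'
#' The diagnostic behind choosing an edge-count cutoff: for a ladder of
#' correlation cutoffs, report how many edges survive and how stable the
#' node degree ranking is (Spearman correlation over nodes shared by each
#' cutoff pair).
#'
#' @param edges an edge list (`otu_a`, `otu_b`, `rho`).
#' @param cutoffs increasing vector of |rho| cutoffs.
#' @return List: `edge_counts` (named by cutoff), `rank_correlation`
#'   (cutoff x cutoff Spearman matrix), `cutoffs` actually used.
#' @export
degree_rank_stability <- function(edges, cutoffs) {
  if (length(cutoffs) < 2) stop("need at least 2 cutoffs")
  cutoffs <- sort(cutoffs)
  degs <- list()
  counts <- integer(0)
  used <- numeric(0)
  for (ct in cutoffs) {
    sub <- edges[abs(edges$rho) >= ct, , drop = FALSE]
    if (!nrow(sub)) {
      warning("cutoff ", ct, " yields an empty graph; excluded")
      next
    }
    d <- table(c(sub$otu_a, sub$otu_b))
    degs[[as.character(ct)]] <- setNames(as.integer(d), names(d))
    counts <- c(counts, nrow(sub))
    used <- c(used, ct)
  }
  if (length(used) < 2) stop("fewer than 2 cutoffs yield a nonempty graph")
  k <- length(used)
  rc <- matrix(1, k, k, dimnames = list(used, used))
  rank_cor <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    ## fully tied degree vectors: identical rankings agree perfectly, but
    ## Spearman's denominator vanishes; one-sided ties stay undefined
    if (sd(x) == 0 && sd(y) == 0) return(1)
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    shared <- intersect(names(degs[[i]]), names(degs[[j]]))
    rc[i, j] <- rc[j, i] <- rank_cor(degs[[i]][shared], degs[[j]][shared])
  }
  list(edge_counts = setNames(counts, used), rank_correlation = rc, cutoffs = used)
}
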