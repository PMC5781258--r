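#' Signed log2 fold change between two positive means
#'
#' The fold change is always expressed as a magnitude >= 1
#' (`max(r, 1/r)` for `r = mean_treatment / mean_control`), log2-transformed,
#' and given the sign of the direction of change; equal means give exactly 0.
#'
#' @param mean_treatment,mean_control positive means (vectorized).
#' @return Signed log2 fold change(s).
#' @export
signed_log2_fc <- function(mean_treatment, mean_control) {
  if (any(mean_treatment <= 0) || any(mean_control <= 0))
    stop("means must be strictly positive")
  r <- mean_treatment / mean_control
  sign(r - 1) * log2(pmax(r, 1 / r))
}

#' Pearson correlation link table between two feature matrices
#'
#' Tests every row of `X` against every row of `Y` on their shared samples:
#' product-moment correlation with a two-sided p-value from the t-transform
#' on n - 2 degrees of freedom; pairs with `p < p_thresh` are retained. No
#' multiple-testing correction is applied by default (set `fdr = TRUE` for a
#' BH-adjusted `q` column and filtering on it).
#'
#' @param X,Y numeric matrices, features x samples, with sample ids as
#'   column names; constant rows are skipped with a warning.
#' @param p_thresh retention threshold (default 0.05).
#' @param fdr apply BH adjustment across all pairs and filter on q instead.
#' @return data.frame of class `link_table`: `feature_a` (rows of X),
#'   `feature_b` (rows of Y), `r`, `p`, `n_samples`.
#' @export
pearson_link_table <- function(X, Y, p_thresh = 0.05, fdr = FALSE) {
  shared <- intersect(colnames(X), colnames(Y))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  Xs <- X[, shared, drop = FALSE]
  Ys <- Y[, shared, drop = FALSE]
  const_x <- apply(Xs, 1, function(v) var(v) == 0)
  const_y <- apply(Ys, 1, function(v) var(v) == 0)
  if (any(const_x) || any(const_y))
    warning("skipping constant features: ",
            paste(c(rownames(Xs)[const_x], rownames(Ys)[const_y]), collapse = ", "))
  Xs <- Xs[!const_x, , drop = FALSE]
  Ys <- Ys[!const_y, , drop = FALSE]
  n <- length(shared)
  R <- cor(t(Xs), t(Ys))
  tt <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tt), n - 2)
  P[abs(R) >= 1] <- 0
  idx <- which(!is.na(R), arr.ind = TRUE)
  out <- data.frame(feature_a = rownames(R)[idx[, 1]],
                    feature_b = colnames(R)[idx[, 2]],
                    r = R[idx], p = P[idx], n_samples = n,
                    stringsAsFactors = FALSE)
  if (fdr) {
    out$q <- bh_fdr(out$p)
    out <- out[out$q < p_thresh, , drop = FALSE]
  } else {
    out <- out[out$p < p_thresh, , drop = FALSE]
  }
  out <- out[order(out$p, out$feature_a, out$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("link_table", "data.frame")
  out
}

#' Correlate core OTUs with omics features
#'
#' Convenience wrapper: relative abundances of the chosen OTUs against a
#' metabolite or gene-expression matrix on their shared samples.
#'
#' @param table an [otu_table] (rarefied).
#' @param omics features x samples matrix.
#' @param otus OTU ids to test (e.g. the core stress set); default all.
#' @param transform `"relative"` abundance or `"clr"`.
#' @inheritParams pearson_link_table
#' @return A `link_table` with OTUs as `feature_a`.
#' @export
otu_omics_links <- function(table, omics, otus = rownames(table$counts),
                            p_thresh = 0.05, fdr = FALSE,
                            transform = c("relative", "clr")) {
  stopifnot(inherits(table, "cs_otu_table"))
  transform <- match.arg(transform)
  bad <- setdiff(otus, rownames(table$counts))
  if (length(bad)) stop("unknown OTU ids: ", paste(bad, collapse = ", "))
  A <- switch(transform,
              relative = relative_abundance(table),
              clr = clr_transform(table))
  pearson_link_table(A[otus, , drop = FALSE], omics, p_thresh = p_thresh, fdr = fdr)
}

#' Rank features by number of distinct correlation partners
#'
#' @param links a [pearson_link_table] result.
#' @param side count partners of `feature_a` (`"a"`) or `feature_b` (`"b"`).
#' @return data.frame `feature`, `n_links`, descending by count with ties
#'   broken by feature id.
#' @export
rank_by_link_count <- function(links, side = c("a", "b")) {
  side <- match.arg(side)
  if (!nrow(links))
    return(data.frame(feature = character(0), n_links = integer(0)))
  key <- links[[paste0("feature_", side)]]
  other <- links[[paste0("feature_", if (side == "a") "b" else "a")]]
  counts <- tapply(other, key, function(x) length(unique(x)))
  out <- data.frame(feature = names(counts), n_links = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_links, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
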