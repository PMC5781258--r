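## fixture builders shared across the suite

make_table <- function(counts, treatments = NULL, taxonomy = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  md <- NULL
  if (!is.null(treatments))
    md <- data.frame(sample = colnames(counts), treatment = treatments,
                     compartment = "root", stringsAsFactors = FALSE)
  otu_table(counts, taxonomy = taxonomy, metadata = md)
}

## independent per-branch weighted UniFrac oracle: for every branch, find the
## descendant tip set by its own recursion over the edge table, sum branch
## length times |p_A - p_B| over an explicit double loop of sample pairs
unifrac_oracle <- function(counts, tree, normalized = FALSE) {
  R <- sweep(counts, 2, colSums(counts), "/")
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  n <- ncol(R)
  D <- matrix(0, n, n, dimnames = list(colnames(R), colnames(R)))
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tips_below(tree$edge[e, 2])
      tips <- intersect(tips, rownames(R))
      pa <- sum(R[tips, a]); pb <- sum(R[tips, b])
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    D[a, b] <- D[b, a] <- if (normalized) num / den else num
  }
  D
}

## brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[seq(i, m)] * m / seq(i, m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## log-normal + multinomial counts with independent basis (null community)
null_counts <- function(D, n, depth = 5000, sd = 1, seed = 1) {
  set.seed(seed)
  logA <- matrix(rnorm(D * n, 0, sd), D, n)
  counts <- sapply(seq_len(n), function(s) {
    p <- exp(logA[, s]); rmultinom(1, depth, p / sum(p))
  })
  rownames(counts) <- sprintf("OTU_%04d", seq_len(D))
  colnames(counts) <- sprintf("s%03d", seq_len(n))
  counts
}

## same generator with one basis-correlated pair planted on OTUs 1 and 2
planted_pair_counts <- function(D, n, rho, depth = 5000, sd = 1, seed = 1) {
  set.seed(seed)
  logA <- matrix(rnorm(D * n, 0, sd), D, n)
  z <- rnorm(n)
  logA[1, ] <- sd * z
  logA[2, ] <- sd * (rho * z + sqrt(1 - rho^2) * rnorm(n))
  counts <- sapply(seq_len(n), function(s) {
    p <- exp(logA[, s]); rmultinom(1, depth, p / sum(p))
  })
  rownames(counts) <- sprintf("OTU_%04d", seq_len(D))
  colnames(counts) <- sprintf("s%03d", seq_len(n))
  counts
}
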