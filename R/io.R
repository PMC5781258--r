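## Readers and writers for the plain-text formats the pipeline touches.
## TSV dialect throughout: tab-separated, UTF-8, no quoting; OTU tables carry
## the OTU id in the first column and (optionally) a semicolon-delimited
## lineage in a final column named "taxonomy".

#' Read an OTU table from TSV or BIOM-JSON
#'
#' @param path file path.
#' @param format `"tsv"` (header row of sample ids, first column `otu_id`,
#'   optional final `taxonomy` column) or `"biom-json"` (dense or sparse BIOM
#'   1.0, parsed via the biomformat package).
#' @param metadata optional path to a metadata TSV with columns
#'   `sample`, `treatment`, `compartment`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"), metadata = NULL) {
  format <- match.arg(format)
  tab <- switch(format,
    "tsv" = read_otu_tsv(path),
    "biom-json" = read_otu_biom(path))
  if (!is.null(metadata)) {
    md <- read_metadata(metadata)
    tab <- otu_table(tab$counts, taxonomy = tab$taxonomy, metadata = md)
  }
  tab
}

read_otu_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty OTU table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  has_tax <- identical(header[ncol_expect], "taxonomy")
  sample_ids <- header[seq(2, ncol_expect - has_tax)]
  body <- fields[-1]
  counts <- matrix(0, length(body), length(sample_ids))
  otu_ids <- character(length(body))
  taxonomy <- if (has_tax) character(length(body)) else NULL
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != ncol_expect)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, ncol_expect, length(f)))
    otu_ids[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[seq(2, 1 + length(sample_ids))]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      stop(sprintf("line %d, column '%s': invalid count '%s'",
                   i + 1L, sample_ids[bad[1]], f[1 + bad[1]]))
    counts[i, ] <- vals
    if (has_tax) taxonomy[i] <- f[ncol_expect]
  }
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  dimnames(counts) <- list(otu_ids, sample_ids)
  if (has_tax) names(taxonomy) <- otu_ids
  otu_table(counts, taxonomy = taxonomy)
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM-JSON requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  md <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (is.data.frame(md) && ncol(md) > 0) {
    taxonomy <- apply(md, 1, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = "; "))
    names(taxonomy) <- rownames(counts)
  } else if (is.list(md) && length(md)) {
    taxonomy <- vapply(md, function(r) paste(unlist(r), collapse = "; "), character(1))
    names(taxonomy) <- rownames(counts)
  }
  otu_table(counts, taxonomy = taxonomy)
}

#' Write an OTU table as TSV
#'
#' Round-trips bit-identically with [read_otu_table] for integer counts.
#'
#' @param table an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "cs_otu_table"))
  header <- c("otu_id", colnames(table$counts))
  rows <- cbind(rownames(table$counts),
                matrix(format(table$counts, scientific = FALSE, trim = TRUE),
                       nrow = nrow(table$counts)))
  if (!is.null(table$taxonomy)) {
    header <- c(header, "taxonomy")
    rows <- cbind(rows, unname(table$taxonomy))
  }
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write per-sample metadata TSV
#'
#' Columns: `sample`, `treatment`, `compartment`.
#' @param path file path.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "treatment") %in% names(md)))
    stop("metadata must have 'sample' and 'treatment' columns: ", path)
  md
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Missing branch lengths are set to 0 with a warning (weighted UniFrac stays
#' defined); an unrooted tree is an error.
#'
#' @param path newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths read as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path)
  tree
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Remove organelle-derived OTUs by taxonomy
#'
#' Drops OTUs whose lineage string contains any of the given substrings,
#' case-insensitively. The defaults remove the chloroplast and mitochondrial
#' 16S reads that plant material contributes to amplicon libraries.
#'
#' @param table an [otu_table] with taxonomy.
#' @param patterns lineage substrings marking organelle OTUs.
#' @return The filtered [otu_table]; counts of surviving OTUs are untouched.
#' @export
filter_organelle_otus <- function(table, patterns = c("chloroplast", "mitochondria")) {
  stopifnot(inherits(table, "cs_otu_table"))
  if (is.null(table$taxonomy)) stop("table carries no taxonomy")
  hit <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, table$taxonomy, ignore.case = TRUE, fixed = FALSE)))
  keep <- rownames(table$counts)[!hit]
  if (!length(keep)) {
    warning("all OTUs matched organelle patterns; returning empty table")
    tab <- table
    tab$counts <- table$counts[0, , drop = FALSE]
    tab$taxonomy <- table$taxonomy[0]
    return(tab)
  }
  subset_otu_table(table, otus = keep)
}

#' Read / write a labelled square distance matrix TSV
#'
#' @param path file path.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("not a labelled square matrix: ", path)
  stats::as.dist(m)
}

#' @rdname read_distance_matrix
#' @param dm a [stats::dist] object or square matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  write.table(cbind(sample = rownames(m), as.data.frame(m)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a correlation-network edge list TSV
#'
#' Columns: `otu_a`, `otu_b`, `rho`, `p`, with `otu_a < otu_b`.
#' @param path file path.
#' @export
read_edge_list <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_a", "otu_b", "rho", "p") %in% names(e)))
    stop("edge list must have columns otu_a, otu_b, rho, p: ", path)
  e
}

#' @rdname read_edge_list
#' @param edges an edge-list data.frame.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
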