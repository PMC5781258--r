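#' OTU count table with sample metadata and taxonomy
#'
#' The universal substrate of the pipeline: an integer count matrix with OTUs
#' as rows and samples as columns, optionally carrying a taxonomy string per
#' OTU and a treatment/compartment label per sample.
#'
#' @param counts non-negative integer matrix, OTUs x samples, with unique row
#'   (OTU id) and column (sample id) names.
#' @param taxonomy optional named character vector mapping OTU id to a
#'   semicolon-delimited lineage string (e.g. `"k__Bacteria; p__Proteobacteria"`).
#' @param metadata optional data.frame with columns `sample`, `treatment`,
#'   `compartment` covering every sample in `counts`.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `metadata`.
#' @export
#'
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2", "s3")))
#' otu_table(m)
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (OTUs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (any(counts != round(counts))) stop("`counts` must be integers")
  storage.mode(counts) <- "double"   # tolerate depths beyond .Machine$integer.max sums

  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(rownames(counts) %in% names(taxonomy)))
      stop("`taxonomy` must be a character vector named by every OTU id")
    taxonomy <- taxonomy[rownames(counts)]
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    req <- c("sample", "treatment")
    if (!all(req %in% names(metadata)))
      stop("`metadata` must have columns 'sample' and 'treatment'")
    if (!"compartment" %in% names(metadata)) metadata$compartment <- "root"
    missing <- setdiff(colnames(counts), metadata$sample)
    if (length(missing))
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    metadata <- metadata[match(colnames(counts), metadata$sample),
                         c("sample", "treatment", "compartment")]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "cs_otu_table")
}

#' @export
print.cs_otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$metadata)) {
    tr <- table(x$metadata$treatment)
    cat("treatments:", paste(sprintf("%s (%d)", names(tr), tr), collapse = ", "), "\n")
  }
  if (!is.null(x$taxonomy)) cat("taxonomy: present\n")
  cat(sprintf("library depths: %s-%s reads\n",
              format(min(colSums(x$counts))), format(max(colSums(x$counts)))))
  invisible(x)
}

#' @export
dim.cs_otu_table <- function(x) dim(x$counts)

n_otus <- function(x) nrow(x$counts)
n_samples <- function(x) ncol(x$counts)

#' Per-sample relative abundances
#'
#' @param table an [otu_table].
#' @return Matrix of the same shape as `table$counts` whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "cs_otu_table"))
  tot <- colSums(table$counts)
  if (any(tot == 0)) stop("samples with zero total reads: ",
                          paste(colnames(table$counts)[tot == 0], collapse = ", "))
  sweep(table$counts, 2, tot, "/")
}

#' Subset an OTU table by OTUs and/or samples
#'
#' @param table an [otu_table].
#' @param otus,samples character vectors of ids to retain (default: all).
#' @return The subsetted [otu_table]; taxonomy and metadata follow.
#' @export
subset_otu_table <- function(table, otus = rownames(table$counts),
                             samples = colnames(table$counts)) {
  stopifnot(inherits(table, "cs_otu_table"))
  bad <- setdiff(otus, rownames(table$counts))
  if (length(bad)) stop("unknown OTU ids: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples, colnames(table$counts))
  if (length(bad)) stop("unknown sample ids: ", paste(bad, collapse = ", "))
  md <- table$metadata
  if (!is.null(md)) md <- md[md$sample %in% samples, , drop = FALSE]
  otu_table(table$counts[otus, samples, drop = FALSE],
            taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[otus],
            metadata = md)
}

## sample ids belonging to one treatment (compartment-agnostic)
treatment_samples <- function(table, treatment) {
  md <- table$metadata
  if (is.null(md)) stop("OTU table carries no metadata")
  ids <- md$sample[md$treatment == treatment]
  if (!length(ids)) stop("no samples with treatment '", treatment, "'")
  ids
}
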