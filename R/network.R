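#' Build a correlation network from an edge list
#'
#' @param edges data.frame with `otu_a`, `otu_b` and optionally `rho`, `p`
#'   (see [select_edges]).
#' @param taxonomy optional named lineage vector used as a vertex attribute.
#' @param treatment optional treatment label stored as a graph attribute.
#' @return An undirected [igraph::igraph] with no self-loops.
#' @export
build_network <- function(edges, taxonomy = NULL, treatment = NULL) {
  edges <- edges[edges$otu_a != edges$otu_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxonomy <- unname(taxonomy[igraph::V(g)$name])
  }
  if (!is.null(treatment)) g <- igraph::set_graph_attr(g, "treatment", treatment)
  g
}

#' Hub subnetwork: most-connected nodes and their neighbors
#'
#' Selects the `top_n` highest-degree nodes (all nodes tied at the boundary
#' degree are included, with a message), adds every immediate neighbor, and
#' returns the vertex-induced subgraph on that set.
#'
#' @param net an [igraph::igraph].
#' @param top_n number of hub nodes (default 20).
#' @return The induced subgraph, same class.
#' @export
hub_subnetwork <- function(net, top_n = 20) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  if (igraph::vcount(net) <= top_n) return(net)
  deg <- igraph::degree(net)
  thresh <- sort(deg, decreasing = TRUE)[top_n]
  hubs <- names(deg)[deg >= thresh]
  if (length(hubs) > top_n)
    message("degree ties at rank ", top_n, ": keeping ", length(hubs), " hubs")
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(net, hubs), names)))
  keep <- union(hubs, nb)
  igraph::induced_subgraph(net, keep)
}

#' Merge per-treatment hub subnetworks
#'
#' Takes one subnetwork per treatment, forms the node and edge union, and
#' partitions nodes by the set of treatments whose subnetwork contains them:
#' treatment-specific classes, k-treatment shared classes, and the
#' all-treatment "core" class (the central subnetwork). Per-treatment edge
#' weights are kept separately — the treatments are separate estimations.
#'
#' @param subnets named list, treatment label -> [igraph::igraph].
#' @return Object of class `network_merge`: `membership` (data.frame `otu`,
#'   `treatments` (comma-joined), `n_treatments`, `class`), `edges`
#'   (data.frame with a `treatment` column), `class_sizes`, and the merged
#'   `graph`.
#' @export
merge_subnetworks <- function(subnets) {
  if (length(subnets) < 2 || is.null(names(subnets)))
    stop("`subnets` must be a named list of >= 2 treatment subnetworks")
  treatments <- names(subnets)
  membership <- list()
  edge_rows <- list()
  for (tr in treatments) {
    g <- subnets[[tr]]
    for (v in igraph::V(g)$name) membership[[v]] <- c(membership[[v]], tr)
    e <- igraph::as_data_frame(g, what = "edges")
    if (nrow(e)) {
      names(e)[1:2] <- c("otu_a", "otu_b")
      swap <- e$otu_a > e$otu_b
      tmp <- e$otu_a[swap]; e$otu_a[swap] <- e$otu_b[swap]; e$otu_b[swap] <- tmp
      e$treatment <- tr
      edge_rows[[tr]] <- e
    }
  }
  otus <- sort(names(membership))
  sets <- membership[otus]
  n_tr <- lengths(sets)
  classify <- function(s) {
    if (length(s) == length(treatments)) "core"
    else if (length(s) == 1) paste0(s, "-only")
    else paste0("shared-", length(s))
  }
  cls <- vapply(sets, classify, character(1))
  md <- data.frame(otu = otus,
                   treatments = vapply(sets, function(s)
                     paste(sort(s), collapse = ","), character(1)),
                   n_treatments = as.integer(n_tr), class = unname(cls),
                   stringsAsFactors = FALSE, row.names = NULL)
  edges <- if (length(edge_rows)) do.call(rbind, unname(edge_rows)) else
    data.frame(otu_a = character(0), otu_b = character(0), treatment = character(0))
  rownames(edges) <- NULL
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = otus))
  sizes <- table(md$class)
  stopifnot(sum(sizes) == length(otus))   # classes partition the node union
  structure(list(membership = md, edges = edges,
                 class_sizes = sizes, graph = graph,
                 treatments = treatments),
            class = "network_merge")
}

#' @export
print.network_merge <- function(x, ...) {
  cat(sprintf("merged network: %d OTUs across %d treatments\n",
              nrow(x$membership), length(x$treatments)))
  core <- sum(x$membership$class == "core")
  cat(sprintf("  all-treatment core subnetwork: %d OTUs\n", core))
  only <- x$membership$class[grepl("-only$", x$membership$class)]
  if (length(only)) {
    t1 <- table(only)
    cat("  treatment-specific:",
        paste(sprintf("%s (%d)", sub("-only$", "", names(t1)), t1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Taxonomic composition of a node set
#'
#' Fractions of nodes per taxon at the requested rank; lineages that do not
#' resolve at that rank count as `"unclassified"`. With
#' `split_proteobacteria = TRUE` the Proteobacteria are reported at class
#' level (Alpha/Beta/Gamma/Delta) while other phyla stay at phylum level,
#' following the usual convention of subnetwork pie charts.
#'
#' @param nodes character vector of OTU ids.
#' @param taxonomy named lineage vector (semicolon-separated ranks with
#'   optional `p__`/`c__` prefixes).
#' @param rank `"phylum"` or `"class"`.
#' @param split_proteobacteria split Proteobacteria to class level.
#' @return Named numeric vector of fractions summing to 1.
#' @export
taxonomy_composition <- function(nodes, taxonomy, rank = c("phylum", "class"),
                                 split_proteobacteria = FALSE) {
  rank <- match.arg(rank)
  if (!length(nodes)) stop("empty node set")
  pos <- c(phylum = 2L, class = 3L)[[rank]]
  get_rank <- function(lineage, pos) {
    if (is.na(lineage) || !nzchar(lineage)) return("unclassified")
    parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
    parts <- sub("^[a-z]__", "", parts)
    if (length(parts) < pos || !nzchar(parts[pos])) return("unclassified")
    parts[pos]
  }
  labels <- vapply(nodes, function(v) {
    lin <- taxonomy[v]
    lab <- get_rank(lin, pos)
    if (split_proteobacteria && rank == "phylum" && identical(lab, "Proteobacteria")) {
      cl <- get_rank(lin, 3L)
      if (!identical(cl, "unclassified")) lab <- cl
    }
    lab
  }, character(1))
  tab <- table(labels)
  setNames(as.numeric(tab) / length(nodes), names(tab))
}
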