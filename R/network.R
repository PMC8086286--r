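#' Export a sponge-triplet network
#'
#' Writes the bipartite-style interaction network implied by a set of scored
#' triplets: one lncRNA--miRNA and one miRNA--mRNA edge per triplet, with
#' repeated (node, node) pairs emitted once. SIF is the tab-delimited
#' source/interaction/target format consumed by Cytoscape; GraphML carries
#' the edge attributes `r_xy` and `Sz` and a node attribute `role`
#' (lncRNA/miRNA/mRNA).
#'
#' @param triplets data.frame with columns `lncRNA`, `miRNA`, `mRNA` and,
#'   for GraphML attributes, `r_xy` and `Sz`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_network <- function(triplets, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (!is.data.frame(triplets) || nrow(triplets) == 0)
    stop("non-empty triplet data.frame required")
  need <- c("lncRNA", "miRNA", "mRNA")
  if (!all(need %in% names(triplets)))
    stop("triplets must have columns: ", paste(need, collapse = ", "))

  e1 <- data.frame(from = triplets$lncRNA, to = triplets$miRNA,
                   interaction = "lncRNA-miRNA", stringsAsFactors = FALSE)
  e2 <- data.frame(from = triplets$miRNA, to = triplets$mRNA,
                   interaction = "miRNA-mRNA", stringsAsFactors = FALSE)
  if (all(c("r_xy", "Sz") %in% names(triplets))) {
    e1$r_xy <- e2$r_xy <- triplets$r_xy
    e1$Sz <- e2$Sz <- triplets$Sz
  }
  edges <- rbind(e1, e2)
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]

  if (format == "sif") {
    writeLines(paste(edges$from, edges$interaction, edges$to, sep = "\t"), path)
  } else {
    nodes <- data.frame(name = unique(c(triplets$lncRNA, triplets$miRNA, triplets$mRNA)),
                        stringsAsFactors = FALSE)
    nodes$role <- ifelse(nodes$name %in% triplets$lncRNA, "lncRNA",
                         ifelse(nodes$name %in% triplets$miRNA, "miRNA", "mRNA"))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
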