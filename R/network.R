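#' Build the drug-target network
#'
#' Base construction: an undirected bipartite graph with one edge per
#' (drug, target gene) pair of the map (edge relation `"targets"`). With
#' `connect_targets_to_all_drugs = TRUE`, every target gene is additionally
#' connected to every other drug in the map (relation `"connected"`),
#' giving the fully connected-node rendering in which all targets of each
#' drug reach all other drugs. No self-loops, no duplicate edges.
#'
#' @param map drug-target map (data.frame drug, gene).
#' @param connect_targets_to_all_drugs add gene-to-other-drug edges.
#' @return an igraph with vertex attributes `kind` (`"drug"`/`"gene"`) and
#'   edge attribute `relation`.
#' @export
build_drug_target_network <- function(map, connect_targets_to_all_drugs = FALSE) {
  map <- drug_target_map(map)
  if (nrow(map) == 0) stop_input("empty drug-target map")
  drugs <- unique(map$drug)
  genes <- unique(map$gene)
  if (length(intersect(drugs, genes)) > 0)
    stop_input("drug and gene namespaces overlap: ",
               paste(utils::head(intersect(drugs, genes), 3), collapse = ", "))

  edges <- data.frame(from = map$drug, to = map$gene,
                      relation = "targets", stringsAsFactors = FALSE)
  if (connect_targets_to_all_drugs) {
    cross <- expand.grid(to = genes, from = drugs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    have <- paste(edges$from, edges$to, sep = "\r")
    cross <- cross[!(paste(cross$from, cross$to, sep = "\r") %in% have), ,
                   drop = FALSE]
    if (nrow(cross) > 0)
      edges <- rbind(edges, data.frame(from = cross$from, to = cross$to,
                                       relation = "connected",
                                       stringsAsFactors = FALSE))
  }
  verts <- data.frame(name = c(drugs, genes),
                      kind = c(rep("drug", length(drugs)),
                               rep("gene", length(genes))),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Eccentricity centrality scores
#'
#' The eccentricity of a node is the length of its longest shortest path;
#' the score is its reciprocal, so higher means more central (closer to
#' everything). Unweighted shortest paths; on disconnected graphs each node
#' is scored within its own connected component. Singleton components have
#' no defined eccentricity and are flagged with `NA`.
#'
#' @param net an igraph (e.g. from [build_drug_target_network()]).
#' @return data.frame (node, kind, degree, eccentricity, score) sorted by
#'   descending score.
#' @export
eccentricity_scores <- function(net) {
  stopifnot(igraph::is_igraph(net))
  d <- igraph::distances(net)          # unweighted BFS distances
  d[is.infinite(d)] <- NA              # other components
  ecc <- apply(d, 1, max, na.rm = TRUE)
  score <- ifelse(ecc > 0, 1 / ecc, NA_real_)  # singleton: undefined
  kind <- igraph::vertex_attr(net, "kind")
  out <- data.frame(
    node = igraph::V(net)$name,
    kind = if (is.null(kind)) NA_character_ else kind,
    degree = igraph::degree(net),
    eccentricity = ecc,
    score = score,
    stringsAsFactors = FALSE
  )
  out <- out[order(-ifelse(is.na(out$score), -Inf, out$score), out$node), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top hub nodes by eccentricity score
#'
#' Descending score; ties broken by degree (descending) then node id.
#'
#' @param scores score table from [eccentricity_scores()].
#' @param n number of hubs (default 20); capped at the node count.
#' @return the top `min(n, nodes)` rows.
#' @export
top_hubs <- function(scores, n = 20) {
  stopifnot(is.data.frame(scores), all(c("node", "score") %in% names(scores)))
  ord <- order(-ifelse(is.na(scores$score), -Inf, scores$score),
               -scores$degree, scores$node)
  out <- scores[ord[seq_len(min(n, nrow(scores)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the subnetwork induced by gene sets
#'
#' Induced subgraph on the union of the supplied gene sets plus every drug
#' retaining at least one target (by `"targets"` edges) in that union.
#'
#' @param net drug-target network.
#' @param gene_sets named list of gene-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @return igraph subnetwork; attributes `drugs_retained` and `genes_matched`
#'   record what survived.
#' @export
extract_geneset_subnetwork <- function(net, gene_sets) {
  stopifnot(igraph::is_igraph(net), is.list(gene_sets))
  want <- toupper(unique(unlist(gene_sets)))
  kind <- igraph::vertex_attr(net, "kind")
  name <- igraph::V(net)$name
  genes_matched <- name[kind == "gene" & name %in% want]
  if (length(genes_matched) == 0)
    stop_input("no genes of the supplied sets occur in the network")

  el <- igraph::as_data_frame(net, what = "edges")
  targ <- el[el$relation == "targets", , drop = FALSE]
  # either endpoint may be the drug in an undirected edge list
  d1 <- targ$from[targ$to %in% genes_matched]
  d2 <- targ$to[targ$from %in% genes_matched]
  drugs_retained <- intersect(name[kind == "drug"], unique(c(d1, d2)))

  sub <- igraph::induced_subgraph(net, c(genes_matched, drugs_retained))
  attr(sub, "genes_matched") <- genes_matched
  attr(sub, "drugs_retained") <- drugs_retained
  sub
}

#' Report node and edge counts of a network
#'
#' @param net an igraph.
#' @return named list (nodes, edges).
#' @export
network_counts <- function(net) {
  list(nodes = igraph::vcount(net), edges = igraph::ecount(net))
}
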