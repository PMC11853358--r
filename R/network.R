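# Correlation-weighted residue interaction network, Girvan-Newman community
# detection, betweenness, and intercommunity coupling.

#' Construct a residue graph from explicit node and edge tables
#'
#' Lower-level constructor used by [build_network()] and directly in tests:
#' nodes are residues, edges carry the correlation-derived distance weight
#' d = -log(max(|C|, floor)), the underlying |C| and the contact persistence.
#'
#' @param nodes data.frame with columns `id` (residue id, "chain:resno"),
#'   `chain`, `resno`, and optionally `resname`.
#' @param edges data.frame with columns `from`, `to` (node ids), `absC`,
#'   `persistence`.
#' @param floor |C| floor preventing infinite weights (default 1e-6).
#' @return Object of class `residue_graph`: `nodes`, `edges` (with `weight`
#'   column added), `floor`.
#' @export
residue_graph <- function(nodes, edges, floor = 1e-6) {
  stopifnot(all(c("id", "chain", "resno") %in% names(nodes)),
            all(c("from", "to", "absC", "persistence") %in% names(edges)))
  if (!"resname" %in% names(nodes)) nodes$resname <- NA_character_
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad)) stop("edge endpoint not in node table: ", bad[1])
    edges$weight <- -log(pmax(edges$absC, floor))
    # undirected: canonical order, no duplicates
    swap <- match(edges$from, nodes$id) > match(edges$to, nodes$id)
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to)))
      stop("duplicate edges")
  } else edges$weight <- numeric(0)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, floor = floor),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "weight", "absC", "persistence"),
                drop = FALSE],
    directed = FALSE, vertices = graph$nodes)
  g
}

#' Build a correlation-weighted residue interaction network
#'
#' Nodes are the residues of the correlation matrix; an edge joins two
#' residues whose minimum interatomic distance stays within the cutoff for
#' at least the persistence fraction of analysis frames (inclusive). Edge
#' weights are d = -log|C| with |C| floored, so strongly correlated residues
#' are "close".
#'
#' @param traj an `md_trajectory`.
#' @param dccm an `md_dccm` whose residues match the trajectory's.
#' @param cutoff contact distance cutoff (default 4.5 A).
#' @param persistence minimum contact persistence (default 0.75, inclusive).
#' @param contact_mode `"heavy"` (any heavy-atom pair, default) or `"ca"`.
#' @param floor |C| floor (default 1e-6).
#' @param mask_backbone drop edges between consecutive residues of the same
#'   chain (default FALSE).
#' @return A `residue_graph`.
#' @export
build_network <- function(traj, dccm, cutoff = 4.5, persistence = 0.75,
                          contact_mode = c("heavy", "ca"), floor = 1e-6,
                          mask_backbone = FALSE) {
  contact_mode <- match.arg(contact_mode)
  top <- traj$topology
  idx <- if (contact_mode == "heavy") which(top$atoms$element != "H") else
    which(top$atoms$atom == "CA")
  rid <- residue_ids(top, idx)
  if (!setequal(unique(rid), dccm$labels))
    stop("residue labels of the correlation matrix do not match the trajectory")
  po <- pair_occupancy_matrix(traj, idx, idx, cutoff)
  # occupancy matrix rows/cols ordered as unique(rid); align to dccm labels
  ord <- match(dccm$labels, po$resA)
  occ <- po$occ[ord, ord, drop = FALSE]
  n <- length(dccm$labels)
  first <- idx[match(dccm$labels, rid)]
  nodes <- data.frame(id = dccm$labels,
                      chain = top$atoms$chain[first],
                      resno = top$atoms$resno[first],
                      resname = top$atoms$resname[first],
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (occ[i, j] < persistence) next
    if (mask_backbone && nodes$chain[i] == nodes$chain[j] &&
        abs(nodes$resno[i] - nodes$resno[j]) == 1L) next
    cij <- dccm$C[i, j]
    if (is.na(cij)) next
    rows[[length(rows) + 1L]] <-
      data.frame(from = nodes$id[i], to = nodes$id[j],
                 absC = abs(cij), persistence = occ[i, j],
                 stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(0), to = character(0),
               absC = numeric(0), persistence = numeric(0))
  residue_graph(nodes, edges, floor)
}

#' Node and edge betweenness centrality
#'
#' Weighted-shortest-path betweenness (Brandes algorithm via igraph), with
#' path lengths summing the -log|C| edge weights and tied shortest paths
#' splitting the dependency equally.
#'
#' @param graph a `residue_graph`.
#' @return List with `node` (named vector) and `edge` (edge table with a
#'   `betweenness` column).
#' @export
graph_betweenness <- function(graph) {
  if (!nrow(graph$nodes)) stop("empty graph")
  g <- as_igraph(graph)
  w <- if (nrow(graph$edges)) igraph::E(g)$weight else NULL
  nb <- igraph::betweenness(g, weights = w)
  eb <- if (nrow(graph$edges))
    igraph::edge_betweenness(g, weights = w) else numeric(0)
  edges <- graph$edges
  edges$betweenness <- eb
  list(node = nb, edge = edges)
}

# Newman-Girvan modularity of a membership vector on the ORIGINAL graph
# (unweighted: fraction of edges within communities minus the degree-based
# expectation)
ng_modularity <- function(graph, membership) {
  m <- nrow(graph$edges)
  if (m == 0L) return(0)
  ids <- graph$nodes$id
  ci <- membership[match(graph$edges$from, ids)]
  cj <- membership[match(graph$edges$to, ids)]
  deg <- table(factor(c(graph$edges$from, graph$edges$to), levels = ids))
  e_in <- sum(ci == cj) / m
  a2 <- sum(tapply(as.numeric(deg) / (2 * m), membership, sum)^2)
  e_in - a2
}

#' Girvan-Newman community detection
#'
#' Divisive algorithm: repeatedly remove the edge of maximum weighted edge
#' betweenness (shortest paths over the -log|C| distances) and keep the
#' connected-component partition of maximum Newman-Girvan modularity
#' (evaluated on the original graph). Communities smaller than `min_size`
#' are omitted from the reported community list; the full membership is
#' still recorded.
#'
#' @param graph a `residue_graph`.
#' @param min_size minimum reported community size (default 3).
#' @return Object of class `community_partition`: `membership` (named
#'   integer vector over all nodes), `communities` (list of node-id vectors,
#'   size >= min_size, largest first), `modularity`, `min_size`.
#' @export
girvan_newman <- function(graph, min_size = 3L) {
  if (!nrow(graph$nodes)) stop("empty graph")
  g0 <- as_igraph(graph)
  g <- g0
  best_mod <- -Inf
  best_mem <- NULL
  repeat {
    comp <- igraph::components(g)
    mem <- comp$membership[graph$nodes$id]
    q <- ng_modularity(graph, mem)
    if (q > best_mod + 1e-12) {
      best_mod <- q
      best_mem <- mem
    }
    if (igraph::ecount(g) == 0L) break
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
    g <- igraph::delete_edges(g, which.max(eb))   # first max: deterministic
  }
  names(best_mem) <- graph$nodes$id
  # relabel communities by decreasing size (ties by first member)
  sizes <- table(best_mem)
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relab <- match(best_mem, as.integer(names(sizes))[ord])
  names(relab) <- names(best_mem)
  comms <- split(names(relab), relab)
  keep <- vapply(comms, length, 1L) >= min_size
  structure(list(membership = relab,
                 communities = unname(comms[keep]),
                 modularity = best_mod,
                 min_size = min_size),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(unique(x$membership)),
      "communities (", length(x$communities), "of size >=", x$min_size,
      "reported ), modularity", sprintf("%.3f", x$modularity), "\n")
  invisible(x)
}

#' Intercommunity coupling strengths
#'
#' For every pair of communities joined by at least one edge, the summed
#' |C| over crossing edges (convention recorded in the output attribute).
#'
#' @param graph a `residue_graph`.
#' @param partition a `community_partition` covering the graph's nodes.
#' @return data.frame with columns `communityA`, `communityB`, `strength`,
#'   `n_edges`; zero rows when no edges cross.
#' @export
intercommunity_strength <- function(graph, partition) {
  mem <- partition$membership
  if (!all(graph$nodes$id %in% names(mem)))
    stop("partition does not cover all graph nodes")
  e <- graph$edges
  out <- data.frame(communityA = integer(0), communityB = integer(0),
                    strength = numeric(0), n_edges = integer(0))
  if (nrow(e)) {
    ca <- mem[e$from]; cb <- mem[e$to]
    cross <- ca != cb
    if (any(cross)) {
      lo <- pmin(ca[cross], cb[cross]); hi <- pmax(ca[cross], cb[cross])
      key <- paste(lo, hi)
      agg_s <- tapply(e$absC[cross], key, sum)
      agg_n <- tapply(rep(1L, sum(cross)), key, sum)
      parts <- do.call(rbind, strsplit(names(agg_s), " "))
      out <- data.frame(communityA = as.integer(parts[, 1]),
                        communityB = as.integer(parts[, 2]),
                        strength = as.numeric(agg_s),
                        n_edges = as.integer(agg_n))
      out <- out[order(-out$strength), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "convention") <- "sum of |C| over crossing edges"
  out
}

#' Write a residue graph as an edge list
#'
#' TSV columns: `resA resB weight absC persistence`.
#'
#' @param graph a `residue_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(graph, path) {
  e <- graph$edges
  utils::write.table(
    data.frame(resA = e$from, resB = e$to, weight = e$weight,
               absC = e$absC, persistence = e$persistence),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a residue graph as GraphML
#' @param graph a `residue_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write a community table as TSV (`resnum chain community`)
#' @param graph a `residue_graph`.
#' @param partition a `community_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(graph, partition, path) {
  mem <- partition$membership[graph$nodes$id]
  utils::write.table(
    data.frame(resnum = graph$nodes$resno, chain = graph$nodes$chain,
               community = as.integer(mem)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
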