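# Node definitions shared by the contact graph and the node trajectory:
# one node per protein residue at its C-alpha; one node per ligand residue,
# placed at the heavy-atom centroid (or at a named atom).
network_nodes <- function(x, ligand_node = "centroid") {
  rt <- residue_table(x)
  ri <- atom_res_index(x)
  nodes <- list()
  for (k in seq_len(nrow(rt))) {
    if (rt$is_water[k]) next
    if (rt$is_ligand[k]) {
      if (identical(ligand_node, "none")) next
      idx <- which(ri == k & x$atoms$is_heavy)
      if (!identical(ligand_node, "centroid")) {
        named <- which(ri == k & x$atoms$name == ligand_node)
        if (length(named) == 0L)
          stop("ligand atom '", ligand_node, "' not found in ", rt$id[k])
        idx <- named
      }
      if (length(idx) == 0L) stop("no heavy atoms in ", rt$id[k])
      nodes[[length(nodes) + 1L]] <-
        list(id = rt$id[k], res_index = k, kind = "ligand",
             pos_atoms = idx,
             heavy_atoms = which(ri == k & x$atoms$is_heavy))
    } else {
      ca <- which(ri == k & x$atoms$name == "CA")
      heavy <- which(ri == k & x$atoms$is_heavy)
      if (length(heavy) == 0L) stop("no heavy atoms in residue ", rt$id[k])
      if (length(ca) == 0L) next  # residue without C-alpha cannot be a node
      nodes[[length(nodes) + 1L]] <-
        list(id = rt$id[k], res_index = k, kind = "protein",
             pos_atoms = ca[1], heavy_atoms = heavy)
    }
  }
  if (length(nodes) == 0L) stop("no network nodes in topology")
  nodes
}

node_positions <- function(x, nodes) {
  # frames x 3*n_nodes matrix of node positions
  out <- matrix(0, n_frames(x), 3L * length(nodes))
  for (k in seq_along(nodes)) {
    cols <- atom2xyz(nodes[[k]]$pos_atoms)
    m <- x$xyz[, cols, drop = FALSE]
    if (length(nodes[[k]]$pos_atoms) > 1L) {
      m <- cbind(rowMeans(m[, seq(1, ncol(m), 3), drop = FALSE]),
                 rowMeans(m[, seq(2, ncol(m), 3), drop = FALSE]),
                 rowMeans(m[, seq(3, ncol(m), 3), drop = FALSE]))
    }
    out[, (3 * k - 2):(3 * k)] <- m
  }
  out
}

#' Node displacement trajectory for network and PCA analysis
#'
#' One node per protein residue (C-alpha position) and, optionally, one per
#' ligand residue (heavy-atom centroid or a named atom). Frames are
#' superposed on the protein C-alpha nodes to the ensemble mean (two-pass)
#' unless `fit = FALSE` (for ensembles generated already in the fitted
#' frame); the node means are then removed exactly.
#'
#' @param x a `traj` with >= 2 frames
#' @param ligand_node `"centroid"`, `"none"`, or a ligand atom name
#' @param fit superpose frames before taking displacements?
#' @return object of class `node_traj`: list with `ids`, `kind`,
#'   `delta` (frames x 3*n_nodes mean-removed displacements, Angstrom),
#'   `mean` (mean node coordinates) and `res_index`
#' @export
node_trajectory <- function(x, ligand_node = "centroid", fit = TRUE) {
  if (n_frames(x) < 2L) stop("need at least 2 frames")
  nodes <- network_nodes(x, ligand_node)
  xs <- x
  if (fit) {
    ca <- unlist(lapply(nodes, function(n)
      if (n$kind == "protein") n$pos_atoms else integer()))
    xs <- superpose_to_mean(x, ca)
  }
  pos <- node_positions(xs, nodes)
  mu <- colMeans(pos)
  structure(list(ids = vapply(nodes, `[[`, "", "id"),
                 kind = vapply(nodes, `[[`, "", "kind"),
                 delta = sweep(pos, 2, mu),
                 mean = mu,
                 res_index = vapply(nodes, `[[`, 1L, "res_index")),
            class = "node_traj")
}

#' Contact graph from trajectory occupancy
#'
#' An edge joins two nodes when any heavy-atom pair across their residues is
#' within `cutoff` in at least a fraction `min_occupancy` of the frames.
#' Residue pairs within `neighbor_exclusion` positions in the same protein
#' chain are excluded (trivial covalent contacts); ligand nodes are exempt.
#'
#' @param x a `traj`
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5)
#' @param min_occupancy minimum contact occupancy (default 0.75, i.e. at
#'   least 75 percent of the frames; 0.70 is a common alternative preset)
#' @param neighbor_exclusion sequence-separation exclusion (default 2);
#'   set 0 to disable
#' @param ligand_node as in [node_trajectory()]
#' @return object of class `contact_graph`: list with `nodes` (ids),
#'   `kind`, and `edges` (data.frame i, j, node_i, node_j, occupancy)
#' @export
build_contact_graph <- function(x, cutoff = 4.5, min_occupancy = 0.75,
                                neighbor_exclusion = 2L,
                                ligand_node = "centroid") {
  if (cutoff <= 0) stop("cutoff must be positive")
  nodes <- network_nodes(x, ligand_node)
  nn <- length(nodes)
  heavy <- lapply(nodes, `[[`, "heavy_atoms")
  nf <- n_frames(x)
  # per-atom mean position and maximum deviation from it, for a rigorous
  # lower bound on the pairwise distance (prunes far-apart residue pairs)
  na <- n_atoms(x)
  mu <- matrix(colMeans(x$xyz), ncol = 3L, byrow = TRUE)
  dev2 <- matrix(0, nf, na)
  for (k in 1:3)
    dev2 <- dev2 + (x$xyz[, seq(k, 3 * na, 3), drop = FALSE] -
                      matrix(mu[, k], nf, na, byrow = TRUE))^2
  max_dev <- sqrt(apply(dev2, 2, max))
  pair_d2 <- function(ai, aj) {
    (x$xyz[, 3 * ai - 2] - x$xyz[, 3 * aj - 2])^2 +
      (x$xyz[, 3 * ai - 1] - x$xyz[, 3 * aj - 1])^2 +
      (x$xyz[, 3 * ai] - x$xyz[, 3 * aj])^2
  }
  occ <- matrix(0, nn, nn)
  for (i in seq_len(nn - 1L)) {
    for (j in (i + 1L):nn) {
      ai <- heavy[[i]]
      aj <- heavy[[j]]
      # closest the pair can ever get: mean separation minus max deviations
      mind <- Inf
      for (a in ai) {
        gap <- sqrt((mu[a, 1] - mu[aj, 1])^2 + (mu[a, 2] - mu[aj, 2])^2 +
                      (mu[a, 3] - mu[aj, 3])^2) -
          max_dev[a] - max_dev[aj]
        mind <- min(mind, min(gap))
      }
      if (mind > cutoff) next
      d2min <- rep(Inf, nf)
      for (a in ai) for (b in aj) d2min <- pmin(d2min, pair_d2(a, b))
      occ[i, j] <- mean(d2min <= cutoff^2)
    }
  }
  # sequence-neighbour exclusion applies to protein residue pairs in the
  # same chain; residue indices follow file order, so the residue-table
  # index difference is the sequence separation
  ids <- vapply(nodes, `[[`, "", "id")
  kind <- vapply(nodes, `[[`, "", "kind")
  res_index <- vapply(nodes, `[[`, 1L, "res_index")
  edges <- list()
  for (i in seq_len(nn - 1L)) {
    for (j in (i + 1L):nn) {
      if (occ[i, j] < min_occupancy) next
      if (kind[i] == "protein" && kind[j] == "protein" &&
          abs(res_index[i] - res_index[j]) <= neighbor_exclusion) next
      edges[[length(edges) + 1L]] <-
        data.frame(i = i, j = j, node_i = ids[i], node_j = ids[j],
                   occupancy = occ[i, j], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(i = integer(), j = integer(), node_i = character(),
               node_j = character(), occupancy = numeric())
  structure(list(nodes = ids, kind = kind, edges = edges),
            class = "contact_graph")
}

#' Normalised cross-correlation matrix of node displacements
#'
#' C(i, j) = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>), the time average
#' of the dot product of the 3-D displacement vectors, normalised so that
#' C is 1 for identical motion and -1 for exactly opposed motion.
#'
#' @param nt a [node_trajectory()] result
#' @return symmetric matrix with unit diagonal, entries in `[-1, 1]`,
#'   dimnames = node ids
#' @export
correlation_matrix <- function(nt) {
  D <- nt$delta
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 frames")
  nn <- length(nt$ids)
  ix <- seq(1, 3 * nn, by = 3)
  num <- (crossprod(D[, ix]) + crossprod(D[, ix + 1]) +
            crossprod(D[, ix + 2])) / n
  v <- diag(num)
  zero <- which(v <= 0 | !is.finite(v))
  if (length(zero))
    stop("zero-variance node(s): ", paste(nt$ids[zero], collapse = ", "))
  C <- num / sqrt(outer(v, v))
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(nt$ids, nt$ids)
  C
}

#' Weight contact-graph edges from correlations
#'
#' w_ij = -log(|C_ij|), natural log: perfectly correlated nodes get weight 0
#' (information flows freely), weak correlations get long edges. |C| is
#' floored at 1e-12 to keep weights finite; floored edges are flagged.
#'
#' @param graph a [build_contact_graph()] result
#' @param C correlation matrix over the same nodes
#' @return object of class `weighted_graph`: contact graph whose edges gain
#'   `C`, `absC` and `w` columns
#' @export
weight_edges <- function(graph, C) {
  e <- graph$edges
  if (nrow(e) > 0 && !is.null(dimnames(C))) {
    if (!all(graph$nodes %in% rownames(C)))
      stop("correlation matrix does not cover all graph nodes")
    cij <- C[cbind(match(e$node_i, rownames(C)),
                   match(e$node_j, colnames(C)))]
  } else {
    cij <- C[cbind(e$i, e$j)]
  }
  if (any(!is.finite(cij))) stop("non-finite correlation on an edge")
  absc <- abs(cij)
  floored <- absc < 1e-12
  if (any(floored))
    message(sum(floored), " edge(s) had |C| < 1e-12; weight floored")
  e$C <- cij
  e$absC <- pmax(absc, 1e-12)
  e$w <- -log(pmax(absc, 1e-12))
  structure(list(nodes = graph$nodes, kind = graph$kind, edges = e),
            class = "weighted_graph")
}

as_igraph <- function(wg) {
  g <- igraph::graph_from_data_frame(
    wg$edges[, c("node_i", "node_j")], directed = FALSE,
    vertices = data.frame(name = wg$nodes))
  igraph::E(g)$weight <- wg$edges$w
  igraph::E(g)$absC <- wg$edges$absC
  g
}

#' Weighted edge betweenness
#'
#' Shortest-path edge betweenness with edge weights used as path lengths
#' and equal splitting over tied shortest paths; each unordered node pair
#' is counted once.
#'
#' @param wg a [weight_edges()] result
#' @return numeric vector, one value per edge of `wg$edges`
#' @export
edge_betweenness <- function(wg) {
  if (nrow(wg$edges) == 0L) return(numeric())
  g <- as_igraph(wg)
  # igraph requires strictly positive weights; w = 0 (|C| = 1) is nudged
  igraph::edge_betweenness(g, weights = pmax(igraph::E(g)$weight, 1e-12),
                           directed = FALSE)
}

# weighted modularity of a membership vector on the weighted graph,
# using |C| (edge strength) as the affinity
graph_modularity <- function(wg, membership) {
  g <- as_igraph(wg)
  igraph::modularity(g, membership[igraph::V(g)$name],
                     weights = igraph::E(g)$absC)
}

components_membership <- function(wg, edges_keep) {
  g <- igraph::graph_from_data_frame(
    wg$edges[edges_keep, c("node_i", "node_j"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = wg$nodes))
  mm <- igraph::components(g)$membership
  mm[wg$nodes]
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest weighted betweenness (ties broken
#' by the lexicographically smallest endpoint pair) and returns the partition
#' along the removal sequence that maximises the weighted modularity of the
#' original graph, with |C| = exp(-w) as the edge strength. Earlier
#' partitions win modularity ties, making the result deterministic.
#'
#' @param wg a [weight_edges()] result (nonempty)
#' @return object of class `community_partition`: list with `communities`
#'   (list of node-id vectors, largest first), `membership` (named integer
#'   vector), `modularity`, and `critical_nodes` / `critical_edges` from
#'   [critical_elements()]
#' @export
girvan_newman <- function(wg) {
  if (length(wg$nodes) == 0L) stop("empty graph")
  ne <- nrow(wg$edges)
  if (ne == 0L) stop("graph has no edges")
  alive <- rep(TRUE, ne)
  best_m <- components_membership(wg, alive)
  best_q <- graph_modularity(wg, best_m)
  # lexicographic edge key for the tie rule
  ekey <- apply(wg$edges[, c("node_i", "node_j")], 1, function(p)
    paste(sort(p), collapse = "\r"))
  while (any(alive)) {
    sub <- structure(list(nodes = wg$nodes, kind = wg$kind,
                          edges = wg$edges[alive, , drop = FALSE]),
                     class = "weighted_graph")
    bet <- edge_betweenness(sub)
    cand <- which(bet >= max(bet) - 1e-12)
    kill <- cand[order(ekey[alive][cand])][1]
    alive[which(alive)[kill]] <- FALSE
    m <- components_membership(wg, alive)
    q <- graph_modularity(wg, m)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_m <- m
    }
  }
  comms <- split(names(best_m), best_m)
  ord <- order(-lengths(comms), vapply(comms, min, ""))
  comms <- unname(comms[ord])
  memb <- stats::setNames(rep(seq_along(comms), lengths(comms)),
                          unlist(comms))[wg$nodes]
  crit <- critical_elements(list(membership = memb), wg)
  structure(list(communities = comms, membership = memb,
                 modularity = best_q,
                 critical_nodes = crit$critical_nodes,
                 critical_edges = crit$critical_edges),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, modularity %.4f\n",
              length(x$communities), x$modularity))
  cat(sprintf("critical nodes: %s\n",
              paste(x$critical_nodes, collapse = ", ")))
  invisible(x)
}

#' Critical nodes and edges between communities
#'
#' For every pair of communities joined by at least one edge, the connecting
#' edge of highest betweenness (on the full graph) is critical; its two
#' endpoints are the critical nodes mediating that inter-community contact.
#'
#' @param partition a [girvan_newman()] result, or any list with a named
#'   `membership` vector over the graph nodes
#' @param wg the weighted graph the partition was computed on
#' @return list with `critical_nodes` (character) and `critical_edges`
#'   (data.frame node_i, node_j, betweenness, community_i, community_j)
#' @export
critical_elements <- function(partition, wg) {
  memb <- partition$membership
  e <- wg$edges
  empty <- data.frame(node_i = character(), node_j = character(),
                      betweenness = numeric(), community_i = integer(),
                      community_j = integer(), stringsAsFactors = FALSE)
  if (nrow(e) == 0L)
    return(list(critical_nodes = character(), critical_edges = empty))
  bet <- edge_betweenness(wg)
  ci <- memb[e$node_i]
  cj <- memb[e$node_j]
  cross <- which(ci != cj)
  if (length(cross) == 0L)
    return(list(critical_nodes = character(), critical_edges = empty))
  pair <- paste(pmin(ci[cross], cj[cross]), pmax(ci[cross], cj[cross]))
  picked <- vapply(split(cross, pair), function(idx) {
    top <- idx[bet[idx] >= max(bet[idx]) - 1e-12]
    key <- apply(e[top, c("node_i", "node_j"), drop = FALSE], 1,
                 function(p) paste(sort(p), collapse = "\r"))
    top[order(key)][1]
  }, 1L)
  ce <- data.frame(node_i = e$node_i[picked], node_j = e$node_j[picked],
                   betweenness = bet[picked],
                   community_i = pmin(ci[picked], cj[picked]),
                   community_j = pmax(ci[picked], cj[picked]),
                   stringsAsFactors = FALSE)
  rownames(ce) <- NULL
  list(critical_nodes = sort(unique(c(ce$node_i, ce$node_j))),
       critical_edges = ce)
}

#' Write the network edge list as TSV
#'
#' Columns: node_i, node_j, occupancy, C, w, betweenness, community_i,
#' community_j, critical_flag.
#'
#' @param wg a `weighted_graph`
#' @param partition a [girvan_newman()] result
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(wg, partition, path) {
  e <- wg$edges
  e$betweenness <- edge_betweenness(wg)
  e$community_i <- partition$membership[e$node_i]
  e$community_j <- partition$membership[e$node_j]
  ce <- partition$critical_edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e$critical_flag <- key(e$node_i, e$node_j) %in% key(ce$node_i, ce$node_j)
  utils::write.table(e[, c("node_i", "node_j", "occupancy", "C", "w",
                           "betweenness", "community_i", "community_j",
                           "critical_flag")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
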