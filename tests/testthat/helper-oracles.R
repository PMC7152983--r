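# Independent brute-force oracles used by the test suite. These deliberately
# avoid the package's own code paths (and igraph) so that agreement is a
# genuine two-route check.

# ---- shortest-path machinery: Floyd-Warshall with path counting ----------

fw_paths <- function(n, edges, w) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sig <- matrix(0, n, n)
  diag(sig) <- 1
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (w[k] < d[i, j] - 1e-12) {
      d[i, j] <- d[j, i] <- w[k]
      sig[i, j] <- sig[j, i] <- 1
    } else if (abs(w[k] - d[i, j]) <= 1e-12) {
      sig[i, j] <- sig[j, i] <- sig[i, j] + 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || i == k || j == k) next
        alt <- d[i, k] + d[k, j]
        if (!is.finite(alt)) next
        if (alt < d[i, j] - 1e-12) {
          d[i, j] <- alt
          sig[i, j] <- sig[i, k] * sig[k, j]
        } else if (abs(alt - d[i, j]) <= 1e-12) {
          sig[i, j] <- sig[i, j] + sig[i, k] * sig[k, j]
        }
      }
    }
  }
  list(d = d, sig = sig)
}

# edge betweenness: sum over unordered pairs s<t of the fraction of
# shortest s-t paths that traverse the edge
oracle_edge_betweenness <- function(n, edges, w) {
  fp <- fw_paths(n, edges, w)
  bet <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(fp$d[s, t]) || fp$sig[s, t] == 0) next
        thr <- 0
        if (abs(fp$d[s, u] + w[k] + fp$d[v, t] - fp$d[s, t]) <= 1e-9)
          thr <- thr + fp$sig[s, u] * fp$sig[v, t]
        if (abs(fp$d[s, v] + w[k] + fp$d[u, t] - fp$d[s, t]) <= 1e-9)
          thr <- thr + fp$sig[s, v] * fp$sig[u, t]
        bet[k] <- bet[k] + thr / fp$sig[s, t]
      }
    }
  }
  bet
}

# connected components by BFS on an adjacency list
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (comp[u] == 0L) {
        comp[u] <- cur
        queue <- c(queue, u)
      }
    }
  }
  comp
}

# weighted modularity, direct formula (strengths as affinities)
oracle_modularity <- function(n, edges, strength, membership) {
  m <- sum(strength)
  if (m == 0) return(0)
  deg <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + strength[k]
    deg[edges[k, 2]] <- deg[edges[k, 2]] + strength[k]
  }
  q <- 0
  for (c in unique(membership)) {
    inc <- membership[edges[, 1]] == c & membership[edges[, 2]] == c
    lc <- sum(strength[inc])
    dc <- sum(deg[membership == c])
    q <- q + lc / m - (dc / (2 * m))^2
  }
  q
}

# full Girvan-Newman replay: remove max-betweenness edge (lexicographic tie
# rule on node labels 1..n), track the best-modularity partition
oracle_girvan_newman <- function(n, edges, w, strength) {
  alive <- rep(TRUE, nrow(edges))
  best <- oracle_components(n, edges)
  bestq <- oracle_modularity(n, edges, strength, best)
  while (any(alive)) {
    idx <- which(alive)
    bet <- oracle_edge_betweenness(n, edges[idx, , drop = FALSE], w[idx])
    cand <- idx[bet >= max(bet) - 1e-12]
    key <- apply(edges[cand, , drop = FALSE], 1, function(p)
      sprintf("%09d-%09d", min(p), max(p)))
    kill <- cand[order(key)][1]
    alive[kill] <- FALSE
    memb <- oracle_components(n, edges[alive, , drop = FALSE])
    q <- oracle_modularity(n, edges, strength, memb)
    if (q > bestq + 1e-12) {
      bestq <- q
      best <- memb
    }
  }
  list(membership = best, modularity = bestq)
}

# ---- naive average-linkage agglomeration --------------------------------

# maintains pairwise inter-cluster distance *sums*; merges while the
# minimum average distance is <= cutoff
oracle_average_linkage <- function(d, cutoff) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  S <- d  # sums of pairwise distances between clusters
  repeat {
    k <- length(members)
    if (k == 1L) break
    sizes <- lengths(members)
    avg <- S / outer(sizes, sizes)
    diag(avg) <- Inf
    mn <- min(avg)
    if (mn > cutoff) break
    ij <- which(avg == mn, arr.ind = TRUE)[1, ]
    a <- min(ij); b <- max(ij)
    members[[a]] <- c(members[[a]], members[[b]])
    newS <- S[, a] + S[, b]
    S[a, ] <- newS
    S[, a] <- newS
    S[a, a] <- 0
    members[[b]] <- NULL
    S <- S[-b, -b, drop = FALSE]
  }
  memb <- integer(n)
  for (c in seq_along(members)) memb[members[[c]]] <- c
  memb
}

# ---- rotation brute force ------------------------------------------------

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# minimum RMSD over rotations by coarse grid + Nelder-Mead refinement
oracle_min_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  X <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((M %*% R - X)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  bgrid <- seq(0, pi, length.out = 7)
  best <- Inf
  bestp <- c(0, 0, 0)
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) {
      best <- v
      bestp <- c(a, b, c)
    }
  }
  o <- stats::optim(bestp, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  min(best, o$value)
}

# ---- misc helpers --------------------------------------------------------

# package internals used to build fixtures
apply_rigid <- trajcomm:::apply_rigid
random_rotation <- trajcomm:::random_rotation

# ensemble whose displacements are confined to a single 3N direction with a
# smooth per-residue amplitude profile (CA displacements along x)
planted_direction_ensemble <- function(n_res = 12, n_frames = 400,
                                       seed = 41) {
  ref <- trajcomm::make_reference(n_res, "chain")
  amp <- sin(seq_len(n_res) / n_res * pi) + 0.2
  v <- as.vector(t(cbind(amp, 0, 0)))
  v <- v / sqrt(sum(v^2))
  ri <- trajcomm:::atom_res_index(ref)
  trajcomm:::local_seed(seed, {
    a <- stats::rnorm(n_frames, sd = 1.5)
    xyz <- matrix(rep(ref$xyz, n_frames), nrow = n_frames, byrow = TRUE)
    for (f in seq_len(n_frames)) {
      dr <- matrix(a[f] * v, ncol = 3, byrow = TRUE)
      dxyz <- dr[ri, , drop = FALSE]
      xyz[f, ] <- xyz[f, ] + as.vector(t(dxyz))
    }
    list(traj = trajcomm::new_traj(ref$atoms, xyz), v = v, amp = amp)
  })
}

# canonical form of a partition for set-wise comparison
canonical_partition <- function(membership) {
  groups <- split(seq_along(membership), membership)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, 1L, 1))])
}

same_partition <- function(m1, m2) {
  identical(canonical_partition(m1), canonical_partition(m2))
}

# random connected graph on n nodes with uniform random weights
random_connected_graph <- function(n, p = 0.5, wmin = 0.2, wmax = 2) {
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    if (nrow(edges) >= 1 &&
        max(oracle_components(n, edges)) == 1L) break
  }
  list(edges = edges, w = stats::runif(nrow(edges), wmin, wmax))
}

# wrap a raw edge list into the package's weighted_graph structure
wg_from_edges <- function(n, edges, w) {
  nodes <- sprintf("N%03d", seq_len(n))
  ed <- data.frame(i = edges[, 1], j = edges[, 2],
                   node_i = nodes[edges[, 1]], node_j = nodes[edges[, 2]],
                   occupancy = 1, C = exp(-w), absC = exp(-w), w = w,
                   stringsAsFactors = FALSE)
  structure(list(nodes = nodes, kind = rep("protein", n), edges = ed),
            class = "weighted_graph")
}

membership_ints <- function(part, nodes) {
  unname(part$membership[nodes])
}

# independent geometric scan for protein-ligand hydrophobic contacts and
# hydrogen bonds on tiny fixtures
oracle_scan_events <- function(x) {
  a <- x$atoms
  el <- toupper(a$element)
  co <- trajcomm::frame_coords(x, 1L)
  n <- nrow(a)
  dmat <- as.matrix(stats::dist(co))
  nbrs <- function(i, lim) which(dmat[i, ] <= lim & seq_len(n) != i)
  apolar <- function(i) el[i] == "C" &&
    !any(el[nbrs(i, 1.7)] %in% c("N", "O", "S"))
  ev <- NULL
  for (f in seq_len(trajcomm::n_frames(x))) {
    cf <- trajcomm::frame_coords(x, f)
    df <- as.matrix(stats::dist(cf))
    for (i in which(!a$is_ligand & !a$is_water)) {
      for (j in which(a$is_ligand)) {
        if (el[i] == "C" && el[j] == "C" && apolar(i) && apolar(j) &&
            df[i, j] <= 3.6)
          ev <- rbind(ev, data.frame(frame = f, i = i, j = j,
                                     category = "hydrophobic"))
      }
    }
    # hydrogen bonds, both directions
    hs <- which(el == "H")
    for (h in hs) {
      d_heavy <- nbrs(h, 1.2)
      d_heavy <- d_heavy[el[d_heavy] %in% c("N", "O", "S")]
      if (length(d_heavy) == 0) next
      don <- d_heavy[which.min(dmat[h, d_heavy])]
      for (acc in which(el %in% c("N", "O"))) {
        if (acc == don) next
        same_side <- a$is_ligand[acc] == a$is_ligand[don]
        if (same_side || a$is_water[acc] || a$is_water[don]) next
        if (df[h, acc] > 2.5) next
        u <- cf[don, ] - cf[h, ]; v <- cf[acc, ] - cf[h, ]
        ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
        if (ang < 120) next
        accnb <- nbrs(acc, 1.7)
        accnb <- accnb[el[accnb] != "H"]
        if (length(accnb)) {
          u2 <- cf[accnb[1], ] - cf[acc, ]; v2 <- cf[h, ] - cf[acc, ]
          ang2 <- acos(sum(u2 * v2) / sqrt(sum(u2^2) * sum(v2^2))) * 180 / pi
          if (ang2 < 90) next
        }
        ev <- rbind(ev, data.frame(frame = f, i = if (a$is_ligand[don]) acc
                                   else don,
                                   j = if (a$is_ligand[don]) don else acc,
                                   category = "hbond"))
      }
    }
  }
  unique(ev)
}
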