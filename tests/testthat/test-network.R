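test_that("contact occupancy honours the inclusive 'at least' threshold", {
  # two residues 3 A apart in 74 of 100 frames, 6 A apart otherwise
  ref <- make_reference(4, "chain")
  near <- ref$xyz
  co <- frame_coords(ref, 1)
  far <- co
  far[7:8, 2] <- far[7:8, 2] + 10  # push residue 4 away
  xyz <- rbind(matrix(rep(near, 74), nrow = 74, byrow = TRUE),
               matrix(rep(as.vector(t(far)), 26), nrow = 26, byrow = TRUE))
  x <- new_traj(ref$atoms, xyz)
  # residues 3-4 are 3.8 A apart when near; 74% occupancy fails at 0.75
  g74 <- build_contact_graph(x, cutoff = 4.5, min_occupancy = 0.75,
                             neighbor_exclusion = 0)
  has_34 <- any(g74$edges$i == 3 & g74$edges$j == 4)
  expect_false(has_34)
  g74b <- build_contact_graph(x, cutoff = 4.5, min_occupancy = 0.74,
                              neighbor_exclusion = 0)
  e34 <- g74b$edges[g74b$edges$i == 3 & g74b$edges$j == 4, ]
  expect_equal(e34$occupancy, 0.74)
  # a pair in contact in every frame has occupancy exactly 1
  e12 <- g74b$edges[g74b$edges$i == 1 & g74b$edges$j == 2, ]
  expect_equal(e12$occupancy, 1.0)
})

test_that("static edge set equals a brute-force all-pairs distance scan", {
  ref <- make_reference(10, "helix", ligand = TRUE)
  x <- new_traj(ref$atoms, ref$xyz[rep(1, 3), ])
  g <- build_contact_graph(x, cutoff = 6, min_occupancy = 0.75,
                           neighbor_exclusion = 2)
  co <- frame_coords(ref, 1)
  ri <- trajcomm:::atom_res_index(ref)
  nres <- max(ri)
  want <- NULL
  for (i in seq_len(nres - 1)) {
    for (j in (i + 1):nres) {
      if (j <= 10 && abs(i - j) <= 2) next  # protein sequence neighbours
      dmin <- min(as.matrix(stats::dist(co))[ri == i, ri == j])
      if (dmin <= 6) want <- rbind(want, c(i, j))
    }
  }
  got <- as.matrix(g$edges[, c("i", "j")])
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               want[order(want[, 1], want[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("correlation matrix: identical, opposed and planted-block motion", {
  withr::local_seed(31)
  n <- 500
  z <- matrix(rnorm(3 * n), n, 3)
  delta <- cbind(z, z, -z)  # node2 = node1, node3 = -node1
  delta <- sweep(delta, 2, colMeans(delta))
  nt <- structure(list(ids = c("A", "B", "C"), kind = rep("protein", 3),
                       delta = delta, mean = rep(0, 9),
                       res_index = 1:3), class = "node_traj")
  C <- correlation_matrix(nt)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C["A", "B"], 1, tolerance = 1e-10)
  expect_equal(C["A", "C"], -1, tolerance = 1e-10)
  expect_true(isSymmetric(C))

  # planted blocks: intra-block C = rho, inter-block C = 0
  ref <- make_reference(24, "chain")
  blocks <- list(list(members = 1:8, rho = 0.6),
                 list(members = 9:16, rho = 0.6))
  ens <- sample_correlated_ensemble(ref, 5000, sigma = 0.5,
                                    blocks = blocks, seed = 32)
  C2 <- correlation_matrix(node_trajectory(ens, "none", fit = FALSE))
  intra <- c(C2[1:8, 1:8][upper.tri(diag(8))],
             C2[9:16, 9:16][upper.tri(diag(8))])
  inter <- C2[1:8, 9:16]
  expect_equal(mean(intra), 0.6, tolerance = 0.03)
  expect_lt(max(abs(intra - 0.6)), 0.1)
  expect_lt(max(abs(inter)), 0.1)

  # zero-variance node is reported by id
  bad <- nt
  bad$delta[, 4:6] <- 0
  expect_error(correlation_matrix(bad), "zero-variance.*B")
})

test_that("correlation matrix is symmetric with unit diagonal on random ensembles", {
  withr::local_seed(33)
  for (rep in 1:5) {
    ens <- sample_correlated_ensemble(make_reference(8, "chain"), 50,
                                      sigma = runif(1, 0.2, 1),
                                      seed = sample.int(1000, 1))
    C <- correlation_matrix(node_trajectory(ens, "none", fit = FALSE))
    expect_true(isSymmetric(C))
    expect_equal(diag(C), rep(1, 8), ignore_attr = TRUE)
    expect_true(all(abs(C) <= 1 + 1e-12))
  }
})

test_that("edge weights are -ln|C|, floored, and monotone in |C|", {
  g <- structure(list(nodes = c("A", "B", "C", "D"),
                      kind = rep("protein", 4),
                      edges = data.frame(
                        i = c(1, 1, 1), j = c(2, 3, 4),
                        node_i = "A", node_j = c("B", "C", "D"),
                        occupancy = 1)), class = "contact_graph")
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 1
  C[1, 3] <- C[3, 1] <- exp(-1)
  C[1, 4] <- C[4, 1] <- -0.5
  dimnames(C) <- list(g$nodes, g$nodes)
  wg <- weight_edges(g, C)
  expect_equal(wg$edges$w, c(0, 1, -log(0.5)), tolerance = 1e-12)
  expect_true(all(wg$edges$w >= 0))
  # monotone: larger |C| -> smaller w
  ord <- order(abs(wg$edges$C), decreasing = TRUE)
  expect_true(all(diff(wg$edges$w[ord]) >= 0))
  # flooring keeps weights finite
  C[1, 2] <- C[2, 1] <- 0
  expect_message(wg0 <- weight_edges(g, C), "floored")
  expect_true(all(is.finite(wg0$edges$w)))
})

test_that("edge betweenness matches closed forms and the brute-force oracle", {
  # path A-B-C with unit weights: each edge carries its side-product counts
  wg <- wg_from_edges(3, rbind(c(1, 2), c(2, 3)), c(1, 1))
  expect_equal(edge_betweenness(wg), c(2, 2))

  # bridge between two triangles is strictly maximal
  ed <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
              c(3, 4))
  wgb <- wg_from_edges(6, ed, rep(1, 7))
  bet <- edge_betweenness(wgb)
  expect_equal(which.max(bet), 7L)
  expect_gt(bet[7], max(bet[-7]))

  withr::local_seed(34)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    gr <- random_connected_graph(n)
    wg <- wg_from_edges(n, gr$edges, gr$w)
    expect_equal(edge_betweenness(wg),
                 oracle_edge_betweenness(n, gr$edges, gr$w),
                 tolerance = 1e-8)
  }
})

test_that("girvan-newman: cliques, bridges, and the exhaustive 2-partition", {
  # complete K5 with uniform weights stays one community
  pairs <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  wg5 <- wg_from_edges(5, pairs, rep(0.5, nrow(pairs)))
  p5 <- girvan_newman(wg5)
  expect_equal(length(p5$communities), 1L)
  expect_equal(length(p5$critical_nodes), 0L)

  # two K5 cliques + bridge: split at the bridge; equals the exhaustive
  # best 2-partition by modularity
  ed <- NULL
  for (i in 1:4) for (j in (i + 1):5) ed <- rbind(ed, c(i, j), c(i + 5, j + 5))
  ed <- rbind(ed, c(5, 6))
  w <- rep(0.5, nrow(ed))
  wg <- wg_from_edges(10, ed, w)
  p <- girvan_newman(wg)
  expect_equal(length(p$communities), 2L)
  got <- membership_ints(p, wg$nodes)
  expect_true(same_partition(got, rep(1:2, each = 5)))

  # exhaustive scan over all 2^9 bipartitions
  strength <- exp(-w)
  best_q <- -Inf
  for (mask in 0:(2^9 - 1)) {
    memb <- c(1L, as.integer(intToBits(mask)[1:9]) + 1L)
    q <- oracle_modularity(10, ed, strength, memb)
    if (q > best_q) {
      best_q <- q
      best_memb <- memb
    }
  }
  expect_true(same_partition(got, best_memb))
  expect_equal(p$modularity, best_q, tolerance = 1e-10)
})

test_that("girvan-newman partitions match the brute-force replay oracle", {
  withr::local_seed(35)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    gr <- random_connected_graph(n)
    wg <- wg_from_edges(n, gr$edges, gr$w)
    p <- girvan_newman(wg)
    o <- oracle_girvan_newman(n, gr$edges, gr$w, exp(-gr$w))
    expect_true(same_partition(membership_ints(p, wg$nodes), o$membership))
    expect_equal(p$modularity, o$modularity, tolerance = 1e-9)
  }
})

test_that("community detection is invariant to node relabeling", {
  withr::local_seed(36)
  gr <- random_connected_graph(7)
  wg <- wg_from_edges(7, gr$edges, gr$w)
  p1 <- girvan_newman(wg)
  perm <- sample(7)
  ed2 <- cbind(perm[gr$edges[, 1]], perm[gr$edges[, 2]])
  wg2 <- wg_from_edges(7, ed2, gr$w)
  p2 <- girvan_newman(wg2)
  m1 <- membership_ints(p1, wg$nodes)
  m2 <- membership_ints(p2, wg2$nodes)
  expect_true(same_partition(m1, m2[perm]))
})

test_that("recovered modularity is at least the planted partition's", {
  withr::local_seed(37)
  for (rep in 1:5) {
    # two K6 communities with random intra weights joined by 1-2 bridges:
    # the removal sequence reaches the planted split, so the maximised
    # modularity cannot fall below the planted partition's
    n <- 12
    truth <- rep(1:2, each = 6)
    ed <- NULL
    for (i in 1:5) for (j in (i + 1):6) ed <- rbind(ed, c(i, j),
                                                    c(i + 6, j + 6))
    n_bridge <- sample(1:2, 1)
    ed <- rbind(ed, c(6, 7))
    if (n_bridge == 2) ed <- rbind(ed, c(1, 12))
    w <- runif(nrow(ed), 0.3, 0.7)
    wg <- wg_from_edges(n, ed, w)
    p <- girvan_newman(wg)
    expect_gte(p$modularity,
               oracle_modularity(n, ed, exp(-w), truth) - 1e-9)
    expect_true(same_partition(membership_ints(p, wg$nodes), truth))
  }
})

test_that("critical elements are the strongest inter-community connectors", {
  # two triangles joined by two parallel bridges of different betweenness
  ed <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
              c(3, 4), c(1, 6))
  w <- c(rep(0.2, 6), 0.3, 1.5)  # bridge 3-4 is much shorter: all traffic
  wg <- wg_from_edges(6, ed, w)
  p <- girvan_newman(wg)
  expect_equal(length(p$communities), 2L)
  expect_equal(nrow(p$critical_edges), 1L)
  expect_setequal(c(p$critical_edges$node_i, p$critical_edges$node_j),
                  c("N003", "N004"))
  expect_setequal(p$critical_nodes, c("N003", "N004"))
  bet <- edge_betweenness(wg)
  expect_equal(bet[7], max(bet[7:8]))

  # single community -> empty critical sets
  pairs <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  wg1 <- wg_from_edges(4, pairs, rep(0.4, nrow(pairs)))
  p1 <- girvan_newman(wg1)
  crit <- critical_elements(p1, wg1)
  expect_equal(length(crit$critical_nodes), 0L)
  expect_equal(nrow(crit$critical_edges), 0L)
})

test_that("planted domains are recovered from correlated ensembles", {
  ref <- make_domain_reference(3, 8)
  blocks <- list(list(members = 1:8, rho = 0.6),
                 list(members = 9:16, rho = 0.6),
                 list(members = 17:24, rho = 0.6))
  hits <- 0
  for (s in 1:5) {
    ens <- sample_correlated_ensemble(ref, 2000, sigma = 0.5,
                                      blocks = blocks, seed = 100 + s)
    g <- build_contact_graph(ens, cutoff = 4.5, min_occupancy = 0.75,
                             neighbor_exclusion = 0)
    nt <- node_trajectory(ens, "none", fit = FALSE)
    p <- girvan_newman(weight_edges(g, correlation_matrix(nt)))
    sets <- lapply(p$communities, function(cm)
      sort(as.integer(sub("ALA_", "", cm))))
    truth <- list(1:8, 9:16, 17:24)
    if (length(sets) == 3 &&
        all(vapply(truth, function(t)
          any(vapply(sets, identical, TRUE, t)), TRUE)))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})
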