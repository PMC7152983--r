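fix_mode_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

new_mode_set <- function(values, vectors, n_modes, origin, ids,
                         extra = list()) {
  structure(c(list(values = values, vectors = vectors, n_modes = n_modes,
                   origin = origin, ids = ids), extra),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d node(s), %d mode(s) retained\n",
              x$origin, length(x$ids), x$n_modes))
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Covariance principal component analysis of node displacements
#'
#' Eigendecomposition of the 3N x 3N covariance of the fitted, mean-removed
#' node displacement trajectory (denominator n, matching the RMSF
#' convention). Eigenvalues are in square Angstrom, descending; eigenvectors
#' are orthonormal 3N-vectors with the sign fixed so the largest-magnitude
#' component is positive.
#'
#' @param nt a [node_trajectory()] result
#' @param n_modes number of eigenvectors to retain (default 5, the usual
#'   essential-dynamics depth); `NULL` keeps all 3N
#' @return a `mode_set` with `values` (all 3N eigenvalues, descending),
#'   `vectors` (3N x n_modes), `origin = "pca"`
#' @export
covariance_pca <- function(nt, n_modes = 5L) {
  D <- nt$delta
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 frames")
  p <- ncol(D)
  if (n <= p)
    warning("fewer frames (", n, ") than coordinates (", p,
            "); trailing eigenvalues are sampling zeros")
  cv <- crossprod(D) / n
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (is.null(n_modes)) n_modes <- p
  n_modes <- min(n_modes, p)
  V <- fix_mode_signs(eg$vectors[, seq_len(n_modes), drop = FALSE])
  new_mode_set(vals, V, n_modes, "pca", nt$ids,
               extra = list(trace = sum(diag(cv))))
}

#' Per-node RMSF contribution of one mode
#'
#' For PCA mode k the contribution of node i is sqrt(lambda_k |v_k,i|^2)
#' where v_k,i is the mode's 3-vector at node i; summing the squared
#' contributions over all modes recovers the total squared RMSF. For ANM
#' modes the thermal amplitude is proportional to 1/lambda, so the
#' contribution is sqrt(|v_k,i|^2 / lambda_k) (arbitrary units, gamma = 1).
#'
#' @param ms a `mode_set`
#' @param k mode index (1 = leading)
#' @return data.frame with columns `key`, `rmsf`
#' @export
mode_rmsf <- function(ms, k = 1L) {
  if (k < 1L || k > ms$n_modes) stop("mode index out of range")
  v <- ms$vectors[, k]
  per_node <- rowSums(matrix(v^2, ncol = 3L, byrow = TRUE))
  lam <- if (ms$origin == "anm") {
    lk <- ms$values[k]
    if (lk <= 0) stop("zero-frequency mode has no finite amplitude")
    1 / lk
  } else {
    ms$values[k]
  }
  data.frame(key = ms$ids, rmsf = sqrt(lam * per_node),
             stringsAsFactors = FALSE)
}

#' Block-consistency PCA
#'
#' Splits the trajectory into `n_blocks` contiguous blocks, runs
#' [covariance_pca()] per block (each block re-centred), and reports the
#' absolute inner products between corresponding modes of consecutive
#' blocks - a convergence check: a stationary, well-sampled ensemble gives
#' overlaps near 1, while unconverged sampling gives overlaps near the
#' random-vector expectation of about 1/sqrt(3N).
#'
#' @param nt a [node_trajectory()] result
#' @param n_blocks number of contiguous blocks (default 2)
#' @param n_modes modes per block
#' @return list with `blocks` (list of `mode_set`) and `overlaps` (matrix
#'   n_modes x (n_blocks - 1), entry `[k, b]` = |<v_k(b), v_k(b+1)>|)
#' @export
block_pca <- function(nt, n_blocks = 2L, n_modes = 5L) {
  n <- nrow(nt$delta)
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  bounds <- floor(seq(0, n, length.out = n_blocks + 1L))
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- (bounds[b] + 1L):bounds[b + 1L]
    if (length(rows) < 2L) stop("block ", b, " has fewer than 2 frames")
    sub <- nt
    sub$delta <- sweep(nt$delta[rows, , drop = FALSE], 2,
                       colMeans(nt$delta[rows, , drop = FALSE]))
    blocks[[b]] <- covariance_pca(sub, n_modes)
  }
  overlaps <- NULL
  if (n_blocks > 1L) {
    overlaps <- sapply(seq_len(n_blocks - 1L), function(b)
      abs(colSums(blocks[[b]]$vectors * blocks[[b + 1L]]$vectors)))
    overlaps <- matrix(overlaps, nrow = blocks[[1]]$n_modes)
  }
  list(blocks = blocks, overlaps = overlaps)
}

#' Anisotropic network model normal modes
#'
#' Builds the standard ANM Hessian on the selected atoms of a single
#' structure: every pair within `cutoff` contributes a harmonic term with
#' uniform spring constant `gamma`, giving 3x3 super-elements
#' -gamma d d^T / |d|^2. Requires a connected contact network. Exactly six
#' zero eigenvalues correspond to rigid-body motion and are excluded from
#' the reported internal modes (eigenvalues ascending).
#'
#' @param x a `traj` (first frame used) or an N x 3 coordinate matrix
#' @param selection atoms to use when `x` is a `traj`
#'   (default protein C-alpha)
#' @param cutoff interaction cutoff in Angstrom (default 15, the common
#'   C-alpha ANM choice)
#' @param gamma uniform spring constant (default 1; rescales eigenvalues
#'   only)
#' @return a `mode_set` with `values`/`vectors` of the internal modes
#'   (ascending), plus `all_values`, `n_zero` and the `hessian`
#' @export
anm_modes <- function(x, selection = "name CA and protein", cutoff = 15,
                      gamma = 1.0) {
  if (inherits(x, "traj")) {
    sel <- resolve_selection(x, selection)
    co <- frame_coords(x, 1L, sel$indices)
    ids <- fluct_keys(x, sel$indices)
  } else {
    co <- as.matrix(x)
    ids <- as.character(seq_len(nrow(co)))
  }
  N <- nrow(co)
  if (N < 3L) stop("need at least 3 nodes")
  d2 <- outer(rowSums(co^2), rowSums(co^2), "+") - 2 * tcrossprod(co)
  adj <- d2 <= cutoff^2 & d2 > 1e-12
  gcomp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (gcomp$no > 1L)
    stop("contact network is disconnected at cutoff ", cutoff, ": ",
         gcomp$no, " components of sizes ",
         paste(gcomp$csize, collapse = ", "))
  H <- matrix(0, 3L * N, 3L * N)
  for (i in seq_len(N - 1L)) {
    for (j in which(adj[i, ] & seq_len(N) > i)) {
      dv <- co[i, ] - co[j, ]
      blk <- gamma * tcrossprod(dv) / sum(dv^2)
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
    }
  }
  eg <- eigen(H, symmetric = TRUE)
  vals <- rev(eg$values)            # ascending
  vecs <- eg$vectors[, rev(seq_len(3 * N)), drop = FALSE]
  tol <- 1e-8 * max(vals)
  n_zero <- sum(vals < tol)
  internal <- (n_zero + 1L):(3L * N)
  V <- fix_mode_signs(vecs[, internal, drop = FALSE])
  new_mode_set(vals[internal], V, length(internal), "anm", ids,
               extra = list(all_values = vals, n_zero = n_zero,
                            hessian = H))
}
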