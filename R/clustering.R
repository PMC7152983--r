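#' Pairwise frame RMSD matrix
#'
#' d(i, j) is the RMSD between frames i and j measured on
#' `measure_selection` after a pairwise Kabsch fit on `fit_selection`.
#' Frames are subsampled with a stride chosen so that at most `max_frames`
#' frames enter the O(n^2) matrix.
#'
#' @param x a `traj` with >= 2 frames
#' @param fit_selection,measure_selection selections; measure defaults to fit
#' @param max_frames cap on the number of frames entering the matrix
#' @param stride explicit subsampling stride (overrides `max_frames`)
#' @return object of class `frame_dist`: list with `d` (symmetric matrix,
#'   Angstrom, zero diagonal), `frames` (original frame ids of the rows) and
#'   `times`
#' @export
pairwise_rmsd_matrix <- function(x, fit_selection = "name CA",
                                 measure_selection = fit_selection,
                                 max_frames = 2000L, stride = NULL) {
  if (n_frames(x) < 2L) stop("need at least 2 frames")
  if (is.null(stride)) stride <- ceiling(n_frames(x) / max_frames)
  frames <- seq(1L, n_frames(x), by = stride)
  fs <- resolve_selection(x, fit_selection)
  ms <- resolve_selection(x, measure_selection)
  same <- identical(fs$indices, ms$indices)
  n <- length(frames)
  fitc <- lapply(frames, function(f) frame_coords(x, f, fs$indices))
  measc <- if (same) fitc else
    lapply(frames, function(f) frame_coords(x, f, ms$indices))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      fit <- kabsch_fit(fitc[[j]], fitc[[i]])
      d[i, j] <- d[j, i] <- if (same) fit$rmsd else
        rmsd_points(apply_superposition(measc[[j]], fit), measc[[i]])
    }
  }
  structure(list(d = d, frames = frames, times = x$times[frames]),
            class = "frame_dist")
}

as_dist_matrix <- function(m) {
  if (inherits(m, "frame_dist")) return(m$d)
  as.matrix(m)
}

#' Agglomerative average-linkage clustering of frames
#'
#' Merges clusters by average inter-cluster distance, stopping when the
#' minimum average distance exceeds `merge_cutoff` (all merges at height
#' <= cutoff are applied). Clusters are ordered by descending population;
#' each cluster's representative is the centroid frame - the member with the
#' most neighbours within `neighbor_cutoff` ([centroid_frame()]).
#'
#' @param m a [pairwise_rmsd_matrix()] result or a symmetric distance matrix
#' @param merge_cutoff merging distance cutoff in Angstrom (> 0);
#'   2.5 Angstrom is the conventional cutoff for pose clustering
#' @param neighbor_cutoff neighbour cutoff for centroid selection, defaults
#'   to `merge_cutoff`
#' @return object of class `cluster_summary`: list with `clusters`
#'   (data.frame cluster_id, n_members, population_percent, centroid_frame),
#'   `members` (list of member frame ids), `cutoff`, `n_frames`
#' @export
average_linkage <- function(m, merge_cutoff = 2.5,
                            neighbor_cutoff = merge_cutoff) {
  if (merge_cutoff <= 0) stop("merge_cutoff must be positive")
  fd <- if (inherits(m, "frame_dist")) m else
    structure(list(d = as.matrix(m), frames = seq_len(nrow(as.matrix(m)))),
              class = "frame_dist")
  d <- fd$d
  n <- nrow(d)
  memb <- if (n == 1L) 1L else {
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    stats::cutree(tree, h = merge_cutoff)
  }
  groups <- split(seq_len(n), memb)
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, min, 1L))
  groups <- groups[ord]
  members <- lapply(groups, function(g) fd$frames[g])
  centroids <- vapply(groups, function(g)
    fd$frames[centroid_frame(g, d, neighbor_cutoff)], numeric(1))
  clusters <- data.frame(
    cluster_id = seq_along(groups),
    n_members = lengths(groups),
    population_percent = 100 * lengths(groups) / n,
    centroid_frame = as.integer(centroids))
  rownames(clusters) <- NULL
  names(members) <- NULL
  structure(list(clusters = clusters, members = members,
                 cutoff = merge_cutoff, n_frames = n),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: %d cluster(s) over %d frames (cutoff %.2f A)\n",
              nrow(x$clusters), x$n_frames, x$cutoff))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Centroid frame of a cluster
#'
#' The member with the largest number of cluster members within
#' `neighbor_cutoff`; ties are broken by the smallest frame index.
#'
#' @param members member indices into the distance matrix
#' @param d symmetric distance matrix (or `frame_dist`)
#' @param neighbor_cutoff neighbour distance cutoff in Angstrom
#' @return the centroid member index
#' @export
centroid_frame <- function(members, d, neighbor_cutoff = 2.5) {
  if (length(members) == 0L) stop("empty cluster")
  d <- as_dist_matrix(d)
  members <- sort(as.integer(members))
  counts <- rowSums(d[members, members, drop = FALSE] <= neighbor_cutoff) - 1L
  members[which.max(counts)]
}

#' Retain only major clusters
#'
#' Keeps clusters whose population is strictly greater than `threshold`
#' (fraction of all frames); population percentages of the retained clusters
#' are kept as-is (they describe the full partition).
#'
#' @param summary a [average_linkage()] result
#' @param threshold population fraction, default 0.01 (> 1 percent)
#' @return a filtered `cluster_summary`
#' @export
report_major_clusters <- function(summary, threshold = 0.01) {
  keep <- summary$clusters$population_percent > 100 * threshold
  if (!any(keep)) warning("no cluster exceeds the population threshold")
  out <- summary
  out$clusters <- summary$clusters[keep, , drop = FALSE]
  rownames(out$clusters) <- NULL
  out$members <- summary$members[keep]
  out
}

#' Write a cluster report CSV and centroid structures
#'
#' @param summary a `cluster_summary`
#' @param path output CSV path
#' @param x optional `traj`; when given, each cluster centroid is written as
#'   a single-model PDB next to `path`
#' @return `path`, invisibly
#' @export
write_cluster_report <- function(summary, path, x = NULL) {
  utils::write.csv(summary$clusters, path, row.names = FALSE)
  if (!is.null(x)) {
    base <- sub("\\.csv$", "", path)
    for (k in seq_len(nrow(summary$clusters))) {
      write_pdb(x, sprintf("%s_centroid_%d.pdb", base, k),
                frames = summary$clusters$centroid_frame[k])
    }
  }
  invisible(path)
}
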