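#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' least-squares deviation of `mobile` onto `reference`, via SVD of the
#' cross-covariance of the centred point sets.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, congruent rows
#' @return object of class `superposition`: list with `rotation` (3x3,
#'   orthonormal, det +1), `translation` (length-3, Angstrom) such that the
#'   fitted coordinates are `mobile %*% rotation + translation`, and `rmsd`,
#'   the post-fit RMSD in Angstrom.
#' @export
kabsch_fit <- function(mobile, reference) {
  M <- as.matrix(mobile)
  X <- as.matrix(reference)
  if (!all(dim(M) == dim(X)) || ncol(M) != 3L)
    stop("mobile and reference must be congruent N x 3 matrices")
  if (nrow(M) < 3L) stop("superposition needs at least 3 points")
  mc <- colMeans(M)
  xc <- colMeans(X)
  Mc <- sweep(M, 2, mc)
  Xc <- sweep(X, 2, xc)
  # collinear / degenerate point sets have rank < 2
  dm <- svd(Mc, nu = 0, nv = 0)$d
  if (dm[2] <= 1e-8 * max(dm[1], 1e-12))
    stop("degenerate (collinear) point set: rotation is not determined")
  s <- svd(crossprod(Mc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Mc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Xc)^2)))
  structure(list(rotation = R,
                 translation = as.vector(xc - mc %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords N x 3 matrix
#' @param fit a [kabsch_fit()] result
#' @return transformed N x 3 matrix
#' @export
apply_superposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

resolve_selection <- function(x, sel) {
  if (inherits(sel, "atom_selection")) return(sel)
  if (is.character(sel)) return(select_atoms(x, sel))
  if (is.numeric(sel))
    return(structure(list(indices = as.integer(sel), label = "indices"),
                     class = "atom_selection"))
  stop("selection must be an atom_selection, expression string or indices")
}

reference_coords <- function(reference, x) {
  if (inherits(reference, "traj")) return(reference)
  stop("reference must be a traj (its first frame is used)")
}

#' Per-frame RMSD after superposition
#'
#' Each frame is fitted on `fit_selection` to the reference structure and the
#' RMSD is measured on `measure_selection` (ligand RMSD uses a protein fit
#' and a ligand measure; pass `measure_selection = fit_selection` for the
#' usual C-alpha RMSD).
#'
#' @param x a `traj`
#' @param reference a `traj` whose first frame is the reference (default:
#'   first frame of `x`); must share the topology of `x`
#' @param fit_selection,measure_selection selections (expression string,
#'   `atom_selection` or atom indices); `measure_selection` defaults to
#'   `fit_selection`
#' @return data.frame with columns `frame`, `time_ns`, `rmsd`
#' @export
rmsd_series <- function(x, reference = NULL, fit_selection = "name CA",
                        measure_selection = fit_selection) {
  fs <- resolve_selection(x, fit_selection)
  ms <- resolve_selection(x, measure_selection)
  if (length(fs$indices) < 3L) stop("fit selection has fewer than 3 atoms")
  if (length(ms$indices) == 0L) stop("empty measure selection")
  ref <- if (is.null(reference)) x else reference_coords(reference, x)
  if (3L * max(fs$indices, ms$indices) > ncol(ref$xyz))
    stop("selection does not fit the reference topology")
  ref_fit <- frame_coords(ref, 1L, fs$indices)
  ref_meas <- frame_coords(ref, 1L, ms$indices)
  r <- vapply(seq_len(n_frames(x)), function(f) {
    fit <- kabsch_fit(frame_coords(x, f, fs$indices), ref_fit)
    rmsd_points(apply_superposition(frame_coords(x, f, ms$indices), fit),
                ref_meas)
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(x)), time_ns = x$times, rmsd = r)
}

# Fit every frame of x on sel to the ensemble mean (two-pass: first pass fits
# to frame 1, mean is taken, frames are refit to the mean). Returns a traj.
superpose_to_mean <- function(x, fit_selection = "name CA") {
  fs <- resolve_selection(x, fit_selection)
  if (length(fs$indices) < 3L) stop("fit selection has fewer than 3 atoms")
  pass <- function(x, target_fit) {
    xyz <- x$xyz
    for (f in seq_len(n_frames(x))) {
      fit <- kabsch_fit(frame_coords(x, f, fs$indices), target_fit)
      xyz[f, ] <- as.vector(t(apply_superposition(frame_coords(x, f), fit)))
    }
    new_traj(x$atoms, xyz, x$times)
  }
  p1 <- pass(x, frame_coords(x, 1L, fs$indices))
  mean_xyz <- colMeans(p1$xyz)
  mean_fit <- matrix(mean_xyz, ncol = 3L, byrow = TRUE)[fs$indices, ,
                                                        drop = FALSE]
  pass(x, mean_fit)
}

fluct_keys <- function(x, indices) {
  rt <- residue_table(x)
  ri <- atom_res_index(x)[indices]
  ids <- rt$id[ri]
  if (anyDuplicated(ids)) paste0(ids, ":", x$atoms$name[indices]) else ids
}

#' Root mean square fluctuation profile
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) per selected atom, computed after
#' superposing every frame on `fit_selection` to the ensemble mean structure
#' (two-pass fit). The initial, unequilibrated part of the trajectory is
#' discarded first: frames with time < `equilibration_cut` ns, defaulting to
#' the first half of the frames (MD ensembles typically relax towards a
#' steady state before fluctuations are meaningful).
#'
#' Keys are residue ids when the selection has at most one atom per residue
#' (e.g. C-alpha), otherwise `residue:atom` (e.g. per-atom ligand RMSF).
#'
#' @param x a `traj`
#' @param selection atoms to profile (default C-alpha)
#' @param fit_selection atoms used for the superposition (default: same)
#' @param equilibration_cut time in ns; frames before it are discarded.
#'   `NULL` discards the first half, `0` keeps everything.
#' @return data.frame with columns `key`, `rmsf` (Angstrom)
#' @export
rmsf_profile <- function(x, selection = "name CA",
                         fit_selection = selection,
                         equilibration_cut = NULL) {
  sel <- resolve_selection(x, selection)
  if (length(sel$indices) == 0L) stop("empty selection")
  n <- n_frames(x)
  keep <- if (is.null(equilibration_cut)) {
    seq_len(n) > floor(n / 2)
  } else {
    x$times >= equilibration_cut
  }
  if (sum(keep) < 2L)
    stop("equilibration cut leaves fewer than 2 frames")
  xs <- subset_frames(x, which(keep))
  fitted <- superpose_to_mean(xs, fit_selection)
  cols <- atom2xyz(sel$indices)
  D <- sweep(fitted$xyz[, cols, drop = FALSE], 2,
             colMeans(fitted$xyz[, cols, drop = FALSE]))
  msd3 <- matrix(colMeans(D^2), ncol = 3L, byrow = TRUE)
  data.frame(key = fluct_keys(x, sel$indices),
             rmsf = sqrt(rowSums(msd3)), stringsAsFactors = FALSE)
}

#' Sub-range (e.g. helix-12) RMSD against a crystal reference
#'
#' Fits each frame globally on `fit_selection` to the reference and measures
#' the RMSD on the C-alpha atoms of an inclusive residue-number range - the
#' standard probe for activation-helix (helix 12 / AF-2) displacement in
#' nuclear-receptor LBD simulations. Also returns a fixed-width histogram of
#' the per-frame values.
#'
#' @param x a `traj`
#' @param reference reference `traj` (first frame used), e.g. the crystal
#'   structure; defaults to the first frame of `x`
#' @param residue_range length-2 inclusive residue-number range, e.g.
#'   `c(457, 477)`
#' @param fit_selection global fit selection (default protein C-alpha)
#' @param bin_width histogram bin width in Angstrom
#' @return list with `rmsd` (data.frame frame, time_ns, rmsd), `histogram`
#'   (data.frame lower, upper, mid, count) and `range`
#' @export
subrange_rmsd <- function(x, reference = NULL, residue_range,
                          fit_selection = "name CA and protein",
                          bin_width = 0.5) {
  if (length(residue_range) != 2L) stop("residue_range must be c(lo, hi)")
  expr <- sprintf("name CA and protein and resno %d:%d",
                  as.integer(residue_range[1]), as.integer(residue_range[2]))
  ms <- select_atoms(x, expr)
  if (length(ms$indices) < 3L)
    stop("residue range resolves to fewer than 3 C-alpha atoms")
  out <- rmsd_series(x, reference, fit_selection, ms)
  top <- max(out$rmsd, bin_width)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(out$rmsd, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  hist <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                     mid = breaks[-length(breaks)] + bin_width / 2,
                     count = counts)
  list(rmsd = out, histogram = hist, range = as.integer(residue_range))
}
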