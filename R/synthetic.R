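# Run code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Build an idealised reference structure
#'
#' A poly-alanine-like chain of `n_residues` residues, each with a C-alpha
#' and a dummy side-chain heavy atom (CB). Geometries: `"chain"` - an
#' extended zig-zag trace (non-collinear) with exact 3.8 Angstrom C-alpha
#' spacing; `"helix"` - ideal alpha-helix
#' C-alpha trace (radius 2.3 A, rise 1.5 A, 100 degrees per residue).
#' Optionally appends a small ligand residue (`LIG`, four carbons and an
#' oxygen) near the middle of the chain.
#'
#' @param n_residues number of residues (>= 3)
#' @param geometry `"chain"` or `"helix"`
#' @param ligand append a ligand residue?
#' @param first_resno residue number of the first residue (author numbering)
#' @return a single-frame `traj`
#' @export
make_reference <- function(n_residues, geometry = c("chain", "helix"),
                           ligand = FALSE, first_resno = 1L) {
  if (n_residues < 3L) stop("need at least 3 residues")
  geometry <- match.arg(geometry)
  i <- seq_len(n_residues)
  if (geometry == "chain") {
    # extended zig-zag (non-collinear) trace with exact 3.8 A CA spacing
    y <- 0.25 * (-1)^i
    ca <- cbind(cumsum(c(0, rep(sqrt(3.8^2 - 0.5^2), n_residues - 1))),
                y, 0)
    cb <- ca + matrix(rep(c(0, 1.5, 0), n_residues), ncol = 3, byrow = TRUE)
  } else {
    phi <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (i - 1))
    radial <- cbind(cos(phi), sin(phi), 0)
    cb <- ca + 1.5 * radial
  }
  atoms <- data.frame(
    serial = seq_len(2L * n_residues),
    name = rep(c("CA", "CB"), n_residues),
    element = "C",
    resno = rep(first_resno + i - 1L, each = 2L),
    resname = "ALA", chain = "A",
    is_ligand = FALSE, is_heavy = TRUE, is_water = FALSE,
    stringsAsFactors = FALSE)
  coords <- matrix(0, nrow = 2L * n_residues, ncol = 3L)
  coords[seq(1, 2 * n_residues, 2), ] <- ca
  coords[seq(2, 2 * n_residues, 2), ] <- cb
  if (ligand) {
    mid <- ca[ceiling(n_residues / 2), ]
    lig_xyz <- sweep(rbind(c(0, 4, 0), c(1.4, 4, 0), c(2.8, 4, 0),
                           c(1.4, 5.4, 0), c(0, 5.2, 0.8)), 2, mid, "+")
    lig_atoms <- data.frame(
      serial = 2L * n_residues + 1:5,
      name = c("C1", "C2", "C3", "C4", "O1"),
      element = c("C", "C", "C", "C", "O"),
      resno = first_resno + n_residues,
      resname = "LIG", chain = "A",
      is_ligand = TRUE, is_heavy = TRUE, is_water = FALSE,
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, lig_atoms)
    coords <- rbind(coords, lig_xyz)
  }
  new_traj(atoms, matrix(as.vector(t(coords)), nrow = 1L), times = 0)
}

#' Build a multi-domain reference with planted community structure
#'
#' `n_domains` compact domains of `per_domain` residues each (single CA
#' heavy atom per residue) arranged on cube-corner lattices with
#' nearest-neighbour spacing `spacing` Angstrom; consecutive domains touch
#' through exactly one residue pair at the same spacing. At a heavy-atom
#' contact cutoff slightly above `spacing` the contact graph is therefore a
#' set of densely connected domains joined by single bridge edges - the
#' planted ground truth for community-recovery tests.
#'
#' @param n_domains number of domains (>= 1)
#' @param per_domain residues per domain (<= 8, cube corners)
#' @param spacing lattice spacing in Angstrom (default 3.8)
#' @return a single-frame `traj`; residues `1:per_domain` form domain 1, etc.
#' @export
make_domain_reference <- function(n_domains = 3L, per_domain = 8L,
                                  spacing = 3.8) {
  if (per_domain < 3L || per_domain > 8L)
    stop("per_domain must be in 3..8 (cube corners)")
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)) * spacing
  coords <- NULL
  for (d in seq_len(n_domains)) {
    origin <- (d - 1L) * c(2 * spacing, spacing, spacing)
    coords <- rbind(coords,
                    sweep(corners[seq_len(per_domain), , drop = FALSE],
                          2, origin, "+"))
  }
  n <- n_domains * per_domain
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resno = seq_len(n), resname = "ALA", chain = "A",
                      is_ligand = FALSE, is_heavy = TRUE, is_water = FALSE,
                      stringsAsFactors = FALSE)
  new_traj(atoms, matrix(as.vector(t(coords)), nrow = 1L), times = 0)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

apply_rigid <- function(m, R, t) sweep(m %*% R, 2, t, "+")

#' Sample a Gaussian ensemble with planted correlation blocks
#'
#' Per frame, every residue of correlation block b is displaced by
#' dr_i = sigma_i (sqrt(rho_b) z_b(t) + sqrt(1 - rho_b) eps_i(t)), with
#' z_b and eps_i standard normal per component: residues sharing a block
#' have pairwise displacement correlation rho_b, unblocked residues are
#' independent, and every residue has per-coordinate standard deviation
#' sigma_i (so its RMSF is sigma_i * sqrt(3)). All atoms of a residue move
#' rigidly with their residue. Frames are generated in the fitted frame; set
#' `rigid_motion = TRUE` to add a random rigid transform per frame (for
#' superposition tests).
#'
#' @param reference a single-frame `traj` (e.g. [make_reference()])
#' @param n_frames number of frames
#' @param sigma per-coordinate displacement SD in Angstrom; scalar or one
#'   value per residue
#' @param blocks list of correlation blocks, each
#'   `list(members = <residue indices>, rho = <0 <= rho < 1>)`; blocks must
#'   be disjoint
#' @param seed RNG seed
#' @param rigid_motion add a random rigid-body transform per frame?
#' @param dt frame spacing in ns
#' @return a `traj` with `n_frames` frames
#' @export
sample_correlated_ensemble <- function(reference, n_frames, sigma = 0.5,
                                       blocks = list(), seed = 1L,
                                       rigid_motion = FALSE, dt = 1) {
  rt <- residue_table(reference)
  nres <- nrow(rt)
  sigma <- rep_len(sigma, nres)
  if (any(sigma <= 0)) stop("sigma must be positive")
  memb <- unlist(lapply(blocks, `[[`, "members"))
  if (anyDuplicated(memb)) stop("correlation blocks must be disjoint")
  rho <- rep(0, nres)
  block_of <- rep(NA_integer_, nres)
  for (b in seq_along(blocks)) {
    r <- blocks[[b]]$rho
    if (r < 0 || r >= 1) stop("rho must be in [0, 1)")
    rho[blocks[[b]]$members] <- r
    block_of[blocks[[b]]$members] <- b
  }
  ri <- atom_res_index(reference)
  ref <- frame_coords(reference, 1L)
  local_seed(seed, {
    xyz <- matrix(0, n_frames, 3L * n_atoms(reference))
    for (f in seq_len(n_frames)) {
      zb <- matrix(stats::rnorm(3L * length(blocks)), ncol = 3L)
      eps <- matrix(stats::rnorm(3L * nres), ncol = 3L)
      dr <- matrix(0, nres, 3L)
      for (k in seq_len(nres)) {
        shared <- if (is.na(block_of[k])) c(0, 0, 0) else zb[block_of[k], ]
        dr[k, ] <- sigma[k] * (sqrt(rho[k]) * shared +
                                 sqrt(1 - rho[k]) * eps[k, ])
      }
      co <- ref + dr[ri, , drop = FALSE]
      if (rigid_motion)
        co <- apply_rigid(co, random_rotation(), stats::rnorm(3, sd = 5))
      xyz[f, ] <- as.vector(t(co))
    }
    new_traj(reference$atoms, xyz, times = (seq_len(n_frames) - 1L) * dt)
  })
}

#' Sample a multi-state conformational mixture
#'
#' Frames are drawn from discrete conformational states with exact planted
#' populations: state s displaces the atoms of `displaced_residues` by
#' `displacements[s]` Angstrom along +x relative to the reference, and every
#' atom then receives isotropic Gaussian noise of per-coordinate SD `noise`.
#' State counts are `round(cumsum(fractions) * n_frames)` differences
#' (so populations are exact up to frame granularity) and frame order is a
#' seeded shuffle. True labels are returned for recovery tests.
#'
#' @param reference a single-frame `traj`
#' @param n_frames number of frames
#' @param fractions state fractions, summing to 1
#' @param displacements per-state displacement along x (Angstrom); default
#'   `c(0, 4)` (a 4 Angstrom two-state separation)
#' @param displaced_residues residue indices displaced by the state change;
#'   default: the second half of the residues (a hinge-like motion; the
#'   static first half serves as the superposition anchor)
#' @param noise per-coordinate Gaussian noise SD in Angstrom
#' @param seed RNG seed
#' @param dt frame spacing in ns
#' @return list with `traj` and integer `labels` (true state per frame)
#' @export
sample_two_state <- function(reference, n_frames, fractions = c(0.7, 0.3),
                             displacements = c(0, 4),
                             displaced_residues = NULL, noise = 0.3,
                             seed = 1L, dt = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(displacements) != length(fractions))
    stop("one displacement per state")
  rt <- residue_table(reference)
  if (is.null(displaced_residues))
    displaced_residues <- seq_len(nrow(rt)) > nrow(rt) / 2
  if (is.logical(displaced_residues))
    displaced_residues <- which(displaced_residues)
  counts <- diff(round(cumsum(c(0, fractions)) * n_frames))
  labels_sorted <- rep(seq_along(fractions), counts)
  ri <- atom_res_index(reference)
  moved_atoms <- which(ri %in% displaced_residues)
  ref <- frame_coords(reference, 1L)
  local_seed(seed, {
    labels <- sample(labels_sorted)
    xyz <- matrix(0, n_frames, 3L * n_atoms(reference))
    for (f in seq_len(n_frames)) {
      co <- ref
      co[moved_atoms, 1] <- co[moved_atoms, 1] + displacements[labels[f]]
      co <- co + matrix(stats::rnorm(length(co), sd = noise), ncol = 3L)
      xyz[f, ] <- as.vector(t(co))
    }
    list(traj = new_traj(reference$atoms, xyz,
                         times = (seq_len(n_frames) - 1L) * dt),
         labels = labels)
  })
}

#' Deterministic on/off interaction schedule
#'
#' Builds a synthetic event table hitting each target fraction exactly
#' (floored to whole frames): a (residue, category) pair with target f gets
#' events in frames 1 .. floor(f * n_frames).
#'
#' @param n_frames number of frames
#' @param targets data.frame with columns `residue`, `category`, `fraction`
#' @return event data.frame compatible with [interaction_fractions()]
#' @export
make_interaction_schedule <- function(n_frames, targets) {
  if (any(targets$fraction < 0 | targets$fraction > 1))
    stop("fractions must be in [0, 1]")
  rows <- lapply(seq_len(nrow(targets)), function(k) {
    n_on <- floor(targets$fraction[k] * n_frames + 1e-9)
    if (n_on == 0L) return(NULL)
    data.frame(frame = seq_len(n_on), residue = targets$residue[k],
               ligand_atom = "L1", category = targets$category[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(), residue = character(),
                      ligand_atom = character(), category = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Generate a synthetic MM-GBSA term table with known truth
#'
#' Independent Gaussian draws per (entity, term) and frame. The analytic
#' binding-energy parameters implied by the spec are returned alongside:
#' mean dG = sum of complex means - ligand means - receptor means, and
#' var dG = sum of all term variances.
#'
#' @param spec data.frame with columns `entity`, `term`, `mean`, `sd`
#'   (kcal/mol); omitted (entity, term) pairs are taken as exactly 0
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return list with `table` (an `energy_table`) and `truth`
#'   (`dG_mean`, `dG_sd`)
#' @export
make_energy_tables <- function(spec, n_frames, seed = 1L) {
  if (any(spec$sd < 0)) stop("sd must be >= 0")
  full <- expand.grid(entity = .energy_entities, term = .energy_terms,
                      stringsAsFactors = FALSE)
  key <- paste(spec$entity, spec$term)
  m <- match(paste(full$entity, full$term), key)
  full$mean <- ifelse(is.na(m), 0, spec$mean[m])
  full$sd <- ifelse(is.na(m), 0, spec$sd[m])
  local_seed(seed, {
    rows <- lapply(seq_len(nrow(full)), function(k) {
      data.frame(frame = seq_len(n_frames), entity = full$entity[k],
                 term = full$term[k],
                 value = stats::rnorm(n_frames, full$mean[k], full$sd[k]),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$frame), ]
    rownames(tab) <- NULL
    sgn <- ifelse(full$entity == "complex", 1, -1)
    list(table = structure(validate_energy_table(tab),
                           class = c("energy_table", "data.frame")),
         truth = list(dG_mean = sum(sgn * full$mean),
                      dG_sd = sqrt(sum(full$sd^2))))
  })
}

#' Write an energy term table as TSV
#' @param tab an `energy_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_energy_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
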