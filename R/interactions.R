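# Bond inference by distance on the first frame (static topology):
# H bonded to the nearest heavy atom within 1.2 A; heavy-heavy bonds at
# <= 1.7 A.
infer_bonds <- function(x) {
  co <- frame_coords(x, 1L)
  el <- toupper(x$atoms$element)
  n <- nrow(co)
  d2 <- outer(rowSums(co^2), rowSums(co^2), "+") - 2 * tcrossprod(co)
  d2[d2 < 0] <- 0
  heavy <- which(el != "H")
  bonds <- vector("list", n)
  for (i in seq_len(n)) {
    lim <- if (el[i] == "H") 1.2 else 1.7
    cand <- which(d2[i, ] <= lim^2 & seq_len(n) != i)
    cand <- cand[el[cand] != "H" | el[i] != "H"]
    if (el[i] == "H" && length(cand) > 1L) {
      ch <- cand[el[cand] != "H"]
      cand <- if (length(ch)) ch[which.min(d2[i, ch])] else integer()
    }
    bonds[[i]] <- cand
  }
  bonds
}

angle_deg <- function(a, b, c) {
  # angle at b
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# atom-role classification shared by detect_interactions
classify_atoms <- function(x) {
  el <- toupper(x$atoms$element)
  bonds <- infer_bonds(x)
  is_h <- el == "H"
  polar_heavy <- el %in% c("N", "O", "S")
  donor_h <- which(is_h & vapply(bonds, function(b)
    length(b) > 0 && any(polar_heavy[b]), TRUE))
  donors <- lapply(donor_h, function(h) {
    d <- bonds[[h]][polar_heavy[bonds[[h]]]][1]
    c(d = d, h = h)
  })
  acceptors <- which(el %in% c("N", "O"))
  apolar_c <- which(el == "C" & !vapply(bonds, function(b)
    any(el[b] %in% c("N", "O", "S")), TRUE))
  list(bonds = bonds, donors = donors, acceptors = acceptors,
       apolar_c = apolar_c, el = el)
}

# charged groups: protein side-chain carboxylates (ASP/GLU, -1),
# amine/guanidinium (LYS/ARG, +1); ligand carboxylate O pairs (-1) and
# N carrying >= 2 hydrogens (+1). Returns list of (atoms, sign, owner).
charged_groups <- function(x, roles) {
  a <- x$atoms
  ri <- atom_res_index(x)
  rt <- residue_table(x)
  out <- list()
  add <- function(atoms, sign, res) {
    if (length(atoms))
      out[[length(out) + 1L]] <<- list(atoms = atoms, sign = sign,
                                       res_index = res)
  }
  for (k in seq_len(nrow(rt))) {
    idx <- which(ri == k)
    rn <- rt$resname[k]
    if (rt$is_ligand[k]) {
      el <- roles$el[idx]
      # carboxylate: two O bonded to one C, no H on either O
      for (ci in idx[el == "C"]) {
        os <- intersect(roles$bonds[[ci]], idx[el == "O"])
        os <- os[vapply(os, function(o)
          !any(roles$el[roles$bonds[[o]]] == "H"), TRUE)]
        if (length(os) >= 2L) add(os, -1, k)
      }
      for (ni in idx[el == "N"]) {
        nh <- sum(roles$el[roles$bonds[[ni]]] == "H")
        if (nh >= 2L) add(ni, +1, k)
      }
    } else if (rn %in% c("ASP", "GLU")) {
      add(idx[a$name[idx] %in% c("OD1", "OD2", "OE1", "OE2")], -1, k)
    } else if (rn == "LYS") {
      add(idx[a$name[idx] == "NZ"], +1, k)
    } else if (rn == "ARG") {
      add(idx[a$name[idx] %in% c("CZ", "NH1", "NH2")], +1, k)
    }
  }
  out
}

hbond_pair <- function(co, donor, acceptor, roles, dmax, amin_donor,
                       amin_acceptor = NULL) {
  h <- donor[["h"]]
  d <- donor[["d"]]
  if (sqrt(sum((co[h, ] - co[acceptor, ])^2)) > dmax) return(FALSE)
  if (angle_deg(co[d, ], co[h, ], co[acceptor, ]) < amin_donor)
    return(FALSE)
  if (!is.null(amin_acceptor)) {
    nb <- roles$bonds[[acceptor]]
    nb <- nb[roles$el[nb] != "H"]
    if (length(nb) &&
        angle_deg(co[nb[1], ], co[acceptor, ], co[h, ]) < amin_acceptor)
      return(FALSE)
  }
  TRUE
}

#' Detect per-frame protein-ligand interactions
#'
#' Geometric criteria, applied frame by frame between the flagged ligand
#' and the protein:
#' \itemize{
#'   \item hbond: H...acceptor <= 2.5 A, donor angle (D-H...A) >= 120
#'     degrees, acceptor angle (neighbour-A...H) >= 90 degrees;
#'   \item hydrophobic: apolar carbon pairs <= 3.6 A (apolar = carbon with
#'     no N/O/S neighbour within bonding distance);
#'   \item ionic: oppositely charged group centroids <= 3.7 A;
#'   \item water_bridge: a water simultaneously hydrogen bonded (relaxed:
#'     2.8 A, 110 degrees) to a protein atom and a ligand atom.
#' }
#' Bonds are inferred by distance on the first frame. Hydrogen-bond and
#' water-bridge detection is disabled with a warning when the topology has
#' no hydrogens.
#'
#' @param x a `traj` with a flagged ligand
#' @return data.frame of events: `frame`, `residue` (protein residue id, or
#'   the water id for water bridges), `ligand_atom`, `category`; at most one
#'   event per (frame, residue, ligand atom, category)
#' @export
detect_interactions <- function(x) {
  a <- x$atoms
  if (!any(a$is_ligand)) stop("no ligand atoms flagged in topology")
  if (!any(nzchar(a$element))) stop("topology lacks element information")
  roles <- classify_atoms(x)
  ri <- atom_res_index(x)
  rt <- residue_table(x)
  lig <- which(a$is_ligand)
  prot <- which(!a$is_ligand & !a$is_water)
  wat <- which(a$is_water)
  have_h <- any(roles$el == "H")
  if (!have_h)
    warning("no hydrogens in topology; H-bond and water-bridge detection disabled")
  side_of <- function(i) if (a$is_ligand[i]) "ligand" else
    if (a$is_water[i]) "water" else "protein"
  donors <- roles$donors
  donor_side <- vapply(donors, function(d) side_of(d[["d"]]), "")
  acc <- roles$acceptors
  acc_side <- vapply(acc, side_of, "")
  groups <- charged_groups(x, roles)
  gsign <- vapply(groups, `[[`, 1, "sign")
  gside <- vapply(groups, function(g)
    if (rt$is_ligand[g$res_index]) "ligand" else "protein", "")
  ev <- list()
  emit <- function(frame, res_idx, lig_atom, category) {
    ev[[length(ev) + 1L]] <<- data.frame(
      frame = frame, residue = rt$id[res_idx],
      ligand_atom = a$name[lig_atom], category = category,
      stringsAsFactors = FALSE)
  }
  for (f in seq_len(n_frames(x))) {
    co <- frame_coords(x, f)
    if (have_h) {
      for (k in seq_along(donors)) {
        dn <- donors[[k]]
        targets <- if (donor_side[k] == "protein") {
          acc[acc_side == "ligand"]
        } else if (donor_side[k] == "ligand") {
          acc[acc_side == "protein"]
        } else next
        for (ac in targets) {
          if (hbond_pair(co, dn, ac, roles, 2.5, 120, 90)) {
            if (donor_side[k] == "protein")
              emit(f, ri[dn[["d"]]], ac, "hbond")
            else
              emit(f, ri[ac], dn[["d"]], "hbond")
          }
        }
      }
      # water bridges: water donates/accepts to both sides
      for (w in unique(ri[wat])) {
        watoms <- which(ri == w)
        wd <- donors[vapply(donors, function(d) d[["d"]] %in% watoms, TRUE)]
        wa <- intersect(acc, watoms)
        touches <- function(side_atoms) {
          for (dn in wd) for (ac in intersect(acc, side_atoms))
            if (hbond_pair(co, dn, ac, roles, 2.8, 110))
              return(ac)
          sd <- donors[vapply(donors, function(d)
            d[["d"]] %in% side_atoms, TRUE)]
          for (dn in sd) for (ac in wa)
            if (hbond_pair(co, dn, ac, roles, 2.8, 110))
              return(dn[["d"]])
          NA_integer_
        }
        pa <- touches(prot)
        la <- touches(lig)
        if (!is.na(pa) && !is.na(la)) emit(f, ri[pa], la, "water_bridge")
      }
    }
    pc <- intersect(roles$apolar_c, prot)
    lc <- intersect(roles$apolar_c, lig)
    if (length(pc) && length(lc)) {
      d2 <- outer(rowSums(co[pc, , drop = FALSE]^2),
                  rowSums(co[lc, , drop = FALSE]^2), "+") -
        2 * tcrossprod(co[pc, , drop = FALSE], co[lc, , drop = FALSE])
      hit <- which(d2 <= 3.6^2, arr.ind = TRUE)
      if (nrow(hit))
        for (r in seq_len(nrow(hit)))
          emit(f, ri[pc[hit[r, 1]]], lc[hit[r, 2]], "hydrophobic")
    }
    if (length(groups) > 1L) {
      cent <- t(vapply(groups, function(g)
        colMeans(co[g$atoms, , drop = FALSE]), numeric(3)))
      for (gi in which(gside == "protein")) {
        for (gj in which(gside == "ligand")) {
          if (gsign[gi] * gsign[gj] >= 0) next
          if (sqrt(sum((cent[gi, ] - cent[gj, ])^2)) <= 3.7)
            emit(f, groups[[gi]]$res_index, groups[[gj]]$atoms[1], "ionic")
        }
      }
    }
  }
  if (length(ev) == 0L)
    return(data.frame(frame = integer(), residue = character(),
                      ligand_atom = character(), category = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  unique(out)
}

#' Interaction fractions and the reporting threshold
#'
#' The fraction for a (residue, category) pair is the number of frames with
#' at least one such event divided by `n_frames`. The report retains pairs
#' with fraction >= `report_threshold` (inclusive); 0.30 - an interaction
#' held for at least 30 percent of the simulated period - is the
#' conventional reporting bar. `by = "residue"` pools categories per
#' residue before thresholding.
#'
#' @param events event data.frame from [detect_interactions()] or
#'   [make_interaction_schedule()]
#' @param n_frames total frame count of the trajectory
#' @param report_threshold reporting fraction (inclusive)
#' @param by `"pair"` (default) or `"residue"` (union over categories)
#' @return list with `table` (residue, category, fraction) and `report`
#'   (rows meeting the threshold, descending fraction)
#' @export
interaction_fractions <- function(events, n_frames, report_threshold = 0.30,
                                  by = c("pair", "residue")) {
  by <- match.arg(by)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (nrow(events) == 0L) {
    tab <- data.frame(residue = character(), category = character(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    return(list(table = tab, report = tab))
  }
  keyvars <- if (by == "pair") c("residue", "category") else "residue"
  key <- do.call(paste, c(events[keyvars], sep = "\r"))
  frames_per <- tapply(events$frame, key, function(f) length(unique(f)))
  parts <- strsplit(names(frames_per), "\r", fixed = TRUE)
  tab <- data.frame(residue = vapply(parts, `[`, "", 1),
                    category = if (by == "pair")
                      vapply(parts, `[`, "", 2) else "any",
                    fraction = as.numeric(frames_per) / n_frames,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$fraction, tab$residue), ]
  rownames(tab) <- NULL
  report <- tab[tab$fraction >= report_threshold, , drop = FALSE]
  rownames(report) <- NULL
  list(table = tab, report = report)
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
          n1[3] * b2u[1] - n1[1] * b2u[3],
          n1[1] * b2u[2] - n1[2] * b2u[1])
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Rotatable-bond torsion profiles
#'
#' Signed dihedral angle per frame for each 4-atom quadruple (standard
#' atan2 construction, degrees in (-180, 180]) plus a 36-bin, 10-degree
#' histogram normalised to unit mass. Frames where the angle is undefined
#' (collinear atoms) are skipped and counted.
#'
#' @param x a `traj`
#' @param bonds list of length-4 atom-index vectors (or an n x 4 matrix),
#'   one dihedral quadruple per rotatable bond
#' @return object of class `torsion_profile`: list per bond with `angles`
#'   (per retained frame), `histogram` (lower, upper, mid, density) and
#'   `n_skipped`
#' @export
torsion_profile <- function(x, bonds) {
  if (is.matrix(bonds)) bonds <- split(bonds, row(bonds))
  breaks <- seq(-180, 180, by = 10)
  out <- lapply(bonds, function(q) {
    q <- as.integer(q)
    if (length(q) != 4L) stop("each bond needs 4 atom indices")
    ang <- vapply(seq_len(n_frames(x)), function(f) {
      co <- frame_coords(x, f, q)
      dihedral_deg(co[1, ], co[2, ], co[3, ], co[4, ])
    }, numeric(1))
    skipped <- sum(is.na(ang))
    ang <- ang[!is.na(ang)]
    ang[ang <= -180] <- ang[ang <= -180] + 360  # land in (-180, 180]
    counts <- tabulate(findInterval(ang, breaks, left.open = TRUE,
                                    all.inside = TRUE), nbins = 36L)
    data_frame <- data.frame(lower = breaks[-37], upper = breaks[-1],
                             mid = breaks[-37] + 5,
                             density = if (length(ang)) counts / length(ang)
                             else rep(0, 36L))
    list(angles = ang, histogram = data_frame, n_skipped = skipped)
  })
  structure(out, class = "torsion_profile")
}
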