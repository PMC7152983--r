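mk_traj <- function(atoms, coords_list) {
  xyz <- do.call(rbind, lapply(coords_list, function(co)
    as.vector(t(co))))
  new_traj(atoms, xyz)
}

atom_row <- function(serial, name, element, resno, resname, lig = FALSE,
                     wat = FALSE) {
  data.frame(serial = serial, name = name, element = element,
             resno = resno, resname = resname, chain = "A",
             is_ligand = lig, is_heavy = element != "H", is_water = wat,
             stringsAsFactors = FALSE)
}

test_that("hydrogen-bond geometry is accepted and its boundary rejected", {
  # protein serine-like donor O-H pointing at a ligand acceptor O
  mk <- function(ha_dist) {
    atoms <- rbind(
      atom_row(1, "CB", "C", 1, "SER"),
      atom_row(2, "OG", "O", 1, "SER"),
      atom_row(3, "HG", "H", 1, "SER"),
      atom_row(4, "O1", "O", 9, "LIG", lig = TRUE),
      atom_row(5, "C1", "C", 9, "LIG", lig = TRUE))
    # D-H along x; acceptor almost in line (angle ~165 deg at H)
    h <- c(0.96, 0, 0)
    acc <- h + ha_dist * c(cos(15 * pi / 180), sin(15 * pi / 180), 0)
    co <- rbind(c(-1.2, 0.8, 0), c(0, 0, 0), h, acc, acc + c(1.3, 0.4, 0))
    mk_traj(atoms, list(co))
  }
  ev <- detect_interactions(mk(1.9))
  hb <- ev[ev$category == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$residue, "SER_1")
  expect_equal(hb$ligand_atom, "O1")

  ev26 <- detect_interactions(mk(2.6))
  expect_equal(nrow(ev26[ev26$category == "hbond", ]), 0L)
})

test_that("a bridging water links protein and ligand oxygens", {
  atoms <- rbind(
    atom_row(1, "CB", "C", 1, "SER"),
    atom_row(2, "OG", "O", 1, "SER"),
    atom_row(3, "O", "O", 50, "HOH", wat = TRUE),
    atom_row(4, "H1", "H", 50, "HOH", wat = TRUE),
    atom_row(5, "H2", "H", 50, "HOH", wat = TRUE),
    atom_row(6, "O1", "O", 9, "LIG", lig = TRUE),
    atom_row(7, "C1", "C", 9, "LIG", lig = TRUE))
  wo <- c(0, 0, 0)
  # water donates to protein OG (left) and to ligand O1 (right)
  h1 <- c(-0.96, 0, 0)
  h2 <- c(0.96, 0, 0)
  og <- h1 + c(-1.8, 0.3, 0)
  o1 <- h2 + c(1.8, -0.3, 0)
  co <- rbind(og + c(-1.1, 0.9, 0), og, wo, h1, h2, o1, o1 + c(1.2, 0.6, 0))
  ev <- detect_interactions(mk_traj(atoms, list(co)))
  wb <- ev[ev$category == "water_bridge", ]
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$residue, "SER_1")
  expect_equal(wb$ligand_atom, "O1")
})

test_that("hydrophobic and ionic contacts follow their distance rules", {
  atoms <- rbind(
    atom_row(1, "CD1", "C", 2, "LEU"),
    atom_row(2, "NZ", "N", 3, "LYS"),
    atom_row(3, "C5", "C", 9, "LIG", lig = TRUE),
    atom_row(4, "C6", "C", 9, "LIG", lig = TRUE),
    atom_row(5, "O2", "O", 9, "LIG", lig = TRUE),
    atom_row(6, "O3", "O", 9, "LIG", lig = TRUE))
  # C5 apolar (no polar neighbour), C6 carboxylate carbon bound to O2/O3
  cd1 <- c(0, 0, 0)
  c5 <- c(3.5, 0, 0)
  c6 <- c(3.5, 8, 0)
  o2 <- c6 + c(1.25, 0.3, 0)
  o3 <- c6 + c(-0.6, 1.1, 0)
  nz <- (o2 + o3) / 2 + c(0, 3.0, 0)
  ev <- suppressWarnings(
    detect_interactions(mk_traj(atoms, list(rbind(cd1, nz, c5, c6, o2, o3)))))
  hyd <- ev[ev$category == "hydrophobic", ]
  expect_equal(nrow(hyd), 1L)
  expect_equal(hyd$residue, "LEU_2")
  expect_equal(hyd$ligand_atom, "C5")
  ion <- ev[ev$category == "ionic", ]
  expect_equal(nrow(ion), 1L)
  expect_equal(ion$residue, "LYS_3")

  # beyond 3.6 A: no hydrophobic contact
  co2 <- rbind(cd1, nz + c(0, 5, 0), c5 + c(0.2, 0, 0), c6, o2, o3)
  ev2 <- suppressWarnings(detect_interactions(mk_traj(atoms, list(co2))))
  expect_equal(nrow(ev2[ev2$category == "hydrophobic", ]), 0L)
  expect_equal(nrow(ev2[ev2$category == "ionic", ]), 0L)
})

test_that("event detection matches an independent geometric scan", {
  withr::local_seed(51)
  # random small protein/ligand soup with mixed elements over 3 frames
  n_p <- 14
  n_l <- 6
  atoms <- rbind(
    do.call(rbind, lapply(seq_len(n_p), function(i)
      atom_row(i, paste0("P", i), sample(c("C", "C", "O", "N"), 1),
               (i + 1) %/% 2, "ALA"))),
    do.call(rbind, lapply(seq_len(n_l), function(i)
      atom_row(n_p + i, paste0("L", i), sample(c("C", "C", "O"), 1),
               90, "LIG", lig = TRUE))))
  frames <- lapply(1:3, function(f) {
    co_p <- matrix(rnorm(3 * n_p, sd = 2.5), n_p, 3)
    co_l <- sweep(matrix(rnorm(3 * n_l, sd = 1.5), n_l, 3), 2,
                  c(2, 0, 0), "+")
    rbind(co_p, co_l)
  })
  x <- mk_traj(atoms, frames)
  expect_warning(ev <- detect_interactions(x), "no hydrogens")
  got <- ev[ev$category == "hydrophobic", c("frame", "residue",
                                            "ligand_atom")]
  got <- got[order(got$frame, got$residue, got$ligand_atom), ]
  oracle <- oracle_scan_events(x)
  oracle <- oracle[oracle$category == "hydrophobic", , drop = FALSE]
  if (nrow(oracle)) {
    rt <- residue_table(x)
    ri <- trajcomm:::atom_res_index(x)
    want <- data.frame(frame = oracle$frame,
                       residue = rt$id[ri[oracle$i]],
                       ligand_atom = x$atoms$name[oracle$j])
    want <- unique(want[order(want$frame, want$residue,
                              want$ligand_atom), ])
    expect_equal(got, want, ignore_attr = TRUE)
  } else {
    expect_equal(nrow(got), 0L)
  }
})

test_that("interaction fractions: arithmetic, boundary, self-concatenation", {
  sched <- make_interaction_schedule(100, data.frame(
    residue = c("TYR_334", "HIS_323", "SER_289"),
    category = c("hbond", "hbond", "hydrophobic"),
    fraction = c(0.40, 0.29, 0.30)))
  fr <- interaction_fractions(sched, 100, report_threshold = 0.30)
  tab <- fr$table
  expect_equal(tab$fraction[tab$residue == "TYR_334"], 0.40)
  expect_equal(tab$fraction[tab$residue == "HIS_323"], 0.29)
  # >= is inclusive: 0.30 reported, 0.29 not
  expect_setequal(fr$report$residue, c("TYR_334", "SER_289"))
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))

  # doubling the trajectory leaves fractions unchanged
  doubled <- rbind(sched, transform(sched, frame = frame + 100))
  fr2 <- interaction_fractions(doubled, 200)
  expect_equal(fr2$table$fraction[order(fr2$table$residue)],
               tab$fraction[order(tab$residue)])
})

test_that("a dominant anchor residue tops the interaction report", {
  # one residue engaged on 97% of frames dwarfs the rest of the profile
  sched <- make_interaction_schedule(200, data.frame(
    residue = c("TYR_334", "CYS_276", "VAL_332", "GLN_277"),
    category = c("hbond", "hbond", "hydrophobic", "hbond"),
    fraction = c(0.97, 0.55, 0.45, 0.12)))
  fr <- interaction_fractions(sched, 200, report_threshold = 0.30)
  expect_equal(fr$report$residue[1], "TYR_334")
  expect_equal(fr$report$fraction[1], 0.97)
  expect_false("GLN_277" %in% fr$report$residue)
})

test_that("torsions: cis/trans closed forms and rigid invariance", {
  atoms <- do.call(rbind, lapply(1:4, function(i)
    atom_row(i, paste0("C", i), "C", 1, "LIG", lig = TRUE)))
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0))
  trans <- rbind(c(0, -1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0))
  x <- mk_traj(atoms, list(cis, trans))
  tp <- torsion_profile(x, list(1:4))
  expect_equal(tp[[1]]$angles[1], 0, tolerance = 1e-10)
  expect_equal(abs(tp[[1]]$angles[2]), 180, tolerance = 1e-10)
  expect_equal(sum(tp[[1]]$histogram$density), 1)

  withr::local_seed(52)
  R <- random_rotation()
  moved <- mk_traj(atoms, list(apply_rigid(cis, R, c(2, 5, -1)),
                               apply_rigid(trans, R, c(-3, 0, 4))))
  tp2 <- torsion_profile(moved, list(1:4))
  expect_equal(abs(tp2[[1]]$angles), abs(tp[[1]]$angles), tolerance = 1e-8)

  # collinear quadruple is skipped and counted
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  xl <- mk_traj(atoms, list(line, cis))
  tpl <- torsion_profile(xl, list(1:4))
  expect_equal(tpl[[1]]$n_skipped, 1L)
  expect_equal(length(tpl[[1]]$angles), 1L)
})

test_that("a uniformly sweeping rotor gives a flat torsion histogram", {
  atoms <- do.call(rbind, lapply(1:4, function(i)
    atom_row(i, paste0("C", i), "C", 1, "LIG", lig = TRUE)))
  n <- 5000
  withr::local_seed(53)
  phis <- runif(n, -180, 180)
  frames <- lapply(phis, function(phi) {
    t <- phi * pi / 180
    rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0),
          c(1.5, cos(t), sin(t)))
  })
  x <- mk_traj(atoms, frames)
  tp <- torsion_profile(x, list(1:4))
  # the sweep parameter is the negative of the IUPAC-signed dihedral here
  expect_equal(tp[[1]]$angles, -phis, tolerance = 1e-6)
  counts <- tp[[1]]$histogram$density * n
  chi2 <- sum((counts - n / 36)^2 / (n / 36))
  expect_lt(chi2, qchisq(0.99, df = 35))
})
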