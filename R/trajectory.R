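.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HIE", "HID", "HIP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.water_resnames <- c("HOH", "WAT", "SPC", "TIP3", "T3P", "SOL", "DOD")

#' Construct a trajectory object
#'
#' A `traj` bundles a topology (one row per atom: serial, name, element,
#' residue number/name, chain, ligand/heavy/water flags) with a frame series:
#' an `n_frames x 3*n_atoms` coordinate matrix in Angstrom (columns grouped
#' x,y,z per atom, file order) and strictly increasing frame times in ns.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `is_ligand`, `is_heavy`, `is_water`.
#' @param xyz numeric matrix, `n_frames` rows, `3 * nrow(atoms)` columns.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @return object of class `traj`.
#' @export
new_traj <- function(atoms, xyz, times = NULL) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  if (is.null(dim(xyz)) || ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must have 3 * n_atoms columns")
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (is.null(times)) times <- as.numeric(seq_len(nrow(xyz)) - 1L)
  if (length(times) != nrow(xyz) || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  atoms$is_heavy <- toupper(atoms$element) != "H"
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times)),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("traj: %d atoms, %d residues (%d ligand), %d frame(s)\n",
              n_atoms(x), nrow(rt), sum(rt$is_ligand), n_frames(x)))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param x a `traj`
#' @return integer
#' @export
n_frames <- function(x) nrow(x$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$atoms)

# xyz column indices of atom indices (x1,y1,z1,x2,...)
atom2xyz <- function(i) as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))

#' Coordinates of one frame as an N x 3 matrix
#' @param x a `traj`
#' @param frame frame index (1-based)
#' @param indices optional atom indices
#' @return numeric matrix with columns x, y, z
#' @export
frame_coords <- function(x, frame = 1L, indices = NULL) {
  if (frame < 1L || frame > n_frames(x)) stop("frame out of range")
  v <- x$xyz[frame, ]
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Residue table of a trajectory
#'
#' One row per residue in file order. A residue is identified by
#' (chain, residue number, residue name); author numbering is preserved.
#' The `id` column is `RESNAME_RESNO`, suffixed with `_<chain>` when the
#' topology has more than one chain.
#'
#' @param x a `traj`
#' @return data.frame with columns `res_index`, `id`, `resno`, `resname`,
#'   `chain`, `is_ligand`, `is_water`
#' @export
residue_table <- function(x) {
  a <- x$atoms
  key <- paste(a$chain, a$resno, a$resname, sep = "|")
  r <- rle(key)
  first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  multi_chain <- length(unique(a$chain)) > 1L
  id <- paste0(a$resname[first], "_", a$resno[first])
  if (multi_chain) id <- paste0(id, "_", a$chain[first])
  data.frame(res_index = seq_along(first),
             id = id,
             resno = a$resno[first],
             resname = a$resname[first],
             chain = a$chain[first],
             is_ligand = a$is_ligand[first],
             is_water = a$is_water[first],
             stringsAsFactors = FALSE)
}

# per-atom residue index into residue_table()
atom_res_index <- function(x) {
  a <- x$atoms
  key <- paste(a$chain, a$resno, a$resname, sep = "|")
  r <- rle(key)
  rep(seq_along(r$lengths), r$lengths)
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  if (nchar(nm) == 0L) return("X")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "SE"))
    return(two)
  toupper(substr(nm, 1, 1))
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL blocks delimit frames and a file
#' without MODEL records yields a single frame. HETATM residues outside the
#' standard amino-acid set and not water are flagged as ligand. Coordinates
#' are in Angstrom. Insertion codes are rejected.
#'
#' @param path PDB file path
#' @param dt time spacing between frames in ns (times are `(0:(n-1)) * dt`)
#' @return a [new_traj()] object
#' @export
read_pdb <- function(path, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # frame id per line: 0 before any MODEL (promoted to 1 if no MODEL at all)
  frame_of <- cumsum(is_model)
  if (!any(is_model)) frame_of <- rep(1L, length(lines))
  frame_of[is_endmdl] <- 0L
  keep <- which(is_atom & frame_of > 0L)
  if (length(keep) == 0L) stop("no ATOM/HETATM records inside MODEL blocks")

  parse_block <- function(ln, lineno) {
    icode <- trimws(substr(ln, 27, 27))
    if (any(icode != ""))
      stop("insertion codes are not supported (line ",
           lineno[which(icode != "")[1]], ")")
    num <- function(from, to, what) {
      v <- suppressWarnings(as.numeric(substr(ln, from, to)))
      if (anyNA(v))
        stop("parse error: malformed ", what, " at line ",
             lineno[which(is.na(v))[1]])
      v
    }
    serial <- num(7, 11, "atom serial")
    resno <- num(23, 26, "residue number")
    data.frame(serial = as.integer(serial),
               name = trimws(substr(ln, 13, 16)),
               resname = trimws(substr(ln, 18, 20)),
               chain = substr(ln, 22, 22),
               resno = as.integer(resno),
               x = num(31, 38, "x coordinate"),
               y = num(39, 46, "y coordinate"),
               z = num(47, 54, "z coordinate"),
               element = trimws(substr(ln, 77, 78)),
               hetatm = startsWith(ln, "HETATM"),
               stringsAsFactors = FALSE)
  }

  blocks <- split(keep, frame_of[keep])
  frames <- lapply(blocks, function(idx) parse_block(lines[idx], idx))
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) != 1L)
    stop("structure error: inconsistent atom count across models (",
         paste(unique(nat), collapse = ", "), ")")

  first <- frames[[1]]
  element <- ifelse(first$element == "",
                    vapply(first$name, guess_element, ""), first$element)
  is_water <- first$resname %in% .water_resnames
  is_ligand <- first$hetatm & !(first$resname %in% .standard_aa) & !is_water
  atoms <- data.frame(serial = first$serial, name = first$name,
                      element = toupper(element), resno = first$resno,
                      resname = first$resname, chain = first$chain,
                      is_ligand = is_ligand,
                      is_heavy = toupper(element) != "H",
                      is_water = is_water, stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.vector(t(as.matrix(f[, c("x", "y", "z")])))))
  new_traj(atoms, xyz, times = (seq_len(nrow(xyz)) - 1L) * dt)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param x a `traj`
#' @param path output path
#' @param frames frame indices to write (default all); a single frame is
#'   written without MODEL records
#' @param selection optional [select_atoms()] result restricting atoms
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path, frames = seq_len(n_frames(x)),
                      selection = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(x)) else selection$indices
  a <- x$atoms[idx, , drop = FALSE]
  rectype <- ifelse(a$is_ligand | a$is_water, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) <= 3L, paste0(" ", a$name), a$name)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- frame_coords(x, frames[k], idx)
    writeLines(sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, a$serial, name4, a$resname, a$chain, a$resno,
      m[, 1], m[, 2], m[, 3], 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms with a small expression grammar
#'
#' Clauses joined by `and`; supported clauses:
#' `name <N1,N2,...>` (atom-name equality), `heavy` (element != H),
#' `ligand`, `protein`, `water`, `all`, `chain <A,B>`, and
#' `resno <a:b>` (inclusive residue-number range; also `a-b`, a single
#' number, or a comma list of ranges). Water atoms are excluded from every
#' selection unless the expression names `water` or `all` explicitly.
#'
#' @param x a `traj`
#' @param expr selection expression, e.g. `"name CA and resno 457:477"`
#' @return object of class `atom_selection`: list with ordered unique
#'   `indices` into the topology and the `label` used
#' @export
select_atoms <- function(x, expr = "protein") {
  a <- x$atoms
  clauses <- trimws(strsplit(expr, "\\band\\b")[[1]])
  clauses <- clauses[nchar(clauses) > 0]
  if (length(clauses) == 0L) stop("empty selection expression")
  mask <- rep(TRUE, nrow(a))
  water_ok <- FALSE
  for (cl in clauses) {
    toks <- strsplit(cl, "[[:space:]]+")[[1]]
    kw <- tolower(toks[1])
    arg <- if (length(toks) > 1) paste(toks[-1], collapse = ",") else ""
    m <- switch(kw,
      name = {
        if (arg == "") stop("selection clause 'name' needs atom names")
        a$name %in% strsplit(arg, ",")[[1]]
      },
      heavy = a$is_heavy,
      ligand = a$is_ligand,
      protein = !a$is_ligand & !a$is_water,
      water = { water_ok <- TRUE; a$is_water },
      all = { water_ok <- TRUE; rep(TRUE, nrow(a)) },
      chain = {
        if (arg == "") stop("selection clause 'chain' needs chain ids")
        a$chain %in% strsplit(arg, ",")[[1]]
      },
      resno = {
        if (arg == "") stop("selection clause 'resno' needs a range")
        keep <- rep(FALSE, nrow(a))
        for (part in strsplit(arg, ",")[[1]]) {
          b <- as.integer(strsplit(part, "[:-]")[[1]])
          if (anyNA(b)) stop("bad residue range: ", part)
          if (length(b) == 1L) b <- c(b, b)
          keep <- keep | (a$resno >= b[1] & a$resno <= b[2])
        }
        keep
      },
      stop("unknown selection token: '", kw, "'")
    )
    mask <- mask & m
  }
  if (!water_ok) mask <- mask & !a$is_water
  idx <- which(mask)
  if (length(idx) == 0L) warning("empty selection: '", expr, "'")
  structure(list(indices = idx, label = expr), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

#' Dump selected coordinates of every frame to CSV
#'
#' Columns: frame, time_ns, serial, name, resno, resname, x, y, z with
#' coordinates rounded to 3 decimals (PDB precision). An empty selection
#' produces a header-only file with a warning.
#'
#' @param x a `traj`
#' @param selection an [select_atoms()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_frames_csv <- function(x, selection, path) {
  idx <- selection$indices
  if (length(idx) == 0L) {
    warning("empty selection: writing header-only file")
    utils::write.csv(data.frame(frame = integer(), time_ns = numeric(),
                                serial = integer(), name = character(),
                                resno = integer(), resname = character(),
                                x = numeric(), y = numeric(), z = numeric()),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_len(n_frames(x)), function(f) {
    m <- frame_coords(x, f, idx)
    data.frame(frame = f, time_ns = x$times[f],
               serial = x$atoms$serial[idx], name = x$atoms$name[idx],
               resno = x$atoms$resno[idx], resname = x$atoms$resname[idx],
               x = round(m[, 1], 3), y = round(m[, 2], 3),
               z = round(m[, 3], 3), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read back a [write_frames_csv()] dump
#' @param path CSV path
#' @return data.frame as written
#' @export
read_frames_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# restrict a trajectory to a subset of frames
subset_frames <- function(x, frames) {
  new_traj(x$atoms, x$xyz[frames, , drop = FALSE], x$times[frames])
}
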