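.energy_terms <- c("coulomb", "hbond", "gb_solvation", "vdw", "pi_pi",
                   "self_contact", "lipophilic")
.energy_entities <- c("complex", "receptor", "ligand")
.energy_groups <- list(
  electrostatic = c("coulomb", "hbond", "gb_solvation"),
  vdw = c("vdw", "pi_pi", "self_contact"),
  lipophilic = "lipophilic")

validate_energy_table <- function(tab) {
  need <- c("frame", "entity", "term", "value")
  if (!all(need %in% names(tab)))
    stop("energy table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$term), .energy_terms)
  if (length(bad)) stop("unknown energy term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$entity), .energy_entities)
  if (length(bad)) stop("unknown entity(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab[, c("frame", "entity", "term")]))
    stop("duplicate (frame, entity, term) rows")
  tab
}

#' Read a long-format MM-GBSA term table
#'
#' Expected columns: `frame` (int), `entity` (complex / receptor / ligand),
#' `term` (coulomb, hbond, gb_solvation, vdw, pi_pi, self_contact,
#' lipophilic) and `value` (kcal/mol).
#'
#' @param path delimited text file
#' @param sep field separator (default tab)
#' @return validated data.frame of class `energy_table`
#' @export
read_energy_table <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  structure(validate_energy_table(tab), class = c("energy_table",
                                                  "data.frame"))
}

entity_totals <- function(tab) {
  agg <- stats::aggregate(value ~ frame + entity, tab, sum)
  wide <- stats::reshape(agg, idvar = "frame", timevar = "entity",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (e in .energy_entities) if (!e %in% names(wide)) wide[[e]] <- NA_real_
  missing <- wide$frame[!stats::complete.cases(
    wide[, .energy_entities, drop = FALSE])]
  if (length(missing))
    stop("frame(s) missing an entity: ",
         paste(utils::head(missing, 5), collapse = ", "))
  wide[order(wide$frame), ]
}

#' Per-frame MM-GBSA binding energy
#'
#' dG(f) = E_complex(f) - (E_ligand(f) + E_receptor(f)), each entity energy
#' being the sum of its term values for the frame.
#'
#' @param tab an energy term table (see [read_energy_table()])
#' @return data.frame with columns `frame`, `dG` (kcal/mol)
#' @export
binding_energy_per_frame <- function(tab) {
  tab <- validate_energy_table(tab)
  w <- entity_totals(tab)
  data.frame(frame = w$frame, dG = w$complex - w$ligand - w$receptor)
}

#' Grouped binding-energy components per frame
#'
#' The seven terms are merged into three groups - electrostatic
#' (coulomb + hbond + gb_solvation), vdw (vdw + pi-pi + self-contact) and
#' lipophilic - each evaluated on the complex - ligand - receptor
#' difference, so the three group series sum exactly to dG per frame.
#'
#' @param tab an energy term table
#' @return data.frame with columns `frame`, `electrostatic`, `vdw`,
#'   `lipophilic`
#' @export
group_components <- function(tab) {
  tab <- validate_energy_table(tab)
  frames <- sort(unique(tab$frame))
  out <- data.frame(frame = frames)
  sgn <- c(complex = 1, ligand = -1, receptor = -1)
  for (g in names(.energy_groups)) {
    sub <- tab[tab$term %in% .energy_groups[[g]], ]
    if (nrow(sub) == 0L) {
      out[[g]] <- 0
      next
    }
    contrib <- sub$value * sgn[sub$entity]
    s <- tapply(contrib, factor(sub$frame, levels = frames), sum,
                default = 0)
    out[[g]] <- as.numeric(s)
  }
  out
}

#' Windowed binding-energy summary
#'
#' Mean and sample (n-1) standard deviation of the per-frame binding energy
#' and of the grouped components over a trailing window - mirroring the
#' convention of summarising MM-GBSA over the final, equilibrated stretch of
#' a trajectory.
#'
#' @param dg data.frame from [binding_energy_per_frame()]
#' @param grouped optional data.frame from [group_components()]
#' @param window_last fraction of frames (0 < x <= 1) or an absolute frame
#'   count (> 1) taken from the end of the series; default 0.2
#' @return object of class `binding_energy_summary`: list with `dE_mean`,
#'   `dE_sd` (kcal/mol), `grouped` (component, mean, sd), `window` (first
#'   and last frame id used), `n_used`
#' @export
summarize_window <- function(dg, grouped = NULL, window_last = 0.2) {
  n <- nrow(dg)
  if (n == 0L) stop("empty energy series")
  n_use <- if (window_last <= 1) max(1L, ceiling(window_last * n)) else
    as.integer(window_last)
  if (n_use > n) stop("window exceeds the series (", n_use, " > ", n, ")")
  rows <- (n - n_use + 1L):n
  sdev <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  gs <- NULL
  if (!is.null(grouped)) {
    gs <- data.frame(component = names(.energy_groups),
                     mean = vapply(names(.energy_groups), function(g)
                       mean(grouped[[g]][rows]), 1),
                     sd = vapply(names(.energy_groups), function(g)
                       sdev(grouped[[g]][rows]), 1))
    rownames(gs) <- NULL
  }
  structure(list(dE_mean = mean(dg$dG[rows]), dE_sd = sdev(dg$dG[rows]),
                 grouped = gs,
                 window = c(dg$frame[rows[1]], dg$frame[rows[n_use]]),
                 n_used = n_use),
            class = "binding_energy_summary")
}

#' @export
print.binding_energy_summary <- function(x, ...) {
  cat(sprintf("dE = %.1f +/- %.1f kcal/mol (frames %d-%d, n = %d)\n",
              x$dE_mean, x$dE_sd, x$window[1], x$window[2], x$n_used))
  if (!is.null(x$grouped)) {
    for (k in seq_len(nrow(x$grouped)))
      cat(sprintf("  %-13s %8.1f +/- %.1f\n", x$grouped$component[k],
                  x$grouped$mean[k], x$grouped$sd[k]))
  }
  invisible(x)
}

#' Relative binding energies across systems
#'
#' ddE_s = dE_s - min_s(dE_s): the most favourable (most negative) system
#' is the reference at 0 and every other system is reported relative to it.
#'
#' @param means named numeric vector of per-system mean binding energies
#'   (kcal/mol, favourable = negative)
#' @return named numeric vector of relative energies (>= 0, exactly one 0
#'   when the minimum is unique)
#' @export
relative_energies <- function(means) {
  if (length(means) < 1L) stop("need at least one system")
  means - min(means)
}

#' Read a per-residue decomposition table
#'
#' Two delimited columns: residue id (e.g. `VAL_332`) and contribution in
#' kcal/mol (favourable = negative).
#'
#' @param path delimited text file with header `residue`, `energy`
#' @param sep field separator (default tab)
#' @return data.frame of class `residue_decomposition`
#' @export
read_residue_decomposition <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("residue", "energy") %in% names(tab)))
    stop("decomposition table needs columns residue, energy")
  if (anyDuplicated(tab$residue)) stop("duplicate residue ids")
  structure(tab[, c("residue", "energy")],
            class = c("residue_decomposition", "data.frame"))
}

decomp_resno <- function(ids) {
  suppressWarnings(as.integer(sub("^.*_([0-9]+).*$", "\\1", ids)))
}

#' Total contribution of a residue set
#'
#' @param decomp a residue decomposition (data.frame residue, energy)
#' @param residue_ids residue ids to sum; every id must be present
#' @return numeric sum in kcal/mol
#' @export
residue_set_total <- function(decomp, residue_ids) {
  if (length(residue_ids) == 0L) return(0)
  miss <- setdiff(residue_ids, decomp$residue)
  if (length(miss))
    stop("residue id(s) not in decomposition: ", paste(miss, collapse = ", "))
  sum(decomp$energy[match(residue_ids, decomp$residue)])
}

#' Top contributing residues by magnitude
#'
#' @param decomp a residue decomposition
#' @param k number of residues to return (default 1)
#' @return decomposition rows ordered by descending |energy|, ties broken
#'   by ascending residue number
#' @export
top_contributors <- function(decomp, k = 1L) {
  if (nrow(decomp) == 0L) stop("empty decomposition")
  ord <- order(-abs(decomp$energy), decomp_resno(decomp$residue))
  out <- decomp[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residues contributing over a magnitude threshold
#'
#' @param decomp a residue decomposition
#' @param min_magnitude strict magnitude bound in kcal/mol (default 1.0)
#' @return decomposition rows with |energy| > `min_magnitude`, sorted by
#'   descending magnitude
#' @export
threshold_report <- function(decomp, min_magnitude = 1.0) {
  keep <- abs(decomp$energy) > min_magnitude
  out <- decomp[keep, , drop = FALSE]
  out <- out[order(-abs(out$energy), decomp_resno(out$residue)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
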