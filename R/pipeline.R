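.default_config <- function() list(
  input = NULL,              # trajectory PDB (required)
  reference = NULL,          # reference PDB (default: first frame of input)
  out_dir = "trajcomm_run",
  seed = 1L,
  stages = c("rmsd", "rmsf", "cluster", "network", "pca"),
  fit_selection = "name CA and protein",
  rmsf = list(equilibration_cut = NULL),
  helix_range = NULL,        # e.g. c(457, 477)
  cluster = list(cutoff = 2.5, max_frames = 2000),
  network = list(cutoff = 4.5, min_occupancy = 0.75,
                 neighbor_exclusion = 2, ligand_node = "centroid"),
  pca = list(n_modes = 5),
  interactions = list(report_threshold = 0.30),
  energy = list(table = NULL, window_last = 0.2)
)

validate_config <- function(config) {
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      merged[[k]][names(config[[k]])] <- config[[k]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  if (is.null(merged$input)) stop("config needs 'input' (a PDB path)")
  if (!file.exists(merged$input)) stop("input not found: ", merged$input)
  if (merged$cluster$cutoff <= 0) stop("cluster cutoff must be positive")
  if (merged$network$cutoff <= 0) stop("network cutoff must be positive")
  if (merged$network$min_occupancy < 0 || merged$network$min_occupancy > 1)
    stop("min_occupancy must be in [0, 1]")
  if (merged$pca$n_modes < 1) stop("pca n_modes must be >= 1")
  bad <- setdiff(merged$stages,
                 c("rmsd", "rmsf", "cluster", "network", "pca",
                   "interactions", "energy", "helix"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  merged
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file
#' @return validated config list
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages on a trajectory in dependency order and
#' writes per-stage CSV/TSV outputs plus a manifest JSON (inputs,
#' parameters, package version, seed) into `out_dir`. Numeric outputs are
#' deterministic for a fixed config and seed. Log lines go to stderr.
#'
#' @param config a config list, or a path to a YAML/JSON config file;
#'   see [read_config()]. Required key: `input` (multi-model PDB).
#' @return invisibly, a list with the computed per-stage results and
#'   `out_dir`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[trajcomm] ", ...)
  out <- list()
  x <- run_stage("io", read_pdb(cfg$input))
  ref <- if (!is.null(cfg$reference))
    run_stage("io", read_pdb(cfg$reference)) else x
  log("input: ", cfg$input, " (", n_frames(x), " frames, ",
      n_atoms(x), " atoms)")
  fit_sel <- cfg$fit_selection
  p <- function(f) file.path(cfg$out_dir, f)

  if ("rmsd" %in% cfg$stages) {
    out$rmsd <- run_stage("rmsd", rmsd_series(x, ref, fit_sel))
    utils::write.csv(out$rmsd, p("rmsd.csv"), row.names = FALSE)
    log("rmsd: mean ", round(mean(out$rmsd$rmsd), 3), " A")
  }
  if ("rmsf" %in% cfg$stages) {
    out$rmsf <- run_stage("rmsf", rmsf_profile(
      x, "name CA and protein", fit_sel,
      equilibration_cut = cfg$rmsf$equilibration_cut))
    utils::write.csv(out$rmsf, p("rmsf.csv"), row.names = FALSE)
  }
  if ("helix" %in% cfg$stages || !is.null(cfg$helix_range)) {
    if (is.null(cfg$helix_range)) stop("stage 'helix' needs helix_range")
    out$helix <- run_stage("helix", subrange_rmsd(
      x, ref, cfg$helix_range, fit_sel))
    utils::write.csv(out$helix$rmsd, p("helix_rmsd.csv"), row.names = FALSE)
    utils::write.csv(out$helix$histogram, p("helix_rmsd_hist.csv"),
                     row.names = FALSE)
  }
  if ("cluster" %in% cfg$stages) {
    out$cluster <- run_stage("cluster", {
      fdm <- pairwise_rmsd_matrix(x, fit_sel,
                                  max_frames = cfg$cluster$max_frames)
      average_linkage(fdm, cfg$cluster$cutoff)
    })
    write_cluster_report(out$cluster, p("clusters.csv"), x)
    log("cluster: ", nrow(out$cluster$clusters), " cluster(s)")
  }
  if ("network" %in% cfg$stages) {
    out$network <- run_stage("network", {
      nt <- node_trajectory(x, cfg$network$ligand_node)
      g <- build_contact_graph(x, cfg$network$cutoff,
                               cfg$network$min_occupancy,
                               cfg$network$neighbor_exclusion,
                               cfg$network$ligand_node)
      wg <- weight_edges(g, correlation_matrix(nt))
      part <- girvan_newman(wg)
      write_edge_list(wg, part, p("network_edges.tsv"))
      utils::write.csv(
        data.frame(node = names(part$membership),
                   community = unname(part$membership),
                   critical = names(part$membership) %in%
                     part$critical_nodes),
        p("communities.csv"), row.names = FALSE)
      list(graph = wg, partition = part)
    })
    log("network: ", length(out$network$partition$communities),
        " communities, modularity ",
        round(out$network$partition$modularity, 3))
  }
  if ("pca" %in% cfg$stages) {
    out$pca <- run_stage("pca", {
      nt <- node_trajectory(x, "none")
      ms <- covariance_pca(nt, cfg$pca$n_modes)
      utils::write.csv(data.frame(mode = seq_along(ms$values),
                                  eigenvalue = ms$values),
                       p("pca_eigenvalues.csv"), row.names = FALSE)
      utils::write.csv(mode_rmsf(ms, 1), p("pca_mode1_rmsf.csv"),
                       row.names = FALSE)
      ms
    })
  }
  if ("interactions" %in% cfg$stages) {
    out$interactions <- run_stage("interactions", {
      ev <- detect_interactions(x)
      fr <- interaction_fractions(ev, n_frames(x),
                                  cfg$interactions$report_threshold)
      utils::write.csv(ev, p("interaction_events.csv"), row.names = FALSE)
      utils::write.csv(fr$table, p("interaction_fractions.csv"),
                       row.names = FALSE)
      fr
    })
  }
  if ("energy" %in% cfg$stages) {
    if (is.null(cfg$energy$table)) stop("stage 'energy' needs energy$table")
    out$energy <- run_stage("energy", {
      tab <- read_energy_table(cfg$energy$table)
      dg <- binding_energy_per_frame(tab)
      grp <- group_components(tab)
      s <- summarize_window(dg, grp, cfg$energy$window_last)
      jsonlite::write_json(
        list(dE_mean = s$dE_mean, dE_sd = s$dE_sd,
             grouped = s$grouped, window = s$window),
        p("energy_summary.json"), auto_unbox = TRUE, digits = NA)
      s
    })
  }
  manifest <- list(
    package = "trajcomm",
    version = as.character(utils::packageVersion("trajcomm")),
    input = cfg$input, reference = cfg$reference,
    seed = cfg$seed, stages = cfg$stages,
    parameters = cfg[c("fit_selection", "rmsf", "helix_range", "cluster",
                       "network", "pca", "interactions", "energy")])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  out$out_dir <- cfg$out_dir
  invisible(out)
}
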