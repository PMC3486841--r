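#' Build a validated analysis configuration
#'
#' Accepts a YAML file path or a named list. Unset fields take the
#' documented defaults; unknown fields are rejected so typos fail loudly.
#'
#' @param config YAML path or named list. Recognized fields: `trajectory`
#'   (PDB path, required unless a `trajectory` object is passed to
#'   [run_analysis()]), `dt_ps` (10), `exclude_ps` (1000), `d_on` (4),
#'   `d_off` (6), `ph` (5.5), `interface_residues` (character vector),
#'   `rho_max` (-0.5), `min_occupancy` (0.05), `window_ps` (100),
#'   `bootstrap` (list `n_boot` 1000, `block_frames` 100), `seed` (1),
#'   `max_rmsd_frames` (60), `output_dir` (required by [run_analysis()]).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(trajectory = NULL, dt_ps = 10, exclude_ps = 1000,
                   d_on = 4.0, d_off = 6.0, ph = 5.5,
                   interface_residues = character(), rho_max = -0.5,
                   min_occupancy = 0.05, window_ps = 100,
                   bootstrap = list(n_boot = 1000, block_frames = 100),
                   seed = 1, max_rmsd_frames = 60, output_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$d_on < cfg$d_off)) stop("config: d_on must be < d_off")
  if (cfg$exclude_ps < 0) stop("config: exclude_ps must be >= 0")
  structure(cfg, class = c("analysis_config", "list"))
}

#' Run the full shuttle analysis pipeline
#'
#' Trajectory in, report out: read the multi-model PDB (or take a
#' `trajectory` directly), identify charged groups under the protonation
#' policy, build the salt-bridge network, detect shuttle motifs by distance
#' anticorrelation, classify open/bridged states for the top motif, compute
#' occupancies, exchange kinetics, a block-bootstrap CI on rho, and a
#' cross-RMSD summary; write `report.json` plus TSV tables
#' (`edges.tsv`, `states.tsv`, `distances.tsv`, `cross_rmsd.tsv`) under
#' `output_dir`. Re-running with identical config and inputs reproduces the
#' report byte for byte (all randomness flows from the config seed; no
#' timestamps in the payload).
#'
#' @param config an [analysis_config()], list, or YAML path.
#' @param traj optional pre-loaded `trajectory` (overrides
#'   `config$trajectory`).
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
run_analysis <- function(config, traj = NULL) {
  cfg <- analysis_config(if (inherits(config, "analysis_config"))
    unclass(config) else config)
  if (is.null(traj)) {
    if (is.null(cfg$trajectory)) {
      stop("config: 'trajectory' path is required when no trajectory ",
           "object is supplied")
    }
    traj <- read_multimodel_pdb(cfg$trajectory, dt_ps = cfg$dt_ps)
  }
  policy <- protonation_policy(pH = cfg$ph)
  groups <- identify_charged_groups(traj, policy)
  labels <- vapply(groups, function(g) g$label, "")
  missing <- setdiff(cfg$interface_residues, labels)
  if (length(missing) > 0L) {
    stop("config validation: interface residue(s) not found in topology: ",
         paste(missing, collapse = ", "))
  }
  network <- build_bridge_network(traj, groups, d_on = cfg$d_on,
                                  d_off = cfg$d_off,
                                  min_occupancy = cfg$min_occupancy,
                                  exclude_ps = cfg$exclude_ps)
  motifs <- detect_shuttle_motifs(network, traj, rho_max = cfg$rho_max,
                                  interface_residues = cfg$interface_residues)
  motif_report <- NULL
  top <- NULL
  if (length(motifs) > 0L) {
    top <- motifs[[1L]]
    p_if <- top$interface_partner %||% top$partner_a
    p_rm <- top$remote_partner %||% top$partner_b
    s_if <- network_series(network, top$central$label, p_if$label)
    s_rm <- network_series(network, top$central$label, p_rm$label)
    b_if <- bridge_state_series(s_if, cfg$d_on, cfg$d_off)
    b_rm <- bridge_state_series(s_rm, cfg$d_on, cfg$d_off)
    states <- classify_shuttle_states(b_if, b_rm)
    stats <- shuttle_kinetics(states, rho = top$rho)
    block <- min(cfg$bootstrap$block_frames, length(s_if$values_A))
    ci <- block_bootstrap_ci(s_if, s_rm, n_boot = cfg$bootstrap$n_boot,
                             block_frames = block, seed = cfg$seed)
    motif_report <- list(
      central = top$central$label, interface = p_if$label,
      remote = p_rm$label,
      roles_assigned = !is.null(top$interface_partner),
      rho = top$rho, rho_ci95 = ci$ci,
      occupancy = as.list(stats$occupancy),
      n_exchanges = stats$n_exchanges,
      exchange_rate_per_ns = stats$exchange_rate_per_ns,
      dwell_mean_ps = lapply(stats$dwell, function(d) d$mean_ps))
  }
  # cross-RMSD over anchors/backbone, subsampled for the O(n^2) pair loop
  rmsd_summary <- NULL
  if (any(traj$topology$name %in% c("CA", "CB"))) {
    nf <- n_frames(traj)
    pick <- unique(round(seq(1, nf, length.out = min(cfg$max_rmsd_frames, nf))))
    sub <- new_trajectory(traj$topology,
                          traj$coords[, , pick, drop = FALSE],
                          dt_ps = traj$dt_ps, t0_ps = traj$t0_ps)
    xr <- cross_rmsd_matrix(sub, "CA,CB")
    off <- xr$rmsd[upper.tri(xr$rmsd)]
    rmsd_summary <- list(n_frames = length(pick),
                         mean_A = if (length(off)) mean(off) else 0,
                         max_A = if (length(off)) max(off) else 0)
  }
  report <- list(
    provenance = list(package = "bridgeswitch",
                      version = as.character(utils::packageVersion("bridgeswitch")),
                      seed = cfg$seed,
                      config = cfg[setdiff(names(cfg), "output_dir")]),
    n_charged_groups = length(groups),
    n_frames_analyzed = network$n_frames_used,
    edges = network$edges,
    n_motifs = length(motifs),
    motif = motif_report,
    cross_rmsd = rmsd_summary)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(network$edges,
                       file.path(cfg$output_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(top)) {
      utils::write.table(
        data.frame(time_ps = states$times_ps, state = states$labels),
        file.path(cfg$output_dir, "states.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      smooth_if <- running_average(s_if, cfg$window_ps)
      smooth_rm <- running_average(s_rm, cfg$window_ps)
      utils::write.table(
        data.frame(time_ps = s_if$times_ps,
                   d_interface_A = s_if$values_A,
                   d_remote_A = s_rm$values_A,
                   d_interface_smooth_A = smooth_if$values_A,
                   d_remote_smooth_A = smooth_rm$values_A),
        file.path(cfg$output_dir, "distances.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(rmsd_summary)) {
      utils::write.table(as.data.frame(rmsd_summary),
                         file.path(cfg$output_dir, "cross_rmsd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(report)
}
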