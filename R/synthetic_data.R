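#' Parameters for the two-state shuttle simulator
#'
#' The generative model is a two-state continuous-time Markov chain over
#' OPEN and BRIDGED, sampled exactly (Gillespie, exponential waiting times)
#' and discretized at the frame interval by interval-midpoint state. Each
#' frame emits two noisy minimum distances: central-interface and
#' central-remote. In BRIDGED frames the interface distance is drawn from
#' the "formed" distribution and the remote one from "broken"; OPEN frames
#' the reverse. Emission defaults (formed 3.0 +/- 0.4 A, broken
#' 8.5 +/- 1.2 A) mimic the bimodal oscillation of salt-bridge distance
#' traces between ~3 A contact and a broken state beyond 8 A.
#'
#' @param k_ob OPEN to BRIDGED rate in 1/ns (> 0).
#' @param k_bo BRIDGED to OPEN rate in 1/ns (> 0).
#' @param n_frames number of frames (>= 1).
#' @param dt_ps frame interval in ps.
#' @param emissions list with `formed` and `broken`, each `c(mean=, sd=)` in
#'   Angstrom; formed mean must lie below broken mean.
#' @param seed integer seed; the whole truth object is reproducible from it.
#' @param scenario `"shuttle"` (coupled, the planted motif), `"uncoupled"`
#'   (remote distance follows an independent second chain; anticorrelation
#'   vanishes) or `"interface_broken"` (interface emissions forced broken
#'   regardless of state, emulating a central residue that can no longer
#'   bridge the interface acid, as in a lysine-to-histidine substitution).
#' @param phi optional AR(1) coefficient in \[0, 1) for temporally
#'   correlated emission noise (default 0, white noise).
#' @param labels central/interface/remote residue labels used for the
#'   emitted series and toy structures.
#' @return object of class `shuttle_params`.
#' @export
shuttle_params <- function(k_ob, k_bo, n_frames, dt_ps = 10,
                           emissions = list(formed = c(mean = 3.0, sd = 0.4),
                                            broken = c(mean = 8.5, sd = 1.2)),
                           seed = 1, scenario = "shuttle", phi = 0,
                           labels = c(central = "K109", interface = "E105",
                                      remote = "D137")) {
  stopifnot(k_ob > 0, k_bo > 0, n_frames >= 1, dt_ps > 0,
            emissions$formed[["sd"]] > 0, emissions$broken[["sd"]] > 0,
            phi >= 0, phi < 1)
  if (!emissions$formed[["mean"]] < emissions$broken[["mean"]]) {
    stop("formed emission mean must be below broken emission mean")
  }
  scenario <- match.arg(scenario, c("shuttle", "uncoupled", "interface_broken"))
  structure(list(k_ob = k_ob, k_bo = k_bo, n_frames = as.integer(n_frames),
                 dt_ps = dt_ps, emissions = emissions, seed = as.integer(seed),
                 scenario = scenario, phi = phi, labels = labels),
            class = "shuttle_params")
}

# Exact Gillespie path of the two-state chain up to t_end (ns), initial
# state drawn from the stationary distribution. Returns transition times and
# the state sequence (1 = OPEN, 2 = BRIDGED).
gillespie_path <- function(k_ob, k_bo, t_end_ns) {
  state <- if (stats::runif(1) < k_bo / (k_ob + k_bo)) 1L else 2L
  t <- 0
  times <- numeric(0)
  states <- state
  while (t < t_end_ns) {
    rate <- if (state == 1L) k_ob else k_bo
    t <- t + stats::rexp(1, rate)
    if (t >= t_end_ns) break
    state <- 3L - state
    times <- c(times, t)
    states <- c(states, state)
  }
  list(transition_times_ns = times, states = states)
}

state_at <- function(path, t_ns) {
  path$states[findInterval(t_ns, path$transition_times_ns) + 1L]
}

ar1_noise <- function(n, sd, phi) {
  if (phi == 0) return(stats::rnorm(n, 0, sd))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  x[1] <- stats::rnorm(1, 0, sd)  # start at stationary marginal
  x
}

#' Simulate a ground-truth shuttle trajectory
#'
#' Draws an exact Gillespie path of the two-state chain, assigns each frame
#' the state at its interval midpoint (less aliasing bias at coarse frame
#' spacing than endpoint sampling), and emits independent Gaussian distances
#' per frame, truncated at a 0.5 A physical floor. Fully reproducible from
#' the seed. If the expected number of transitions per frame exceeds 0.5 an
#' aliasing warning is raised (the run still completes).
#'
#' @param params a [shuttle_params()].
#' @return object of class `shuttle_truth`: per-frame true states
#'   (`"OPEN"`/`"BRIDGED"`), the emitted `d_interface` and `d_remote`
#'   `distance_series`, and the generating parameters.
#' @export
simulate_shuttle <- function(params) {
  stopifnot(inherits(params, "shuttle_params"))
  dt_ns <- params$dt_ps / 1000
  if (dt_ns * max(params$k_ob, params$k_bo) > 0.5) {
    warning("frame interval is coarse relative to exchange rates: ",
            "expected transitions per frame exceed 0.5 (aliasing likely)",
            call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  n <- params$n_frames
  t_end_ns <- n * dt_ns
  mid_ns <- (seq_len(n) - 0.5) * dt_ns
  path <- gillespie_path(params$k_ob, params$k_bo, t_end_ns)
  states <- ifelse(state_at(path, mid_ns) == 1L, "OPEN", "BRIDGED")
  em <- params$emissions
  draw <- function(state_is_formed) {
    mu <- ifelse(state_is_formed, em$formed[["mean"]], em$broken[["mean"]])
    sd <- ifelse(state_is_formed, em$formed[["sd"]], em$broken[["sd"]])
    # one stationary AR(1)/white noise stream per channel, scaled per frame
    pmax(0.5, mu + sd * ar1_noise(n, 1, params$phi))
  }
  interface_formed <- switch(params$scenario,
    shuttle = states == "BRIDGED",
    interface_broken = rep(FALSE, n),
    uncoupled = states == "BRIDGED")
  d_interface <- draw(interface_formed)
  remote_states <- states
  if (params$scenario == "uncoupled") {
    path2 <- gillespie_path(params$k_ob, params$k_bo, t_end_ns)
    remote_states <- ifelse(state_at(path2, mid_ns) == 1L, "OPEN", "BRIDGED")
  }
  d_remote <- draw(remote_states == "OPEN")
  times_ps <- (seq_len(n) - 1L) * params$dt_ps
  lb <- params$labels
  structure(
    list(params = params, times_ps = times_ps, states = states,
         d_interface = new_distance_series(times_ps, d_interface,
                                           lb[["central"]], lb[["interface"]]),
         d_remote = new_distance_series(times_ps, d_remote,
                                        lb[["central"]], lb[["remote"]]),
         transition_times_ns = path$transition_times_ns),
    class = "shuttle_truth"
  )
}

#' @export
print.shuttle_truth <- function(x, ...) {
  cat(sprintf(
    "<shuttle_truth> %d frames (%s), BRIDGED fraction %.3f, %d transitions\n",
    length(x$states), x$params$scenario, mean(x$states == "BRIDGED"),
    length(x$transition_times_ns)))
  invisible(x)
}

label_residue_name <- function(label) {
  switch(substr(label, 1, 1), E = "GLU", D = "ASP", K = "LYS", H = "HIS",
         R = "ARG", "GLY")
}
label_charge_atom <- function(residue_name) {
  switch(residue_name, GLU = "OE1", ASP = "OD1", LYS = "NZ", HIS = "NE2",
         ARG = "NH1", "CA")
}

#' Embed a simulated shuttle as a toy multi-model trajectory
#'
#' Builds pseudo-residues with standard atom names so the whole pipeline
#' (PDB I/O, charged-group identification, distance series, superposition)
#' can run end to end: the central lysine NZ sits at the origin, the
#' interface acid's carboxylate oxygen at distance `d_interface` along x,
#' the remote acid's oxygen at distance `d_remote` at 120 degrees in the
#' xy-plane, plus three static CA anchor atoms for superposition tests.
#' Distances recomputed from the written PDB match the emitted series to
#' within the 3-decimal coordinate precision (2e-3 A).
#'
#' @param truth a `shuttle_truth`.
#' @return a `trajectory`.
#' @export
embed_toy_trajectory <- function(truth) {
  lb <- truth$params$labels
  res_names <- vapply(lb, label_residue_name, "")
  charge_atoms <- vapply(res_names, label_charge_atom, "")
  seqs <- stats::setNames(as.integer(sub("^[A-Z]", "", lb)), names(lb))
  topology <- data.frame(
    serial = 1:6,
    name = c("CA", "CA", "CA", charge_atoms[["central"]],
             charge_atoms[["interface"]], charge_atoms[["remote"]]),
    residue_name = c("GLY", "GLY", "GLY", res_names[["central"]],
                     res_names[["interface"]], res_names[["remote"]]),
    chain = "A",
    residue_seq = c(1L, 2L, 3L, seqs[["central"]], seqs[["interface"]],
                    seqs[["remote"]]),
    stringsAsFactors = FALSE
  )
  n <- length(truth$states)
  di <- truth$d_interface$values_A
  dr <- truth$d_remote$values_A
  if (any(di < 0) || any(dr < 0)) stop("internal error: negative distance")
  coords <- array(0, dim = c(6L, 3L, n))
  coords[1L, , ] <- c(30, 0, 0)   # static anchors, non-collinear
  coords[2L, , ] <- c(0, 30, 0)
  coords[3L, , ] <- c(0, 0, 30)
  coords[5L, 1L, ] <- di
  coords[6L, 1L, ] <- dr * cos(2 * pi / 3)
  coords[6L, 2L, ] <- dr * sin(2 * pi / 3)
  new_trajectory(topology, coords, dt_ps = truth$params$dt_ps, t0_ps = 0)
}

#' Named simulation presets for the fixture suite
#'
#' Five study conditions: a balanced fast-exchanging wild-type-like shuttle;
#' a BRIDGED-biased slower one (a shuttle with a higher population of the
#' binding-impaired conformation and rarer exchange toward the open form);
#' an interface-disabled variant (central residue cannot bridge the
#' interface acid, as for a lysine-to-histidine substitution); a locked
#' BRIDGED variant (remote partner effectively repelled, as when the remote
#' aspartate is replaced by a like-charged lysine); and an uncoupled control
#' with two independent bridges and vanishing anticorrelation.
#'
#' @param n_frames frames per case.
#' @param dt_ps frame interval in ps.
#' @param seed base seed; each case uses a distinct derived seed.
#' @return named list of `shuttle_params`.
#' @export
fixture_presets <- function(n_frames = 20000, dt_ps = 10, seed = 1) {
  case_seed <- function(i) (seed * 101L + i) %% .Machine$integer.max
  list(
    wt_ubch6_like = shuttle_params(
      k_ob = 5, k_bo = 5, n_frames = n_frames, dt_ps = dt_ps,
      seed = case_seed(1L),
      labels = c(central = "K109", interface = "E105", remote = "D137")),
    wt_ubch8_like = shuttle_params(
      k_ob = 3, k_bo = 1, n_frames = n_frames, dt_ps = dt_ps,
      seed = case_seed(2L),
      labels = c(central = "K117", interface = "D113", remote = "D145")),
    k117h_like = shuttle_params(
      k_ob = 5, k_bo = 5, n_frames = n_frames, dt_ps = dt_ps,
      seed = case_seed(3L), scenario = "interface_broken",
      labels = c(central = "K117", interface = "D113", remote = "D145")),
    d145k_like = shuttle_params(
      k_ob = 20, k_bo = 0.1, n_frames = n_frames, dt_ps = dt_ps,
      seed = case_seed(4L),
      labels = c(central = "K117", interface = "D113", remote = "D145")),
    uncoupled_control = shuttle_params(
      k_ob = 5, k_bo = 5, n_frames = n_frames, dt_ps = dt_ps,
      seed = case_seed(5L), scenario = "uncoupled",
      labels = c(central = "K109", interface = "E105", remote = "D137"))
  )
}

#' Write the labelled fixture suite to disk
#'
#' For each preset case writes a toy multi-model PDB, the two distance
#' series as TSV, and a truth JSON (per-frame states, parameters, seed),
#' plus a manifest JSON listing the cases, their seeds and expected summary
#' ranges. The in-memory truth objects are returned alongside the manifest
#' so downstream analyses need not re-parse the PDB text.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed.
#' @param n_frames frames per case.
#' @param dt_ps frame interval in ps.
#' @param write_pdb also write the (large) multi-model PDB files.
#' @return list with `manifest` (as written) and `truths` (named list of
#'   `shuttle_truth`), invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, n_frames = 20000,
                               dt_ps = 10, write_pdb = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  presets <- fixture_presets(n_frames = n_frames, dt_ps = dt_ps, seed = seed)
  expected <- list(
    wt_ubch6_like = list(bridged_occupancy = c(0.40, 0.60), rho_max = -0.5),
    wt_ubch8_like = list(bridged_occupancy = c(0.65, 0.85), rho_max = -0.5),
    k117h_like = list(bridged_occupancy = c(0.0, 0.05), rho_max = NA),
    d145k_like = list(open_occupancy = c(0.0, 0.05), rho_max = NA),
    uncoupled_control = list(abs_rho_max = 0.1)
  )
  manifest <- list(base_seed = seed, n_frames = n_frames, dt_ps = dt_ps,
                   cases = list())
  truths <- list()
  for (case in names(presets)) {
    p <- presets[[case]]
    truth <- simulate_shuttle(p)
    truths[[case]] <- truth
    files <- list(
      d_interface = file.path(out_dir, paste0(case, "_d_interface.tsv")),
      d_remote = file.path(out_dir, paste0(case, "_d_remote.tsv")),
      truth = file.path(out_dir, paste0(case, "_truth.json")))
    write_distance_series(truth$d_interface, files$d_interface)
    write_distance_series(truth$d_remote, files$d_remote)
    jsonlite::write_json(
      list(case = case, seed = p$seed, k_ob = p$k_ob, k_bo = p$k_bo,
           dt_ps = p$dt_ps, scenario = p$scenario,
           labels = as.list(p$labels), states = truth$states),
      files$truth, auto_unbox = TRUE, digits = NA)
    if (write_pdb) {
      files$pdb <- file.path(out_dir, paste0(case, ".pdb"))
      write_multimodel_pdb(embed_toy_trajectory(truth), files$pdb)
    }
    manifest$cases[[case]] <- list(
      seed = p$seed, k_ob = p$k_ob, k_bo = p$k_bo, scenario = p$scenario,
      files = lapply(files, basename), expected = expected[[case]])
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truths = truths))
}
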