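perm_bridged_traj <- function(n = 20) {
  # K109 NZ stays 2.8 A from E105 OE1; D137 far away throughout
  frames <- replicate(n, toy_frame(nz = c(2.8, 0, 0), d137 = c(15, 0, 0)),
                      simplify = FALSE)
  toy_trajectory(frames)
}

test_that("a permanent bridge yields a single full-occupancy edge", {
  traj <- perm_bridged_traj()
  g <- identify_charged_groups(traj)
  net <- build_bridge_network(traj, g)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(sort(c(net$edges$group_a, net$edges$group_b)),
                   c("E105", "K109"))
  expect_equal(net$edges$occupancy, 1.0)
})

test_that("occupancy filtering keeps edges at exactly the threshold", {
  # formed in exactly 1 of 20 frames
  frames <- c(list(toy_frame(nz = c(2.8, 0, 0), d137 = c(15, 0, 0))),
              replicate(19, toy_frame(nz = c(9, 0, 0), d137 = c(15, 0, 0)),
                        simplify = FALSE))
  traj <- toy_trajectory(frames)
  g <- identify_charged_groups(traj)
  at <- build_bridge_network(traj, g, min_occupancy = 0.05)
  expect_true(any(at$edges$occupancy == 0.05))
  above <- build_bridge_network(traj, g, min_occupancy = 0.051)
  expect_false(any(above$edges$occupancy <= 0.05))
})

test_that("network edges only join opposite charges; empty input is fine", {
  traj <- perm_bridged_traj()
  g <- identify_charged_groups(traj)
  net <- build_bridge_network(traj, g)
  labels <- vapply(net$nodes, function(x) x$label, "")
  signs <- vapply(net$nodes, function(x) x$sign, 0L)
  for (k in seq_len(nrow(net$edges))) {
    sa <- signs[match(net$edges$group_a[k], labels)]
    sb <- signs[match(net$edges$group_b[k], labels)]
    expect_equal(sa * sb, -1L)
  }
  expect_message(empty <- build_bridge_network(traj, list()),
                 "no charged groups")
  expect_equal(nrow(empty$edges), 0L)
  expect_length(detect_shuttle_motifs(empty, traj), 0L)
})

test_that("the planted shuttle produces two central edges and one motif", {
  truth <- simulate_shuttle(shuttle_params(k_ob = 5, k_bo = 5,
                                           n_frames = 4000, seed = 141))
  traj <- embed_toy_trajectory(truth)
  g <- identify_charged_groups(traj)
  net <- build_bridge_network(traj, g, exclude_ps = 1000)
  central_edges <- net$edges$group_a == "K109" | net$edges$group_b == "K109"
  expect_equal(sum(central_edges), 2L)
  motifs <- detect_shuttle_motifs(net, traj,
                                  interface_residues = "E105")
  expect_length(motifs, 1L)
  m <- motifs[[1]]
  expect_identical(m$central$label, "K109")
  expect_identical(m$interface_partner$label, "E105")
  expect_identical(m$remote_partner$label, "D137")
  expect_lt(m$rho, -0.5)
})

test_that("uncoupled bridges are not reported as motifs", {
  truth <- simulate_shuttle(shuttle_params(k_ob = 5, k_bo = 5,
                                           n_frames = 6000, seed = 151,
                                           scenario = "uncoupled"))
  traj <- embed_toy_trajectory(truth)
  g <- identify_charged_groups(traj)
  net <- build_bridge_network(traj, g, exclude_ps = 1000)
  expect_length(detect_shuttle_motifs(net, traj, rho_max = -0.5), 0L)
  rho <- anticorrelation(truth$d_interface, truth$d_remote)$rho
  expect_lt(abs(rho), 0.2)
})

test_that("state classification applies the four-way rule", {
  mk <- function(labels) {
    structure(list(times_ps = (seq_along(labels) - 1) * 10, labels = labels,
                   d_on = 4, d_off = 6), class = "bridge_state_series")
  }
  st <- classify_shuttle_states(mk(c("FORMED", "BROKEN")),
                                mk(c("BROKEN", "FORMED")))
  expect_identical(st$labels, c("BRIDGED", "OPEN"))
  expect_identical(classify_shuttle_states(mk("FORMED"), mk("FORMED"))$labels,
                   "BIFURCATED")
  expect_identical(classify_shuttle_states(mk("BROKEN"), mk("BROKEN"))$labels,
                   "UNBOUND")
  expect_error(classify_shuttle_states(mk(rep("FORMED", 3)),
                                       mk(rep("FORMED", 2))),
               "mismatch")
})

mk_states <- function(labels, dt = 10) {
  structure(list(times_ps = (seq_along(labels) - 1) * dt, labels = labels),
            class = "shuttle_state_series")
}

test_that("kinetics counts occupancies, exchanges and dwells", {
  st <- mk_states(c("OPEN", "OPEN", "BRIDGED", "BRIDGED"))
  kin <- shuttle_kinetics(st)
  expect_equal(unname(kin$occupancy[c("OPEN", "BRIDGED")]), c(0.5, 0.5))
  expect_equal(sum(kin$occupancy), 1, tolerance = 1e-12)
  expect_equal(kin$n_exchanges, 1L)
  expect_equal(kin$dwell$OPEN$mean_ps, 20)

  # gap-tolerant rule: intermediates do not reset the transition
  expect_equal(shuttle_kinetics(mk_states(c("OPEN", "UNBOUND",
                                            "BRIDGED")))$n_exchanges, 1L)
  expect_equal(shuttle_kinetics(mk_states(c("OPEN", "BIFURCATED", "OPEN",
                                            "UNBOUND", "OPEN")))$n_exchanges,
               0L)
  expect_error(shuttle_kinetics(mk_states("OPEN")), "insufficient")
})

test_that("swapping partner roles swaps occupancies, keeps exchanges", {
  set.seed(161)
  labels <- sample(c("OPEN", "BRIDGED", "BIFURCATED", "UNBOUND"), 500,
                   replace = TRUE, prob = c(0.4, 0.4, 0.1, 0.1))
  kin <- shuttle_kinetics(mk_states(labels))
  swapped <- ifelse(labels == "OPEN", "BRIDGED",
                    ifelse(labels == "BRIDGED", "OPEN", labels))
  kin_sw <- shuttle_kinetics(mk_states(swapped))
  expect_equal(kin_sw$occupancy[["OPEN"]], kin$occupancy[["BRIDGED"]])
  expect_equal(kin_sw$occupancy[["BRIDGED"]], kin$occupancy[["OPEN"]])
  expect_equal(kin_sw$n_exchanges, kin$n_exchanges)
  # exchanges never exceed raw label changes
  expect_lte(kin$n_exchanges, sum(labels[-1] != labels[-length(labels)]))
})

test_that("kinetics recovers CTMC stationary occupancy and flux", {
  # symmetric rates: half occupancy in the long run
  occs <- vapply(1:5, function(seed) {
    truth <- simulate_shuttle(shuttle_params(k_ob = 5, k_bo = 5,
                                             n_frames = 20000, seed = seed))
    shuttle_kinetics(mk_states(truth$states))$occupancy[["BRIDGED"]]
  }, 0)
  expect_lt(abs(mean(occs) - 0.5), 0.02)

  # exchange flux ~ 2 * pi_O * k_ob * T; rates slow relative to the frame
  # interval so that sub-frame dwells (invisible at any discretization)
  # stay rare
  exch <- vapply(1:5, function(seed) {
    truth <- simulate_shuttle(shuttle_params(k_ob = 2, k_bo = 2,
                                             n_frames = 20000, seed = seed))
    shuttle_kinetics(mk_states(truth$states))$n_exchanges
  }, 0L)
  expected <- 2 * 0.5 * 2 * 200   # 400 exchanges in 200 ns
  expect_lt(abs(mean(exch) - expected), 3 * sqrt(expected))
})
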