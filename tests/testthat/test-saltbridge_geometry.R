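test_that("charged groups are identified per residue type and policy", {
  top <- toy_topology()
  groups <- identify_charged_groups(top)
  expect_length(groups, 3L)
  expect_identical(vapply(groups, function(g) g$label, ""),
                   c("E105", "K109", "D137"))
  expect_identical(vapply(groups, function(g) g$group_type, ""),
                   c("carboxylate", "ammonium", "carboxylate"))
  expect_identical(vapply(groups, function(g) g$sign, 0L), c(-1L, 1L, -1L))
  # GLY anchors contribute nothing
  expect_false(any(vapply(groups, function(g) g$residue_name, "") == "GLY"))
})

test_that("histidine charge follows the protonation policy", {
  top <- rbind(toy_topology(),
               data.frame(serial = 7:8, name = c("ND1", "NE2"),
                          residue_name = "HIS", chain = "A",
                          residue_seq = 60L))
  at_55 <- identify_charged_groups(top, protonation_policy(pH = 5.5))
  at_74 <- identify_charged_groups(top, protonation_policy(pH = 7.4))
  expect_true("H60" %in% vapply(at_55, function(g) g$label, ""))
  expect_false("H60" %in% vapply(at_74, function(g) g$label, ""))
  expect_identical(at_55[[match("H60", vapply(at_55, function(g) g$label, ""))]]$group_type,
                   "imidazolium")
})

test_that("a residue missing its charge atoms is skipped with a warning", {
  top <- toy_topology()
  top$name[top$residue_name == "LYS"] <- "CB"  # lysine lost its NZ
  expect_warning(groups <- identify_charged_groups(top), "LYS")
  expect_identical(vapply(groups, function(g) g$label, ""), c("E105", "D137"))
})

test_that("minimum pair distance matches hand values and brute force", {
  traj <- toy_trajectory(list(toy_frame(e105 = c(0, 0, 0),
                                        e105b = c(2, 0, 0),
                                        nz = c(3, 4, 0),
                                        d137 = c(5, 0, 0))))
  g <- identify_charged_groups(traj)
  fr <- get_frame(traj, 1)
  # single-atom groups at (3,4,0) vs (5,0,0): 3-4-5-ish -> sqrt(4+16)
  expect_equal(min_pair_distance(fr, g[[2]], g[[3]]), sqrt(20))
  # two carboxylate O's vs NZ: min over pairs
  expect_equal(min_pair_distance(fr, g[[1]], g[[2]]),
               min(sqrt(sum(c(3, 4, 0)^2)), sqrt(sum(c(1, 4, 0)^2))))
  # symmetry
  expect_equal(min_pair_distance(fr, g[[1]], g[[2]]),
               min_pair_distance(fr, g[[2]], g[[1]]))

  # random multi-atom groups against the exhaustive oracle
  set.seed(21)
  for (rep in 1:25) {
    na <- sample(2:10, 1)
    nb <- sample(2:10, 1)
    top <- data.frame(
      serial = seq_len(na + nb),
      name = c(paste0("OD", seq_len(na)), paste0("NH", seq_len(nb))),
      residue_name = c(rep("ASP", na), rep("ARG", nb)),
      chain = "A", residue_seq = c(rep(1L, na), rep(2L, nb)))
    xyz <- matrix(rnorm((na + nb) * 3, sd = 5), ncol = 3)
    ga <- charged_group("A", 1L, "ASP", "carboxylate", -1L,
                        paste0("OD", seq_len(na)))
    gb <- charged_group("A", 2L, "ARG", "guanidinium", 1L,
                        paste0("NH", seq_len(nb)))
    got <- min_pair_distance(list(topology = top, xyz = xyz), ga, gb)
    expect_equal(got, min_dist_oracle(xyz[seq_len(na), , drop = FALSE],
                                      xyz[na + seq_len(nb), , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("minimum pair distance is invariant under rigid-body motion", {
  set.seed(31)
  traj <- toy_trajectory(list(toy_frame(nz = c(4, 1, 2))))
  g <- identify_charged_groups(traj)
  fr <- get_frame(traj, 1)
  d0 <- min_pair_distance(fr, g[[1]], g[[2]])
  for (rep in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 20)
    fr2 <- fr
    fr2$xyz <- sweep(fr$xyz %*% t(rot), 2, -shift)
    expect_equal(min_pair_distance(fr2, g[[1]], g[[2]]), d0,
                 tolerance = 1e-10)
  }
})

test_that("equilibration exclusion drops the leading time span", {
  frames <- replicate(20, toy_frame(), simplify = FALSE)
  traj <- toy_trajectory(frames, dt_ps = 100)
  g <- identify_charged_groups(traj)
  # 20 frames at 100 ps: dropping the first 1 ns keeps frames at t >= 1000
  expect_length(distance_series(traj, g[[1]], g[[2]],
                                exclude_ps = 1000)$values_A, 10L)
  expect_length(distance_series(traj, g[[1]], g[[2]],
                                exclude_ps = 0)$values_A, 20L)
  expect_error(distance_series(traj, g[[1]], g[[2]], exclude_ps = 1e6),
               "no frames")
})

test_that("hysteretic bridge calling holds state inside the gap", {
  s <- make_series(c(3.5, 4.5, 5.5, 6.5, 5.5, 3.5))
  bs <- bridge_state_series(s, d_on = 4, d_off = 6)
  expect_identical(bs$labels, c("FORMED", "FORMED", "FORMED", "BROKEN",
                                "BROKEN", "FORMED"))
  expect_identical(bridge_state_series(make_series(rep(3, 5)))$labels,
                   rep("FORMED", 5))
  # first-frame midpoint tie-break
  expect_identical(bridge_state_series(make_series(c(4.9, 4.9)))$labels[1],
                   "FORMED")
  expect_identical(bridge_state_series(make_series(c(5.1, 5.1)))$labels[1],
                   "BROKEN")
  expect_error(bridge_state_series(s, d_on = 6, d_off = 4), "d_on")
})

test_that("no FORMED-to-BROKEN transition occurs without exceeding d_off", {
  set.seed(41)
  for (rep in 1:20) {
    v <- pmax(0.5, 5 + cumsum(rnorm(300, sd = 1.2)) * 0.2 + rnorm(300))
    bs <- bridge_state_series(make_series(v), d_on = 4, d_off = 6)
    breaks <- which(bs$labels[-1] == "BROKEN" &
                      bs$labels[-length(bs$labels)] == "FORMED") + 1L
    if (length(breaks)) expect_true(all(v[breaks] > 6))
    forms <- which(bs$labels[-1] == "FORMED" &
                     bs$labels[-length(bs$labels)] == "BROKEN") + 1L
    if (length(forms)) expect_true(all(v[forms] < 4))
  }
})

test_that("hysteresis reduces to single-threshold calling off the gap", {
  set.seed(51)
  v <- sample(c(3, 8), 200, replace = TRUE)  # never enters the gap
  eps <- 1e-9
  two <- bridge_state_series(make_series(v), d_on = 5 - eps, d_off = 5 + eps)
  expect_identical(two$labels, ifelse(v < 5, "FORMED", "BROKEN"))
})
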