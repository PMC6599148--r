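test_that("min_distance equals an exhaustive double loop and is symmetric", {
  set.seed(13)
  at <- data.frame(name = paste0("C", 1:20), resname = rep(c("AAA", "BBB"),
                                                           each = 10),
                   chain = "A", resid = rep(1:2, each = 10),
                   x = rnorm(20, 0, 5), y = rnorm(20, 0, 5),
                   z = rnorm(20, 0, 5), element = "C", het = TRUE)
  s <- structure3d(at)
  sa <- select_atoms(s, "resid 1"); sb <- select_atoms(s, "resid 2")
  got <- min_distance(s, sa, sb)
  best <- Inf
  for (i in 1:10) for (j in 11:20) {
    best <- min(best, sqrt(sum((as.numeric(at[i, c("x", "y", "z")]) -
                                as.numeric(at[j, c("x", "y", "z")]))^2)))
  }
  expect_equal(got, best, tolerance = 1e-12)
  expect_equal(min_distance(s, sb, sa), got)
  expect_error(min_distance(s, select_atoms(s, "chain Q"), sb), "empty")
})

test_that("min_distance single-pair cases and hydrogen exclusion", {
  s <- structure3d(data.frame(
    name = c("C1", "H1", "C2"), resname = c("AAA", "AAA", "BBB"), chain = "A",
    resid = c(1L, 1L, 2L), x = c(0, 4.5, 5), y = 0, z = 0,
    element = c("C", "H", "C"), het = TRUE))
  sa <- select_atoms(s, "resid 1"); sb <- select_atoms(s, "resid 2")
  expect_equal(min_distance(s, sa, sb), 5)  # H at 0.5 A ignored
  expect_equal(min_distance(s, sa, sb, heavy_only = FALSE), 0.5)
})

test_that("pair_series reproduces planted gate schedules exactly", {
  plant <- c(3, 8, 3, 8, 3, 8, 3, 8, 3, 8)
  tt <- toy_trajectory(gate_distances = plant,
                       chi_schedule = rep(0, 10))
  ps <- pair_series(tt$traj, list(tt$ledger$gate_pair))
  expect_equal(ps[[1]]$values, plant, tolerance = 1e-12)
  expect_equal(ps[[1]]$unit, "A")
  # stride 2 on 10 frames -> 5 samples
  ps2 <- pair_series(tt$traj, list(c(1, 2)), stride = 2)
  expect_length(ps2[[1]]$values, 5)
  expect_equal(ps2[[1]]$values, plant[c(1, 3, 5, 7, 9)])
  expect_error(pair_series(tt$traj, list(c(1, 999))), "not resolvable")
})

test_that("replica aggregation gives zero standard error for identical replicas", {
  tt <- toy_trajectory(gate_distances = c(3, 5, 7))
  s <- pair_series(tt$traj, list(c(1, 2)))[[1]]
  agg <- aggregate_replicas(list(s, s))
  expect_equal(agg$se, rep(0, 3))
  expect_equal(agg$mean, s$values)
  s2 <- s; s2$values <- s$values + 2
  agg2 <- aggregate_replicas(list(s, s2))
  expect_equal(agg2$mean, s$values + 1)
  expect_equal(agg2$se, rep(1, 3))  # sd = sqrt(2), se = sd/sqrt(2)
})

test_that("chi1 agrees with an independent projection-formula oracle", {
  set.seed(17)
  for (i in 1:100) {
    pts <- matrix(rnorm(12, 0, 3), 4, 3)
    # reject near-degenerate geometries
    if (min(dist(pts)) < 0.5) next
    expect_equal(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-6)
  }
})

test_that("chi1 measures constructed side chains and honors conventions", {
  s <- structure3d(occludeR:::.phe_branch("A", 7L, chi = 60))
  expect_equal(chi1(s, 7), 60, tolerance = 1e-6)
  # invariance under global rigid motion
  for (i in 1:5) {
    R <- rand_rotation()
    s2 <- set_coords(s, sweep(coords(s) %*% t(R), 2, rnorm(3, 0, 8), `+`))
    expect_equal(chi1(s2, 7), 60, tolerance = 1e-9)
  }
  # branch shift for circular means near the cut
  sneg <- set_chi(s, 7, 170)
  expect_equal(chi1(sneg, 7), 170, tolerance = 1e-6)
  expect_equal(chi1(sneg, 7, branch = "unwrapped_minus"), -190,
               tolerance = 1e-6)
  # GLY/missing atoms unevaluable
  g <- structure3d(data.frame(name = c("N", "CA", "C", "O"), resname = "GLY",
                              chain = "A", resid = 1L, x = 1:4, y = 0, z = 0,
                              element = c("N", "C", "C", "O"), het = FALSE))
  expect_true(is.na(chi1(g, 1)))
  expect_match(attr(chi1(g, 1), "reason"), "GLY")
})

test_that("set_chi then chi1 closes the loop over 100 random targets", {
  s <- structure3d(occludeR:::.phe_branch("A", 3L, chi = 10))
  set.seed(19)
  targets <- runif(100, -179.99, 180)
  for (tg in targets) {
    s <- set_chi(s, 3, tg)
    expect_equal(chi1(s, 3), tg, tolerance = 1e-6)
  }
})

test_that("helix_tilt recovers planted rotations and is symmetric", {
  toy0 <- toy_transporter(tilt_angles = c(TM1b = 17, TM6a = 8))
  expect_equal(helix_tilt(toy0$open, toy0$open, "TM1b", toy0$roles), 0,
               tolerance = 1e-9)
  expect_equal(helix_tilt(toy0$occluded, toy0$open, "TM1b", toy0$roles), 17,
               tolerance = 0.1)
  expect_equal(helix_tilt(toy0$occluded, toy0$open, "TM6a", toy0$roles), 8,
               tolerance = 0.1)
  set.seed(23)
  for (ang in c(1, runif(4, 1, 30), 30)) {
    toy <- toy_transporter(tilt_angles = c(TM1b = ang))
    got <- helix_tilt(toy$occluded, toy$open, "TM1b", toy$roles)
    expect_equal(got, ang, tolerance = 0.1)
    # angle symmetric in frame/reference and translation invariant
    expect_equal(helix_tilt(toy$open, toy$occluded, "TM1b", toy$roles), got,
                 tolerance = 1e-6)
    sh <- apply_transform(toy$occluded, structure(list(
      rotation = diag(3), translation = c(7, -4, 2), rmsd = 0),
      class = "rigid_transform"))
    expect_equal(helix_tilt(sh, toy$open, "TM1b", toy$roles), got,
                 tolerance = 1e-6)
  }
})

test_that("helix_tilt recovery also holds under the planted global motion", {
  toy <- toy_transporter(tilt_angles = c(TM1b = 12), global_rotation = 30,
                         global_axis = c(1, 2, 0),
                         global_translation = c(5, 5, 5))
  expect_equal(helix_tilt(toy$occluded, toy$open, "TM1b", toy$roles), 12,
               tolerance = 0.1)
})

test_that("helix_tilt rejects helices that are too short", {
  toy <- toy_transporter()
  short_roles <- unclass(toy$roles)
  short_roles$TM1b <- list(chain = "A", resid = "11-14")
  class(short_roles) <- "role_map"
  expect_error(helix_tilt(toy$occluded, toy$open, "TM1b", short_roles),
               "fewer than 6")
})

test_that("rmsd_series is zero for copies and rigid motions of the reference", {
  tt <- toy_trajectory(gate_distances = rep(5, 4))
  ref <- get_frame(tt$traj, 1)
  rs <- rmsd_series(tt$traj, ref, fit_expr = "protein and backbone")
  expect_equal(rs$values, rep(0, 4), tolerance = 1e-9)
  # a rigidly moved frame still fits to zero
  frames <- lapply(1:3, function(i) ref)
  R <- rand_rotation()
  frames[[2]] <- set_coords(ref, sweep(coords(ref) %*% t(R), 2, c(3, 1, -2),
                                       `+`))
  tr <- trajectory(frames)
  rs2 <- rmsd_series(tr, ref, fit_expr = "protein and backbone")
  expect_equal(rs2$values, rep(0, 3), tolerance = 1e-8)
  expect_error(rmsd_series(tt$traj, ref, fit_expr = "resname XXX"), "empty")
})

test_that("rmsd_series mean matches the analytic RMS of planted noise", {
  sd0 <- 1.2
  tn <- toy_trajectory(gate_distances = rep(5, 60), noise_sd = sd0, seed = 29)
  ref <- get_frame(toy_trajectory(gate_distances = rep(5, 1))$traj, 1)
  rs <- rmsd_series(tn$traj, ref, fit_expr = "protein and backbone")
  # per-atom displacement is isotropic N(0, sd) in 3 coords: RMS = sd*sqrt(3);
  # the 6 fitted rigid dofs absorb a fraction 6/(3*84) of the variance
  n_atoms <- length(select_atoms(ref, "protein and backbone"))
  expected <- sd0 * sqrt(3) * sqrt(1 - 6 / (3 * n_atoms))
  expect_equal(mean(rs$values), expected, tolerance = 0.05)
  # nm conversion is explicit
  rs_nm <- rmsd_series(tn$traj, ref, fit_expr = "protein and backbone",
                       unit = "nm")
  expect_equal(rs_nm$values, rs$values / 10, tolerance = 1e-12)
  expect_equal(rs_nm$unit, "nm")
})

test_that("normalized histograms integrate to one and pool replicas", {
  tt <- toy_trajectory(gate_distances = c(3, 3, 3, 3))
  s <- pair_series(tt$traj, list(c(1, 2)))[[1]]
  h <- normalized_histogram(s, bin_width = 0.5)
  expect_equal(sum(h$density) * 0.5, 1, tolerance = 1e-9)
  # constant series occupies one bin at density 1/bin_width
  expect_equal(max(h$density), 1 / 0.5, tolerance = 1e-9)
  expect_equal(sum(h$density > 0), 1)
  # pooling replicas equals the histogram of concatenated values
  s2 <- s; s2$values <- s$values + 1
  hp <- normalized_histogram(list(s, s2), bin_width = 0.5)
  hc <- normalized_histogram(c(s$values, s2$values), bin_width = 0.5)
  expect_equal(hp$density, hc$density, tolerance = 1e-12)
  expect_error(normalized_histogram(s, 0), "> 0")
})

test_that("uniform samples give a flat density within sampling error", {
  set.seed(37)
  n <- 20000
  vals <- runif(n, 0, 10)
  h <- normalized_histogram(vals, bin_width = 1)
  # each bin's density ~ 0.1 with se = sqrt(p(1-p)/n)/width ~ 0.0021
  expect_true(all(abs(h$density - 0.1) < 5 * sqrt(0.1 * 0.9 / n)))
})

test_that("trajectory containers validate their invariants", {
  tt <- toy_trajectory(gate_distances = c(3, 5))
  expect_equal(n_frames(tt$traj), 2)
  expect_error(trajectory(list(get_frame(tt$traj, 1)), times = c(1, 2)),
               "length")
  expect_error(trajectory(lapply(1:2, get_frame, traj = tt$traj),
                          times = c(2, 1)), "increasing")
  bad <- get_frame(tt$traj, 2)
  bad$atoms <- bad$atoms[-1, ]
  expect_error(trajectory(list(get_frame(tt$traj, 1), bad)), "atom count")
})
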