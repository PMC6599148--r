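test_that("compartment bands are placed analytically from the anchors", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  at <- toy$open$atoms
  z_ec <- mean(at$z[at$resid %in% c(52, 92) & at$name == "CA"])
  z_cy <- at$z[at$resid == 88 & at$name == "CA"]
  ctr <- (z_ec + z_cy) / 2
  expect_equal(spec$z_site, c(ctr - 3.5, ctr + 3.5), tolerance = 1e-9)
  # 9 + 7 + 9 = 25 with strictly ordered bands
  expect_equal(diff(spec$z_ec), 9)
  expect_equal(diff(spec$z_site), 7)
  expect_equal(diff(spec$z_ic), 9)
  if (spec$ec_dir > 0) {
    expect_equal(spec$z_ec[1], spec$z_site[2])
    expect_equal(spec$z_ic[2], spec$z_site[1])
  } else {
    expect_equal(spec$z_ec[2], spec$z_site[1])
    expect_equal(spec$z_ic[1], spec$z_site[2])
  }
  # x,y centered on the geometric center of the site anchors
  anchors <- at[(at$resid %in% c(52, 92, 88)) & at$name == "CA", ]
  expect_equal(as.numeric(spec$center_xy), c(mean(anchors$x), mean(anchors$y)),
               tolerance = 1e-9)
})

test_that("compartments shift rigidly with the structure and enforce the span", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  sh <- set_coords(toy$open, sweep(coords(toy$open), 2, c(0, 0, 11.5), `+`))
  spec2 <- build_compartments(sh, toy$roles)
  expect_equal(spec2$z_site, spec$z_site + 11.5, tolerance = 1e-9)
  expect_equal(spec2$z_ec, spec$z_ec + 11.5, tolerance = 1e-9)
  expect_equal(as.numeric(spec2$center_xy), as.numeric(spec$center_xy),
               tolerance = 1e-9)
  # anchors spanning more than the 7 A site band: error in strict mode,
  # warning otherwise
  wide_roles <- unclass(toy$roles)
  wide_roles$site_anchor_cyt <- list(chain = "A", resid = 81)  # far down TM6
  class(wide_roles) <- "role_map"
  expect_error(build_compartments(toy$open, wide_roles), "exceeds")
  expect_warning(build_compartments(toy$open, wide_roles, strict = FALSE),
                 "exceeds")
})

test_that("planted compartment counts are recovered exactly", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  hf <- hydration_frame(spec, counts = c(3, 2, 4), n_outside = 5, seed = 2)
  wc <- water_counts(hf$frame, spec)
  expect_equal(as.integer(wc), c(3L, 2L, 4L))
  expect_equal(attr(wc, "n_outside"), 5L)
  # zero request
  hf0 <- hydration_frame(spec, counts = c(0, 0, 0), n_outside = 5, seed = 3)
  expect_equal(as.integer(water_counts(hf0$frame, spec)), c(0L, 0L, 0L))
  expect_error(hydration_frame(spec, counts = c(-1, 0, 0)), ">= 0")
})

test_that("a water exactly on a z boundary goes to the lower-z compartment", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  zb <- spec$z_site[2]  # shared boundary site | band above
  mkw <- function(z) structure3d(data.frame(
    name = "O", resname = "HOH", chain = "W", resid = 1L,
    x = spec$center_xy[1], y = spec$center_xy[2], z = z,
    element = "O", het = TRUE))
  wc <- water_counts(mkw(zb), spec)
  if (spec$ec_dir > 0) expect_equal(as.integer(wc), c(0L, 1L, 0L))
  lower_edge <- min(spec$z_ic[1], spec$z_ec[1])
  wc2 <- water_counts(mkw(lower_edge), spec)
  expect_equal(sum(wc2), 0)  # the lowest boundary is outside every band
})

test_that("water counts match a brute-force point-in-box test on 1000 waters", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  set.seed(43)
  n <- 1000
  xyz <- cbind(runif(n, spec$center_xy[1] - 15, spec$center_xy[1] + 15),
               runif(n, spec$center_xy[2] - 12, spec$center_xy[2] + 12),
               runif(n, spec$z_ic[1] - 5, spec$z_ec[2] + 5))
  w <- structure3d(data.frame(name = "O", resname = "HOH", chain = "W",
                              resid = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3], element = "O", het = TRUE))
  wc <- water_counts(w, spec)
  brute <- c(0L, 0L, 0L)
  for (i in seq_len(n)) {
    if (abs(xyz[i, 1] - spec$center_xy[1]) > 10) next
    if (abs(xyz[i, 2] - spec$center_xy[2]) > 7.5) next
    z <- xyz[i, 3]
    if (z > spec$z_ec[1] && z <= spec$z_ec[2]) brute[1] <- brute[1] + 1L
    else if (z > spec$z_site[1] && z <= spec$z_site[2]) brute[2] <- brute[2] + 1L
    else if (z > spec$z_ic[1] && z <= spec$z_ic[2]) brute[3] <- brute[3] + 1L
  }
  expect_equal(as.integer(wc), brute)
})

test_that("compartment counts conserve and ignore water-record permutation", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  set.seed(47)
  for (rep in 1:100) {
    counts <- sample(0:6, 3, replace = TRUE)
    nout <- sample(0:5, 1)
    hf <- hydration_frame(spec, counts = counts, n_outside = nout,
                          seed = 1000 + rep)
    wc <- water_counts(hf$frame, spec)
    expect_equal(sum(wc) + attr(wc, "n_outside"),
                 nrow(hf$frame$atoms))  # conservation
    expect_equal(as.integer(wc), as.integer(counts))
  }
  hf <- hydration_frame(spec, counts = c(5, 3, 6), n_outside = 4, seed = 9)
  perm <- hf$frame
  set.seed(48)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  expect_equal(water_counts(perm, spec), water_counts(hf$frame, spec))
})

test_that("occupancy grids report per-voxel occupied-frame fractions", {
  toy <- toy_transporter()
  base <- toy$open
  # add a ligand atom at the ring center and one water
  add <- function(s, name, resname, resid, xyz, el, chain = "L") {
    a <- data.frame(serial = max(s$atoms$serial) + 1L, name = name,
                    altloc = "", resname = resname, chain = chain,
                    resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
                    occ = 1, b = 0, element = el, het = TRUE)
    s$atoms <- rbind(s$atoms, a)
    s
  }
  with_lig <- add(base, "C1", "LIG", 500L, c(0, 0, 0), "C")
  wpos <- c(3, 0, 0)
  mkframe <- function(has_water) {
    s <- with_lig
    if (has_water) s <- add(s, "O", "HOH", 600L, wpos, "O", chain = "W")
    s
  }
  # immobile water present in all 5 frames: its voxel reads 1.0
  tr <- trajectory(lapply(1:5, function(i) mkframe(TRUE)))
  g <- occupancy_map(tr, "resname LIG", radius = 10, spacing = 2)
  expect_equal(max(g$values), 1)
  expect_equal(sum(g$values == 1), 1)
  expect_true(all(g$values %in% c(0, 1)))
  # topology holds the water; absent coordinates in half the frames is not
  # representable in a shared-topology trajectory, so instead move the water
  # out of range in 2 of 4 frames: voxel reads 0.5
  mkmoved <- function(out) {
    s <- mkframe(TRUE)
    if (out) {
      i <- which(s$atoms$resname == "HOH")
      s$atoms[i, c("x", "y", "z")] <- c(50, 50, 50)
    }
    s
  }
  tr2 <- trajectory(list(mkmoved(FALSE), mkmoved(TRUE), mkmoved(FALSE),
                         mkmoved(TRUE)))
  g2 <- occupancy_map(tr2, "resname LIG", radius = 10, spacing = 2)
  expect_equal(max(g2$values), 0.5)
  # rigid motion of later frames is removed by the backbone alignment:
  # the grid is unchanged within float tolerance
  R <- rand_rotation()
  rot_frames <- lapply(1:4, function(i) {
    s <- list(mkmoved(FALSE), mkmoved(TRUE), mkmoved(FALSE),
              mkmoved(TRUE))[[i]]
    if (i > 1) s <- set_coords(s, sweep(coords(s) %*% t(R), 2, c(4, -6, 2),
                                        `+`))
    s
  })
  g3 <- occupancy_map(trajectory(rot_frames), "resname LIG", radius = 10,
                      spacing = 2)
  expect_equal(g3$values, g2$values, tolerance = 1e-9)
  expect_equal(g3$spacing, 2)
})

test_that("occupancy values stay in [0, 1] and DX output is well-formed", {
  toy <- toy_transporter()
  spec <- build_compartments(toy$open, toy$roles)
  hf <- hydration_frame(spec, counts = c(4, 2, 3), n_outside = 2, seed = 5)
  # protein (for the backbone alignment) + waters + a one-atom ligand
  s <- toy$open
  wat <- hf$frame$atoms
  wat$serial <- max(s$atoms$serial) + seq_len(nrow(wat))
  s$atoms <- rbind(s$atoms, wat)
  lig <- data.frame(serial = max(s$atoms$serial) + 1L, name = "C1",
                    altloc = "", resname = "LIG", chain = "L", resid = 1L,
                    x = spec$center_xy[1], y = spec$center_xy[2],
                    z = mean(spec$z_site), occ = 1, b = 0, element = "C",
                    het = TRUE)
  s$atoms <- rbind(s$atoms, lig)
  tr <- trajectory(list(s, s, s))
  expect_error(occupancy_map(tr, "resname XYZ"), "empty")
  g <- occupancy_map(tr, "resname LIG", radius = 15, spacing = 2)
  expect_true(all(g$values >= 0 & g$values <= 1))
  tf <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, tf)
  lines <- readLines(tf)
  expect_match(lines[2], sprintf("counts %d %d %d", g$dims[1], g$dims[2],
                                 g$dims[3]))
  expect_match(grep("delta", lines, value = TRUE)[1], "2.0000")
  nvals <- sum(vapply(lines[grep("data follows", lines) + 1:(ceiling(prod(g$dims) / 3))],
                      function(l) length(strsplit(trimws(l), "\\s+")[[1]]),
                      numeric(1)))
  expect_equal(nvals, prod(g$dims))
})
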