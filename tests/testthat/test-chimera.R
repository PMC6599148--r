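test_that("build_template with donor = target reproduces the target", {
  toy <- toy_transporter()
  ch <- build_template(toy$open, toy$open, toy$segments, toy$roles)
  expect_equal(coords(ch$structure), coords(toy$open), tolerance = 1e-8)
  expect_true(all(ch$provenance %in% c("unchanged_target",
                                       "repositioned_target")))
})

test_that("repositioned segments overlay the donor; the rest is bit-identical", {
  toy <- toy_transporter(tilt_angles = c(TM1b = 17, TM6a = 8))
  ch <- build_template(toy$open, toy$occluded, toy$segments, toy$roles)
  at <- ch$structure$atoms
  seg <- which(at$resid %in% c(11:20, 91:100))
  bb <- intersect(seg, which(at$name %in% c("N", "CA", "C", "O")))
  expect_equal(rmsd_nofit(coords(ch$structure, bb), coords(toy$occluded, bb)),
               0, tolerance = 1e-6)
  # provenance tags
  expect_true(all(ch$provenance[seg] == "repositioned_target"))
  expect_true(all(ch$provenance[-seg] == "unchanged_target"))
  # unchanged atoms exactly equal the input target coordinates
  expect_identical(coords(ch$structure, setdiff(seq_len(nrow(at)), seg)),
                   coords(toy$open, setdiff(seq_len(nrow(at)), seg)))
  # hash untouched: superposing chimera back onto target is identity
  tr <- hash_superpose(ch$structure, toy$open, toy$roles)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, rep(0, 3), tolerance = 1e-10)
})

test_that("build_template segment rmsd agrees with segment_fit_table", {
  toy <- toy_transporter(tilt_angles = c(TM1b = 11, TM6a = 23), seed = 4)
  ch <- build_template(toy$open, toy$occluded, toy$segments, toy$roles)
  tab <- segment_fit_table(toy$open, toy$occluded, list(d = toy$segments),
                           toy$roles)
  per <- tab$per_segment[[1]]
  expect_equal(ch$transforms$TM1b$rmsd, unname(per["TM1b"]), tolerance = 1e-10)
  expect_equal(ch$transforms$TM6a$rmsd, unname(per["TM6a"]), tolerance = 1e-10)
})

test_that("build_template errors on unresolvable segments", {
  toy <- toy_transporter()
  bad <- segment_map(list(list(label = "ghost", target = "300-310",
                               donor = "300-310")))
  expect_error(build_template(toy$open, toy$occluded, bad, toy$roles),
               "ghost")
})

test_that("chimera PDB carries provenance in the B-factor column", {
  toy <- toy_transporter()
  ch <- build_template(toy$open, toy$occluded, toy$segments, toy$roles)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_chimera(ch, tf)
  back <- read_structure(tf)
  expect_equal(back$atoms$b, as.numeric(ch$provenance == "repositioned_target"))
  expect_true(file.exists(paste0(tf, ".yaml")))
  meta <- yaml::read_yaml(paste0(tf, ".yaml"))
  expect_length(meta$segments, 2)
})

test_that("junction bond lengths are reported at provenance boundaries", {
  toy <- toy_transporter(tilt_angles = c(TM1b = 17))
  ch <- build_template(toy$open, toy$occluded,
                       segment_map(list(list(label = "TM1b", target = "11-20",
                                             donor = "11-20"))), toy$roles)
  jb <- junction_bond_lengths(ch)
  # the toy numbers helices consecutively, so the repositioned 11-20 block
  # has numbering boundaries at 10|11 and 20|21
  expect_equal(nrow(jb), 2)
  expect_equal(jb$resid_c, c(10, 20))
  expect_true(all(jb$length > 0))
})

test_that("PIR emission covers gaps, maps injectively, and round trips", {
  mk <- function(resids, resnames) structure3d(data.frame(
    name = "CA", resname = resnames, chain = "A", resid = resids,
    x = seq_along(resids), y = 0, z = 0, element = "C", het = FALSE))
  s5 <- mk(1:5, c("ALA", "GLY", "PHE", "SER", "TRP"))
  pir <- emit_pir_alignment(s5, "AGFSW")
  parsed <- read_pir(pir)
  expect_identical(unname(unlist(parsed)), c("AGFSW", "AGFSW"))
  # missing residue 3 -> gap character at position 3
  s4 <- mk(c(1, 2, 4, 5), c("ALA", "GLY", "SER", "TRP"))
  pir2 <- emit_pir_alignment(s4, "AGFSW")
  parsed2 <- read_pir(pir2)
  expect_identical(substr(parsed2[[1]], 3, 3), "-")
  expect_identical(parsed2[[2]], "AGFSW")
  # unmappable residue errors with its name
  s_bad <- mk(c(1, 9), c("ALA", "TRP"))
  expect_error(emit_pir_alignment(s_bad, "AGFSW"), "TRP9")
  # long sequences wrap at the fixed column width
  long <- paste(rep("A", 150), collapse = "")
  sl <- mk(1:150, "ALA")
  pirl <- emit_pir_alignment(sl, long)
  expect_true(all(nchar(pirl) <= 60))
})

test_that("transfer_ions preserves, translates and rotates ion positions correctly", {
  toy <- toy_transporter(seed = 6)
  src <- toy$open
  # plant an ion near residue 50
  ca50 <- coords(src, select_atoms(src, "resid 50 and name CA"))[1, ]
  ion <- data.frame(serial = max(src$atoms$serial) + 1L, name = "NA",
                    altloc = "", resname = "NA", chain = "A", resid = 900L,
                    x = ca50[1] + 2, y = ca50[2], z = ca50[3], occ = 1, b = 0,
                    element = "NA", het = TRUE)
  src$atoms <- rbind(src$atoms, ion)
  expr <- "resname NA and resid 900"

  # dest = source (without the ion): position unchanged
  d0 <- transfer_ions(src, toy$open, expr)
  got0 <- d0$atoms[d0$atoms$resid == 900, c("x", "y", "z")]
  expect_equal(as.numeric(got0), as.numeric(ion[, c("x", "y", "z")]),
               tolerance = 1e-8)

  # dest translated by (5, 0, 0): ion displaced identically
  dtr <- toy$open
  dtr <- set_coords(dtr, sweep(coords(dtr), 2, c(5, 0, 0), `+`))
  d1 <- transfer_ions(src, dtr, expr)
  got1 <- d1$atoms[d1$atoms$resid == 900, c("x", "y", "z")]
  expect_equal(as.numeric(got1),
               as.numeric(ion[, c("x", "y", "z")]) + c(5, 0, 0),
               tolerance = 1e-8)

  # dest rotated: ion lands on the rotated image of its source position
  R <- rotation_about_axis(c(0, 1, 1), 40)
  drot <- toy$open
  drot <- set_coords(drot, coords(drot) %*% t(R))
  d2 <- transfer_ions(src, drot, expr)
  got2 <- as.numeric(d2$atoms[d2$atoms$resid == 900, c("x", "y", "z")])
  expect_equal(got2, as.numeric(R %*% as.numeric(ion[, c("x", "y", "z")])),
               tolerance = 1e-6)

  # missing site in destination errors
  empty <- toy$open
  empty$atoms <- empty$atoms[empty$atoms$resid < 30, ]
  expect_error(transfer_ions(src, empty, expr), "absent")
})

test_that("set_chi is absolute, exact, and rigid on the rotated group", {
  toy_phe <- structure3d(occludeR:::.phe_branch("A", 10L, chi = 55))
  s <- set_chi(toy_phe, 10, -166)
  expect_equal(chi1(s, 10), -166, tolerance = 1e-6)
  # setting to the current value moves nothing
  s2 <- set_chi(s, 10, -166)
  expect_equal(coords(s2), coords(s), tolerance = 1e-10)
  # absolute setting: last set wins
  s3 <- set_chi(set_chi(toy_phe, 10, 60), 10, -70)
  expect_equal(coords(s3), coords(set_chi(toy_phe, 10, -70)),
               tolerance = 1e-10)
  # interatomic distances within the rotated rigid group (CG and the ring
  # carbons) preserved, as are all bond lengths along the side chain
  grp <- function(st) coords(st, select_atoms(st, "name CG CD1 CD2"))
  expect_equal(as.numeric(dist(grp(s))), as.numeric(dist(grp(toy_phe))),
               tolerance = 1e-8)
  blen <- function(st, a, b) {
    x <- st$atoms
    sqrt(sum((as.numeric(x[x$name == a, c("x", "y", "z")]) -
                as.numeric(x[x$name == b, c("x", "y", "z")]))^2))
  }
  for (bond in list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1")))
    expect_equal(blen(s, bond[1], bond[2]), blen(toy_phe, bond[1], bond[2]),
                 tolerance = 1e-8)
  # missing defining atoms are an error
  noCG <- toy_phe
  noCG$atoms <- noCG$atoms[noCG$atoms$name != "CG", ]
  expect_error(set_chi(noCG, 10, 30), "unevaluable|missing")
})

test_that("restraint lists emit and round trip in both dialects", {
  toy <- toy_transporter()
  rl <- restraint_list(c("A:50:CA", "A:15:CA"), c("A:95:CA", "A:110:CA"),
                       c(2.3, 4.1), c(10, 200))
  txt <- emit_restraints(rl, toy$open)
  expect_match(txt[2], "2.3")
  expect_match(txt[2], "\t10")
  back <- read_restraints(txt)
  expect_equal(back$distance, rl$distance)
  expect_equal(back$k, rl$k)
  expect_identical(back$atom_a, rl$atom_a)
  # empty list -> header only
  empty <- restraint_list(character(), character(), numeric(), numeric())
  expect_length(emit_restraints(empty, toy$open), 1)
  # plumed dialect: nm and kJ conversion
  pl <- emit_restraints(rl, toy$open, dialect = "plumed_style")
  expect_match(pl[2], "AT=0.2300")
  expect_match(pl[2], "KAPPA=4184.0")
  # dangling reference errors
  bad <- restraint_list("A:999:CA", "A:50:CA", 2, 10)
  expect_error(emit_restraints(bad, toy$open), "not found")
  # invalid physical values rejected at construction
  expect_error(restraint_list("a", "b", -1, 10), "> 0")
  expect_error(restraint_list("a", "b", 2, 0), "> 0")
})
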