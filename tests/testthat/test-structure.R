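# Structure parsing, pair distances, trajectory tracking and interface
# contacts.

min_pdb <- function() {
  c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END")
}

test_that("parse_structure reads records and validates input", {
  m <- parse_structure(min_pdb())
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(as.numeric(m$atoms[1, c("x", "y", "z")]), c(1, 2, 3))
  expect_equal(m$atoms$chain, "A")
  expect_error(parse_structure(c("HEADER junk", "END")), "empty structure")
  bad <- c("ATOM      1  CA  ALA A   1       1.000   xxxxx   3.000  1.00  0.00",
           "END")
  expect_error(parse_structure(bad), "parse error at line 1")
})

test_that("the toy tetramer has four chains with the prescribed geometry", {
  tet <- gen_toy_tetramer(diagonal_gap_A = 10)
  expect_setequal(unique(tet$atoms$chain), c("A", "B", "C", "D"))
  expect_equal(sum(table(unique(tet$atoms$chain))), 4)
  expect_equal(pair_distance(tet, "A:315-B:315"), 10)
  expect_equal(pair_distance(tet, "C:315-D:315"), 10)
  expect_equal(pair_distance(tet, "A:237-C:182"), 6)
  expect_equal(pair_distance(tet, "A:302-D:330"), 6)
  # prescribed value propagates
  tet12 <- gen_toy_tetramer(diagonal_gap_A = 12.5)
  expect_equal(pair_distance(tet12, "A:315-B:315"), 12.5)
  # PDB round trip preserves geometry to the 3-decimal PDB precision
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(tet, f)
  back <- parse_structure(f)
  expect_equal(pair_distance(back, "A:315-B:315"), 10, tolerance = 1e-3)
})

test_that("pair_distance is symmetric and rigid-motion invariant", {
  tet <- gen_toy_tetramer()
  expect_equal(pair_distance(tet, "A:315-B:315"),
               pair_distance(tet, "B:315-A:315"))
  expect_error(pair_distance(tet, "A:999-B:315"), "atom not found")
  # hand-built two-atom model: 3-4-5 triangle
  two <- parse_structure(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1       3.000   4.000   0.000  1.00  0.00           C",
    "END"))
  expect_equal(pair_distance(two, "A:1-B:1"), 5)
  # random rigid transforms leave all tracked distances unchanged
  set.seed(9)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                   sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, byrow = TRUE)
    rot <- Rz %*% Rx
    shift <- runif(3, -50, 50)
    moved <- tet
    xyz <- as.matrix(tet$atoms[c("x", "y", "z")]) %*% t(rot)
    moved$atoms$x <- xyz[, 1] + shift[1]
    moved$atoms$y <- xyz[, 2] + shift[2]
    moved$atoms$z <- xyz[, 3] + shift[3]
    expect_equal(pair_distance(moved, "A:315-B:315"),
                 pair_distance(tet, "A:315-B:315"), tolerance = 1e-9)
    expect_equal(pair_distance(moved, "A:237-C:182"),
                 pair_distance(tet, "A:237-C:182"), tolerance = 1e-9)
  }
})

test_that("track_distances recovers linear separation rates", {
  tet <- gen_toy_tetramer()
  # static trajectory: every rate is zero
  static <- gen_trajectory(tet, velocities = list(), n_frames = 21)
  tr <- track_distances(static, list("A:315-B:315", "A:237-C:182"))
  expect_equal(vapply(tr, `[[`, 0, "rate_A_per_ps"), c(0, 0))
  # chain B receding along the A-B diagonal at 0.1 A/ps
  v <- 0.1 / sqrt(2)
  sep <- gen_trajectory(tet, velocities = list(B = c(v, v, 0)),
                        n_frames = 51, dt_ps = 2)
  tr2 <- track_distances(sep, "A:315-B:315")
  expect_equal(tr2[[1]]$rate_A_per_ps, 0.1, tolerance = 1e-6)
  # missing pair names the offender
  expect_error(track_distances(sep, "A:999-B:315"), "atom not found")
})

test_that("a half-rate pair tracks at half the separation rate", {
  # emulates the wild-type interface whose salt-bridge pair separates at
  # about half the mutant rate
  tet <- gen_toy_tetramer()
  vB <- 0.2 / sqrt(2)
  traj <- gen_trajectory(tet, velocities = list(B = c(vB, vB, 0),
                                                D = c(0, 0.1, 0)),
                         n_frames = 101, dt_ps = 1, jitter = 0.02, seed = 3)
  tracks <- track_distances(traj, list("A:315-B:315", "A:302-D:330"))
  rates <- vapply(tracks, `[[`, 0, "rate_A_per_ps")
  expect_equal(rates[2] / rates[1], 0.5, tolerance = 0.05)
})

test_that("track window restricts the rate fit", {
  tet <- gen_toy_tetramer()
  v <- 0.1 / sqrt(2)
  traj <- gen_trajectory(tet, velocities = list(B = c(v, v, 0)),
                         n_frames = 101, dt_ps = 1)
  full <- track_distances(traj, "A:315-B:315")[[1]]
  late <- track_distances(traj, "A:315-B:315", window = c(80, 100))[[1]]
  expect_equal(late$rate_A_per_ps, full$rate_A_per_ps, tolerance = 1e-9)
  expect_error(track_distances(traj, "A:315-B:315", window = c(200, 300)),
               "at least two frames")
})

test_that("interface_contacts finds the planted polar pair and only it", {
  # default geometry: all cross-chain N/O pairs exceed the cutoff
  clean <- gen_toy_tetramer()
  expect_equal(nrow(interface_contacts(clean, "A", "B")), 0)
  # planted NZ...O pair at 2.9 A across the diagonal interface
  tet <- gen_toy_tetramer(contact_pair = TRUE)
  hits <- interface_contacts(tet, "A", "B")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$elety_a, "NZ")
  expect_equal(hits$resno_a, 315)
  expect_equal(hits$elety_b, "O")
  expect_equal(hits$resno_b, 313)
  expect_equal(hits$distance_A, 2.9, tolerance = 1e-9)
  # symmetric up to partner ordering
  rev <- interface_contacts(tet, "B", "A")
  expect_equal(nrow(rev), 1)
  expect_equal(rev$distance_A, hits$distance_A)
  expect_equal(rev$resno_a, hits$resno_b)
  # zero cutoff finds nothing; unknown chain errors
  expect_equal(nrow(interface_contacts(tet, "A", "B", cutoff_A = 0)), 0)
  expect_error(interface_contacts(tet, "A", "Z"), "chain not found")
  # chains 10 A apart are not in contact at the default cutoff
  apart <- parse_structure(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O   ALA B   1      10.000   0.000   0.000  1.00  0.00           O",
    "END"))
  expect_equal(nrow(interface_contacts(apart, "A", "B")), 0)
})

test_that("multi-model PDB trajectories round-trip through files", {
  tet <- gen_toy_tetramer()
  v <- 0.1 / sqrt(2)
  traj <- gen_trajectory(tet, velocities = list(B = c(v, v, 0)),
                         n_frames = 11, dt_ps = 1)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(traj, f)
  back <- parse_trajectory(f)
  expect_equal(dim(back$coords), dim(traj$coords))
  tr <- track_distances(back, "A:315-B:315")[[1]]
  expect_equal(tr$rate_A_per_ps, 0.1, tolerance = 1e-3)
  # list-of-files input with mismatched rosters errors with frame index
  single <- tempfile(fileext = ".pdb")
  write_structure_pdb(tet, single)
  other <- tempfile(fileext = ".pdb")
  write_structure_pdb(parse_structure(min_pdb()), other)
  expect_error(parse_trajectory(c(single, other)), "frame 2")
})
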