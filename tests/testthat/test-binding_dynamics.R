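test_that("contact fingerprints match the brute-force pairwise scan", {
  for (s in 1:30) {
    set.seed(s)
    tr <- random_traj(50, 3)
    ai <- 1:2
    pi_ <- 3:50
    fp <- contact_fingerprint(tr, ai, pi_, cutoff = 4)
    for (f in 1:3) {
      expect_equal(fp$residues[[f]],
                   brute_contacts(frame_coords(tr, f), ai, pi_,
                                  tr$topology$residue_id, 4, tr$box[f, ]),
                   info = paste("seed", s, "frame", f))
    }
  }
  # anion at 0 A from a residue atom is always a contact
  tr <- random_traj(10, 1)
  tr$coords[1, , 1] <- tr$coords[5, , 1]
  fp <- contact_fingerprint(tr, 1, 2:10, cutoff = 4)
  expect_true(tr$topology$residue_id[5] %in% fp$residues[[1]])
  expect_error(contact_fingerprint(tr, integer(0), 2:10), "empty anion")
})

test_that("cavity occupancy flags, merges and segments residence", {
  mk_fp <- function(sets) structure(list(cutoff = 4, residues = sets,
                                         n_frames = length(sets)),
                                    class = "contact_fingerprint")
  cav <- c(64, 66, 67, 97, 101, 168, 182)
  # bound pattern 1,1,0,0,1,1 with gap_tolerance 2 merges into [0, 6)
  inside <- list(cav[1:3], cav[1:3], 999, integer(0), cav[4:6], cav[4:7])
  fp <- mk_fp(lapply(inside, as.integer))
  occ <- cavity_occupancy(fp, cav, min_residues = 3, gap_tolerance = 2)
  expect_equal(occ$bound, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(occ$segments[, "start"]), 0)
  expect_equal(unname(occ$segments[, "end"]), 6)
  # gap_tolerance 0 gives exactly the maximal bound runs
  occ0 <- cavity_occupancy(fp, cav, min_residues = 3, gap_tolerance = 0)
  expect_equal(nrow(occ0$segments), 2)
  expect_equal(unname(occ0$segments[1, ]), c(0, 2))
  expect_equal(unname(occ0$segments[2, ]), c(4, 6))
  expect_error(cavity_occupancy(fp, cav, min_residues = 8), "exceeds")
  expect_error(cavity_occupancy(fp, integer(0)), "non-empty")
  # always-bound trajectory yields one full segment
  fp_all <- mk_fp(rep(list(cav), 5))
  occ_all <- cavity_occupancy(fp_all, cav)
  expect_equal(unname(occ_all$segments[1, ]), c(0, 5))
})

test_that("segments with default merging cover exactly the merged bound frames", {
  set.seed(99)
  for (i in 1:50) {
    bound <- runif(30) < 0.4
    occ <- occupancy_series(bound, gap_tolerance = 2)
    covered <- rep(FALSE, 30)
    if (nrow(occ$segments))
      for (r in seq_len(nrow(occ$segments)))
        covered[(occ$segments[r, 1] + 1):occ$segments[r, 2]] <- TRUE
    # merged coverage contains every bound frame and only gaps <= 2
    expect_true(all(covered[bound]))
    if (nrow(occ$segments) > 1)
      for (r in 2:nrow(occ$segments))
        expect_gt(occ$segments[r, 1] - occ$segments[r - 1, 2], 2)
  }
})

test_that("entry detection honors hysteresis and reports the gate pair", {
  tr <- gen_trajectory(n_frames = 150, entry_frame = 60, seed = 21)
  truth <- attr(tr, "truth")
  ev <- detect_entry_events(tr, "resname CLA", "resname CRO",
                            gate_candidates = list(truth$gate_pair,
                                                   c(1L, 2L)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, truth$entry_frame)
  expect_gte(ev$persistence, 10)
  expect_equal(c(ev$gate_res1, ev$gate_res2), truth$gate_pair)
  # without candidates, gate columns are NA
  ev2 <- detect_entry_events(tr, "resname CLA", "resname CRO")
  expect_true(is.na(ev2$gate_res1[1]))
  # anion that never approaches produces no events
  tr_bulk <- gen_trajectory(n_frames = 80, anion_script = "bulk_only",
                            seed = 22)
  expect_equal(nrow(detect_entry_events(tr_bulk, "resname CLA",
                                        "resname CRO")), 0)
  expect_error(detect_entry_events(tr, "resname CLA", "resname CRO",
                                   r_inside = 15, r_bulk = 10), "smaller")
})

test_that("an anion starting inside without a prior bulk frame is not an entry", {
  # constant inside distance from frame 0
  top <- topology(1:2, c("CL", "C1"), c("Cl", "C"), c("CLA", "CRO"),
                  c(200L, 100L))
  co <- array(0, c(2, 3, 30))
  co[1, 1, ] <- 5  # anion 5 A from the center in every frame
  tr <- trajectory(top, co)
  expect_equal(nrow(detect_entry_events(tr, 1, 2, min_persistence = 5)), 0)
})

test_that("rmsd obeys rigid-motion invariance and closed forms", {
  set.seed(5)
  A <- matrix(rnorm(36), 12, 3)
  expect_equal(rmsd(A, A), 0, tolerance = 1e-12)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(rep(c(2, -1, 4), each = 12), 12, 3)
  expect_equal(rmsd(A, B), 0, tolerance = 1e-6)
  expect_equal(rmsd(A, B), rmsd(B, A), tolerance = 1e-9)
  # translation by (3,4,0) without superposition is exactly 5
  expect_equal(rmsd(A, A + matrix(rep(c(3, 4, 0), each = 12), 12, 3),
                    superpose = FALSE), 5)
  expect_error(rmsd(A, B[1:10, ]), "cardinality")
  expect_error(rmsd(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("superposed rmsd agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  for (s in 1:10) {
    set.seed(s)
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    # bio3d rounds its result to 3 decimals
    expect_equal(rmsd(A, B), ref, tolerance = 2e-3)
  }
})

test_that("rmsf matches closed forms and the brute-force formula", {
  # static trajectory: all zeros
  top <- topology(1:4, rep("CA", 4), rep("C", 4), rep("GLY", 4), 1:4)
  base <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 0, 0, 5), 4, 3, byrow = TRUE)
  co <- array(rep(base, 5), c(4, 3, 5))
  tr <- trajectory(top, co)
  expect_equal(rmsf(tr, 1:4), rep(0, 4), tolerance = 1e-12)
  # one atom oscillating +-d along x, others fixed (raw coordinates)
  co2 <- co[, , 1:4]
  co2[1, 1, ] <- c(-2, 2, -2, 2)
  tr2 <- trajectory(top, co2)
  expect_equal(rmsf(tr2, 1:4, superpose = FALSE), c(2, 0, 0, 0))
  expect_error(rmsf(trajectory(top, base), 1:4), "at least 2")
  # random trajectories against the independent brute-force implementation
  for (s in 1:20) {
    set.seed(s)
    tr3 <- random_traj(15, 6, box = NULL)
    expect_equal(rmsf(tr3, 1:15), brute_rmsf(tr3, 1:15), tolerance = 1e-9,
                 info = paste("seed", s))
  }
})

test_that("hydrogen bonds follow the distance-angle criterion", {
  mk <- function(coords) {
    top <- topology(1:3, c("O", "H", "O"), c("O", "H", "O"),
                    c("R1", "R1", "R2"), c(1L, 1L, 2L))
    trajectory(top, coords)
  }
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2.8, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(hydrogen_bonds(mk(collinear), cbind(1, 2), 3)$occupancy, 1)
  far <- collinear; far[3, 1] <- 4.0
  expect_equal(hydrogen_bonds(mk(far), cbind(1, 2), 3)$occupancy, 0)
  # angle below 120 degrees fails even at short distance
  bent <- matrix(c(0, 0, 0, 1, 0, 0, 1, 2.5, 0), 3, 3, byrow = TRUE)
  expect_equal(hydrogen_bonds(mk(bent), cbind(1, 2), 3)$occupancy, 0)
  # implausible donor (H 2 A from D) is skipped with a warning
  stretched <- matrix(c(0, 0, 0, 2, 0, 0, 2.8, 0, 0), 3, 3, byrow = TRUE)
  expect_warning(hb <- hydrogen_bonds(mk(stretched), cbind(1, 2), 3),
                 "skipped")
  expect_equal(nrow(hb), 0)
  # random geometries equal the brute-force per-frame evaluation
  for (s in 1:30) {
    set.seed(s)
    tr <- random_traj(12, 4, box = c(15, 15, 15))
    # pin the hydrogen next to its donor so the pair is plausible
    for (f in 1:4)
      tr$coords[2, , f] <- tr$coords[1, , f] + runif(3, -0.5, 0.5)
    hb <- hydrogen_bonds(tr, cbind(1L, 2L), 3:5)
    for (j in 1:3)
      expect_equal(hb$occupancy[hb$acceptor == j + 2],
                   brute_hbond_occupancy(tr, 1, 2, j + 2, 3.5, 120),
                   info = paste("seed", s, "acceptor", j + 2))
  }
})

test_that("Shrake-Rupley SASA reproduces sphere closed forms", {
  # isolated sphere of radius 1.9: all points accessible
  a <- sasa(matrix(0, 1, 3), "X", radii_map = c(X = 1.9))
  expect_equal(a, 4 * pi * 3.3^2, tolerance = 1e-9)
  # two atoms far apart: each equals its isolated area
  two <- sasa(matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE), c("C", "C"))
  expect_equal(two, rep(4 * pi * (1.7 + 1.4)^2, 2), tolerance = 1e-9)
  # a small atom fully inside a large sphere is buried
  buried <- sasa(matrix(c(0, 0, 0, 0, 0, 0.1), 2, 3, byrow = TRUE),
                 c("H", "I"))
  expect_equal(buried[1], 0)
  expect_error(sasa(matrix(0, 1, 3), "Zz"), "Zz")
  # moving a second atom closer never increases the first atom's area
  d_seq <- c(10, 6, 4, 3, 2)
  areas <- vapply(d_seq, function(d)
    sasa(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), c("C", "C"))[1],
    numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("ring planarity is zero for coplanar atoms and rotation-invariant", {
  top <- topology(1:5, paste0("C", 1:5), rep("C", 5), rep("CRO", 5),
                  rep(1L, 5))
  flat <- cbind(runif(5), runif(5), 0)
  expect_equal(chromophore_planarity(trajectory(top, flat), 1:5), 0,
               tolerance = 1e-9)
  # square with one atom lifted: compare against a brute-force SVD plane fit
  lifted <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0, 0.5, 0.5, 1),
                   5, 3, byrow = TRUE)
  ctr <- sweep(lifted, 2, colMeans(lifted))
  normal <- svd(ctr)$v[, 3]
  brute <- sqrt(mean((ctr %*% normal)^2))
  val <- chromophore_planarity(trajectory(top, lifted), 1:5)
  expect_equal(val, brute, tolerance = 1e-9)
  # rigid rotation leaves the value unchanged
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_equal(chromophore_planarity(trajectory(top, lifted %*% R), 1:5),
               val, tolerance = 1e-9)
  expect_error(chromophore_planarity(trajectory(top, lifted), 1:3),
               "at least 4")
})
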