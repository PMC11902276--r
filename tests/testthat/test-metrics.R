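# Kabsch superposition, RMSD/RMSF, Rg, COM distances, H-bonds, salt bridges

random_rotation <- function(seed) {
  set.seed(seed)
  q <- svd(matrix(rnorm(9), 3))$u
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("superpose recovers identity, translations, and known rotations", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  shifted <- sweep(ref, 2, c(5, 0, 0), "+")
  expect_equal(superpose(shifted, ref)$rmsd, 0, tolerance = 1e-10)

  rot <- random_rotation(2)
  fit <- superpose(ref %*% t(rot), ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superpose RMSD matches the rotation-grid-search oracle", {
  set.seed(3)
  ref <- matrix(rnorm(12), ncol = 3)
  mob <- ref %*% t(random_rotation(4)) + matrix(rnorm(12, sd = 0.3), ncol = 3)
  got <- superpose(mob, ref)$rmsd
  expect_equal(got, rotsearch_rmsd(mob, ref), tolerance = 1e-6)
  # dual route: independent implementation
  skip_if_not_installed("bio3d")
  b <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE)
  expect_equal(got, b, tolerance = 1e-3)  # bio3d prints at 1e-3 granularity
})

test_that("rmsd_series removes rigid-body motion and matches an oracle recomputation", {
  sim <- toy_sim(n_frames = 30, seed = 8)
  ref <- frame_coords(sim$ensemble, 1)

  const <- ensemble(array(rep(ref, each = 5), dim = c(5, nrow(ref), 3)))
  expect_equal(max(abs(rmsd_series(const, ref))), 0, tolerance = 1e-10)

  # rigidly rotating ensemble -> all zeros after fitting
  rotating <- array(NA_real_, dim = c(4, nrow(ref), 3))
  for (t in 1:4) rotating[t, , ] <- ref %*% t(random_rotation(t)) + t
  expect_lt(max(rmsd_series(ensemble(rotating), ref)), 1e-9)

  rs <- rmsd_series(sim$ensemble, ref)
  skip_if_not_installed("bio3d")
  oracle <- vapply(seq_len(30), function(t) {
    bio3d::rmsd(as.vector(t(ref)), as.vector(t(frame_coords(sim$ensemble, t))),
                fit = TRUE)
  }, numeric(1))
  expect_equal(as.numeric(rs), oracle, tolerance = 2e-3)
  expect_match(attr(rs, "summary"), "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)$")
})

test_that("rmsf handles constant, two-point, and rigidly transformed ensembles", {
  ref <- matrix(rnorm(30), ncol = 3)
  const <- ensemble(array(rep(ref, each = 6), dim = c(6, 10, 3)))
  expect_equal(max(rmsf(const, fit = FALSE)), 0)

  # one node alternating +/- a along x about a rigid scaffold
  a <- 0.7
  coords <- array(rep(ref, each = 4), dim = c(4, 10, 3))
  coords[, 5, 1] <- coords[, 5, 1] + c(a, -a, a, -a)
  expect_equal(rmsf(ensemble(coords), fit = FALSE)[5], a, tolerance = 1e-12)

  # invariance under an arbitrary rigid transform of every frame
  sim <- toy_sim(n_frames = 40, seed = 13)
  base <- rmsf(sim$ensemble, fit = TRUE)
  moved <- sim$ensemble$coords
  for (t in seq_len(dim(moved)[1])) {
    moved[t, , ] <- frame_coords(sim$ensemble, t) %*% t(random_rotation(t)) +
      matrix(rep(c(t, -t, 2 * t), each = dim(moved)[2]), ncol = 3)
  }
  expect_equal(rmsf(ensemble(moved), fit = TRUE), base, tolerance = 1e-5)
})

test_that("radius of gyration follows the direct mass-weighted formula", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1.0)
  set.seed(6)
  frame <- matrix(rnorm(60), ncol = 3)
  masses <- runif(20, 1, 15)
  com <- colSums(frame * masses) / sum(masses)
  direct <- sqrt(sum(masses * rowSums(sweep(frame, 2, com)^2)) / sum(masses))
  expect_equal(radius_of_gyration(frame, masses), direct, tolerance = 1e-9)
})

test_that("COM distance series matches constructed geometry and a frame loop", {
  sim <- toy_sim(n_frames = 25, seed = 17)
  nn <- dim(sim$ensemble$coords)[2]
  ga <- seq_len(nn / 2); gb <- seq.int(nn / 2 + 1, nn)

  # shifted-copy construction: centroids exactly (3,4,0) apart
  coords <- sim$ensemble$coords
  coords[, gb, ] <- coords[, ga, ]
  coords[, gb, 1] <- coords[, gb, 1] + 3
  coords[, gb, 2] <- coords[, gb, 2] + 4
  expect_equal(as.numeric(com_distance_series(ensemble(coords), ga, gb)),
               rep(5, 25), tolerance = 1e-12)

  cd <- com_distance_series(sim$ensemble, ga, gb)
  oracle <- vapply(seq_len(25), function(t) {
    fc <- frame_coords(sim$ensemble, t)
    sqrt(sum((colMeans(fc[ga, ]) - colMeans(fc[gb, ]))^2))
  }, numeric(1))
  expect_equal(as.numeric(cd), oracle, tolerance = 1e-12)
  expect_error(com_distance_series(sim$ensemble, 1:3, 3:5), "intersect|disjoint")
})

test_that("H-bond criterion applies inclusive distance and donor-angle cutoffs", {
  crit <- hbond_criteria()
  donor <- c(0, 0, 0)
  acc_at <- function(d, ang_deg) d * c(cos(ang_deg * pi / 180),
                                       sin(ang_deg * pi / 180), 0)
  hyd <- c(1, 0, 0)
  expect_true(detect_hbond(donor, acc_at(3.0, 10), hyd, crit))
  expect_false(detect_hbond(donor, acc_at(3.6, 10), hyd, crit))
  expect_true(detect_hbond(donor, acc_at(3.5, 30), hyd, crit))   # both boundaries inclusive
  expect_false(detect_hbond(donor, acc_at(3.0, 31), hyd, crit))
  expect_true(detect_hbond(donor, acc_at(3.0, 170), NULL, crit)) # no hydrogen: distance only
})

test_that("occupancy counting is exact integer arithmetic", {
  for (occ in c(0, 0.25, 0.73, 1)) {
    ev <- make_event_series(100, occ, pattern = "block")
    rep <- hbond_occupancy(ev$donor, ev$acceptor, ev$hydrogen)
    expect_identical(rep$n_true, as.integer(round(occ * 100)))
    expect_identical(rep$occupancy * rep$n_frames, round(occ * 100))
  }
  all_on <- make_event_series(40, 1, pattern = "block")
  expect_identical(hbond_occupancy(all_on$donor, all_on$acceptor)$occupancy, 1)
})

test_that("salt bridges are detected by minimum N-O distance and reported in interaction-table style", {
  mk <- function(d) {
    structure_model(data.frame(
      serial = 1:4,
      name = c("NH1", "NE", "OE1", "OE2"),
      resname = c("ARG", "ARG", "GLU", "GLU"),
      resid = c(83, 83, 86, 86),
      chain = "A",
      x = c(0, 1.2, d, d + 1.1), y = 0, z = 0,
      element = c("N", "N", "O", "O")))
  }
  hits <- detect_salt_bridges(mk(3.5))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$min_ON, 3.5 - 1.2)
  expect_equal(nrow(detect_salt_bridges(mk(5.8))), 0)  # min O-N 4.6 > 4.0

  # engineered 73/100 trajectory
  frames <- lapply(1:100, function(t) mk(if (t <= 73) 4.0 else 6.5))
  rep <- salt_bridge_occupancy(frames, list("A", 83), list("A", 86),
                               label = "meR83-E86")
  expect_identical(rep$n_true, 73L)
  expect_identical(format_occupancy(rep), "73.0%")
  expect_identical(format_occupancy_table(rep), "meR83-E86 (73.00)")

  # residue lacking listed side-chain atoms is skipped with a warning
  m <- mk(3.5)
  m$atoms$name[1:2] <- c("CB", "CG")
  expect_warning(res <- detect_salt_bridges(m), "skipped")
  expect_equal(nrow(res), 0)
})
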