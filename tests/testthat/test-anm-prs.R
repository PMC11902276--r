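# Anisotropic network model and perturbation response scanning

test_that("2-node ANM has the closed-form spectrum", {
  two <- matrix(c(0, 0, 0, 5, 0, 0), 2, byrow = TRUE)
  m <- build_anm(two, cutoff = 6, gamma = 1)
  expect_equal(sort(m$eigenvalues), c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  # nonzero mode is the relative displacement along the bond axis (x)
  v <- m$eigenvectors[, 6]
  expect_equal(abs(v), rep(c(1, 0, 0), 2) / sqrt(2), tolerance = 1e-9)
  expect_equal(sum(v[1] * v[4]), -0.5, tolerance = 1e-9)  # antisymmetric pair
  # gamma scales the spectrum linearly
  expect_equal(max(build_anm(two, cutoff = 6, gamma = 3)$eigenvalues), 6,
               tolerance = 1e-12)
})

test_that("3-node chain Hessian equals the hand-assembled super-element oracle", {
  chain <- matrix(c(0, 0, 0, 5, 0, 0, 10, 0, 0), 3, byrow = TRUE)
  m <- build_anm(chain, cutoff = 6, gamma = 1)
  blk <- matrix(0, 3, 3); blk[1, 1] <- 1   # -gamma/d^2 * d d^T for x-axis bond
  h <- matrix(0, 9, 9)
  for (pair in list(c(1, 2), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- -blk; h[rj, ri] <- -blk
    h[ri, ri] <- h[ri, ri] + blk; h[rj, rj] <- h[rj, rj] + blk
  }
  expect_equal(m$hessian, h, tolerance = 1e-12)
  # block row sums vanish (translation invariance)
  for (i in 1:3) {
    rs <- Reduce(`+`, lapply(1:3, function(j)
      m$hessian[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
    expect_equal(max(abs(rs)), 0, tolerance = 1e-12)
  }
  expect_error(build_anm(matrix(c(0, 0, 0, 100, 0, 0, 200, 0, 0), 3,
                                byrow = TRUE), cutoff = 12), "disconnected")
})

test_that("connected 3-D fixtures have exactly six rigid-body modes", {
  for (seed in c(2, 9)) {
    model <- build_toy_complex(toy_complex_spec(15, 3, seed = seed))
    m <- build_anm(model_coords(model), cutoff = 12)
    expect_equal(m$n_zero_modes, 6)
    expect_true(all(m$eigenvalues[-(1:6)] > 0))
  }
})

test_that("mode-truncated covariance recovers the Moore-Penrose pseudo-inverse", {
  model <- build_toy_complex(toy_complex_spec(12, 0, seed = 4))
  m <- build_anm(model_coords(model), cutoff = 12)
  all_modes <- 3 * 12 - m$n_zero_modes
  cv <- anm_covariance(m, n_modes = all_modes)
  pinv <- MASS::ginv(m$hessian)                 # independent pseudo-inverse
  expect_lt(max(abs(cv - pinv)), 1e-8)
  expect_lt(max(abs(m$hessian %*% cv %*% m$hessian - m$hessian)), 1e-6)

  # truncated rank and trace identity on the slowest mode
  lam1 <- m$eigenvalues[m$n_zero_modes + 1]
  cv1 <- anm_covariance(m, n_modes = 1)
  expect_equal(sum(diag(cv1)), 1 / lam1, tolerance = 1e-9)
  expect_equal(qr(cv1)$rank, 1)
  expect_error(anm_covariance(m, n_modes = all_modes + 1), "modes")
})

test_that("PRS responses: decoupled limit, sampled-vs-analytic, normalization", {
  # rigged model with unit spectrum and identity eigenvectors gives an
  # identity covariance (decoupled nodes): self-response only
  fake <- structure(list(reference_coords = matrix(rnorm(9), 3),
                         eigenvalues = rep(1, 9),
                         eigenvectors = diag(9)), class = "anm_model")
  p0 <- prs_scan(fake, n_modes = 9)
  expect_equal(p0$raw_response, diag(3))
  expect_equal(p0$normalized, diag(3))

  model <- build_toy_complex(toy_complex_spec(10, 0, seed = 6))
  m <- build_anm(model_coords(model), cutoff = 12)
  pa <- prs_scan(m, n_modes = 10)
  expect_equal(diag(pa$normalized), rep(1, 10))
  expect_true(all(pa$raw_response >= 0))
  ps <- prs_scan(m, n_modes = 10, analytic = FALSE,
                 n_force_directions = 10000, seed = 3)
  expect_lt(max(abs(ps$normalized - pa$normalized) / pa$normalized), 0.02)
})

test_that("normalized PRS is invariant to the spring constant", {
  model <- build_toy_complex(toy_complex_spec(10, 0, seed = 8))
  xyz <- model_coords(model)
  a <- prs_scan(build_anm(xyz, cutoff = 12, gamma = 1), n_modes = 12)
  b <- prs_scan(build_anm(xyz, cutoff = 12, gamma = 10), n_modes = 12)
  expect_equal(a$normalized, b$normalized, tolerance = 1e-9)
  expect_equal(a$effector_profile, b$effector_profile, tolerance = 1e-9)
})

test_that("effector/sensor profiles follow the row/column means of the map", {
  model <- build_toy_complex(toy_complex_spec(8, 0, seed = 2))
  m <- build_anm(model_coords(model), cutoff = 12)
  p <- prs_scan(m, n_modes = 10)
  n <- 8
  eff <- vapply(1:n, function(i) mean(p$normalized[i, -i]), numeric(1))
  sen <- vapply(1:n, function(j) mean(p$normalized[-j, j]), numeric(1))
  expect_equal(p$effector_profile, eff)
  expect_equal(p$sensor_profile, sen)
  es <- effector_sensor(p, exclude_self = FALSE)
  expect_equal(es$effector, rowMeans(p$normalized))

  # symmetric normalized map: effector = sensor
  sym <- p
  sym$normalized <- (p$normalized + t(p$normalized)) / 2
  es2 <- effector_sensor(sym)
  expect_equal(es2$effector, es2$sensor)
})

test_that("averaged PRS reduces to the single-frame map for identical frames", {
  model <- build_toy_complex(toy_complex_spec(12, 0, seed = 3))
  xyz <- model_coords(model)
  single <- prs_scan(build_anm(xyz, cutoff = 12), n_modes = 20)
  const <- ensemble(array(rep(xyz, each = 6), dim = c(6, 12, 3)))
  avg <- averaged_prs(const, n_representatives = 6, cutoff = 12, n_modes = 20)
  expect_equal(avg$normalized, single$normalized, tolerance = 1e-9)
  expect_equal(avg$n_frames_used, 6L)

  # stride = F picks one frame
  one <- averaged_prs(const, n_representatives = 1, cutoff = 12, n_modes = 20)
  expect_equal(one$normalized, single$normalized, tolerance = 1e-9)

  # two-frame mean verified elementwise (small fluctuations keep every
  # frame connected at the cutoff)
  mdl <- build_toy_complex(toy_complex_spec(20, 4, seed = 14))
  sim <- sample_anm_ensemble(mdl, n_frames = 2, seed = 14,
                             temperature_scale = 0.02)
  m1 <- prs_scan(build_anm(frame_coords(sim$ensemble, 1), cutoff = 12), n_modes = 20)
  m2 <- prs_scan(build_anm(frame_coords(sim$ensemble, 2), cutoff = 12), n_modes = 20)
  both <- averaged_prs(sim$ensemble, n_representatives = 2, cutoff = 12, n_modes = 20)
  expect_equal(both$normalized, (m1$normalized + m2$normalized) / 2,
               tolerance = 1e-12)
})

test_that("generator covariance and ANM machinery close the loop", {
  sim <- toy_sim(n_frames = 20000, seed = 44)
  m <- sim$ground_truth$anm
  full <- anm_covariance(m, n_modes = length(m$eigenvalues) - m$n_zero_modes)
  sc <- covariance(sim$ensemble, fit = FALSE)
  rel <- norm(sc$matrix - full * sim$ground_truth$temperature_scale, "F") /
    norm(full, "F")
  expect_lt(rel, 0.05)
})
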