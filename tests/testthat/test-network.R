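# Correlation-weighted graph construction and betweenness centrality

# small helper: lmi_correlation object from a bare C matrix
as_lmi <- function(C) {
  structure(list(C = C, I = NULL, d_param = 3L,
                 node_labels = as.character(seq_len(nrow(C)) - 1L)),
            class = "lmi_correlation")
}

# centrality profile directly from an edge list (bypasses contact filtering)
profile_from_edges <- function(n, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- edges$weight
  betweenness_profile(g)
}

test_that("graph construction applies contact filtering and weight clipping", {
  # triangle with equal correlations -> equal weights
  C <- matrix(0.5, 3, 3); diag(C) <- 1
  xyz <- matrix(c(0, 0, 0, 5, 0, 0, 2.5, 4, 0), 3, byrow = TRUE)
  g <- build_graph(as_lmi(C), xyz, contact_cutoff = 10)
  expect_equal(nrow(g$edges), 3)
  expect_equal(unique(g$edges$weight), -log(0.5))

  # below-floor correlation is clipped, edge retained while in contact
  C2 <- C; C2[1, 2] <- C2[2, 1] <- 1e-9
  g2 <- build_graph(as_lmi(C2), xyz, contact_cutoff = 10)
  e12 <- g2$edges[g2$edges$i == 1 & g2$edges$j == 2, ]
  expect_equal(e12$weight, -log(1e-6))

  # distant pair loses its edge even at high correlation; the resulting
  # isolated node triggers the disconnected-graph warning
  far <- xyz; far[3, ] <- c(100, 100, 100)
  expect_warning(g3 <- build_graph(as_lmi(C), far, contact_cutoff = 10),
                 "disconnected")
  expect_equal(nrow(g3$edges), 1)

  # per-frame contact rule on an ensemble: pair within cutoff in only half
  # the frames fails a 75% requirement
  coords <- array(0, dim = c(4, 3, 3))
  for (t in 1:4) coords[t, , ] <- xyz
  coords[3:4, 3, 1] <- 100
  expect_warning(
    g4 <- build_graph(as_lmi(C), xyz, contact_cutoff = 10,
                      contact_fraction = 0.75, ens = ensemble(coords)),
    "disconnected")
  expect_equal(nrow(g4$edges), 1)  # only 1-2 survives
})

test_that("contact set equals the ANM adjacency for small fluctuations", {
  model <- build_toy_complex(toy_complex_spec(20, 4, seed = 19))
  sim <- sample_anm_ensemble(model, n_frames = 50, seed = 19,
                             temperature_scale = 0.02)
  sim$model <- model
  xyz <- model_coords(sim$model)
  nn <- nrow(xyz)
  lm <- lmi_matrix(sim$ensemble)
  g <- build_graph(lm, xyz, contact_cutoff = 12, contact_fraction = 0.75,
                   ens = sim$ensemble)
  adj_graph <- matrix(FALSE, nn, nn)
  adj_graph[cbind(g$edges$i, g$edges$j)] <- TRUE
  adj_graph <- adj_graph | t(adj_graph)
  dmat <- as.matrix(dist(xyz))
  adj_anm <- dmat <= 12 & dmat > 0
  # fluctuations (scale 1 A^2) are small relative to the 12 A cutoff:
  # mismatches can only occur for pairs within ~2 A of the boundary
  mismatch <- which(adj_graph != adj_anm, arr.ind = TRUE)
  dimnames(adj_anm) <- NULL
  if (nrow(mismatch)) {
    expect_true(all(abs(dmat[mismatch] - 12) < 2))
  } else {
    expect_identical(adj_graph, adj_anm)
  }
})

test_that("betweenness matches hand counts on path, star, and diamond graphs", {
  path3 <- data.frame(i = c(1, 2), j = c(2, 3), weight = 1)
  bp <- profile_from_edges(3, path3)
  expect_equal(bp$bc_raw, c(0, 1, 0))

  star <- data.frame(i = rep(1, 4), j = 2:5, weight = 1)
  bs <- profile_from_edges(5, star)
  expect_equal(bs$bc_raw[1], 6)             # (n-1)(n-2)/2 pairs routed via hub
  expect_equal(bs$bc_normalized[1], 1)
  expect_equal(bs$bc_raw[-1], rep(0, 4))

  # 4-node diamond: two equal-weight routes 1-2-4 and 1-3-4 split the pair
  diamond <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4), weight = 1)
  bd <- profile_from_edges(4, diamond)
  expect_equal(bd$bc_raw[2], 0.5)
  expect_equal(bd$bc_raw[3], 0.5)
})

test_that("weighted betweenness equals the brute-force path enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 8
    # random connected graph: spanning tree plus extra edges
    edges <- data.frame(i = 2:n, j = vapply(2:n, function(v) sample(v - 1, 1), 1L))
    extra <- t(combn(n, 2))
    extra <- extra[sample(nrow(extra), 6), , drop = FALSE]
    edges <- unique(rbind(edges, data.frame(i = extra[, 1], j = extra[, 2])))
    edges <- edges[edges$i != edges$j, ]
    edges[c("i", "j")] <- list(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    edges <- unique(edges)
    edges$weight <- round(runif(nrow(edges), 0.2, 2), 3)
    got <- profile_from_edges(n, edges)$bc_raw
    expect_equal(got, bf_betweenness(n, edges), tolerance = 1e-9)
  }
})

test_that("betweenness is invariant to uniform weight scaling and reduces to unweighted Brandes", {
  set.seed(99)
  edges <- data.frame(i = c(1, 1, 2, 2, 3, 4, 5), j = c(2, 3, 3, 4, 5, 5, 6),
                      weight = runif(7, 0.5, 2))
  a <- profile_from_edges(6, edges)
  edges2 <- edges; edges2$weight <- edges$weight * 10
  expect_equal(profile_from_edges(6, edges2)$bc_raw, a$bc_raw, tolerance = 1e-12)

  unit <- edges; unit$weight <- 1
  g <- igraph::graph_from_data_frame(unit[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = 1:6))
  expect_equal(profile_from_edges(6, unit)$bc_raw,
               as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA)),
               tolerance = 1e-12)
})

test_that("delta-BC flags rerouted nodes against an oracle recomputation", {
  # reference: all A-C traffic through B (cheap); D expensive detour
  ref_edges <- data.frame(i = c(1, 2, 1, 3), j = c(2, 4, 3, 4),
                          weight = c(1, 1, 5, 5))
  # state: B link broken (expensive), traffic reroutes through D
  st_edges <- ref_edges
  st_edges$weight <- c(5, 5, 1, 1)
  ref <- profile_from_edges(4, ref_edges)
  st <- profile_from_edges(4, st_edges)
  d <- delta_bc(st, ref, threshold = 0.1)
  expect_equal(d$delta_bc[2], -1 / 3)   # B loses its one interior pair
  expect_equal(d$delta_bc[3], 1 / 3)    # D gains it
  expect_identical(d$flagged, c(FALSE, TRUE, TRUE, FALSE))

  z <- delta_bc(ref, ref)
  expect_true(all(z$delta_bc == 0) && !any(z$flagged))
  d0 <- delta_bc(st, ref, threshold = 0)
  expect_identical(d0$flagged, d0$delta_bc != 0)
  expect_error(delta_bc(st, profile_from_edges(3, ref_edges[1, ])), "mismatch")
})
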