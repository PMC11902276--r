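# Independent oracles used across the suite. Each is deliberately naive and
# shares no code with the package implementation it checks.

# --- brute-force weighted betweenness: enumerate all simple paths ----------
# adjacency: data frame (i, j, weight), undirected, 1-based nodes.
bf_betweenness <- function(n, edges) {
  wmat <- matrix(Inf, n, n)
  for (k in seq_len(nrow(edges))) {
    wmat[edges$i[k], edges$j[k]] <- edges$weight[k]
    wmat[edges$j[k], edges$i[k]] <- edges$weight[k]
  }
  all_paths <- function(a, b) {
    out <- list()
    walk <- function(path, cost) {
      v <- path[length(path)]
      if (v == b) {
        out[[length(out) + 1L]] <<- list(path = path, cost = cost)
        return()
      }
      for (u in which(is.finite(wmat[v, ]))) {
        if (!(u %in% path)) walk(c(path, u), cost + wmat[v, u])
      }
    }
    walk(a, 0)
    out
  }
  bc <- numeric(n)
  for (a in seq_len(n - 1)) {
    for (b in seq.int(a + 1, n)) {
      ps <- all_paths(a, b)
      if (!length(ps)) next
      costs <- vapply(ps, `[[`, numeric(1), "cost")
      cmin <- min(costs)
      short <- ps[costs <= cmin * (1 + 1e-9) + 1e-12]
      g_ab <- length(short)
      for (p in short) {
        interior <- setdiff(p$path, c(a, b))
        bc[interior] <- bc[interior] + 1 / g_ab
      }
    }
  }
  bc
}

# --- Jacobi eigensolver for symmetric matrices -----------------------------
jacobi_eigen <- function(a, tol = 1e-12, max_sweeps = 100) {
  n <- nrow(a)
  v <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(a[upper.tri(a)]^2))
    if (off < tol) break
    for (p in seq_len(n - 1)) {
      for (q in seq.int(p + 1, n)) {
        if (abs(a[p, q]) < tol / n) next
        theta <- 0.5 * atan2(2 * a[p, q], a[q, q] - a[p, p])
        c_ <- cos(theta); s_ <- sin(theta)
        rot <- diag(n); rot[p, p] <- c_; rot[q, q] <- c_
        rot[p, q] <- s_; rot[q, p] <- -s_
        a <- t(rot) %*% a %*% rot
        v <- v %*% rot
      }
    }
  }
  ord <- order(diag(a), decreasing = TRUE)
  list(values = diag(a)[ord], vectors = v[, ord, drop = FALSE])
}

# --- rotation-search RMSD oracle: coarse Euler grid + Nelder-Mead refine ---
rotsearch_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rotmat(ang)) - b)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- NULL; best_val <- Inf
  for (x in grid) for (y in grid) for (z in grid) {
    val <- obj(c(x, y, z))
    if (val < best_val) { best_val <- val; best <- c(x, y, z) }
  }
  for (k in 1:3) {
    opt <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- opt$par; best_val <- opt$value
  }
  best_val
}

# --- determinant by cofactor expansion (for entropy log-det oracle) --------
cofactor_det <- function(m) {
  n <- nrow(m)
  if (n == 1) return(m[1, 1])
  sum(vapply(seq_len(n), function(j) {
    (-1)^(1 + j) * m[1, j] * cofactor_det(m[-1, -j, drop = FALSE])
  }, numeric(1)))
}

# --- small random SPD matrix ------------------------------------------------
random_spd <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) + diag(0.1, n)
}

# Toy ensemble reused by several files (small, fast, connected ANM).
toy_sim <- function(n_frames = 1500, seed = 11, n_protein = 20, n_dna = 4) {
  model <- build_toy_complex(toy_complex_spec(n_protein, n_dna, seed = seed))
  sim <- sample_anm_ensemble(model, n_frames = n_frames, seed = seed)
  sim$model <- model
  sim$sel <- select_nodes(model, "A", if (n_dna > 0) "B" else character(0))
  sim
}
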