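# Anisotropic network model and perturbation response scanning.
#
# The ANM represents the structure as nodes joined by harmonic springs
# within a cutoff distance (default 12 A). Its 3N x 3N Hessian has six
# zero modes (rigid-body translations/rotations) for a connected network;
# the slow non-zero modes approximate the collective dynamics. PRS applies
# a unit force at each node in turn and reads the network response through
# Hooke's law, dR = H^-1 F, using a mode-truncated pseudo-inverse.

#' Build an anisotropic network model
#'
#' Off-diagonal 3x3 super-element for a contacting pair (i, j):
#' -gamma / |d_ij|^2 * d_ij d_ij^T; diagonal blocks make block rows sum to
#' zero. The eigendecomposition (ascending) is attached.
#'
#' @param coords N x 3 reference coordinates (Angstrom), N >= 3.
#' @param cutoff spring cutoff distance, Angstrom (default 12).
#' @param gamma uniform spring constant (default 1; normalized outputs are
#'   gamma-independent).
#' @param gamma_scale optional symmetric N x N per-pair stiffness multiplier.
#' @return list of class `anm_model`: `reference_coords`, `cutoff`, `gamma`,
#'   `hessian` (3N x 3N), `eigenvalues` (ascending), `eigenvectors`,
#'   `n_zero_modes` (6 for a connected, non-degenerate geometry; collinear
#'   toys have more because transverse motion costs no spring energy).
#' @export
build_anm <- function(coords, cutoff = 12, gamma = 1, gamma_scale = NULL) {
  coords <- as.matrix(coords)
  nn <- nrow(coords)
  stopifnot(nn >= 2, ncol(coords) == 3)
  h <- matrix(0, 3 * nn, 3 * nn)
  dmat <- as.matrix(stats::dist(coords))
  adj <- dmat <= cutoff & dmat > 0
  comp <- .graph_components(adj)
  if (comp > 1) {
    stop(sprintf("build_anm: network disconnected at cutoff %g A (%d components)",
                 cutoff, comp))
  }
  for (i in seq_len(nn - 1)) {
    for (j in seq.int(i + 1, nn)) {
      dij <- dmat[i, j]
      if (dij <= cutoff && dij > 0) {
        g <- gamma * if (is.null(gamma_scale)) 1 else gamma_scale[i, j]
        v <- coords[j, ] - coords[i, ]
        blk <- -(g / dij^2) * tcrossprod(v)
        ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
        h[ri, rj] <- blk
        h[rj, ri] <- blk
        h[ri, ri] <- h[ri, ri] - blk
        h[rj, rj] <- h[rj, rj] - blk
      }
    }
  }
  eig <- eigen(h, symmetric = TRUE)
  lam <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_len(3 * nn)), drop = FALSE]
  nzero <- sum(lam <= 1e-8 * max(lam))
  structure(list(reference_coords = coords, cutoff = cutoff, gamma = gamma,
                 hessian = h, eigenvalues = lam, eigenvectors = vec,
                 n_zero_modes = nzero),
            class = "anm_model")
}

# number of connected components of a logical adjacency matrix (BFS)
.graph_components <- function(adj) {
  nn <- nrow(adj)
  seen <- logical(nn)
  comp <- 0L
  for (s in seq_len(nn)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Mode-truncated ANM covariance (pseudo-inverse)
#'
#' sum over the `n_modes` slowest non-zero modes of (1/lambda_k) v_k v_k^T.
#' With all 3N - 6 modes this equals the Moore-Penrose pseudo-inverse of the
#' Hessian.
#'
#' @param model an [build_anm()] result.
#' @param n_modes number of slowest non-zero modes (default 20).
#' @return 3N x 3N covariance matrix (units 1/gamma).
#' @export
anm_covariance <- function(model, n_modes = 20L) {
  lam <- model$eigenvalues
  nzero <- sum(lam <= 1e-8 * max(lam))
  avail <- length(lam) - nzero
  if (n_modes > avail) {
    stop(sprintf("anm_covariance: %d modes requested but only %d non-zero modes available",
                 n_modes, avail))
  }
  keep <- seq.int(nzero + 1, nzero + n_modes)
  v <- model$eigenvectors[, keep, drop = FALSE]
  cov <- v %*% (t(v) / lam[keep])
  (cov + t(cov)) / 2
}

#' Perturbation response scanning
#'
#' A unit force applied at node i produces the response dR = C F with C the
#' mode-truncated ANM covariance; raw_response(i, j) is the squared
#' displacement magnitude of node j averaged over isotropic force
#' directions. The isotropic average has the closed form
#' (1/3) * sum of squared entries of the 3x3 block C_ji (`analytic = TRUE`,
#' default); Monte-Carlo direction sampling is retained for validation.
#' Rows of the normalized map are divided by their diagonal (self-response),
#' making the diagonal exactly 1.
#'
#' @param model an [build_anm()] result.
#' @param n_modes slowest non-zero modes used (default 20, capped at 3N-6).
#' @param analytic closed-form isotropic averaging (default) or sampling.
#' @param n_force_directions directions per node when sampling.
#' @param seed integer seed for sampled directions.
#' @return list of class `prs_map`: `raw_response`, `normalized` (N x N),
#'   `effector_profile`, `sensor_profile`, `n_modes_used`.
#' @export
prs_scan <- function(model, n_modes = 20L, analytic = TRUE,
                     n_force_directions = 100L, seed = 1L) {
  nn <- nrow(model$reference_coords)
  lam <- model$eigenvalues
  nzero <- sum(lam <= 1e-8 * max(lam))
  n_modes <- min(n_modes, length(lam) - nzero)
  cov <- anm_covariance(model, n_modes)
  raw <- matrix(NA_real_, nn, nn)
  if (analytic) {
    for (i in seq_len(nn)) {
      ci <- cov[, (3 * i - 2):(3 * i), drop = FALSE]     # 3N x 3 block column i
      blk2 <- ci^2
      raw[i, ] <- (rowSums(blk2[seq(1, 3 * nn, 3), ]) +
                   rowSums(blk2[seq(2, 3 * nn, 3), ]) +
                   rowSums(blk2[seq(3, 3 * nn, 3), ])) / 3
    }
  } else {
    dirs <- with_seed(seed, {
      m <- matrix(stats::rnorm(3 * n_force_directions), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    for (i in seq_len(nn)) {
      ci <- cov[, (3 * i - 2):(3 * i), drop = FALSE]
      acc <- numeric(nn)
      for (k in seq_len(n_force_directions)) {
        dr <- ci %*% dirs[k, ]
        acc <- acc + rowSums(matrix(dr^2, ncol = 3, byrow = TRUE))
      }
      raw[i, ] <- acc / n_force_directions
    }
  }
  normalized <- raw / diag(raw)
  pr <- .prs_profiles(normalized)
  structure(list(raw_response = raw, normalized = normalized,
                 effector_profile = pr$effector, sensor_profile = pr$sensor,
                 n_modes_used = n_modes),
            class = "prs_map")
}

.prs_profiles <- function(normalized) {
  nn <- nrow(normalized)
  off <- normalized
  diag(off) <- NA
  list(effector = rowMeans(off, na.rm = TRUE),
       sensor = colMeans(off, na.rm = TRUE))
}

#' Effector and sensor profiles of a PRS map
#'
#' effector_i = mean over j != i of normalized(i, j) — how strongly node i
#' displaces the rest of the network when perturbed; sensor_j = mean over
#' i != j of normalized(i, j) — how strongly node j responds to
#' perturbations elsewhere.
#'
#' @param prs a `prs_map`.
#' @param exclude_self drop the diagonal from the means (default TRUE).
#' @return list: `effector`, `sensor` per-node vectors.
#' @export
effector_sensor <- function(prs, exclude_self = TRUE) {
  m <- prs$normalized
  if (exclude_self) return(.prs_profiles(m))
  list(effector = rowMeans(m), sensor = colMeans(m))
}

#' PRS map averaged over representative structures
#'
#' Takes `n_representatives` evenly spaced frames (default 100, or all
#' frames if fewer), builds an ANM per frame, and averages the normalized
#' PRS maps elementwise. Frames whose network is disconnected at the cutoff
#' are skipped with a warning.
#'
#' @param ens an `ensemble`.
#' @param n_representatives number of evenly spaced frames to use.
#' @param cutoff ANM cutoff, Angstrom.
#' @param n_modes slowest non-zero modes per frame.
#' @return a `prs_map` (elementwise mean of per-frame normalized maps) with
#'   an extra field `n_frames_used`.
#' @export
averaged_prs <- function(ens, n_representatives = 100L, cutoff = 12,
                         n_modes = 20L) {
  nf <- n_frames(ens)
  take <- unique(round(seq(1, nf, length.out = min(n_representatives, nf))))
  acc <- NULL
  used <- 0L
  for (t in take) {
    m <- tryCatch(build_anm(frame_coords(ens, t), cutoff = cutoff),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("averaged_prs: frame %d disconnected at cutoff; skipped", t))
      next
    }
    p <- prs_scan(m, n_modes = n_modes)
    acc <- if (is.null(acc)) p$normalized else acc + p$normalized
    used <- used + 1L
  }
  if (used == 0L) stop("averaged_prs: every representative frame was disconnected")
  normalized <- acc / used
  pr <- .prs_profiles(normalized)
  structure(list(raw_response = NULL, normalized = normalized,
                 effector_profile = pr$effector, sensor_profile = pr$sensor,
                 n_modes_used = n_modes, n_frames_used = used),
            class = "prs_map")
}
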