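# Essential dynamics: Cartesian covariance of the node coordinates,
# eigen-analysis with cosine-content screening, projections, and
# free-energy landscapes over two principal components.

#' Cartesian covariance matrix of an ensemble
#'
#' M = <(r - <r>)(r - <r>)^T> over frames (population divisor F), computed on
#' the flattened 3N coordinate vectors after optional iterative superposition
#' of every frame onto the ensemble mean. No mass weighting.
#'
#' @param ens an `ensemble` with >= 2 frames.
#' @param fit superpose frames onto the mean first (default TRUE).
#' @return list of class `covariance_matrix`: `matrix` (3N x 3N, A^2),
#'   `mean_structure` (N x 3), `n_frames`.
#' @export
covariance <- function(ens, fit = TRUE) {
  if (n_frames(ens) < 2) stop("covariance: need at least 2 frames")
  coords <- if (fit) .fit_to_mean(ens$coords) else ens$coords
  nf <- dim(coords)[1]; nn <- dim(coords)[2]
  # flatten frames to F x 3N (x1 y1 z1 x2 ...)
  flat <- matrix(aperm(coords, c(3, 2, 1)), nrow = 3 * nn)  # 3N x F
  mu <- rowMeans(flat)
  dev <- flat - mu
  m <- tcrossprod(dev) / nf
  m <- (m + t(m)) / 2
  structure(list(matrix = m,
                 mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
                 n_frames = nf),
            class = "covariance_matrix")
}

# Flatten an ensemble (optionally fitted) to F x 3N, centered on `mu` (3N).
.flat_frames <- function(coords) {
  nn <- dim(coords)[2]
  t(matrix(aperm(coords, c(3, 2, 1)), nrow = 3 * nn))
}

#' Principal component analysis of a covariance matrix
#'
#' Dense symmetric eigendecomposition in descending eigenvalue order. The
#' sign of each eigenvector is fixed so its largest-magnitude component is
#' positive. Frame projections are the centered, fitted coordinates dotted
#' with the eigenvectors; the cosine content of the first
#' `min(20, n_keep)` projections is attached.
#'
#' @param cov a [covariance()] result.
#' @param ens the same ensemble (for projections); may be NULL.
#' @param n_keep number of components to keep projections for.
#' @param fit must match the `fit` used for `cov`.
#' @return list of class `pca_result`: `eigenvalues` (descending, A^2),
#'   `eigenvectors` (3N x 3N, columns), `variance_fractions`,
#'   `cosine_contents`, `projections` (F x n_keep or NULL).
#' @export
pca <- function(cov, ens = NULL, n_keep = 20L, fit = TRUE) {
  stopifnot(inherits(cov, "covariance_matrix"))
  n3 <- nrow(cov$matrix)
  n_keep <- min(n_keep, n3)
  eig <- eigen(cov$matrix, symmetric = TRUE)
  vec <- eig$vectors
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  val <- pmax(eig$values, 0)
  vfrac <- if (sum(val) > 0) val / sum(val) else rep(0, n3)
  proj <- NULL
  cosc <- NULL
  if (!is.null(ens)) {
    coords <- if (fit) .fit_to_mean(ens$coords) else ens$coords
    flat <- .flat_frames(coords)
    centered <- sweep(flat, 2, as.vector(t(cov$mean_structure)))
    proj <- centered %*% vec[, seq_len(n_keep), drop = FALSE]
    cosc <- apply(proj[, seq_len(min(20L, n_keep)), drop = FALSE], 2,
                  cosine_content)
  }
  structure(list(eigenvalues = val, eigenvectors = vec,
                 variance_fractions = vfrac, cosine_contents = cosc,
                 projections = proj),
            class = "pca_result")
}

#' Cosine content of a principal-component projection
#'
#' c = (2/F) (sum_t p_t cos(pi t / F))^2 / sum_t p_t^2, t = 0..F-1 — the
#' overlap with the first half-period cosine. Values near 1 indicate
#' random-diffusion-like, unconverged sampling; projections with c <= 0.1
#' pass the screening.
#'
#' @param p per-frame projection series, length >= 4.
#' @param threshold pass threshold (default 0.1).
#' @return the cosine content, with attribute `pass`.
#' @export
cosine_content <- function(p, threshold = 0.1) {
  ff <- length(p)
  stopifnot(ff >= 4)
  denom <- sum(p^2)
  if (denom == 0) {
    warning("cosine_content: all-zero projection; defined as 0")
    c <- 0
  } else {
    t <- seq_len(ff) - 1
    c <- (2 / ff) * sum(p * cos(pi * t / ff))^2 / denom
  }
  attr(c, "pass") <- c <= threshold
  c
}

#' Select the two PCs for the free-energy landscape
#'
#' Among the first 20 components, the two highest-variance ones whose cosine
#' content passes the threshold, in variance order. Indices are 1-based.
#'
#' @param pca_res a [pca()] result with projections.
#' @param threshold cosine-content pass threshold.
#' @return integer vector of length 2.
#' @export
select_pcs <- function(pca_res, threshold = 0.1) {
  cosc <- pca_res$cosine_contents
  if (is.null(cosc)) stop("select_pcs: pca result has no projections")
  pass <- which(cosc <= threshold)
  if (length(pass) < 2) {
    stop("select_pcs: fewer than two components pass the cosine-content ",
         "threshold; sampling is unconverged - extend the trajectory")
  }
  pass[1:2]
}

#' Free-energy landscape over two projections
#'
#' 2-D histogram of (proj_a, proj_b) -> probability P; G = -kT ln(P / P_max),
#' so the most populated bin has exactly G = 0. Empty bins are NA (masked),
#' never zero.
#'
#' @param proj_a,proj_b equal-length per-frame series, F >= n_bins.
#' @param n_bins bins per axis (default 32).
#' @param temperature_kT energy scale (default 1: energies in kT units).
#' @return list of class `fel_grid`: `free_energy` (n_bins x n_bins, kT),
#'   `edges_a`, `edges_b`, `counts`.
#' @export
free_energy_landscape <- function(proj_a, proj_b, n_bins = 32L,
                                  temperature_kT = 1) {
  stopifnot(length(proj_a) == length(proj_b), length(proj_a) >= n_bins)
  edges_a <- seq(min(proj_a), max(proj_a), length.out = n_bins + 1)
  edges_b <- seq(min(proj_b), max(proj_b), length.out = n_bins + 1)
  ia <- pmin(pmax(findInterval(proj_a, edges_a, all.inside = TRUE), 1), n_bins)
  ib <- pmin(pmax(findInterval(proj_b, edges_b, all.inside = TRUE), 1), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  p <- counts / length(proj_a)
  g <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0
  g[occ] <- -temperature_kT * log(p[occ] / max(p))
  structure(list(free_energy = g, edges_a = edges_a, edges_b = edges_b,
                 counts = counts, temperature_kT = temperature_kT),
            class = "fel_grid")
}

#' Scree table of a PCA result
#'
#' @param pca_res a [pca()] result.
#' @param n number of leading components to tabulate.
#' @return data frame: `pc`, `eigenvalue`, `fraction`, `cumulative`,
#'   `cosine_content` (NA beyond the screened range).
#' @export
scree_table <- function(pca_res, n = 20L) {
  n <- min(n, length(pca_res$eigenvalues))
  cosc <- rep(NA_real_, n)
  if (!is.null(pca_res$cosine_contents)) {
    k <- min(n, length(pca_res$cosine_contents))
    cosc[seq_len(k)] <- as.numeric(pca_res$cosine_contents[seq_len(k)])
  }
  data.frame(pc = seq_len(n),
             eigenvalue = pca_res$eigenvalues[seq_len(n)],
             fraction = pca_res$variance_fractions[seq_len(n)],
             cumulative = cumsum(pca_res$variance_fractions)[seq_len(n)],
             cosine_content = cosc)
}
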