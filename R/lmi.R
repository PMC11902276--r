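# Linear-mutual-information generalized cross-correlation.
#
# Under a Gaussian model of the coordinate fluctuations, the mutual
# information between the 3-D position vectors of nodes i and j is
#   I_ij = H_i + H_j - H_ij,   H = 1/2 ln[(2*pi*e)^k det(Sigma)]
# with Sigma the 3x3 marginal (k = 3) or 6x6 joint (k = 6) covariance block,
# and the generalized correlation coefficient is
#   C_ij = sqrt(1 - exp(-2 I_ij / d)),  d = 3,
# which is 0 for uncorrelated and 1 for fully correlated motion, and unlike
# the Pearson DCCM does not miss correlated motion in orthogonal directions.

.block3 <- function(m, i) m[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i), drop = FALSE]

.block_joint <- function(m, i, j) {
  idx <- c((3 * i - 2):(3 * i), (3 * j - 2):(3 * j))
  m[idx, idx, drop = FALSE]
}

# log-determinant via Cholesky; NA if not positive definite
.logdet <- function(s) {
  r <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(r)) return(NA_real_)
  2 * sum(log(diag(r)))
}

#' Gaussian differential entropies for a node pair
#'
#' H = 1/2 ln of (2 pi e)^k det Sigma in nats, with Sigma the regularized 3x3
#' marginal (k = 3) or 6x6 joint (k = 6) covariance block of the 3N x 3N
#' covariance matrix. The density estimator is the Gaussian implied by the
#' sample covariance — the "linear" in LMI.
#'
#' @param cov a [covariance()] result or a bare 3N x 3N matrix.
#' @param i,j 1-based node indices.
#' @param regularization epsilon added (times mean diagonal) to block
#'   diagonals before the determinant (default 1e-8).
#' @return list: `H_i`, `H_j`, `H_ij` (nats), and `degenerate` (TRUE when
#'   the joint block is singular relative to the marginals — exact-copy
#'   motion).
#' @export
gaussian_entropy_terms <- function(cov, i, j, regularization = 1e-8) {
  m <- if (inherits(cov, "covariance_matrix")) cov$matrix else cov
  eps <- regularization * sum(diag(m)) / nrow(m)
  if (eps <= 0) eps <- regularization          # motionless input: C -> 0
  si <- .block3(m, i); sj <- .block3(m, j); sij <- .block_joint(m, i, j)
  ld_i_raw <- .logdet(si); ld_j_raw <- .logdet(sj); ld_ij_raw <- .logdet(sij)
  # degeneracy: joint block (near-)singular while marginals are not
  degenerate <- FALSE
  if (!is.na(ld_i_raw) && !is.na(ld_j_raw) &&
      (is.na(ld_ij_raw) || ld_ij_raw < ld_i_raw + ld_j_raw + log(1e-12))) {
    degenerate <- TRUE
  }
  reg <- function(s) s + diag(eps, nrow(s))
  ld_i <- .logdet(reg(si)); ld_j <- .logdet(reg(sj)); ld_ij <- .logdet(reg(sij))
  if (anyNA(c(ld_i, ld_j, ld_ij))) {
    stop("gaussian_entropy_terms: covariance block not positive definite after regularization")
  }
  k2 <- log(2 * pi * exp(1))
  list(H_i = 0.5 * (3 * k2 + ld_i),
       H_j = 0.5 * (3 * k2 + ld_j),
       H_ij = 0.5 * (6 * k2 + ld_ij),
       degenerate = degenerate)
}

#' Linear mutual information between two nodes
#'
#' I = H_i + H_j - H_ij, floored at 0; `Inf` for degenerate (exact-copy)
#' pairs.
#'
#' @inheritParams gaussian_entropy_terms
#' @return mutual information in nats (>= 0, possibly `Inf`).
#' @export
lmi <- function(cov, i, j, regularization = 1e-8) {
  if (i == j) return(Inf)
  h <- gaussian_entropy_terms(cov, i, j, regularization)
  if (h$degenerate) return(Inf)
  max(0, h$H_i + h$H_j - h$H_ij)
}

#' Convert mutual information to a generalized correlation coefficient
#'
#' C = (1 - exp(-2 I / d))^(1/2) with d = 3 for 3-D position vectors;
#' C(0) = 0 exactly and C(Inf) = 1 exactly.
#'
#' @param I mutual information in nats (vectorized), >= 0.
#' @param d dimensionality parameter (default 3).
#' @return values in \[0, 1\].
#' @export
lmi_to_correlation <- function(I, d = 3) {
  if (any(I < 0, na.rm = TRUE)) stop("lmi_to_correlation: negative mutual information")
  out <- sqrt(1 - exp(-2 * I / d))
  out[is.infinite(I)] <- 1
  out
}

#' All-pairs LMI correlation matrix of an ensemble
#'
#' Computes the sample covariance (with superposition, matching the PCA
#' pipeline) and evaluates the Gaussian LMI correlation for every node pair.
#' The diagonal is 1 by convention (continuous self-information diverges).
#'
#' @param ens an `ensemble`.
#' @param regularization block-diagonal regularization epsilon.
#' @param fit superpose frames first (default TRUE).
#' @param cov optional precomputed [covariance()] of the same ensemble.
#' @return list of class `lmi_correlation`: `C` (N x N in \[0, 1\]), `I`
#'   (N x N nats, Inf on the diagonal), `d_param`, `node_labels`.
#' @export
lmi_matrix <- function(ens, regularization = 1e-8, fit = TRUE, cov = NULL) {
  if (is.null(cov)) cov <- covariance(ens, fit = fit)
  out <- lmi_matrix_from_covariance(cov$matrix, regularization)
  if (!is.null(ens$selection)) {
    out$node_labels <- paste0(ens$selection$chain, ens$selection$resid)
  }
  out
}

#' @rdname lmi_matrix
#' @param cov3n a 3N x 3N covariance matrix (e.g. analytic ground truth).
#' @export
lmi_matrix_from_covariance <- function(cov3n, regularization = 1e-8) {
  nn <- nrow(cov3n) / 3
  stopifnot(nn == round(nn))
  I <- matrix(Inf, nn, nn)
  C <- diag(1, nn)
  if (nn > 1) {
    for (i in seq_len(nn - 1)) {
      for (j in seq.int(i + 1, nn)) {
        v <- lmi(cov3n, i, j, regularization)
        I[i, j] <- I[j, i] <- v
        C[i, j] <- C[j, i] <- lmi_to_correlation(v)
      }
    }
  }
  structure(list(C = C, I = I, d_param = 3L,
                 node_labels = as.character(seq_len(nn) - 1L)),
            class = "lmi_correlation")
}

#' Difference map between two LMI correlation states
#'
#' delta C = C_state - C_reference elementwise; antisymmetric under swapping
#' the arguments.
#'
#' @param state,reference `lmi_correlation` objects over the same nodes.
#' @param state_label,reference_label labels recorded in the result.
#' @return list of class `correlation_difference`: `delta_C`,
#'   `state_label`, `reference_label`.
#' @export
difference_map <- function(state, reference, state_label = "state",
                           reference_label = "reference") {
  stopifnot(inherits(state, "lmi_correlation"),
            inherits(reference, "lmi_correlation"))
  if (!identical(dim(state$C), dim(reference$C)) ||
      !identical(state$node_labels, reference$node_labels)) {
    stop("difference_map: node label mismatch between states")
  }
  structure(list(delta_C = state$C - reference$C,
                 state_label = state_label, reference_label = reference_label),
            class = "correlation_difference")
}
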