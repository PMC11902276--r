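# Synthetic coordinate ensembles with analytically known ground truth:
# helical toy complexes, ANM-Gaussian frame sampling, designed H-bond /
# salt-bridge event series, correlated node pairs.

# Run expr under a local RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a toy protein-DNA complex
#'
#' The protein trace is a regular helix whose consecutive node spacing equals
#' `rise`; the DNA trace is a straight line of P pseudo-atoms parallel to the
#' helix axis. Defaults approximate C-alpha geometry (3.8 A spacing on a
#' 2.3 A-radius, 5.4 A-pitch helix) and backbone P spacing (7 A).
#'
#' @param n_protein_nodes number of CA pseudo-atoms (>= 4).
#' @param n_dna_nodes number of P pseudo-atoms (>= 0).
#' @param rise consecutive CA-CA distance, Angstrom.
#' @param radius,pitch helix radius and pitch, Angstrom.
#' @param dna_spacing P-P spacing, Angstrom.
#' @param dna_offset lateral offset of the DNA trace from the helix axis, A.
#' @param domain_ranges optional [domain_annotation()].
#' @param seed integer seed (stored; geometry itself is deterministic).
#' @return a `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_protein_nodes, n_dna_nodes = 0L,
                             rise = 3.8, radius = 2.3, pitch = 5.4,
                             dna_spacing = 7.0, dna_offset = 12.0,
                             domain_ranges = NULL, seed = 1L) {
  stopifnot(n_protein_nodes >= 4, n_dna_nodes >= 0, rise > 0, radius >= 0)
  structure(list(n_protein_nodes = as.integer(n_protein_nodes),
                 n_dna_nodes = as.integer(n_dna_nodes),
                 rise = rise, radius = radius, pitch = pitch,
                 dna_spacing = dna_spacing, dna_offset = dna_offset,
                 domain_ranges = domain_ranges, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Build the node-level toy complex
#'
#' One CA pseudo-atom per protein residue on the helical trace (chain A) and
#' one P pseudo-atom per nucleotide on the straight DNA trace (chain B).
#' Deterministic for a given spec; errors if any inter-node distance < 1 A.
#'
#' @param spec a [toy_complex_spec()].
#' @return a [structure_model()].
#' @export
build_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  np <- spec$n_protein_nodes; nd <- spec$n_dna_nodes
  # axial step dz solving chord(dz) = rise on the helix
  chord <- function(dz) {
    theta <- 2 * pi * dz / spec$pitch
    sqrt(dz^2 + 2 * spec$radius^2 * (1 - cos(theta)))
  }
  if (spec$radius == 0) {
    dz <- spec$rise
  } else {
    dz <- stats::uniroot(function(d) chord(d) - spec$rise,
                         c(1e-6, spec$rise), tol = 1e-12)$root
  }
  k <- seq_len(np) - 1
  theta <- 2 * pi * dz * k / spec$pitch
  prot <- cbind(spec$radius * cos(theta), spec$radius * sin(theta), dz * k)
  atoms <- data.frame(serial = seq_len(np), name = "CA", resname = "ALA",
                      resid = seq_len(np), chain = "A",
                      x = prot[, 1], y = prot[, 2], z = prot[, 3],
                      element = "C")
  if (nd > 0) {
    j <- seq_len(nd) - 1
    zc <- (np - 1) * dz / 2                      # center DNA along the helix
    dna <- cbind(rep(spec$dna_offset, nd), rep(0, nd),
                 zc + (j - (nd - 1) / 2) * spec$dna_spacing)
    atoms <- rbind(atoms,
                   data.frame(serial = np + seq_len(nd), name = "P",
                              resname = "DA", resid = seq_len(nd), chain = "B",
                              x = dna[, 1], y = dna[, 2], z = dna[, 3],
                              element = "P"))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1 && min(stats::dist(xyz)) < 1) {
    stop("build_toy_complex: geometry places nodes closer than 1 A")
  }
  structure_model(atoms, title = sprintf("toy complex %dCA+%dP", np, nd))
}

#' Sample an ensemble from the Gaussian implied by an ANM
#'
#' Frames are drawn independently from the zero-mean multivariate normal with
#' covariance `temperature_scale` times the pseudo-inverse of the ANM Hessian
#' (12 A cutoff by default), added to the reference coordinates. Sampling is
#' done in mode space excluding the six rigid-body modes, so the ensemble has
#' finite covariance without superposition. The returned ground truth carries
#' the exact covariance and the analytic LMI correlation matrix it implies.
#'
#' @param model reference [structure_model()] (every atom is a node).
#' @param n_frames number of frames (>= 2).
#' @param cutoff ANM spring cutoff, Angstrom.
#' @param temperature_scale overall covariance scale, Angstrom^2.
#' @param seed integer seed.
#' @param gamma_scale optional N x N spring-stiffness multiplier matrix.
#' @return list with elements `ensemble` and `ground_truth` (fields
#'   `true_covariance` 3N x 3N, `true_lmi_correlation` N x N,
#'   `anm` the underlying [build_anm()] model).
#' @export
sample_anm_ensemble <- function(model, n_frames, cutoff = 12, temperature_scale = 1,
                                seed = 1L, gamma_scale = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (n_frames < 2) stop("sample_anm_ensemble: n_frames must be >= 2")
  ref <- model_coords(model)
  nn <- nrow(ref)
  anm <- build_anm(ref, cutoff = cutoff, gamma = 1, gamma_scale = gamma_scale)
  lam <- anm$eigenvalues
  nzero <- sum(lam <= 1e-8 * max(lam))
  if (nzero != 6) {
    stop(sprintf("sample_anm_ensemble: network disconnected (%d near-zero modes)", nzero))
  }
  keep <- seq.int(7, length(lam))
  v <- anm$eigenvectors[, keep, drop = FALSE]
  sdv <- sqrt(temperature_scale / lam[keep])
  true_cov <- v %*% (t(v) * (temperature_scale / lam[keep]))
  true_cov <- (true_cov + t(true_cov)) / 2
  coords <- with_seed(seed, {
    z <- matrix(stats::rnorm(length(keep) * n_frames), nrow = length(keep))
    disp <- v %*% (z * sdv)                     # 3N x F
    out <- array(NA_real_, dim = c(n_frames, nn, 3))
    refv <- as.vector(t(ref))
    for (t in seq_len(n_frames)) {
      out[t, , ] <- matrix(refv + disp[, t], ncol = 3, byrow = TRUE)
    }
    out
  })
  sel <- tryCatch(select_nodes(model, protein_chains = unique(model$atoms$chain[model$atoms$name == "CA"]),
                               dna_chains = unique(model$atoms$chain[model$atoms$name == "P"])),
                  error = function(e) NULL)
  if (!is.null(sel) && nrow(sel) != nn) sel <- NULL
  ens <- ensemble(coords, sel, provenance = sprintf("anm-gaussian seed=%d", seed))
  gt <- list(true_covariance = true_cov,
             true_lmi_correlation = lmi_matrix_from_covariance(true_cov)$C,
             temperature_scale = temperature_scale,
             anm = anm)
  list(ensemble = ens, ground_truth = gt)
}

#' Designed hydrogen-bond / salt-bridge event series
#'
#' Emits per-frame donor, hydrogen and acceptor coordinates engineered so the
#' geometric criterion (donor-acceptor distance <= 3.5 A, donor angle <= 30
#' degrees) holds in exactly `round(occupancy * n_frames)` frames for the
#' `"block"` pattern, or in a Bernoulli(occupancy) draw per frame for
#' `"bernoulli"` (the realized count is reported). Bound frames place the
#' acceptor 2.8 A from the donor with a 10-degree donor angle; unbound frames
#' use 5.0 A.
#'
#' @param n_frames number of frames.
#' @param occupancy target fraction in \[0, 1\].
#' @param seed integer seed (used by `"bernoulli"`).
#' @param pattern `"block"` or `"bernoulli"`.
#' @return list: `bound` logical series, `donor`/`hydrogen`/`acceptor`
#'   F x 3 coordinate matrices, `realized_occupancy`.
#' @export
make_event_series <- function(n_frames, occupancy, seed = 1L,
                              pattern = c("block", "bernoulli")) {
  pattern <- match.arg(pattern)
  if (occupancy < 0 || occupancy > 1) stop("make_event_series: occupancy outside [0, 1]")
  bound <- switch(pattern,
    block = {
      k <- round(occupancy * n_frames)
      c(rep(TRUE, k), rep(FALSE, n_frames - k))
    },
    bernoulli = with_seed(seed, stats::runif(n_frames) < occupancy)
  )
  donor <- matrix(0, n_frames, 3)
  hydrogen <- matrix(rep(c(1, 0, 0), each = n_frames), n_frames, 3)
  d_on <- 2.8; d_off <- 5.0; ang <- 10 * pi / 180
  acceptor <- matrix(NA_real_, n_frames, 3)
  acceptor[, 1] <- ifelse(bound, d_on * cos(ang), d_off * cos(ang))
  acceptor[, 2] <- ifelse(bound, d_on * sin(ang), d_off * sin(ang))
  acceptor[, 3] <- 0
  list(bound = bound, donor = donor, hydrogen = hydrogen, acceptor = acceptor,
       realized_occupancy = mean(bound))
}

#' Two nodes with prescribed per-axis correlation
#'
#' Each axis is an independent bivariate Gaussian with correlation `rho` and
#' unit variance; node 2 carries a fixed spatial offset. With `rho = 1`
#' node 2 is an exact copy of node 1 plus the offset. Under this model the
#' LMI generalized correlation equals |rho| exactly in the infinite-sample
#' limit.
#'
#' @param n_frames number of frames.
#' @param rho per-axis correlation in \[-1, 1\].
#' @param seed integer seed.
#' @param offset fixed displacement of node 2, length-3.
#' @return an `ensemble` of 2 nodes.
#' @export
make_correlated_pair <- function(n_frames, rho, seed = 1L, offset = c(10, 0, 0)) {
  if (abs(rho) > 1) stop("make_correlated_pair: |rho| must be <= 1")
  coords <- with_seed(seed, {
    out <- array(NA_real_, dim = c(n_frames, 2, 3))
    for (ax in 1:3) {
      a <- stats::rnorm(n_frames)
      if (abs(rho) == 1) {
        b <- sign(rho) * a
      } else {
        b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n_frames)
      }
      out[, 1, ax] <- a
      out[, 2, ax] <- b + offset[ax]
    }
    out
  })
  ensemble(coords, provenance = sprintf("correlated-pair rho=%g seed=%d", rho, seed))
}

#' Write ground-truth matrices as plain-text sidecar files
#'
#' Matrices are written whitespace-delimited with a one-line header naming
#' the dimension and units, readable back with [read_matrix_txt()].
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param units units string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(mat, path, units = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %s", nrow(mat), ncol(mat), units), con)
  utils::write.table(format(mat, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  hdr <- strsplit(trimws(sub("^#", "", readLines(path, n = 1))), "\\s+")[[1]]
  mat <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(mat) <- NULL
  stopifnot(nrow(mat) == as.integer(hdr[1]), ncol(mat) == as.integer(hdr[2]))
  mat
}
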