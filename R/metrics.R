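# Structural metrics: Kabsch superposition, RMSD/RMSF series, radius of
# gyration, center-of-mass distances, hydrogen-bond and salt-bridge
# detection with occupancy reporting.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `mobile` onto `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3 non-collinear.
#' @param weights optional per-node weights.
#' @return list: `rotation` 3 x 3 (det +1), `translation` length-3, `rmsd`
#'   (Angstrom). Applying `sweep(mobile %*% R, 2, tr, "+")` with the returned
#'   `R`/`tr` yields the fitted coordinates.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  n <- nrow(mobile)
  if (n < 3) stop("superpose: need at least 3 nodes")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  # collinearity / degeneracy check on the mobile set
  sv_a <- svd(a * sqrt(w))$d
  if (sv_a[2] <= 1e-10 * max(sv_a[1], 1e-300)) {
    stop("superpose: degenerate (collinear or coincident) configuration")
  }
  h <- t(a * w) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot)                                  # so that fitted = mobile %*% rot
  fitted <- sweep(a %*% rot, 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = cr - as.vector(cm %*% rot), rmsd = rmsd)
}

# Apply a superpose() result to arbitrary coordinates.
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

.rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is rigid-fitted on `fit_selection` and the RMSD is then
#' measured over `measure_selection` (1-based node indices; both default to
#' all nodes, the single-group convention of standard RMSD tools).
#'
#' @param ens an `ensemble`.
#' @param reference N x 3 reference coordinates.
#' @param fit_selection,measure_selection integer node subsets.
#' @return numeric per-frame RMSD (Angstrom) with attributes `mean`, `sd`
#'   and a `summary` string formatted "mean (sd)".
#' @export
rmsd_series <- function(ens, reference, fit_selection = NULL,
                        measure_selection = NULL) {
  nn <- dim(ens$coords)[2]
  if (is.null(fit_selection)) fit_selection <- seq_len(nn)
  if (is.null(measure_selection)) measure_selection <- fit_selection
  stopifnot(length(fit_selection) > 0, length(measure_selection) > 0)
  reference <- as.matrix(reference)
  out <- vapply(seq_len(n_frames(ens)), function(t) {
    fc <- frame_coords(ens, t)
    ft <- superpose(fc[fit_selection, , drop = FALSE],
                    reference[fit_selection, , drop = FALSE])
    .rmsd_plain(apply_transform(fc[measure_selection, , drop = FALSE], ft),
                reference[measure_selection, , drop = FALSE])
  }, numeric(1))
  attr(out, "mean") <- mean(out)
  attr(out, "sd") <- stats::sd(out)
  attr(out, "summary") <- sprintf("%.2f (%.2f)", mean(out), stats::sd(out))
  out
}

# Iteratively superpose all frames onto their mean; returns fitted F x N x 3.
# The converged mean is rotated into its principal-axes frame (proper
# rotation, largest-|component| sign convention), so the result is invariant
# to any global rigid transform applied to every input frame.
.fit_to_mean <- function(coords, tol = 1e-6, max_iter = 20) {
  nf <- dim(coords)[1]
  fitted <- coords
  ref <- matrix(coords[1, , ], ncol = 3)
  for (iter in seq_len(max_iter)) {
    for (t in seq_len(nf)) {
      fc <- matrix(fitted[t, , ], ncol = 3)
      fitted[t, , ] <- apply_transform(fc, superpose(fc, ref))
    }
    new_mean <- apply(fitted, c(2, 3), mean)
    converged <- max(abs(new_mean - ref)) < tol
    ref <- new_mean
    if (converged) break
  }
  cen <- colMeans(ref)
  mu <- sweep(ref, 2, cen)
  q <- eigen(crossprod(mu), symmetric = TRUE)$vectors
  for (k in 1:2) {
    proj <- mu %*% q[, k]
    if (proj[which.max(abs(proj))] < 0) q[, k] <- -q[, k]
  }
  q[, 3] <- c(q[2, 1] * q[3, 2] - q[3, 1] * q[2, 2],
              q[3, 1] * q[1, 2] - q[1, 1] * q[3, 2],
              q[1, 1] * q[2, 2] - q[2, 1] * q[1, 2])
  for (t in seq_len(nf)) {
    fitted[t, , ] <- sweep(matrix(fitted[t, , ], ncol = 3), 2, cen) %*% q
  }
  attr(fitted, "mean_structure") <- mu %*% q
  fitted
}

#' Per-node root-mean-square fluctuation
#'
#' RMSF of node i is sqrt of the mean squared displacement about the node's
#' ensemble-average position, after (optionally) superposing every frame onto
#' the iteratively refined mean structure (convergence tolerance 1e-6 A).
#'
#' @param ens an `ensemble` with >= 2 frames.
#' @param fit superpose frames onto the mean first (default TRUE).
#' @return per-node RMSF values (Angstrom).
#' @export
rmsf <- function(ens, fit = TRUE) {
  stopifnot(n_frames(ens) >= 2)
  coords <- if (fit) .fit_to_mean(ens$coords) else ens$coords
  mean_xyz <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_xyz)^2
  msd <- apply(dev2[, , 1] + dev2[, , 2] + dev2[, , 3], 2, mean)
  sqrt(msd)
}

#' Radius of gyration of a single frame
#'
#' sqrt(sum m_i |r_i - r_com|^2 / sum m_i); unit masses by default.
#'
#' @param coords N x 3 matrix.
#' @param masses optional per-node masses.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  m <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  com <- colSums(coords * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
}

#' Per-frame distance between two group centroids
#'
#' Geometric (unweighted) centroids by default.
#'
#' @param ens an `ensemble`.
#' @param group_a,group_b disjoint, non-empty 1-based node index vectors.
#' @param masses optional per-node masses for mass-weighted centers.
#' @return per-frame distances (Angstrom) with `mean`, `sd`, `summary`
#'   attributes as in [rmsd_series()].
#' @export
com_distance_series <- function(ens, group_a, group_b, masses = NULL) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            !length(intersect(group_a, group_b)))
  centroid <- function(fc, idx) {
    m <- if (is.null(masses)) rep(1, length(idx)) else masses[idx]
    colSums(fc[idx, , drop = FALSE] * m) / sum(m)
  }
  out <- vapply(seq_len(n_frames(ens)), function(t) {
    fc <- frame_coords(ens, t)
    sqrt(sum((centroid(fc, group_a) - centroid(fc, group_b))^2))
  }, numeric(1))
  attr(out, "mean") <- mean(out)
  attr(out, "sd") <- stats::sd(out)
  attr(out, "summary") <- sprintf("%.2f (%.2f)", mean(out), stats::sd(out))
  out
}

# ---- Hydrogen bonds --------------------------------------------------------

#' Hydrogen-bond geometric criteria
#'
#' Donor-acceptor distance cutoff (default 3.5 A) and the angle at the donor
#' between donor->hydrogen and donor->acceptor (default 30 degrees), both
#' inclusive. When no hydrogen coordinate is available only the distance is
#' tested.
#'
#' @param max_donor_acceptor_distance Angstrom, > 0.
#' @param angle_cutoff degrees, in (0, 180).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5, angle_cutoff = 30) {
  stopifnot(max_donor_acceptor_distance > 0,
            angle_cutoff > 0, angle_cutoff < 180)
  structure(list(max_donor_acceptor_distance = max_donor_acceptor_distance,
                 angle_cutoff = angle_cutoff), class = "hbond_criteria")
}

#' Test the hydrogen-bond criterion for one geometry
#'
#' @param donor,acceptor length-3 coordinates (Angstrom).
#' @param hydrogen optional length-3 hydrogen coordinate.
#' @param criteria an [hbond_criteria()].
#' @return logical.
#' @export
detect_hbond <- function(donor, acceptor, hydrogen = NULL,
                         criteria = hbond_criteria()) {
  stopifnot(all(is.finite(donor)), all(is.finite(acceptor)))
  d <- sqrt(sum((donor - acceptor)^2))
  if (d > criteria$max_donor_acceptor_distance) return(FALSE)
  if (is.null(hydrogen)) return(TRUE)
  u <- hydrogen - donor; v <- acceptor - donor
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang <= criteria$angle_cutoff
}

#' Occupancy of an interaction over a trajectory
#'
#' Applies [detect_hbond()] per frame to per-frame donor / hydrogen /
#' acceptor coordinates (F x 3 matrices, e.g. from [make_event_series()]) and
#' reports exact integer counts.
#'
#' @param donor,acceptor F x 3 coordinate matrices.
#' @param hydrogen optional F x 3 matrix.
#' @param criteria an [hbond_criteria()].
#' @param label report label.
#' @return an `occupancy_report`: list with `label`, `n_frames`, `n_true`,
#'   `occupancy` (= n_true / n_frames exactly).
#' @export
hbond_occupancy <- function(donor, acceptor, hydrogen = NULL,
                            criteria = hbond_criteria(), label = "hbond") {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  stopifnot(nrow(donor) == nrow(acceptor))
  nf <- nrow(donor)
  hits <- vapply(seq_len(nf), function(t) {
    detect_hbond(donor[t, ], acceptor[t, ],
                 hydrogen = if (is.null(hydrogen)) NULL else hydrogen[t, ],
                 criteria = criteria)
  }, logical(1))
  occupancy_report(label, n_frames = nf, n_true = sum(hits), series = hits)
}

#' @rdname hbond_occupancy
#' @param n_frames,n_true integer counts.
#' @param series optional logical per-frame series.
#' @export
occupancy_report <- function(label, n_frames, n_true, series = NULL) {
  stopifnot(n_true >= 0, n_true <= n_frames)
  structure(list(label = label, n_frames = as.integer(n_frames),
                 n_true = as.integer(n_true),
                 occupancy = n_true / n_frames, series = series),
            class = "occupancy_report")
}

#' Render an occupancy as a percentage string
#'
#' `format_occupancy(r)` gives e.g. "73.0%"; `format_occupancy_table(r)`
#' gives the "label (percent)" convention used in interaction tables, e.g.
#' "meR83-E86 (73.04)".
#'
#' @param report an `occupancy_report`.
#' @param digits decimal places.
#' @return character scalar.
#' @export
format_occupancy <- function(report, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), 100 * report$occupancy)
}

#' @rdname format_occupancy
#' @export
format_occupancy_table <- function(report, digits = 2) {
  sprintf(paste0("%s (%.", digits, "f)"), report$label, 100 * report$occupancy)
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d frames = %s\n", x$label, x$n_true, x$n_frames,
              format_occupancy(x)))
  invisible(x)
}

# ---- Salt bridges ----------------------------------------------------------

#' Salt-bridge criteria
#'
#' A basic/acidic side-chain pair is bridged in a frame when the minimum
#' distance over the listed N x O atom pairs is <= `max_ON_distance`
#' (inclusive; default 4.0 A, the conventional definition).
#'
#' @param max_ON_distance Angstrom, > 0.
#' @param basic_atoms,acidic_atoms named lists: residue name -> atom names.
#' @return list of class `salt_bridge_criteria`.
#' @export
salt_bridge_criteria <- function(max_ON_distance = 4.0,
                                 basic_atoms = list(ARG = c("NH1", "NH2", "NE"),
                                                    LYS = "NZ"),
                                 acidic_atoms = list(GLU = c("OE1", "OE2"),
                                                     ASP = c("OD1", "OD2"))) {
  stopifnot(max_ON_distance > 0)
  structure(list(max_ON_distance = max_ON_distance,
                 basic_atoms = basic_atoms, acidic_atoms = acidic_atoms),
            class = "salt_bridge_criteria")
}

# Side-chain atom coordinates of a residue role ("basic"/"acidic"), or NULL.
.sb_atoms <- function(model, chain, resid, role, criteria) {
  at <- model$atoms
  sub <- at[at$chain == chain & at$resid == resid, ]
  if (!nrow(sub)) return(NULL)
  table <- if (role == "basic") criteria$basic_atoms else criteria$acidic_atoms
  wanted <- table[[sub$resname[1]]]
  if (is.null(wanted)) return(NULL)
  sub <- sub[sub$name %in% wanted, ]
  if (!nrow(sub)) return(NULL)
  as.matrix(sub[, c("x", "y", "z")])
}

#' Detect salt bridges in one frame
#'
#' Scans all basic x acidic residue pairs recognized by the criteria and
#' returns those whose minimum N-O distance is within the cutoff.
#'
#' @param model frame-level [structure_model()] with side-chain atoms.
#' @param criteria a [salt_bridge_criteria()].
#' @return data frame: `basic_chain`, `basic_resid`, `acidic_chain`,
#'   `acidic_resid`, `min_ON` (Angstrom), bridged pairs only.
#' @export
detect_salt_bridges <- function(model, criteria = salt_bridge_criteria()) {
  at <- model$atoms
  res <- unique(at[, c("chain", "resid", "resname")])
  basic <- res[res$resname %in% names(criteria$basic_atoms), ]
  acidic <- res[res$resname %in% names(criteria$acidic_atoms), ]
  out <- list()
  for (i in seq_len(nrow(basic))) {
    bcoords <- .sb_atoms(model, basic$chain[i], basic$resid[i], "basic", criteria)
    if (is.null(bcoords)) {
      warning(sprintf("detect_salt_bridges: %s %s%d lacks listed side-chain atoms; skipped",
                      basic$resname[i], basic$chain[i], basic$resid[i]), call. = FALSE)
      next
    }
    for (j in seq_len(nrow(acidic))) {
      acoords <- .sb_atoms(model, acidic$chain[j], acidic$resid[j], "acidic", criteria)
      if (is.null(acoords)) next
      d2 <- outer(rowSums(bcoords^2), rowSums(acoords^2), "+") -
        2 * bcoords %*% t(acoords)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= criteria$max_ON_distance) {
        out[[length(out) + 1L]] <- data.frame(
          basic_chain = basic$chain[i], basic_resid = basic$resid[i],
          acidic_chain = acidic$chain[j], acidic_resid = acidic$resid[j],
          min_ON = dmin)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(basic_chain = character(0), basic_resid = integer(0),
               acidic_chain = character(0), acidic_resid = integer(0),
               min_ON = numeric(0))
}

#' Salt-bridge occupancy over a list of frame models
#'
#' @param models list of frame-level `structure_model`s.
#' @param basic,acidic `(chain, resid)` pairs, e.g. `list("A", 83)`.
#' @param criteria a [salt_bridge_criteria()].
#' @param label report label (e.g. "meR83-E86").
#' @return an `occupancy_report`.
#' @export
salt_bridge_occupancy <- function(models, basic, acidic,
                                  criteria = salt_bridge_criteria(),
                                  label = NULL) {
  hits <- vapply(models, function(m) {
    b <- .sb_atoms(m, basic[[1]], basic[[2]], "basic", criteria)
    a <- .sb_atoms(m, acidic[[1]], acidic[[2]], "acidic", criteria)
    if (is.null(b) || is.null(a)) stop("salt_bridge_occupancy: pair atoms missing in a frame")
    d2 <- outer(rowSums(b^2), rowSums(a^2), "+") - 2 * b %*% t(a)
    sqrt(max(0, min(d2))) <= criteria$max_ON_distance
  }, logical(1))
  if (is.null(label)) label <- sprintf("%s%d-%s%d", basic[[1]], basic[[2]],
                                       acidic[[1]], acidic[[2]])
  occupancy_report(label, n_frames = length(models), n_true = sum(hits),
                   series = hits)
}
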