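# Correlation-weighted dynamical network: contact-filtered graph with edge
# weight -ln C_ij, weighted betweenness centrality (Brandes, via igraph),
# and delta-BC comparison against a reference state.

#' Build the dynamical network graph
#'
#' Nodes are the analysis nodes (protein C-alpha, DNA P); an edge (i, j)
#' exists iff the pair is in contact — node-node distance within
#' `contact_cutoff` in at least `contact_fraction` of frames (or in the mean
#' structure when no ensemble is given). Sequence adjacency alone never
#' creates an edge. Edge weight is -ln(C_ij) with C clipped to
#' \[1e-6, 1 - 1e-6\], so highly correlated pairs are dynamically "close".
#'
#' @param lmi_cor an [lmi_matrix()] result.
#' @param mean_structure N x 3 mean coordinates.
#' @param contact_cutoff Angstrom (default 10).
#' @param contact_fraction minimum fraction of frames in contact (default 0.75).
#' @param ens optional `ensemble` for per-frame contact evaluation.
#' @return list of class `dynamics_graph`: `graph` (igraph, undirected,
#'   weighted), `edges` data frame (i, j, C, weight; 1-based), `n_nodes`,
#'   and the contact rule metadata.
#' @export
build_graph <- function(lmi_cor, mean_structure, contact_cutoff = 10,
                        contact_fraction = 0.75, ens = NULL) {
  stopifnot(inherits(lmi_cor, "lmi_correlation"))
  nn <- nrow(lmi_cor$C)
  if (is.null(ens)) {
    dmat <- as.matrix(stats::dist(mean_structure))
    contact <- dmat <= contact_cutoff
  } else {
    nf <- n_frames(ens)
    hits <- matrix(0L, nn, nn)
    for (t in seq_len(nf)) {
      dmat <- as.matrix(stats::dist(frame_coords(ens, t)))
      hits <- hits + (dmat <= contact_cutoff)
    }
    contact <- hits >= contact_fraction * nf
  }
  diag(contact) <- FALSE
  cclip <- pmin(pmax(lmi_cor$C, 1e-6), 1 - 1e-6)
  idx <- which(contact & upper.tri(contact), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      C = cclip[idx],
                      weight = -log(cclip[idx]))
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nn)))
  igraph::E(g)$weight <- edges$weight
  if (igraph::components(g)$no > 1) {
    warning("build_graph: graph is disconnected; betweenness computed per component")
  }
  structure(list(graph = g, edges = edges, n_nodes = nn,
                 contact_cutoff = contact_cutoff,
                 contact_fraction = contact_fraction),
            class = "dynamics_graph")
}

#' Betweenness centrality profile
#'
#' BC_i = sum over node pairs (a, b), a,b != i, of n_ab(i) / g_ab: the
#' fraction of minimal-weight paths between a and b passing through i
#' (Brandes' algorithm on the weighted graph; equal-weight parallel shortest
#' paths split counts fractionally). Normalization divides by
#' (N-1)(N-2)/2, the number of pairs excluding i.
#'
#' @param graph a [build_graph()] result (or a bare igraph with `weight`).
#' @return data frame of class `centrality_profile`: `node` (0-based),
#'   `bc_raw`, `bc_normalized`.
#' @export
betweenness_profile <- function(graph) {
  g <- if (inherits(graph, "dynamics_graph")) graph$graph else graph
  raw <- igraph::betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$weight)
  nn <- igraph::vcount(g)
  norm <- if (nn > 2) raw / ((nn - 1) * (nn - 2) / 2) else raw * 0
  out <- data.frame(node = seq_len(nn) - 1L, bc_raw = as.numeric(raw),
                    bc_normalized = as.numeric(norm))
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Per-node change in normalized betweenness versus a reference
#'
#' delta = BC_state - BC_reference (normalized); nodes with |delta| above
#' the threshold (default 0.1, the conventional significance band) are
#' flagged.
#'
#' @param state,reference `centrality_profile`s over the same nodes.
#' @param threshold flag threshold on |delta| (exclusive).
#' @param selection optional `node_selection` for resid reporting.
#' @param annotation optional [domain_annotation()] for domain labels.
#' @return data frame: `node`, `delta_bc`, `flagged`, plus `chain`, `resid`,
#'   `domain` when selection/annotation are given.
#' @export
delta_bc <- function(state, reference, threshold = 0.1, selection = NULL,
                     annotation = NULL) {
  if (nrow(state) != nrow(reference)) stop("delta_bc: profile size mismatch")
  out <- data.frame(node = state$node,
                    delta_bc = state$bc_normalized - reference$bc_normalized)
  out$flagged <- abs(out$delta_bc) > threshold
  if (!is.null(selection)) {
    out$chain <- selection$chain
    out$resid <- selection$resid
    if (!is.null(annotation)) out$domain <- domain_of(out$resid, annotation)
  }
  out
}
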