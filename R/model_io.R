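# Structure and ensemble I/O: fixed-column PDB (ATOM/HETATM, MODEL/ENDMDL),
# node selection (protein CA / DNA P), domain annotations.

#' Construct a structure model
#'
#' A `structure_model` is a light container for node-level (or atomic)
#' coordinates: a data frame of atoms plus a title. It is the unit that
#' [read_structure()] returns and that all frame-level operations accept.
#'
#' @param atoms data frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z`, `element`.
#' @param title character scalar.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  required <- c("serial", "name", "resname", "resid", "chain", "x", "y", "z", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("structure_model: missing atom columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, required]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("structure_model: non-finite coordinates")
  }
  if (any(atoms$resid < 1)) stop("structure_model: resid must be >= 1")
  if (any(!nzchar(atoms$name))) stop("structure_model: empty atom name")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    stop("structure_model: duplicate (chain, resid, name): ", key[duplicated(key)][1])
  }
  structure(list(atoms = atoms, title = as.character(title)[1]),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chains%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" | ", x$title) else ""))
  invisible(x)
}

#' Coordinates of a structure model as an N x 3 matrix
#' @param model a `structure_model`.
#' @return numeric matrix with one row per atom, columns x, y, z (Angstrom).
#' @export
model_coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# ---- PDB parsing -----------------------------------------------------------

# Split raw PDB lines into per-model blocks of ATOM/HETATM record lines.
# Files without MODEL records are a single block.
.pdb_model_blocks <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM" |
    substr(lines, 1, 6) == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_model)) {
    return(list(lines[is_atom]))
  }
  blocks <- list()
  current <- NULL
  inside <- FALSE
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      inside <- TRUE
      current <- character(0)
    } else if (is_end[i]) {
      if (inside) blocks[[length(blocks) + 1L]] <- current
      inside <- FALSE
      current <- NULL
    } else if (inside && is_atom[i]) {
      current <- c(current, lines[i])
    }
  }
  if (inside && length(current)) blocks[[length(blocks) + 1L]] <- current
  blocks
}

# Parse ATOM/HETATM lines (PDB v3 fixed columns) into the atoms data frame.
# altloc: only '' , 'A' or '1' kept (take-first rule).
.parse_atom_lines <- function(lines, source = "<pdb>") {
  if (!length(lines)) {
    return(data.frame(serial = integer(0), name = character(0),
                      resname = character(0), resid = integer(0),
                      chain = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), element = character(0)))
  }
  field <- function(a, b) trimws(substr(lines, a, b))
  altloc <- field(17, 17)
  keep <- altloc %in% c("", "A", "1")
  lines <- lines[keep]
  field <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(field(a, b)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed %s field in %s at ATOM line %d: '%s'",
                   what, source, bad, lines[bad]), call. = FALSE)
    }
    v
  }
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = field(13, 16),
    resname = field(18, 20),
    resid = as.integer(num(23, 26, "resid")),
    chain = field(22, 22),
    x = num(31, 38, "x-coordinate"),
    y = num(39, 46, "y-coordinate"),
    z = num(47, 54, "z-coordinate"),
    element = field(77, 78),
    stringsAsFactors = FALSE
  )
}

#' Read one model from a PDB file
#'
#' Parses ATOM/HETATM records of the requested MODEL block (0-based index;
#' single-model files have index 0). Coordinates are taken from the fixed
#' PDB columns, in Angstrom. Alternate locations beyond the first are dropped.
#'
#' @param path path to a PDB-format text file.
#' @param model_index 0-based model index over MODEL records.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, model_index = 0L) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- .pdb_model_blocks(lines)
  if (model_index < 0 || model_index >= length(blocks)) {
    stop(sprintf("read_structure: model_index %d out of range (file has %d model(s))",
                 model_index, length(blocks)))
  }
  atoms <- .parse_atom_lines(blocks[[model_index + 1L]], source = path)
  title_line <- lines[startsWith(lines, "TITLE")]
  title <- if (length(title_line)) trimws(substr(title_line[1], 11, 80)) else ""
  structure_model(atoms, title = title)
}

.format_atom_line <- function(a) {
  # PDB name column convention: names of <4 chars start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4), sprintf(" %-3s", a$name))
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, nm, "", a$resname, a$chain, a$resid, "",
          a$x, a$y, a$z, 1, 0, a$element)
}

#' Write a structure model as a single-model PDB file
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- c(
    if (nzchar(model$title)) sprintf("TITLE     %s", model$title),
    .format_atom_line(model$atoms),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- Node selection --------------------------------------------------------

#' Select analysis nodes: protein C-alpha and DNA phosphorus atoms
#'
#' One node per protein residue that has a `CA` atom and one per nucleotide
#' that has a `P` atom (5'-terminal nucleotides without a phosphate are
#' skipped with a warning, as are residues lacking the node atom). Node order
#' is protein nodes by (chain, resid), then DNA nodes by (chain, resid);
#' node indices are 0-based.
#'
#' @param model a `structure_model`.
#' @param protein_chains character vector of protein chain ids.
#' @param dna_chains character vector of DNA chain ids (may be empty).
#' @return a `node_selection`: data frame (`node`, `chain`, `resid`,
#'   `kind`) with attributes `n_protein`, `n_dna`.
#' @export
select_nodes <- function(model, protein_chains, dna_chains = character(0)) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  have <- unique(at$chain)
  absent <- setdiff(c(protein_chains, dna_chains), have)
  if (length(absent)) {
    stop("select_nodes: chain(s) not in model: ", paste(absent, collapse = ", "))
  }
  pick <- function(chains, atom_name, kind) {
    rows <- list()
    for (ch in sort(chains)) {
      sub <- at[at$chain == ch, ]
      resids <- sort(unique(sub$resid))
      has_node <- resids %in% sub$resid[sub$name == atom_name]
      if (any(!has_node)) {
        warning(sprintf("select_nodes: chain %s residue(s) %s lack a %s atom; skipped",
                        ch, paste(resids[!has_node], collapse = ","), atom_name),
                call. = FALSE)
      }
      resids <- resids[has_node]
      if (length(resids)) {
        rows[[length(rows) + 1L]] <-
          data.frame(chain = ch, resid = resids, kind = kind,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(chain = character(0), resid = integer(0), kind = character(0))
  }
  sel <- rbind(pick(protein_chains, "CA", "CA"), pick(dna_chains, "P", "P"))
  sel <- data.frame(node = seq_len(nrow(sel)) - 1L, sel, stringsAsFactors = FALSE)
  attr(sel, "n_protein") <- sum(sel$kind == "CA")
  attr(sel, "n_dna") <- sum(sel$kind == "P")
  class(sel) <- c("node_selection", "data.frame")
  sel
}

#' Number of nodes in a selection
#' @param selection a `node_selection`.
#' @return integer node count.
#' @export
n_nodes <- function(selection) nrow(selection)

# Row indices into model$atoms matching a selection, erroring on absences.
.selection_atom_rows <- function(model, selection, frame = NA) {
  at <- model$atoms
  key <- paste(at$chain, at$resid, at$name)
  want <- paste(selection$chain, selection$resid, selection$kind)
  idx <- match(want, key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("node %d (%s chain %s resid %d) missing%s",
                 selection$node[miss], selection$kind[miss],
                 selection$chain[miss], selection$resid[miss],
                 if (is.na(frame)) "" else sprintf(" in frame %d", frame)),
         call. = FALSE)
  }
  idx
}

# ---- Ensembles -------------------------------------------------------------

#' Construct a coordinate ensemble
#'
#' An `ensemble` holds an F x N x 3 coordinate array (Angstrom) of the
#' selected nodes over frames, plus the selection and provenance metadata.
#'
#' @param coords numeric array, frames x nodes x 3.
#' @param selection a `node_selection` (or NULL for anonymous nodes).
#' @param frame_spacing informational time per frame.
#' @param provenance free-text origin string.
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(coords, selection = NULL, frame_spacing = NA_real_,
                     provenance = "") {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("ensemble: non-finite coordinates")
  if (!is.null(selection) && nrow(selection) != dim(coords)[2]) {
    stop("ensemble: selection size does not match coordinate array")
  }
  structure(list(coords = coords, selection = selection,
                 frame_spacing = frame_spacing, provenance = provenance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<ensemble> %d frames x %d nodes%s\n", d[1], d[2],
              if (nzchar(x$provenance)) paste0(" | ", x$provenance) else ""))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Extract one frame as an N x 3 matrix
#' @param ens an `ensemble`.
#' @param t frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(ens, t) {
  matrix(ens$coords[t, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a multi-model PDB as a coordinate ensemble
#'
#' Every MODEL must contain all selected nodes; frames follow MODEL order.
#'
#' @param path multi-model PDB file.
#' @param selection `node_selection` built on the reference structure.
#' @return an `ensemble` of dimension frames x nodes x 3.
#' @export
read_ensemble <- function(path, selection) {
  if (!file.exists(path)) stop("read_ensemble: file not found: ", path)
  blocks <- .pdb_model_blocks(readLines(path, warn = FALSE))
  blocks <- Filter(length, blocks)
  if (!length(blocks)) stop("read_ensemble: no frames in ", path)
  nf <- length(blocks)
  nn <- nrow(selection)
  coords <- array(NA_real_, dim = c(nf, nn, 3))
  for (t in seq_len(nf)) {
    atoms <- .parse_atom_lines(blocks[[t]], source = path)
    m <- structure_model(atoms)
    idx <- .selection_atom_rows(m, selection, frame = t)
    coords[t, , ] <- as.matrix(m$atoms[idx, c("x", "y", "z")])
  }
  ensemble(coords, selection, provenance = path)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ens an `ensemble` with a non-NULL selection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"), !is.null(ens$selection))
  sel <- ens$selection
  resname <- ifelse(sel$kind == "CA", "ALA", "DA")
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(ens))) {
    fc <- frame_coords(ens, t)
    at <- data.frame(serial = seq_len(nrow(sel)), name = sel$kind,
                     resname = resname, resid = sel$resid, chain = sel$chain,
                     x = fc[, 1], y = fc[, 2], z = fc[, 3],
                     element = ifelse(sel$kind == "CA", "C", "P"))
    writeLines(c(sprintf("MODEL     %4d", t), .format_atom_line(at), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read/write a plain-text frame table (frame, node, x, y, z)
#'
#' Whitespace-delimited alternative trajectory container; nodes are 0-based
#' selection indices.
#'
#' @param path file path.
#' @param selection optional `node_selection` to attach.
#' @return an `ensemble`.
#' @export
read_frame_table <- function(path, selection = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("frame", "node", "x", "y", "z") %in% names(tab)))
  frames <- sort(unique(tab$frame))
  nodes <- sort(unique(tab$node))
  nf <- length(frames); nn <- length(nodes)
  if (nrow(tab) != nf * nn) stop("read_frame_table: ragged table")
  coords <- array(NA_real_, dim = c(nf, nn, 3))
  fi <- match(tab$frame, frames); ni <- match(tab$node, nodes)
  for (k in seq_len(nrow(tab))) {
    coords[fi[k], ni[k], ] <- c(tab$x[k], tab$y[k], tab$z[k])
  }
  ensemble(coords, selection, provenance = path)
}

#' @rdname read_frame_table
#' @param ens an `ensemble` to write.
#' @export
write_frame_table <- function(ens, path) {
  d <- dim(ens$coords)
  tab <- data.frame(
    frame = rep(seq_len(d[1]), each = d[2]),
    node = rep(seq_len(d[2]) - 1L, times = d[1]),
    x = as.vector(t(ens$coords[, , 1])),
    y = as.vector(t(ens$coords[, , 2])),
    z = as.vector(t(ens$coords[, , 3]))
  )
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Domain annotation -----------------------------------------------------

#' Domain annotation as labeled inclusive residue ranges
#'
#' @param labels character vector of domain labels.
#' @param starts,ends integer vectors of inclusive residue ranges.
#' @return data frame of class `domain_annotation`.
#' @export
domain_annotation <- function(labels, starts, ends) {
  stopifnot(length(labels) == length(starts), length(starts) == length(ends),
            all(starts <= ends))
  ann <- data.frame(label = labels, start = as.integer(starts),
                    end = as.integer(ends), stringsAsFactors = FALSE)
  covered <- unlist(Map(seq, ann$start, ann$end))
  if (anyDuplicated(covered)) stop("domain_annotation: overlapping ranges")
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Default pol beta domain layout
#'
#' Lyase 10-87, DNA-binding (D, thumb) 90-150, catalytic (C, palm) 151-260,
#' nascent-base-pairing (N, fingers) 261-335.
#' @return a `domain_annotation`.
#' @export
polb_domains <- function() {
  domain_annotation(c("Lyase", "D", "C", "N"),
                    c(10, 90, 151, 261), c(87, 150, 260, 335))
}

#' Map residue ids to domain labels
#' @param resid integer vector of residue ids.
#' @param annotation a `domain_annotation`.
#' @return character vector (NA where unannotated).
#' @export
domain_of <- function(resid, annotation) {
  out <- rep(NA_character_, length(resid))
  for (k in seq_len(nrow(annotation))) {
    hit <- resid >= annotation$start[k] & resid <= annotation$end[k]
    out[hit] <- annotation$label[k]
  }
  out
}
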