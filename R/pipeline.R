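# Config-driven orchestration: validate a YAML/list config, run the enabled
# stages per state in dependency order, write per-state tables plus
# state-minus-reference difference reports, and record a run manifest.

.default_stage_params <- function() {
  list(
    hbond = list(distance = 3.5, angle = 30),
    salt_bridge = list(distance = 4.0),
    fel = list(n_bins = 32L, temperature_kT = 1),
    pca = list(n_keep = 20L, cosine_threshold = 0.1),
    anm = list(cutoff = 12, n_modes = 20L, n_representatives = 100L),
    network = list(contact_cutoff = 10, contact_fraction = 0.75,
                   bc_threshold = 0.1)
  )
}

#' Validate a pipeline configuration
#'
#' A config (YAML file or list) names a reference structure, one coordinate
#' ensemble per labeled state, the designated reference state, node-selection
#' chains, optional domain annotation, stage toggles and stage parameters,
#' an output directory and a seed. Missing parameters take package defaults.
#'
#' @param config list or path to a YAML file.
#' @return the normalized config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  req <- c("reference_structure", "states", "reference_state", "output_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("pipeline_config: missing field(s): ",
                         paste(miss, collapse = ", "))
  if (!file.exists(config$reference_structure)) {
    stop("pipeline_config: reference structure not found: ",
         config$reference_structure)
  }
  for (s in names(config$states)) {
    if (!file.exists(config$states[[s]])) {
      stop(sprintf("pipeline_config: ensemble for state '%s' not found: %s",
                   s, config$states[[s]]))
    }
  }
  if (!config$reference_state %in% names(config$states)) {
    stop("pipeline_config: reference_state must be one of the states")
  }
  config$protein_chains <- config$protein_chains %||% "A"
  config$dna_chains <- config$dna_chains %||% character(0)
  config$seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("metrics", "pca", "lmi", "network", "prs")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) stop("pipeline_config: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  defaults <- .default_stage_params()
  config$params <- utils::modifyList(defaults, config$params %||% list())
  if (!is.null(config$domains)) {
    config$domains <- domain_annotation(
      vapply(config$domains, `[[`, "", "label"),
      vapply(config$domains, function(d) as.integer(d$start), 1L),
      vapply(config$domains, function(d) as.integer(d$end), 1L))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (io, metrics, pca/fel,
#' lmi, network, prs) for every state, writes per-state CSV tables and
#' plain-text matrices under the output directory, then the
#' state-minus-reference difference reports (delta RMSF, delta correlation
#' map, delta BC, PRS profile comparison), and finally a JSON run manifest
#' with md5 checksums of every output. The `network` stage implies `lmi`
#' (recorded in the manifest).
#'
#' @param config a [pipeline_config()] (or list / YAML path).
#' @return the manifest list, invisibly; side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, msg)
  }
  stages <- cfg$stages
  implied <- character(0)
  if ("network" %in% stages && !"lmi" %in% stages) {
    stages <- c(stages, "lmi")
    implied <- "lmi"
    note("stage 'lmi' implied by 'network'")
  }
  ref_model <- read_structure(cfg$reference_structure)
  sel <- select_nodes(ref_model, cfg$protein_chains, cfg$dna_chains)
  note("selected %d nodes (%d CA + %d P)", nrow(sel),
       attr(sel, "n_protein"), attr(sel, "n_dna"))
  ref_coords <- model_coords(ref_model)[.selection_atom_rows(ref_model, sel), , drop = FALSE]
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  per_state <- list()
  for (st in names(cfg$states)) {
    note("state '%s': reading ensemble", st)
    ens <- read_ensemble(cfg$states[[st]], sel)
    res <- list(ens = ens)
    sdir <- file.path(cfg$output_dir, st)
    dir.create(sdir, showWarnings = FALSE)

    if ("metrics" %in% stages) {
      rs <- rmsd_series(ens, ref_coords)
      rf <- rmsf(ens)
      rg <- vapply(seq_len(n_frames(ens)), function(t)
        radius_of_gyration(frame_coords(ens, t)), numeric(1))
      emit(.write_csv(data.frame(frame = seq_along(rs), rmsd = as.numeric(rs)),
                      file.path(sdir, "rmsd.csv")))
      rf_df <- data.frame(node = sel$node, chain = sel$chain,
                          resid = sel$resid, rmsf = rf)
      if (!is.null(cfg$domains)) rf_df$domain <- domain_of(rf_df$resid, cfg$domains)
      emit(.write_csv(rf_df, file.path(sdir, "rmsf.csv")))
      emit(.write_csv(data.frame(frame = seq_along(rg), rg = rg),
                      file.path(sdir, "rg.csv")))
      prot <- which(sel$kind == "CA"); dna <- which(sel$kind == "P")
      if (length(prot) && length(dna)) {
        cd <- com_distance_series(ens, prot, dna)
        emit(.write_csv(data.frame(frame = seq_along(cd), com_distance = as.numeric(cd)),
                        file.path(sdir, "com_distance.csv")))
      }
      res$rmsf <- rf
      smry <- data.frame(
        metric = c("rmsd", "rg"),
        mean_sd = c(attr(rs, "summary"),
                    sprintf("%.2f (%.2f)", mean(rg), stats::sd(rg))))
      emit(.write_csv(smry, file.path(sdir, "summary.csv")))
      note("state '%s': metrics done (RMSD %s A)", st, attr(rs, "summary"))
    }

    if (any(c("pca", "lmi", "network") %in% stages)) {
      res$cov <- covariance(ens)
    }
    if ("pca" %in% stages) {
      p <- pca(res$cov, ens, n_keep = cfg$params$pca$n_keep)
      emit(.write_csv(scree_table(p), file.path(sdir, "scree.csv")))
      pcs <- tryCatch(select_pcs(p, cfg$params$pca$cosine_threshold),
                      error = function(e) { note("state '%s': %s", st, conditionMessage(e)); NULL })
      if (!is.null(pcs)) {
        fel <- free_energy_landscape(p$projections[, pcs[1]],
                                     p$projections[, pcs[2]],
                                     n_bins = cfg$params$fel$n_bins,
                                     temperature_kT = cfg$params$fel$temperature_kT)
        emit(write_matrix_txt(fel$free_energy,
                              file.path(sdir, "fel.txt"), units = "kT"))
        emit(.write_csv(data.frame(frame = seq_len(nrow(p$projections)),
                                   pc_a = p$projections[, pcs[1]],
                                   pc_b = p$projections[, pcs[2]]),
                        file.path(sdir, "projections.csv")))
        note("state '%s': FEL over PCs %d/%d", st, pcs[1], pcs[2])
      }
      res$pca <- p
    }
    if ("lmi" %in% stages) {
      res$lmi <- lmi_matrix(ens, cov = res$cov)
      emit(write_matrix_txt(res$lmi$C, file.path(sdir, "lmi_correlation.txt"),
                            units = "correlation"))
      note("state '%s': LMI matrix done", st)
    }
    if ("network" %in% stages) {
      g <- build_graph(res$lmi, res$cov$mean_structure,
                       contact_cutoff = cfg$params$network$contact_cutoff,
                       contact_fraction = cfg$params$network$contact_fraction,
                       ens = ens)
      res$bc <- betweenness_profile(g)
      emit(.write_csv(g$edges, file.path(sdir, "edges.csv")))
      bc_df <- cbind(res$bc, chain = sel$chain, resid = sel$resid)
      if (!is.null(cfg$domains)) bc_df$domain <- domain_of(bc_df$resid, cfg$domains)
      emit(.write_csv(bc_df, file.path(sdir, "betweenness.csv")))
      note("state '%s': network done (%d edges)", st, nrow(g$edges))
    }
    if ("prs" %in% stages) {
      pm <- averaged_prs(ens,
                         n_representatives = cfg$params$anm$n_representatives,
                         cutoff = cfg$params$anm$cutoff,
                         n_modes = cfg$params$anm$n_modes)
      emit(write_matrix_txt(pm$normalized, file.path(sdir, "prs_map.txt"),
                            units = "normalized-response"))
      prof <- data.frame(node = sel$node, chain = sel$chain, resid = sel$resid,
                         effector = pm$effector_profile,
                         sensor = pm$sensor_profile)
      if (!is.null(cfg$domains)) prof$domain <- domain_of(prof$resid, cfg$domains)
      emit(.write_csv(prof, file.path(sdir, "prs_profiles.csv")))
      res$prs <- pm
      note("state '%s': PRS done (%d representative frames)", st, pm$n_frames_used)
    }
    per_state[[st]] <- res
  }

  # state-minus-reference difference reports
  refst <- cfg$reference_state
  for (st in setdiff(names(cfg$states), refst)) {
    ddir <- file.path(cfg$output_dir, paste0(st, "_vs_", refst))
    dir.create(ddir, showWarnings = FALSE)
    a <- per_state[[st]]; b <- per_state[[refst]]
    if (!is.null(a$rmsf)) {
      emit(.write_csv(data.frame(node = sel$node, resid = sel$resid,
                                 delta_rmsf = a$rmsf - b$rmsf),
                      file.path(ddir, "delta_rmsf.csv")))
    }
    if (!is.null(a$lmi)) {
      dm <- difference_map(a$lmi, b$lmi, st, refst)
      emit(write_matrix_txt(dm$delta_C, file.path(ddir, "delta_lmi.txt"),
                            units = "delta-correlation"))
    }
    if (!is.null(a$bc)) {
      db <- delta_bc(a$bc, b$bc, threshold = cfg$params$network$bc_threshold,
                     selection = sel, annotation = cfg$domains)
      emit(.write_csv(db, file.path(ddir, "delta_bc.csv")))
      note("'%s' vs '%s': %d node(s) beyond the BC threshold", st, refst,
           sum(db$flagged))
    }
    if (!is.null(a$prs)) {
      emit(.write_csv(data.frame(node = sel$node, resid = sel$resid,
                                 delta_effector = a$prs$effector_profile - b$prs$effector_profile,
                                 delta_sensor = a$prs$sensor_profile - b$prs$sensor_profile),
                      file.path(ddir, "delta_prs_profiles.csv")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("allodyn")),
    seed = cfg$seed,
    stages = stages,
    implied_stages = implied,
    states = names(cfg$states),
    reference_state = refst,
    outputs = as.list(tools::md5sum(sort(unique(outputs)))),
    warnings = log_lines
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Generate a paired reference/perturbed demo fixture set
#'
#' Builds a toy protein-DNA complex, samples a "reference" ensemble from its
#' ANM Gaussian and a "perturbed" ensemble from the same network with springs
#' touching two designated nodes stiffened (emulating a local chemical
#' modification), writes both as multi-model PDB with ground-truth covariance
#' sidecars, and emits a ready-to-run pipeline config.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param n_protein,n_dna toy complex size.
#' @param n_frames frames per state.
#' @param perturbed_nodes nodes (1-based) whose springs are stiffened.
#' @param stiffening multiplier applied to springs touching those nodes.
#' @return list: `config_path`, `ground_truth` (per state), `spec`.
#' @export
make_demo <- function(seed = 42L, out_dir, n_protein = 60L, n_dna = 8L,
                      n_frames = 400L, perturbed_nodes = c(15L, 40L),
                      stiffening = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- toy_complex_spec(n_protein, n_dna, seed = seed)
  model <- build_toy_complex(spec)
  write_structure(model, file.path(out_dir, "reference_structure.pdb"))
  nn <- nrow(model$atoms)
  gs <- matrix(1, nn, nn)
  gs[perturbed_nodes, ] <- stiffening
  gs[, perturbed_nodes] <- stiffening
  gt <- list()
  for (st in c("reference", "perturbed")) {
    sim <- sample_anm_ensemble(
      model, n_frames = n_frames, cutoff = 12, temperature_scale = 1,
      seed = seed + (st == "perturbed"),
      gamma_scale = if (st == "perturbed") gs else NULL)
    write_ensemble(sim$ensemble, file.path(out_dir, paste0(st, ".pdb")))
    write_matrix_txt(sim$ground_truth$true_covariance,
                     file.path(out_dir, paste0(st, "_true_covariance.txt")),
                     units = "A^2")
    write_matrix_txt(sim$ground_truth$true_lmi_correlation,
                     file.path(out_dir, paste0(st, "_true_lmi.txt")),
                     units = "correlation")
    gt[[st]] <- sim$ground_truth
  }
  cfg <- list(
    reference_structure = file.path(out_dir, "reference_structure.pdb"),
    states = list(reference = file.path(out_dir, "reference.pdb"),
                  perturbed = file.path(out_dir, "perturbed.pdb")),
    reference_state = "reference",
    protein_chains = "A", dna_chains = "B",
    stages = c("metrics", "pca", "lmi", "network", "prs"),
    output_dir = file.path(out_dir, "results"),
    seed = seed
  )
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  list(config_path = config_path, ground_truth = gt, spec = spec)
}
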