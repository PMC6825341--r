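#' End-to-end pipeline orchestration
#'
#' Runs the stages alignment-statistics -> consensus contacts -> folding ->
#' clustering -> confidence scoring, communicating between stages only
#' through files in standard formats (aligned FASTA, RR contact lists,
#' multi-model PDB, TSV, JSON), so any stage can be re-run in isolation.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' Thresholds mirror the pipeline defaults: Nf cutoff 64 for modelability,
#' Nff cutoff 0.5 for the metagenome-driven label, 0.8 identity inside Nf,
#' Nf switch 50 for the consensus scheme branch.
#'
#' @param seed mandatory seed for the folding stage.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(seed = NULL) {
  structure(list(
    msa = NULL, base_msa = NULL, msa_format = "fasta",
    contacts = list(),            # list of list(path, category)
    sequence = NULL,
    nf = NULL,
    out_dir = ".",
    nf_cutoff = 64, nff_cutoff = 0.5, identity_threshold = 0.8,
    nf_switch = 50,
    max_gap_fraction = 0.75, max_identity = 0.90, min_coverage = 0.75,
    fragments = NULL,             # FragmentLibrary (in-memory) or NULL
    simulation = simulation_config(seed = seed),
    cluster_cutoff = "auto",
    seed = seed
  ), class = "RunConfig")
}

#' Read a JSON run configuration
#'
#' Scalar fields override [default_run_config()]; the `simulation` block is
#' passed to [simulation_config()].
#'
#' @param path JSON file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    cf_abort("cf_unreadable_error", "cannot read config '%s'", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config(seed = raw$seed %||% NULL)
  sim_args <- raw$simulation
  raw$simulation <- NULL
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (!is.null(sim_args)) {
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$weights)) sim_args$weights <- as.list(sim_args$weights)
    cfg$simulation <- do.call(simulation_config, sim_args)
  } else {
    cfg$simulation <- simulation_config(seed = cfg$seed)
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cf_abort("cf_stage_error", "[stage %s] %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes every stage for which the configuration provides inputs and
#' writes artifacts under `config$out_dir`: `consensus.rr`, `decoys.pdb`,
#' `clusters.tsv`, `confidence.json` and `pipeline.log` (with a full
#' parameter echo). Stages with missing inputs raise stage-tagged errors.
#'
#' @param config a `RunConfig`.
#' @return a `ConfidenceReport`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logcon <- file(log_path, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)
  say("# contactfold pipeline")
  say("# parameters:")
  for (nm in setdiff(names(config), c("fragments", "simulation"))) {
    say("#   %s = %s", nm, paste(deparse(config[[nm]]), collapse = " "))
  }
  sim <- config$simulation
  say("#   simulation: replicas=%d steps=%d t=[%.2f,%.2f] seed=%s",
      sim$n_replicas, sim$steps_per_replica, min(sim$temperatures),
      max(sim$temperatures), format(sim$seed))

  # --- stage nf ----------------------------------------------------------
  nf_val <- config$nf
  if (!is.null(config$msa)) {
    res <- stage("nf", {
      msa <- read_alignment(config$msa, config$msa_format)
      msa <- filter_gap_rows(msa, config$max_gap_fraction)
      msa <- filter_redundancy(msa, config$max_identity, config$min_coverage)
      ec <- effective_count(msa, config$identity_threshold)
      base_nf <- NA_real_
      if (!is.null(config$base_msa)) {
        bmsa <- read_alignment(config$base_msa, config$msa_format)
        bmsa <- filter_gap_rows(bmsa, config$max_gap_fraction)
        bmsa <- filter_redundancy(bmsa, config$max_identity,
                                  config$min_coverage)
        base_nf <- effective_count(bmsa, config$identity_threshold)$nf
      }
      list(ec = ec, base_nf = base_nf)
    })
    nf_val <- res$ec$nf
    say("nf: Nf = %.3f (n_seq = %d, L = %d)", nf_val, res$ec$n_seq, res$ec$L)
    if (!is.na(res$base_nf)) {
      fr <- nff(nf_val, res$base_nf)
      say("nf: Nff = %.3f, triage = %s", fr$nff,
          triage_family(nf_val, res$base_nf, config$nf_cutoff,
                        config$nff_cutoff))
    }
  }
  if (is.null(nf_val)) {
    cf_abort("cf_stage_error", "[stage nf] no MSA and no explicit nf given")
  }

  # --- stage consensus ---------------------------------------------------
  if (length(config$contacts) == 0L) {
    cf_abort("cf_stage_error", "[stage consensus] no contact files configured")
  }
  if (is.null(config$sequence)) {
    cf_abort("cf_stage_error", "[stage fold] no query sequence configured")
  }
  L <- nchar(config$sequence)
  cs <- stage("consensus", {
    outputs <- lapply(config$contacts, function(spec) {
      spec <- as.list(spec)
      read_rr(spec$path, L = L, category = spec$category %||% NULL)
    })
    build_consensus(outputs, L = L, nf = nf_val,
                    scheme = category_scheme(config$nf_switch))
  })
  write_rr(cs, file.path(config$out_dir, "consensus.rr"))
  say("consensus: %d contacts (%d long-range)", nrow(cs$contacts),
      sum(cs$contacts$sep_class == "long"))

  # --- stage fold --------------------------------------------------------
  if (is.null(sim$seed)) {
    cf_abort("cf_stage_error", "[stage fold] simulation seed is mandatory")
  }
  ens <- stage("fold", {
    run_folding(config$sequence, cs, frags = config$fragments, config = sim)
  })
  write_pdb(ens$decoys, file.path(config$out_dir, "decoys.pdb"))
  say("fold: %d decoys, best energy %.3f", ens$M_tot, min(ens$energies))

  # --- stage cluster -----------------------------------------------------
  sols <- stage("cluster", spicker_cluster(ens, cutoff = config$cluster_cutoff))
  rep_tab <- cluster_report(sols, ens$M_tot)
  utils::write.table(rep_tab, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  first <- select_first_model(sols, ens)
  write_pdb(first, file.path(config$out_dir, "model1.pdb"))
  say("cluster: top cluster M = %d, <R> = %.2f", sols[[1]]$M,
      sols[[1]]$mean_rmsd_to_centroid)

  # --- stage cscore ------------------------------------------------------
  report <- stage("cscore", {
    sr <- satisfaction_rate(first, cs)
    dc <- convergence_density(sols[[which.max(vapply(sols, `[[`, 0, "M"))]],
                              ens$M_tot)
    confidence_report(nf_val, sr, dc)
  })
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "confidence.json"),
                       auto_unbox = TRUE, digits = NA)
  say("cscore: C-score = %.3f, estimated TM = %.3f +/- %.3f",
      report$c_score, report$tm_estimate, report$tm_uncertainty)
  invisible(report)
}
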