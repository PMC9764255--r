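#' Read and validate a pipeline run configuration
#'
#' A single YAML file drives an end-to-end run. It must contain exactly
#' one of `paths` (locations of a protein-groups table, design file and
#' optional fasta / annotations / landmarks / categories files) or
#' `simulate` (overrides for [simulation_params()]), plus optional
#' `thresholds`, `enrichment` and `topology` blocks, a `seed` and an
#' `out_dir`.
#'
#' @param path Path to the YAML configuration.
#' @return A validated list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, base_dir = dirname(path))
}

validate_run_config <- function(cfg, base_dir = ".") {
  has_paths <- !is.null(cfg$paths)
  has_sim <- !is.null(cfg$simulate)
  if (has_paths == has_sim)
    stop("config must contain exactly one of 'paths' or 'simulate'")
  if (has_paths) {
    for (key in c("table", "design")) {
      if (is.null(cfg$paths[[key]]))
        stop("config paths block is missing required entry '", key, "'")
    }
    for (key in names(cfg$paths)) {
      p <- cfg$paths[[key]]
      if (!file.exists(p) && !file.exists(file.path(base_dir, p)))
        stop("configured ", key, " file not found: ", p)
      if (!file.exists(p)) cfg$paths[[key]] <- file.path(base_dir, p)
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "apexlfq_run"
  cfg$thresholds <- do.call(filter_thresholds,
                            as.list(cfg$thresholds %||% list()))
  class(cfg) <- "RunConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, the sequential multi-control filter,
#' replicate-reproducibility QC, category enrichment and
#' membrane/luminal classification with topology inference, writing
#' per-stage tables and a machine-readable JSON summary. A rerun with
#' the same configuration and seed reproduces the outputs byte for
#' byte.
#'
#' @param config A `RunConfig` (see [read_run_config()]) or the path to
#'   one.
#' @param out_dir Optional override of the configured output directory.
#' @return The run summary (also written to `summary.json`), invisibly
#'   a list with stage counts, landmark summary and QC minima.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "RunConfig"))
    config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  landmarks <- NULL
  categories <- NULL
  annotations <- NULL
  sequences <- NULL

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    if (!is.null(sim_args$n_per_class))
      sim_args$n_per_class <- unlist(sim_args$n_per_class)
    params <- do.call(simulation_params, sim_args)
    proteome <- generate_proteome(params)
    sim <- simulate_experiment(proteome, default_design(), params)
    table <- sim$table
    input_paths <- write_experiment(sim, proteome,
                                    file.path(out_dir, "inputs"))
    landmarks <- synthetic_landmarks(proteome)
    categories <- read_categories(input_paths[["categories"]])
    sequences <- read_fasta_seqs(input_paths[["fasta"]])
    annotations <- read_annotations(input_paths[["annotations"]], sequences)
  } else {
    design <- read_design(config$paths$design)
    table <- read_protein_groups(config$paths$table, design)
    if (!is.null(config$paths$fasta))
      sequences <- read_fasta_seqs(config$paths$fasta)
    if (!is.null(config$paths$annotations))
      annotations <- read_annotations(config$paths$annotations, sequences)
    if (!is.null(config$paths$categories))
      categories <- read_categories(config$paths$categories)
    if (!is.null(config$paths$landmarks)) {
      lm <- utils::read.delim(config$paths$landmarks,
                              stringsAsFactors = FALSE)
      landmarks <- list(positives = lm$protein_id[lm$role == "positive"],
                        negatives = lm$protein_id[lm$role == "negative"])
    }
  }

  # sequential filter -------------------------------------------------
  report <- sequential_filter(table, config$thresholds, landmarks)
  unflagged <- drop_flagged(table)
  present <- presence_filter(unflagged, config$thresholds)
  for (ctrl in names(report$stages)) {
    utils::write.table(report$stages[[ctrl]],
                       file.path(out_dir, paste0("stage_", ctrl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$final_set, file.path(out_dir, "final_set.tsv"))

  # replicate QC -------------------------------------------------------
  min_r2 <- list()
  for (g in levels(unflagged$design$group)) {
    if (sum(unflagged$design$group == g) >= 2L) {
      r2 <- replicate_correlation(present, g)
      min_r2[[g]] <- min(r2[upper.tri(r2)], na.rm = TRUE)
    }
  }

  # enrichment ---------------------------------------------------------
  enrich <- NULL
  if (!is.null(categories) && length(report$final_set) > 0L) {
    bg_mode <- config$enrichment$background %||% "detected"
    background <- if (bg_mode == "proteome") unflagged$ids else present$ids
    enrich <- fisher_enrichment(
      intersect(report$final_set, background), background, categories,
      ef_cutoff = config$enrichment$ef_cutoff %||% 2,
      p_cutoff = config$enrichment$p_cutoff %||% 0.05)
    utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # localization + topology -------------------------------------------
  topo <- NULL
  n_imp <- n_luminal <- NA_integer_
  if (!is.null(annotations) && length(report$final_set) > 0L) {
    hit_ann <- lapply(report$final_set, function(id) {
      if (id %in% names(annotations)) annotations[[id]]
      else protein_annotation(id, sequence = if (!is.null(sequences) &&
                                                 id %in% names(sequences))
        sequences[[id]] else NA_character_)
    })
    names(hit_ann) <- report$final_set
    topo <- topology_table(
      hit_ann,
      labelable = labelable_set(
        tyrosine_only = isTRUE(config$topology$tyrosine_only)),
      overlap_default = config$topology$overlap_default %||% "luminal",
      use_heuristics = isTRUE(config$topology$use_heuristics))
    utils::write.table(topo, file.path(out_dir, "topology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_imp <- sum(topo$class == "IMP")
    n_luminal <- sum(topo$class != "IMP")
  }

  summary <- list(
    n_input = report$n_input,
    n_after_presence = report$n_after_presence,
    stage_survivors = as.list(report$stage_survivors),
    n_final = length(report$final_set),
    n_IMP = n_imp,
    n_luminal = n_luminal,
    min_r2 = min_r2,
    landmark_summary = if (!is.null(report$landmark_summary))
      report$landmark_summary[c("positives_retained", "negatives_removed")],
    n_enriched_categories = if (!is.null(enrich)) sum(enrich$significant),
    thresholds = report$thresholds[c("min_target_replicates",
                                     "min_msms_total", "p_cutoff",
                                     "fold_change", "control_order",
                                     "missing_policy", "var_equal",
                                     "adjust_p")],
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
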