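TRUE_CLASSES <- c("bait_proximal_luminal", "bait_proximal_imp",
                  "distal_luminal", "cytoplasmic", "endogenous_biotinylated",
                  "phycobilisome_like_landmark", "oec_like_landmark")

# residue pools: polar/soluble (no APEX2-labelable letter, strongly
# hydrophilic), transmembrane core (hydrophobic, no labelable letter),
# and the labelable set itself
AA_POLAR <- c("A", "G", "S", "T", "N", "Q", "D", "E", "K", "R", "P")
AA_TM <- c("L", "I", "V", "F", "M", "A")
AA_LABELABLE <- c("Y", "W", "H", "C")

#' Simulation parameters for a synthetic proximity-labeling experiment
#'
#' Defaults describe a plausible four-group APEX2 pull-down on the log2
#' intensity scale: a strong (8-fold) enrichment of bait-proximal
#' proteins in the target channel, a weak endogenous-peroxidase
#' background in the wild-type control, endogenous biotinylated proteins
#' visible in every channel including the no-substrate control, and a
#' partial cytoplasmic leak of the bait fusion. Intensities are
#' left-censored by a logistic detection model, mimicking label-free
#' missingness.
#'
#' @param n_per_class Named integer vector of protein counts per
#'   ground-truth class (see `TRUE_CLASSES`). Defaults give 50
#'   bait-proximal proteins (including 3 OEC-like positive landmarks)
#'   against 200 background proteins (including 6 phycobilisome-like
#'   negative landmarks).
#' @param base_log_intensity_mean,base_log_intensity_sd Mean / sd of the
#'   per-protein baseline log2 intensity (nonspecific pull-down level).
#' @param target_enrichment_log2fc Log2 enrichment added to bait-proximal
#'   classes in the target group.
#' @param peroxidase_background_log2 Weak signal added to every protein
#'   in the wild-type control (endogenous peroxidase activity).
#' @param endogenous_biotin_log2 Signal added to endogenous biotinylated
#'   proteins in every group, including the no-substrate control.
#' @param cyto_leak_log2fc Signal added to cytoplasmic proteins in the
#'   cytoplasmic-bait control; `cyto_leak_target_fraction` of it also
#'   leaks into the target group (newly synthesised bait in the
#'   cytoplasm).
#' @param cyto_leak_target_fraction Fraction in `[0,1]` of the
#'   cytoplasmic leak present in the target group.
#' @param replicate_sd Between-replicate log2 noise sd.
#' @param detection_logistic_midpoint,detection_logistic_slope Logistic
#'   detection model: `P(detected) = plogis(slope * (log2int - midpoint))`.
#'   A midpoint of `-Inf` disables missingness.
#' @param msms_per_log2intensity Poisson mean per unit log2 intensity for
#'   MS/MS counts of detected proteins (floored at 1).
#' @param seed Integer master seed; each simulation stage derives its own
#'   stream from it.
#' @return A validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_per_class = c(bait_proximal_luminal = 25,
                                              bait_proximal_imp = 22,
                                              oec_like_landmark = 3,
                                              distal_luminal = 40,
                                              cytoplasmic = 124,
                                              endogenous_biotinylated = 30,
                                              phycobilisome_like_landmark = 6),
                              base_log_intensity_mean = 25,
                              base_log_intensity_sd = 2,
                              target_enrichment_log2fc = 3,
                              peroxidase_background_log2 = 0.5,
                              endogenous_biotin_log2 = 3,
                              cyto_leak_log2fc = 2,
                              cyto_leak_target_fraction = 0.3,
                              replicate_sd = 0.3,
                              detection_logistic_midpoint = 20,
                              detection_logistic_slope = 1.5,
                              msms_per_log2intensity = 0.4,
                              seed = 1L) {
  full <- stats::setNames(integer(length(TRUE_CLASSES)), TRUE_CLASSES)
  bad <- setdiff(names(n_per_class), TRUE_CLASSES)
  if (length(bad) > 0L) stop("unknown class: ", paste(bad, collapse = ", "))
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (any(full < 0L)) stop("n_per_class values must be >= 0")
  stopifnot(base_log_intensity_sd >= 0, replicate_sd >= 0,
            target_enrichment_log2fc >= 0,
            cyto_leak_target_fraction >= 0, cyto_leak_target_fraction <= 1,
            msms_per_log2intensity >= 0)
  structure(list(n_per_class = full,
                 base_log_intensity_mean = base_log_intensity_mean,
                 base_log_intensity_sd = base_log_intensity_sd,
                 target_enrichment_log2fc = target_enrichment_log2fc,
                 peroxidase_background_log2 = peroxidase_background_log2,
                 endogenous_biotin_log2 = endogenous_biotin_log2,
                 cyto_leak_log2fc = cyto_leak_log2fc,
                 cyto_leak_target_fraction = cyto_leak_target_fraction,
                 replicate_sd = replicate_sd,
                 detection_logistic_midpoint = detection_logistic_midpoint,
                 detection_logistic_slope = detection_logistic_slope,
                 msms_per_log2intensity = msms_per_log2intensity,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Default four-group, three-replicate design
#'
#' @param replicates Replicates per group.
#' @return A validated design data.frame.
#' @export
default_design <- function(replicates = 3L) {
  design <- expand.grid(replicate = seq_len(replicates),
                        group = GROUP_LEVELS, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_r%d", design$group, design$replicate)
  validate_design(design[, c("sample_id", "group", "replicate")])
}

# per-stage random streams derived from the master seed, so that e.g.
# the detection draws do not shift when the proteome grows
stage_seed <- function(params, stage) {
  offs <- c(proteome = 101L, base = 202L, noise = 303L, detect = 404L,
            msms = 505L, impute = 606L)
  set.seed((params$seed * 1009L + offs[[stage]]) %% .Machine$integer.max)
}

random_seq <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                      collapse = "")

# soluble stretch with labelable residues sprinkled in
soluble_seq <- function(n, label_rate = 0.08) {
  aa <- sample(AA_POLAR, n, replace = TRUE)
  k <- stats::rbinom(1L, n, label_rate)
  if (k > 0L) aa[sample.int(n, k)] <- sample(AA_LABELABLE, k, replace = TRUE)
  paste(aa, collapse = "")
}

# signal peptide: n-region with a basic residue, hydrophobic h-region,
# cleavage-site-like A; detectable by the package's heuristic predictor
plant_signal_peptide <- function() {
  n_reg <- paste0("M", sample(c("K", "R"), 1L),
                  random_seq(2L, setdiff(AA_POLAR, c("K", "R"))))
  h_reg <- random_seq(11L, c("L", "I", "V"))
  paste0(n_reg, h_reg, "A")  # 16 residues, core within 1..35
}

# loop stretch with no labelable residue at all
quiet_loop <- function(n) random_seq(n, AA_POLAR)

# loop carrying >=1 labelable residue
labeled_loop <- function(n) {
  aa <- sample(AA_POLAR, n, replace = TRUE)
  k <- max(1L, stats::rbinom(1L, n, 0.15))
  aa[sample.int(n, min(k, n))] <- sample(AA_LABELABLE, min(k, n),
                                         replace = TRUE)
  paste(aa, collapse = "")
}

build_imp <- function() {
  n_tm <- sample(1:2, 1L)
  lumen_first <- sample(c(TRUE, FALSE), 1L)  # N-terminal loop lumenal?
  loop_len <- c(sample(15:40, 1L),
                if (n_tm == 2L) sample(10:20, 1L),
                sample(8:20, 1L))
  n_loops <- n_tm + 1L
  lumenal <- (seq_len(n_loops) %% 2L == 1L) == lumen_first
  loops <- vapply(seq_len(n_loops), function(j) {
    if (lumenal[j]) labeled_loop(loop_len[j]) else quiet_loop(loop_len[j])
  }, character(1))
  tms <- vapply(seq_len(n_tm), function(j) random_seq(21L, AA_TM),
                character(1))
  seq_parts <- character(0)
  segs <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  pos <- 0L
  for (j in seq_len(n_tm)) {
    seq_parts <- c(seq_parts, loops[j], tms[j])
    s <- pos + nchar(loops[j]) + 1L
    segs <- rbind(segs, c(s, s + 20L))
    pos <- s + 20L
  }
  seq_parts <- c(seq_parts, loops[n_loops])
  list(sequence = paste(seq_parts, collapse = ""),
       tm_segments = segs,
       orientation = if (lumen_first) "N_lumen" else "C_lumen")
}

#' Generate a synthetic proteome with known ground truth
#'
#' Builds protein sequences for every ground-truth class. Integral
#' membrane proteins get one or two planted transmembrane segments with
#' APEX2-labelable residues (Y/W/H/C) placed exclusively in the loops of
#' a randomly chosen, recorded membrane orientation; most luminal
#' proteins get a planted N-terminal signal peptide. Landmark classes
#' reuse the generating distributions of the classes they mirror
#' (OEC-like behaves bait-proximal-luminal, phycobilisome-like behaves
#' cytoplasmic).
#'
#' @param params A [simulation_params()] object.
#' @return A data.frame of class `SyntheticProteome` with columns
#'   `protein_id`, `true_class`, `sequence`, `planted_orientation`,
#'   `has_signal_peptide`, plus list-columns `tm_segments` and
#'   `sp_region`. Deterministic given `params$seed`.
#' @export
generate_proteome <- function(params = simulation_params()) {
  stage_seed(params, "proteome")
  tag <- c(bait_proximal_luminal = "LUM", bait_proximal_imp = "IMP",
           distal_luminal = "DIS", cytoplasmic = "CYT",
           endogenous_biotinylated = "BIO",
           phycobilisome_like_landmark = "PBS", oec_like_landmark = "OEC")
  rows <- list()
  for (cls in TRUE_CLASSES) {
    for (i in seq_len(params$n_per_class[[cls]])) {
      id <- sprintf("%s%03d", tag[[cls]], i)
      orientation <- NA_character_
      sp_region <- NULL
      has_sp <- FALSE
      if (cls == "bait_proximal_imp") {
        imp <- build_imp()
        sequence <- imp$sequence
        segs <- imp$tm_segments
        orientation <- imp$orientation
      } else {
        segs <- matrix(integer(), 0, 2,
                       dimnames = list(NULL, c("start", "end")))
        luminal <- cls %in% c("bait_proximal_luminal", "distal_luminal",
                              "oec_like_landmark")
        if (luminal && stats::runif(1) < 0.8) {
          sp <- plant_signal_peptide()
          sequence <- paste0(sp, soluble_seq(sample(80:200, 1L)))
          sp_region <- c(1L, nchar(sp))
          has_sp <- TRUE
        } else {
          sequence <- paste0("M", soluble_seq(sample(80:200, 1L)))
        }
      }
      rows[[length(rows) + 1L]] <-
        list(protein_id = id, true_class = cls, sequence = sequence,
             planted_orientation = orientation, has_signal_peptide = has_sp,
             tm_segments = segs, sp_region = sp_region)
    }
  }
  out <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    true_class = vapply(rows, `[[`, character(1), "true_class"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    planted_orientation = vapply(rows, `[[`, character(1),
                                 "planted_orientation"),
    has_signal_peptide = vapply(rows, `[[`, logical(1),
                                "has_signal_peptide"),
    stringsAsFactors = FALSE)
  out$tm_segments <- lapply(rows, `[[`, "tm_segments")
  out$sp_region <- lapply(rows, `[[`, "sp_region")
  class(out) <- c("SyntheticProteome", "data.frame")
  out
}

# log2 effect of (true_class, group) on top of the per-protein baseline;
# landmarks inherit the distribution of the class they mirror
class_group_effect <- function(true_class, group, params) {
  cls <- true_class
  cls[cls == "oec_like_landmark"] <- "bait_proximal_luminal"
  cls[cls == "phycobilisome_like_landmark"] <- "cytoplasmic"
  eff <- numeric(length(cls))
  proximal <- cls %in% c("bait_proximal_luminal", "bait_proximal_imp")
  eff[proximal & group == "target"] <- params$target_enrichment_log2fc
  eff[cls == "cytoplasmic" & group == "ctrl_cyto_bait"] <-
    params$cyto_leak_log2fc
  eff[cls == "cytoplasmic" & group == "target"] <-
    params$cyto_leak_log2fc * params$cyto_leak_target_fraction
  eff[cls == "endogenous_biotinylated"] <-
    eff[cls == "endogenous_biotinylated"] + params$endogenous_biotin_log2
  if (group == "ctrl_wildtype") eff <- eff + params$peroxidase_background_log2
  eff
}

#' Simulate a four-group quantification experiment
#'
#' Per protein and sample, log2 intensity = per-protein baseline +
#' class/group effect + Normal(0, `replicate_sd`). Detection is a
#' logistic function of log2 intensity (left-censoring); undetected
#' cells get intensity 0 and MS/MS count 0; detected cells get a Poisson
#' MS/MS count with mean proportional to log2 intensity, floored at 1.
#' Deterministic given `params$seed`.
#'
#' @param proteome A [generate_proteome()] result.
#' @param design A validated design containing all four groups.
#' @param params A [simulation_params()] object.
#' @return List with `table` (a [quant_table()]) and `truth` (data.frame
#'   `protein_id`, `true_class`, `planted_orientation`).
#' @export
simulate_experiment <- function(proteome, design = default_design(),
                                params = simulation_params()) {
  design <- validate_design(design)
  missing_groups <- setdiff(GROUP_LEVELS, as.character(unique(design$group)))
  if (length(missing_groups) > 0L)
    stop("design is missing group(s): ", paste(missing_groups, collapse = ", "))
  n <- nrow(proteome)
  S <- nrow(design)

  stage_seed(params, "base")
  base <- stats::rnorm(n, params$base_log_intensity_mean,
                       params$base_log_intensity_sd)
  mu <- vapply(seq_len(S), function(s) {
    base + class_group_effect(proteome$true_class,
                              as.character(design$group[s]), params)
  }, numeric(n))
  mu <- matrix(mu, nrow = n)

  stage_seed(params, "noise")
  log2int <- mu + matrix(stats::rnorm(n * S, 0, params$replicate_sd), n, S)

  stage_seed(params, "detect")
  if (is.finite(params$detection_logistic_midpoint)) {
    p_det <- stats::plogis(params$detection_logistic_slope *
                             (log2int - params$detection_logistic_midpoint))
    detected <- matrix(stats::runif(n * S), n, S) < p_det
  } else {
    detected <- matrix(TRUE, n, S)
  }

  stage_seed(params, "msms")
  lambda <- pmax(params$msms_per_log2intensity * log2int, 0)
  msms <- matrix(stats::rpois(n * S, lambda), n, S)
  msms <- pmax(msms, 1L)
  msms[!detected] <- 0L

  intens <- 2^log2int
  intens[!detected] <- 0

  table <- quant_table(proteome$protein_id, intens, msms,
                       list(is_contaminant = rep(FALSE, n),
                            is_decoy = rep(FALSE, n),
                            only_by_site = rep(FALSE, n)),
                       design)
  truth <- data.frame(protein_id = proteome$protein_id,
                      true_class = proteome$true_class,
                      planted_orientation = proteome$planted_orientation,
                      stringsAsFactors = FALSE)
  list(table = table, truth = truth)
}

#' Landmark sets of a synthetic proteome
#'
#' @param proteome A [generate_proteome()] result.
#' @return List with `positives` (OEC-like ids) and `negatives`
#'   (phycobilisome-like ids).
#' @export
synthetic_landmarks <- function(proteome) {
  list(positives = proteome$protein_id[proteome$true_class ==
                                         "oec_like_landmark"],
       negatives = proteome$protein_id[proteome$true_class ==
                                         "phycobilisome_like_landmark"])
}

tm_field <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) return("")
  paste(sprintf("%d-%d", segs[, 1L], segs[, 2L]), collapse = ";")
}

#' Write a synthetic experiment to disk
#'
#' Emits the same plain-text dialects the readers consume: a
#' protein-groups TSV, a design TSV, a FASTA of sequences, an annotation
#' TSV with the planted TM/SP truth, a landmarks TSV, a simple category
#' TSV derived from the ground-truth classes, and the ground-truth table
#' itself.
#'
#' @param sim A [simulate_experiment()] result.
#' @param proteome The matching [generate_proteome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_experiment <- function(sim, proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "proteinGroups.tsv"),
             design = file.path(dir, "design.tsv"),
             fasta = file.path(dir, "sequences.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             landmarks = file.path(dir, "landmarks.tsv"),
             categories = file.path(dir, "categories.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_protein_groups(sim$table, paths[["table"]])
  utils::write.table(sim$table$design, paths[["design"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", proteome$protein_id, " synthetic\n",
                    proteome$sequence), paths[["fasta"]])
  ann <- data.frame(
    protein_id = proteome$protein_id,
    tm_segments = vapply(proteome$tm_segments, tm_field, character(1)),
    signal_peptide = as.integer(proteome$has_signal_peptide),
    sp_region = vapply(proteome$sp_region, function(r) {
      if (is.null(r)) "" else sprintf("%d-%d", r[1L], r[2L])
    }, character(1)),
    categories = proteome$true_class,
    stringsAsFactors = FALSE)
  utils::write.table(ann, paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lm <- synthetic_landmarks(proteome)
  utils::write.table(
    data.frame(protein_id = c(lm$positives, lm$negatives),
               role = rep(c("positive", "negative"),
                          c(length(lm$positives), length(lm$negatives)))),
    paths[["landmarks"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = proteome$protein_id,
               category = proteome$true_class, source = "custom"),
    paths[["categories"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
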