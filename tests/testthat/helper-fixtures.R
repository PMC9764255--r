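# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except what a test itself writes.

toy_design <- function(replicates = 3L) default_design(replicates)

# random QuantTable: detected cells are log-normal intensities with
# MS/MS counts, a fraction of cells is missing uniformly at random
random_quant_table <- function(n = 50L, design = toy_design(),
                               miss_rate = 0.2, seed = 1L) {
  set.seed(seed)
  S <- nrow(design)
  intens <- matrix(2^stats::rnorm(n * S, 24, 2), n, S)
  msms <- matrix(stats::rpois(n * S, 8) + 1L, n, S)
  gone <- matrix(stats::runif(n * S) < miss_rate, n, S)
  intens[gone] <- 0
  msms[gone] <- 0L
  quant_table(sprintf("P%04d", seq_len(n)), intens, msms,
              list(is_contaminant = rep(FALSE, n),
                   is_decoy = rep(FALSE, n),
                   only_by_site = rep(FALSE, n)),
              design)
}

# write a QuantTable-shaped protein-groups TSV by hand (independent of
# write_protein_groups) for reader tests
write_toy_protein_groups <- function(path, ids, intens, msms, design,
                                     contaminants = character(),
                                     marker_cols = FALSE) {
  header <- c("Protein IDs",
              paste("LFQ intensity", design$sample_id),
              paste("MS/MS count", design$sample_id),
              if (marker_cols) c("Potential contaminant", "Reverse"))
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i],
            format(intens[i, ], scientific = FALSE, trim = TRUE),
            msms[i, ],
            if (marker_cols) c(if (ids[i] %in% contaminants) "+" else "",
                               "")), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  path
}

# brute-force presence filter: per-row scan applying both predicates
oracle_presence <- function(table, min_reps = 2L, min_msms = 2L) {
  tcols <- which(as.character(table$design$group) == "target")
  keep <- logical(length(table$ids))
  for (i in seq_along(table$ids)) {
    det <- 0L; ms <- 0L
    for (j in tcols) {
      if (table$intensities[i, j] > 0) det <- det + 1L
      ms <- ms + table$msms[i, j]
    }
    keep[i] <- det >= min_reps && ms >= min_msms
  }
  table$ids[keep]
}

# brute-force single-stage pass set under the detected-only policy
oracle_stage_pass <- function(table, ctrl, p_cutoff = 0.05, fc = 2) {
  tcols <- which(as.character(table$design$group) == "target")
  ccols <- which(as.character(table$design$group) == ctrl)
  pass <- logical(length(table$ids))
  for (i in seq_along(table$ids)) {
    tv <- table$intensities[i, tcols]
    cv <- table$intensities[i, ccols]
    td <- log2(tv[tv > 0])
    cd <- log2(cv[cv > 0])
    if (length(td) == length(tcols) && length(cd) == 0L) {
      pass[i] <- TRUE
    } else if (length(td) >= 2L && length(cd) >= 2L) {
      ratio <- mean(td) - mean(cd)
      p <- if (stats::sd(c(td - mean(td), cd - mean(cd))) == 0) {
        if (mean(td) == mean(cd)) 1 else 0
      } else stats::t.test(td, cd, var.equal = TRUE)$p.value
      pass[i] <- p < p_cutoff && ratio >= log2(fc)
    }
  }
  table$ids[pass]
}

# brute-force evaluator of the labelable-residue topology rule, written
# directly from its statement and independent of infer_topology
oracle_topology <- function(sequence, tm_segments,
                            labelable = c("Y", "W", "H", "C")) {
  aa <- strsplit(sequence, "")[[1L]]
  segs <- tm_segments[order(tm_segments[, 1L]), , drop = FALSE]
  loop_of <- rep(NA_integer_, length(aa))
  loop_id <- 1L
  pos <- 1L
  for (r in seq_len(nrow(segs))) {
    if (pos <= segs[r, 1L] - 1L) loop_of[pos:(segs[r, 1L] - 1L)] <- loop_id
    loop_id <- loop_id + 1L
    pos <- segs[r, 2L] + 1L
  }
  if (pos <= length(aa)) loop_of[pos:length(aa)] <- loop_id
  lab <- which(aa %in% labelable & !is.na(loop_of))
  if (length(lab) == 0L) return("ambiguous")
  side <- ifelse(loop_of[lab] %% 2L == 1L, "A", "B")
  if (all(side == "A")) "N_lumen"
  else if (all(side == "B")) "C_lumen"
  else "ambiguous"
}

prox_classes <- c("bait_proximal_luminal", "bait_proximal_imp",
                  "oec_like_landmark")
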