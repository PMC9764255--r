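#' Filtering thresholds for the sequential multi-control filter
#'
#' Defaults reproduce the published criteria exactly: proteins must be
#' detected in at least two target replicates with a summed target MS/MS
#' count of at least two ("MS/MS count > 1"), and each control
#' comparison requires a two-sample Student's t-test p below 0.05
#' together with at least a two-fold enrichment over the control.
#'
#' @param min_target_replicates Minimum number of target samples with a
#'   detection (intensity > 0).
#' @param min_msms_total Minimum summed MS/MS count over target samples.
#' @param p_cutoff Per-stage p-value cutoff.
#' @param fold_change Per-stage minimum fold change (linear scale, > 1).
#' @param control_order Order in which the control groups are applied;
#'   the final set is order-invariant but the per-stage survivor counts
#'   are not.
#' @param missing_policy `"detected_only"` computes each test on detected
#'   values only (needing at least two per side); `"impute"` fills
#'   missing cells with a seeded downshifted-normal draw per sample
#'   before testing.
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` switches to Welch.
#' @param adjust_p `"none"` (the published criterion uses raw p) or
#'   `"BH"` for Benjamini-Hochberg within each stage.
#' @param impute_width,impute_downshift Downshifted-normal imputation
#'   parameters in units of each sample's detected-value sd.
#' @param impute_seed Seed for the imputation draws.
#' @return A list of class `FilterThresholds`.
#' @export
filter_thresholds <- function(min_target_replicates = 2L,
                              min_msms_total = 2L,
                              p_cutoff = 0.05,
                              fold_change = 2,
                              control_order = c("ctrl_no_substrate",
                                                "ctrl_wildtype",
                                                "ctrl_cyto_bait"),
                              missing_policy = c("detected_only", "impute"),
                              var_equal = TRUE,
                              adjust_p = c("none", "BH"),
                              impute_width = 0.3,
                              impute_downshift = 1.8,
                              impute_seed = 1L) {
  stopifnot(p_cutoff > 0, p_cutoff < 1, fold_change > 1,
            min_target_replicates >= 1, min_msms_total >= 0)
  bad <- setdiff(control_order, GROUP_LEVELS)
  if (length(bad) > 0L) stop("unknown control group: ",
                             paste(bad, collapse = ", "))
  structure(list(min_target_replicates = as.integer(min_target_replicates),
                 min_msms_total = as.integer(min_msms_total),
                 p_cutoff = p_cutoff,
                 fold_change = fold_change,
                 control_order = control_order,
                 missing_policy = match.arg(missing_policy),
                 var_equal = isTRUE(var_equal),
                 adjust_p = match.arg(adjust_p),
                 impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 impute_seed = as.integer(impute_seed)),
            class = "FilterThresholds")
}

group_cols <- function(table, group) {
  which(as.character(table$design$group) == group)
}

#' Presence filter on the target group
#'
#' Retains proteins detected (intensity > 0) in at least
#' `min_target_replicates` target samples and with a summed target MS/MS
#' count of at least `min_msms_total`.
#'
#' @param table A `QuantTable`.
#' @param thresholds A [filter_thresholds()] object.
#' @return The filtered `QuantTable`.
#' @export
presence_filter <- function(table, thresholds = filter_thresholds()) {
  tcols <- group_cols(table, "target")
  if (length(tcols) == 0L) stop("design has no target samples")
  if (thresholds$min_target_replicates > length(tcols))
    stop("min_target_replicates (", thresholds$min_target_replicates,
         ") exceeds the number of target samples (", length(tcols), ")")
  det <- rowSums(table$intensities[, tcols, drop = FALSE] > 0)
  ms <- rowSums(table$msms[, tcols, drop = FALSE])
  subset_quant(table, det >= thresholds$min_target_replicates &
                 ms >= thresholds$min_msms_total)
}

# pooled / Welch two-sample t-test on per-protein row vectors, vectorised
# over proteins; returns two-sided p. Degenerate rows (pooled sd 0) get
# p = 1 when the means agree and p = 0 otherwise.
row_t_test <- function(x, y, var_equal = TRUE) {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1L, stats::var, na.rm = TRUE)
  vy <- apply(y, 1L, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p <- 2 * stats::pt(abs(mx - my) / se, df, lower.tail = FALSE)
  degen <- !is.na(se) & se == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  p
}

# Perseus-style missing-value imputation: per sample, draw missing cells
# from Normal(mean - downshift * sd, (width * sd)^2) of that sample's
# detected log2 values; seeded for reproducibility
impute_downshifted <- function(log2m, thresholds) {
  set.seed(thresholds$impute_seed)
  for (j in seq_len(ncol(log2m))) {
    obs <- log2m[, j][!is.na(log2m[, j])]
    nas <- which(is.na(log2m[, j]))
    if (length(nas) == 0L || length(obs) < 2L) next
    m <- mean(obs); s <- stats::sd(obs)
    log2m[nas, j] <- stats::rnorm(length(nas),
                                  m - thresholds$impute_downshift * s,
                                  thresholds$impute_width * s)
  }
  log2m
}

#' Compare the target group against one control group
#'
#' For each protein, computes the log2 ratio of (geometric) mean target
#' intensity over mean control intensity and a two-sided two-sample
#' t-test on the log2 intensities. Under the default `detected_only`
#' policy, only detected values enter and at least two are required per
#' side; a protein detected in every target sample but in no control
#' sample passes by the absent-in-control rule with an infinite ratio
#' and a sentinel (`NA`) p-value. A protein unquantifiable under the
#' policy gets sentinel values and does not pass.
#'
#' @param table A `QuantTable` (normally presence-filtered).
#' @param control_group One of the control group labels.
#' @param thresholds A [filter_thresholds()] object.
#' @param target_group Group compared against the control.
#' @return A data.frame of class `StageResult` with columns
#'   `protein_id`, `log2_ratio`, `p_value`, `n_target_detected`,
#'   `n_control_detected`, `passed`, and attribute `control_group`.
#' @export
compare_groups <- function(table, control_group,
                           thresholds = filter_thresholds(),
                           target_group = "target") {
  tcols <- group_cols(table, target_group)
  ccols <- group_cols(table, control_group)
  if (length(tcols) == 0L) stop("no samples for group '", target_group, "'")
  if (length(ccols) == 0L) stop("no samples for group '", control_group, "'")

  ti <- table$intensities[, tcols, drop = FALSE]
  ci <- table$intensities[, ccols, drop = FALSE]
  lt <- log2(ti); lt[ti == 0] <- NA
  lc <- log2(ci); lc[ci == 0] <- NA
  n_t <- rowSums(!is.na(lt))
  n_c <- rowSums(!is.na(lc))

  if (thresholds$missing_policy == "impute") {
    both <- impute_downshifted(cbind(lt, lc), thresholds)
    lt <- both[, seq_along(tcols), drop = FALSE]
    lc <- both[, length(tcols) + seq_along(ccols), drop = FALSE]
  }
  nt_eff <- rowSums(!is.na(lt))
  nc_eff <- rowSums(!is.na(lc))
  testable <- nt_eff >= 2L & nc_eff >= 2L

  ratio <- rowMeans(lt, na.rm = TRUE) - rowMeans(lc, na.rm = TRUE)
  ratio[nt_eff == 0L] <- NA
  ratio[nt_eff > 0L & nc_eff == 0L] <- Inf

  p <- rep(NA_real_, length(table$ids))
  if (any(testable))
    p[testable] <- row_t_test(lt[testable, , drop = FALSE],
                              lc[testable, , drop = FALSE],
                              var_equal = thresholds$var_equal)
  if (thresholds$adjust_p == "BH")
    p[testable] <- stats::p.adjust(p[testable], method = "BH")

  absent_in_control <- n_t == length(tcols) & n_c == 0L
  passed <- (!is.na(p) & p < thresholds$p_cutoff &
               !is.na(ratio) & ratio >= log2(thresholds$fold_change)) |
    absent_in_control

  out <- data.frame(protein_id = table$ids,
                    log2_ratio = ratio,
                    p_value = p,
                    n_target_detected = n_t,
                    n_control_detected = n_c,
                    passed = passed,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "control_group") <- control_group
  class(out) <- c("StageResult", "data.frame")
  out
}

#' Sequential multi-control filter
#'
#' Applies the presence filter, then compares the survivors against each
#' control group in `thresholds$control_order`, keeping at every stage
#' only the proteins that pass (p below cutoff and fold change at least
#' the threshold, or absent-in-control). The final set is the
#' intersection of the three per-stage pass sets and therefore does not
#' depend on the order of the controls.
#'
#' @param table A `QuantTable` (flagged rows are dropped first).
#' @param thresholds A [filter_thresholds()] object.
#' @param landmarks Optional list with `positives` and `negatives`
#'   protein-id vectors for landmark validation.
#' @return A list of class `FilterReport` with `n_input`,
#'   `n_after_presence`, `stages` (named list of `StageResult` for the
#'   survivors entering each stage), `stage_survivors` (counts),
#'   `final_set`, `thresholds` and, when landmarks are given,
#'   `landmark_summary`.
#' @export
sequential_filter <- function(table, thresholds = filter_thresholds(),
                              landmarks = NULL) {
  table <- drop_flagged(table)
  n_input <- length(table$ids)
  present <- presence_filter(table, thresholds)
  current <- present
  stages <- list()
  survivors <- integer()
  for (ctrl in thresholds$control_order) {
    st <- compare_groups(current, ctrl, thresholds)
    stages[[ctrl]] <- st
    current <- subset_quant(current, st$passed)
    survivors[[ctrl]] <- length(current$ids)
    if (length(current$ids) == 0L)
      warning("no proteins left after comparison against ", ctrl)
  }
  report <- structure(list(n_input = n_input,
                           n_after_presence = length(present$ids),
                           stages = stages,
                           stage_survivors = survivors,
                           final_set = current$ids,
                           thresholds = thresholds),
                      class = "FilterReport")
  if (!is.null(landmarks))
    report$landmark_summary <- landmark_check(report, landmarks$positives,
                                              landmarks$negatives)
  report
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("Sequential proximity filter\n")
  cat(sprintf("  input proteins:        %d\n", x$n_input))
  cat(sprintf("  after presence filter: %d\n", x$n_after_presence))
  for (ctrl in names(x$stage_survivors))
    cat(sprintf("  after vs %-18s %d\n", paste0(ctrl, ":"),
                x$stage_survivors[[ctrl]]))
  cat(sprintf("  final proximal set:    %d\n", length(x$final_set)))
  if (!is.null(x$landmark_summary))
    cat(sprintf("  landmarks: %.0f%% positives retained, %.0f%% negatives removed\n",
                100 * x$landmark_summary$positives_retained,
                100 * x$landmark_summary$negatives_removed))
  invisible(x)
}

#' Landmark validation of a filter report
#'
#' Positive landmarks (e.g. OEC subunits) should survive the filter;
#' negative landmarks (e.g. phycobilisome subunits) should be removed.
#' Empty landmark sets report a fraction of 1 by convention.
#'
#' @param report A [sequential_filter()] report.
#' @param positives,negatives Character vectors of protein ids.
#' @return List with `positives_retained`, `negatives_removed`,
#'   `positives_lost`, `negatives_leaked`.
#' @export
landmark_check <- function(report, positives, negatives) {
  frac <- function(num, den) if (den == 0L) 1 else num / den
  pos_in <- sum(positives %in% report$final_set)
  neg_in <- sum(negatives %in% report$final_set)
  list(positives_retained = frac(pos_in, length(positives)),
       negatives_removed = frac(length(negatives) - neg_in,
                                length(negatives)),
       positives_lost = setdiff(positives, report$final_set),
       negatives_leaked = intersect(negatives, report$final_set))
}

#' Pairwise replicate reproducibility (R-squared)
#'
#' For every pair of samples in a group, the squared Pearson correlation
#' of log2 intensities over the proteins detected in both samples.
#' Pairs with fewer than three co-detected proteins get `NA`.
#'
#' @param table A `QuantTable`.
#' @param group Group label.
#' @return Symmetric matrix of R-squared values with unit diagonal.
#' @export
replicate_correlation <- function(table, group = "target") {
  cols <- group_cols(table, group)
  if (length(cols) < 2L) stop("group '", group, "' has fewer than 2 samples")
  m <- table$intensities[, cols, drop = FALSE]
  k <- length(cols)
  r2 <- diag(1, k)
  dimnames(r2) <- list(colnames(m), colnames(m))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      both <- m[, a] > 0 & m[, b] > 0
      r2[a, b] <- r2[b, a] <- if (sum(both) < 3L) NA_real_ else
        stats::cor(log2(m[both, a]), log2(m[both, b]))^2
    }
  }
  r2
}
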