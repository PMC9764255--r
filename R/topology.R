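# Kyte-Doolittle hydropathy index (standard scale)
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy values of a sequence
#'
#' @param sequence Amino-acid string. Non-standard residues score 0.
#' @return Numeric vector of per-residue hydropathy values.
#' @export
kd_hydropathy <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  v <- KD_SCALE[aa]
  v[is.na(v)] <- 0
  unname(v)
}

#' The set of APEX2-labelable residues
#'
#' The phenoxyl radical generated by APEX2 reacts with electron-rich
#' side chains: tyrosine, tryptophan, histidine and cysteine. Tyrosine
#' is the primary site, so a tyrosine-only mode is available.
#'
#' @param tyrosine_only Restrict to Y.
#' @param residues Override the residue set.
#' @return Character vector of residue letters.
#' @export
labelable_set <- function(tyrosine_only = FALSE,
                          residues = c("Y", "W", "H", "C")) {
  res <- if (tyrosine_only) "Y" else toupper(residues)
  if (length(res) == 0L) stop("labelable set must be non-empty")
  res
}

rolling_mean <- function(v, w) {
  if (length(v) < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) / w
}

#' Heuristic transmembrane-segment prediction
#'
#' A deliberately simple stand-in for a dedicated TM predictor, for
#' annotation-free inputs only: windows of Kyte-Doolittle hydropathy
#' whose mean exceeds a threshold seed candidate segments; overlapping
#' windows are merged and over-long merged regions are split into
#' equal consecutive segments so every reported segment has a
#' TM-helix-like length.
#'
#' @param sequence Amino-acid string.
#' @param window Window length (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param min_len,max_len Allowed segment lengths after merging/splitting.
#' @return Integer matrix with columns `start`, `end` (1-based,
#'   inclusive); zero rows when the sequence is shorter than the window
#'   or no window qualifies.
#' @export
heuristic_tm_predict <- function(sequence, window = 19L, threshold = 1.6,
                                 min_len = 17L, max_len = 35L) {
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  v <- kd_hydropathy(sequence)
  means <- rolling_mean(v, window)
  if (length(means) == 0L) return(empty)
  hits <- which(means > threshold)
  if (length(hits) == 0L) return(empty)
  covered <- rep(FALSE, length(v))
  for (i in hits) covered[i:(i + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(start = starts[r$values], end = ends[r$values])
  out <- list()
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2L] - segs[i, 1L] + 1L
    if (len < min_len) next
    pieces <- ceiling(len / max_len)
    cuts <- round(seq(segs[i, 1L] - 1L, segs[i, 2L], length.out = pieces + 1L))
    for (p in seq_len(pieces))
      out[[length(out) + 1L]] <- c(cuts[p] + 1L, cuts[p + 1L])
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Heuristic signal-peptide prediction
#'
#' A stand-in for a dedicated signal-peptide predictor: calls a signal
#' peptide when a 10-residue hydrophobic core (mean Kyte-Doolittle
#' hydropathy above 1.6) lies entirely within residues 1-35 and at
#' least one of the first five residues is lysine or arginine (the
#' n-region's positive charge). The reported region runs from residue 1
#' to the first small residue (G/A/S) after the core, capped at 40.
#'
#' @param sequence Amino-acid string.
#' @param core_window Core window length (default 10).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param n_region_max Last residue at which the basic residue may sit.
#' @param core_max_end Last residue the core may touch.
#' @param region_cap Maximum reported region end.
#' @return `c(start = 1, end = e)` or `NULL` when no signal peptide is
#'   called.
#' @export
heuristic_sp_predict <- function(sequence, core_window = 10L,
                                 threshold = 1.6, n_region_max = 5L,
                                 core_max_end = 35L, region_cap = 40L) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (!any(aa[seq_len(min(n_region_max, length(aa)))] %in% c("K", "R")))
    return(NULL)
  means <- rolling_mean(kd_hydropathy(sequence), core_window)
  if (length(means) == 0L) return(NULL)
  starts <- which(means > threshold)
  starts <- starts[starts + core_window - 1L <= core_max_end]
  if (length(starts) == 0L) return(NULL)
  core_end <- starts[1L] + core_window - 1L
  after <- which(aa %in% c("G", "A", "S"))
  after <- after[after > core_end]
  end <- if (length(after) > 0L) min(after[1L], region_cap)
  else min(region_cap, length(aa))
  c(start = 1L, end = as.integer(end))
}

intervals_overlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

#' Classify a protein as integral-membrane or luminal
#'
#' Applies, in order: two or more TM segments make an integral membrane
#' protein (IMP); exactly one TM without a signal peptide makes an IMP;
#' one TM overlapping the signal-peptide region is the ambiguous case a
#' hydrophobic core cannot resolve and is decided by literature evidence
#' (IMP only when `literature_imp` is `TRUE`, configurable); a signal
#' peptide alone makes a luminal protein; neither makes a luminal
#' protein presumably imported by an unknown route.
#'
#' @param annotation A [protein_annotation()] with resolved
#'   `tm_segments` and `has_signal_peptide`.
#' @param overlap_default Class for the unresolved single-TM/SP overlap
#'   case when no literature flag is available: `"luminal"` (default) or
#'   `"IMP"`.
#' @return A list of class `LocalizationCall` with `protein_id`, `class`
#'   (one of `IMP`, `luminal_with_SP`, `luminal_no_SP_no_TM`) and
#'   `basis`.
#' @export
classify_localization <- function(annotation,
                                  overlap_default = c("luminal", "IMP")) {
  overlap_default <- match.arg(overlap_default)
  segs <- annotation$tm_segments
  ntm <- if (is.null(segs)) 0L else nrow(segs)
  has_sp <- isTRUE(annotation$has_signal_peptide)
  call <- if (ntm >= 2L) {
    list(class = "IMP", basis = "multi_TM")
  } else if (ntm == 1L && !has_sp) {
    list(class = "IMP", basis = "single_TM_no_SP")
  } else if (ntm == 1L && has_sp) {
    spr <- annotation$sp_region
    if (is.null(spr)) spr <- c(1L, 40L)  # region unknown: assume N-terminal
    if (intervals_overlap(segs[1L, ], spr)) {
      imp <- if (!is.na(annotation$literature_imp))
        isTRUE(annotation$literature_imp) else overlap_default == "IMP"
      list(class = if (imp) "IMP" else "luminal_with_SP",
           basis = "SP_TM_overlap_resolved_literature")
    } else {
      warning("protein ", annotation$protein_id,
              " has one TM and a non-overlapping signal peptide; ",
              "classified IMP")
      list(class = "IMP", basis = "single_TM_no_SP")
    }
  } else if (has_sp) {
    list(class = "luminal_with_SP", basis = "SP_only")
  } else {
    list(class = "luminal_no_SP_no_TM", basis = "neither")
  }
  structure(c(list(protein_id = annotation$protein_id), call),
            class = "LocalizationCall")
}

#' Infer membrane orientation from labelable-residue distribution
#'
#' Partitions the sequence into the N-terminal region, inter-TM loops
#' and the C-terminal region, and counts APEX2-labelable residues in
#' each. Consecutive loops alternate sides of the membrane. If every
#' labelable residue falls in loops of a single alternation class and
#' that class carries at least one such residue, that class is inferred
#' to face the lumen (the protein was biotinylated by a luminal bait);
#' otherwise the orientation is ambiguous. Proteins with no labelable
#' residue at all are ambiguous.
#'
#' @param sequence Amino-acid string.
#' @param tm_segments Integer matrix with columns `start`, `end`;
#'   1-based inclusive, sorted, non-overlapping, at least one row,
#'   within the sequence.
#' @param labelable Residue letters counted as labelable, see
#'   [labelable_set()].
#' @return A list of class `TopologyCall`: `loops` (data.frame `start`,
#'   `end`, `side` in A/B where A contains the N-terminal region,
#'   `labelable_count`), `orientation` (`N_lumen` when the N-terminal
#'   loop's class faces the lumen, `C_lumen` for the other class,
#'   `ambiguous`), and `evidence_exclusive`.
#' @export
infer_topology <- function(sequence, tm_segments,
                           labelable = labelable_set()) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(aa)
  segs <- matrix(as.integer(tm_segments), ncol = 2)
  if (nrow(segs) < 1L) stop("at least one TM segment is required")
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  if (any(segs[, 1L] < 1L) || any(segs[, 2L] > L))
    stop("TM segment outside sequence")
  if (any(segs[, 2L] < segs[, 1L]) ||
      (nrow(segs) > 1L && any(segs[-1L, 1L] <= segs[-nrow(segs), 2L])))
    stop("TM segments must be sorted and non-overlapping")

  bounds <- rbind(c(1L, segs[1L, 1L] - 1L),
                  if (nrow(segs) > 1L)
                    cbind(segs[-nrow(segs), 2L] + 1L, segs[-1L, 1L] - 1L),
                  c(segs[nrow(segs), 2L] + 1L, L))
  loops <- data.frame(start = bounds[, 1L], end = bounds[, 2L],
                      side = rep(c("A", "B"), length.out = nrow(bounds)),
                      labelable_count = vapply(seq_len(nrow(bounds)),
                                               function(j) {
    if (bounds[j, 2L] < bounds[j, 1L]) return(0L)
    sum(aa[bounds[j, 1L]:bounds[j, 2L]] %in% labelable)
  }, integer(1)), stringsAsFactors = FALSE)

  count_a <- sum(loops$labelable_count[loops$side == "A"])
  count_b <- sum(loops$labelable_count[loops$side == "B"])
  orientation <- if (count_a > 0L && count_b == 0L) "N_lumen"
  else if (count_b > 0L && count_a == 0L) "C_lumen"
  else "ambiguous"
  structure(list(loops = loops, orientation = orientation,
                 evidence_exclusive = orientation != "ambiguous"),
            class = "TopologyCall")
}

#' @export
print.TopologyCall <- function(x, ...) {
  cat("Topology:", x$orientation,
      if (x$evidence_exclusive) "(exclusive labelable-residue evidence)\n"
      else "(evidence not exclusive)\n")
  for (j in seq_len(nrow(x$loops)))
    cat(sprintf("  loop %d-%d side %s: %d labelable\n", x$loops$start[j],
                x$loops$end[j], x$loops$side[j], x$loops$labelable_count[j]))
  invisible(x)
}

#' Classify and orient a set of annotated proteins
#'
#' Convenience wrapper producing one row per protein: the
#' integral-membrane / luminal class, its basis, the TM count and, for
#' proteins with TM segments and a sequence, the inferred orientation.
#' When `use_heuristics` is `TRUE`, proteins lacking imported TM / SP
#' annotations but carrying a sequence are annotated with the heuristic
#' predictors first.
#'
#' @param annotations Named list of [protein_annotation()] records.
#' @param labelable Labelable residue set.
#' @param overlap_default See [classify_localization()].
#' @param use_heuristics Fill missing TM/SP annotation from sequence.
#' @return data.frame with columns `protein_id`, `class`, `basis`,
#'   `n_tm`, `has_signal_peptide`, `orientation`, `loop_summary`.
#' @export
topology_table <- function(annotations, labelable = labelable_set(),
                           overlap_default = "luminal",
                           use_heuristics = FALSE) {
  rows <- lapply(annotations, function(ann) {
    if (use_heuristics && !is.na(ann$sequence)) {
      if (nrow(ann$tm_segments) == 0L)
        ann$tm_segments <- heuristic_tm_predict(ann$sequence)
      if (!ann$has_signal_peptide) {
        spr <- heuristic_sp_predict(ann$sequence)
        if (!is.null(spr)) {
          ann$has_signal_peptide <- TRUE
          ann$sp_region <- spr
        }
      }
    }
    loc <- classify_localization(ann, overlap_default = overlap_default)
    orientation <- NA_character_
    loop_summary <- ""
    if (nrow(ann$tm_segments) > 0L && !is.na(ann$sequence)) {
      topo <- infer_topology(ann$sequence, ann$tm_segments, labelable)
      orientation <- topo$orientation
      loop_summary <- paste(sprintf("%d-%d:%s:%d", topo$loops$start,
                                    topo$loops$end, topo$loops$side,
                                    topo$loops$labelable_count),
                            collapse = ";")
    }
    data.frame(protein_id = ann$protein_id, class = loc$class,
               basis = loc$basis, n_tm = nrow(ann$tm_segments),
               has_signal_peptide = ann$has_signal_peptide,
               orientation = orientation, loop_summary = loop_summary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
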