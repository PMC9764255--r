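polyseq <- function(...) paste(rep(c(...), each = 1), collapse = "")
rep_aa <- function(aa, n) paste(rep(aa, n), collapse = "")

test_that("heuristic TM predictor finds constructed hydrophobic cores", {
  one_tm <- paste0(rep_aa("D", 20), rep_aa("L", 25), rep_aa("D", 20))
  segs <- heuristic_tm_predict(one_tm)
  expect_equal(nrow(segs), 1L)
  # segment covers the Leu run; window arithmetic allows at most a
  # 5-residue overhang into the flanks (14 of 19 residues must be Leu)
  expect_lte(segs[1, "start"], 21L)
  expect_gte(segs[1, "end"], 45L)
  expect_lte(21L - segs[1, "start"], 5L)
  expect_lte(segs[1, "end"] - 45L, 5L)

  expect_equal(nrow(heuristic_tm_predict(rep_aa("D", 60))), 0L)
  expect_equal(nrow(heuristic_tm_predict("MKL")), 0L)  # shorter than window

  two_tm <- paste0(rep_aa("D", 15), rep_aa("L", 22), rep_aa("D", 30),
                   rep_aa("I", 22), rep_aa("D", 15))
  segs2 <- heuristic_tm_predict(two_tm)
  expect_equal(nrow(segs2), 2L)
  # direct window-scan oracle: all residues covered by a qualifying
  # window must fall inside some reported segment
  v <- kd_hydropathy(two_tm)
  w <- 19L
  covered <- rep(FALSE, nchar(two_tm))
  for (s in seq_len(nchar(two_tm) - w + 1L))
    if (mean(v[s:(s + w - 1L)]) > 1.6) covered[s:(s + w - 1L)] <- TRUE
  inside <- rep(FALSE, nchar(two_tm))
  for (r in seq_len(nrow(segs2)))
    inside[segs2[r, "start"]:segs2[r, "end"]] <- TRUE
  expect_identical(inside, covered)
  # segment lengths in the allowed TM-helix range
  lens <- segs2[, "end"] - segs2[, "start"] + 1L
  expect_true(all(lens >= 17L & lens <= 35L))
})

test_that("over-long merged hydrophobic regions are split", {
  long <- paste0(rep_aa("D", 10), rep_aa("L", 60), rep_aa("D", 10))
  segs <- heuristic_tm_predict(long)
  lens <- segs[, "end"] - segs[, "start"] + 1L
  expect_true(all(lens >= 17L & lens <= 35L))
  expect_gte(nrow(segs), 2L)
  # segments are consecutive and non-overlapping
  expect_true(all(segs[-1L, "start"] > segs[-nrow(segs), "end"]))
})

test_that("heuristic SP predictor on constructed N-termini", {
  sp <- paste0("MKK", rep_aa("L", 12), "ASD", rep_aa("D", 40))
  region <- heuristic_sp_predict(sp)
  expect_false(is.null(region))
  expect_equal(unname(region["start"]), 1L)
  expect_equal(unname(region["end"]), 16L)  # ends at the A after the core

  # hydrophobic core too deep in the sequence -> no call
  deep <- paste0("MKK", rep_aa("D", 46), rep_aa("L", 12), rep_aa("D", 20))
  expect_null(heuristic_sp_predict(deep))
  # no basic residue in the n-region -> no call
  nobasic <- paste0("MSS", rep_aa("L", 12), "A", rep_aa("D", 20))
  expect_null(heuristic_sp_predict(nobasic))
})

test_that("planted signal peptides are recalled at >= 0.9", {
  pr <- generate_proteome(simulation_params(seed = 17L))
  sp_bearing <- pr[pr$has_signal_peptide, ]
  expect_gt(nrow(sp_bearing), 20L)
  called <- vapply(sp_bearing$sequence,
                   function(s) !is.null(heuristic_sp_predict(s)), logical(1))
  expect_gte(mean(called), 0.9)
})

test_that("localization rules applied in order", {
  ann <- function(...) protein_annotation("X", ...)
  expect_equal(classify_localization(
    ann(tm_segments = rbind(c(10, 30), c(50, 70), c(90, 110))))$class, "IMP")
  expect_equal(classify_localization(
    ann(tm_segments = rbind(c(10, 30))))$basis, "single_TM_no_SP")
  # 1 TM overlapping the SP region, no literature flag -> luminal
  overlap <- ann(tm_segments = rbind(c(5, 25)), has_signal_peptide = TRUE,
                 sp_region = c(1, 26))
  call <- classify_localization(overlap)
  expect_equal(call$class, "luminal_with_SP")
  expect_equal(call$basis, "SP_TM_overlap_resolved_literature")
  # ... unless literature says IMP
  lit <- ann(tm_segments = rbind(c(5, 25)), has_signal_peptide = TRUE,
             sp_region = c(1, 26), literature_imp = TRUE)
  expect_equal(classify_localization(lit)$class, "IMP")
  # configurable default for the unresolved overlap
  expect_equal(classify_localization(overlap, overlap_default = "IMP")$class,
               "IMP")
  # SP only / neither
  expect_equal(classify_localization(
    ann(has_signal_peptide = TRUE, sp_region = c(1, 22)))$class,
    "luminal_with_SP")
  expect_equal(classify_localization(ann())$class, "luminal_no_SP_no_TM")
  # non-overlapping TM + SP: IMP with a warning
  expect_warning(
    res <- classify_localization(ann(tm_segments = rbind(c(60, 80)),
                                     has_signal_peptide = TRUE,
                                     sp_region = c(1, 20))),
    "non-overlapping")
  expect_equal(res$class, "IMP")
})

test_that("classification is total: the three classes partition any set", {
  pr <- generate_proteome(simulation_params(seed = 29L))
  anns <- lapply(seq_len(nrow(pr)), function(i)
    protein_annotation(pr$protein_id[i], sequence = pr$sequence[i],
                       tm_segments = pr$tm_segments[[i]],
                       has_signal_peptide = pr$has_signal_peptide[i],
                       sp_region = pr$sp_region[[i]]))
  names(anns) <- pr$protein_id
  tab <- topology_table(anns)
  expect_equal(nrow(tab), nrow(pr))
  expect_true(all(tab$class %in% c("IMP", "luminal_with_SP",
                                   "luminal_no_SP_no_TM")))
})

test_that("infer_topology implements the exclusive-evidence rule", {
  # cytochrome-f-like: long N-terminal region rich in labelable sites,
  # one TM, short quiet C-terminal tail -> N-terminus lumenal
  cytf <- paste0("MA", rep_aa("Y", 3), rep_aa("S", 30), "YY",
                 rep_aa("L", 21), rep_aa("S", 15))
  topo <- infer_topology(cytf, rbind(c(38, 58)))
  expect_equal(topo$orientation, "N_lumen")
  expect_true(topo$evidence_exclusive)

  # two TMs, single Y in the inter-TM loop only
  seq2 <- paste0(rep_aa("S", 10), rep_aa("L", 21), "SSYSS",
                 rep_aa("I", 21), rep_aa("S", 8))
  topo2 <- infer_topology(seq2, rbind(c(11, 31), c(37, 57)))
  expect_equal(topo2$orientation, "C_lumen")  # inter-TM loop is side B
  expect_equal(topo2$loops$labelable_count, c(0L, 1L, 0L))

  # labelable residues on both sides -> ambiguous
  both <- paste0("SYS", rep_aa("L", 21), "SYS")
  topo3 <- infer_topology(both, rbind(c(4, 24)))
  expect_equal(topo3$orientation, "ambiguous")
  expect_false(topo3$evidence_exclusive)

  # no labelable residues anywhere -> ambiguous
  none <- paste0("SSS", rep_aa("L", 21), "SSS")
  expect_equal(infer_topology(none, rbind(c(4, 24)))$orientation,
               "ambiguous")

  # TM outside sequence -> input error
  expect_error(infer_topology("SSSLLLSSS", rbind(c(5, 40))), "outside")
})

test_that("topology is invariant under non-labelable insertions and flips under reversal", {
  base <- paste0("SY", rep_aa("S", 8), rep_aa("L", 21), rep_aa("S", 6))
  tm <- rbind(c(11, 31))
  expect_equal(infer_topology(base, tm)$orientation, "N_lumen")
  # insert non-labelable residues into the N-terminal loop
  grown <- paste0("SGGGY", rep_aa("S", 8), rep_aa("L", 21), rep_aa("S", 6))
  expect_equal(infer_topology(grown, rbind(c(14, 34)))$orientation, "N_lumen")
  # reverse the sequence and mirror the TM coordinates
  L <- nchar(base)
  revseq <- paste(rev(strsplit(base, "")[[1]]), collapse = "")
  revtm <- rbind(c(L - tm[1, 2] + 1L, L - tm[1, 1] + 1L))
  expect_equal(infer_topology(revseq, revtm)$orientation, "C_lumen")
})
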