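#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("target", "ctrl_no_substrate", "ctrl_wildtype", "ctrl_cyto_bait")

#' Read an experimental design table
#'
#' The design maps each quantified sample to one of the four experimental
#' groups of a multi-control APEX2 proximity-labeling experiment: the bait
#' fusion with substrate (`target`), the bait fusion without biotin-phenol
#' (`ctrl_no_substrate`), the wild type with substrate (`ctrl_wildtype`),
#' and a cytoplasmic bait fusion (`ctrl_cyto_bait`).
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `group`, `replicate`, or a YAML file with a list of such records.
#' @return A `data.frame` with columns `sample_id` (character), `group`
#'   (factor with the four canonical levels) and `replicate` (integer).
#' @export
read_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    design <- do.call(rbind, lapply(recs, function(r) {
      data.frame(sample_id = as.character(r$sample_id),
                 group = as.character(r$group),
                 replicate = as.integer(r$replicate))
    }))
  } else {
    design <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  validate_design(design)
}

#' Validate a design data.frame
#'
#' Checks the structural invariants of a sample design: known group labels,
#' unique (group, replicate) pairs, and at least two target replicates,
#' which the presence filter requires.
#'
#' @param design A data.frame with columns `sample_id`, `group`, `replicate`.
#' @return The validated design with `group` as a factor.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "group", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0L)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(design$group), GROUP_LEVELS)
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  key <- paste(design$group, design$replicate)
  if (anyDuplicated(key))
    stop("duplicate (group, replicate) pair in design")
  if (sum(design$group == "target") < 2L)
    stop("design must contain at least two target replicates")
  design$sample_id <- as.character(design$sample_id)
  design$group <- factor(design$group, levels = GROUP_LEVELS)
  design$replicate <- as.integer(design$replicate)
  design
}

maxquant_flag_cols <- c(is_contaminant = "Potential contaminant",
                        is_decoy = "Reverse",
                        only_by_site = "Only identified by site")

#' Construct a QuantTable
#'
#' Low-level constructor for the protein-by-sample quantification container
#' every filtering step consumes. `intensities` holds label-free
#' quantification signals where 0 encodes "not detected"; `msms` holds
#' per-sample fragment-spectrum counts used as identification evidence.
#'
#' @param ids Character vector of protein (group) accessions, unique.
#' @param intensities Numeric matrix, proteins x samples, nonnegative.
#' @param msms Integer matrix of MS/MS counts with the same shape.
#' @param flags data.frame with logical columns `is_contaminant`,
#'   `is_decoy`, `only_by_site`, one row per protein.
#' @param design Validated design (see [read_design()]); its `sample_id`
#'   order defines the column order of both matrices.
#' @return An object of class `QuantTable`.
#' @export
quant_table <- function(ids, intensities, msms, flags, design) {
  design <- validate_design(design)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate protein accession: ",
                               ids[duplicated(ids)][1L])
  intensities <- as.matrix(intensities)
  msms <- as.matrix(msms)
  storage.mode(intensities) <- "double"
  storage.mode(msms) <- "integer"
  if (!identical(dim(intensities), dim(msms)))
    stop("intensity and MS/MS matrices must share shape")
  if (nrow(intensities) != length(ids))
    stop("matrix rows must match protein ids")
  if (ncol(intensities) != nrow(design))
    stop("matrix columns must match design samples")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  if (any(msms < 0)) stop("MS/MS counts must be nonnegative")
  dimnames(intensities) <- list(ids, design$sample_id)
  dimnames(msms) <- list(ids, design$sample_id)
  for (f in names(maxquant_flag_cols)) {
    if (is.null(flags[[f]])) flags[[f]] <- rep(FALSE, length(ids))
    flags[[f]] <- as.logical(flags[[f]])
  }
  flags <- data.frame(flags[names(maxquant_flag_cols)], row.names = ids)
  structure(list(ids = ids,
                 lead_ids = vapply(strsplit(ids, ";", fixed = TRUE), `[`,
                                   character(1), 1L),
                 intensities = intensities,
                 msms = msms,
                 flags = flags,
                 design = design),
            class = "QuantTable")
}

#' @export
print.QuantTable <- function(x, ...) {
  cat("QuantTable:", length(x$ids), "proteins x", nrow(x$design), "samples\n")
  cat("  groups:", paste(sprintf("%s(%d)", levels(x$design$group),
                                 table(x$design$group)), collapse = " "), "\n")
  cat("  flagged:", sum(rowSums(as.matrix(x$flags)) > 0), "\n")
  invisible(x)
}

#' @export
dim.QuantTable <- function(x) c(length(x$ids), nrow(x$design))

num0 <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[is.na(v)] <- 0
  v
}

#' Read a MaxQuant-style protein-groups table
#'
#' Expects a tab-delimited table with one `LFQ intensity <sample>` (or
#' `Intensity <sample>`) and one `MS/MS count <sample>` column for every
#' sample in the design. Contaminant / decoy / identified-by-site rows are
#' flagged, never dropped here (see [drop_flagged()]). Empty or
#' non-numeric quantification cells parse as 0 = not detected, matching
#' the search engine's convention.
#'
#' @param path Path to the tab-delimited protein-groups file.
#' @param design Validated design (see [read_design()]).
#' @param id_col Name of the accession column (default `"Protein IDs"`,
#'   falling back to the first column).
#' @return A [quant_table()] object.
#' @export
read_protein_groups <- function(path, design, id_col = "Protein IDs") {
  design <- validate_design(design)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!id_col %in% names(tab)) id_col <- names(tab)[1L]
  ids <- tab[[id_col]]

  pick <- function(prefixes, sample, kind) {
    for (p in prefixes) {
      col <- paste(p, sample)
      if (col %in% names(tab)) return(col)
    }
    stop(sprintf("missing required %s column for sample '%s' (looked for %s)",
                 kind, sample,
                 paste(sprintf("'%s %s'", prefixes, sample), collapse = ", ")))
  }
  int_cols <- vapply(design$sample_id, pick, character(1),
                     prefixes = c("LFQ intensity", "Intensity"),
                     kind = "intensity")
  msms_cols <- vapply(design$sample_id, pick, character(1),
                      prefixes = c("MS/MS count", "MS/MS Count"),
                      kind = "MS/MS count")
  intens <- vapply(int_cols, function(cl) num0(tab[[cl]]),
                   numeric(nrow(tab)))
  msms <- vapply(msms_cols, function(cl) num0(tab[[cl]]),
                 numeric(nrow(tab)))
  if (nrow(tab) == 1L) {  # vapply collapses to vector
    intens <- matrix(intens, nrow = 1L)
    msms <- matrix(msms, nrow = 1L)
  }

  marker <- function(col, prefix) {
    if (col %in% names(tab)) tab[[col]] %in% c("+", "TRUE", "1")
    else startsWith(ids, prefix)
  }
  flags <- list(
    is_contaminant = marker("Potential contaminant", "CON__"),
    is_decoy = marker("Reverse", "REV__"),
    only_by_site = marker("Only identified by site", ""))  # no prefix form
  quant_table(ids, intens, round(msms), flags, design)
}

#' Write a QuantTable back to the protein-groups dialect
#'
#' Emits the same tab-delimited format [read_protein_groups()] reads, so
#' that write/read round-trips are lossless for intensities and MS/MS
#' counts.
#'
#' @param table A `QuantTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  out <- data.frame(`Protein IDs` = table$ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(table$design))) {
    s <- table$design$sample_id[j]
    out[[paste("LFQ intensity", s)]] <- format(table$intensities[, j],
                                               digits = 17, trim = TRUE,
                                               scientific = FALSE)
    out[[paste("MS/MS count", s)]] <- table$msms[, j]
  }
  for (f in names(maxquant_flag_cols))
    out[[maxquant_flag_cols[[f]]]] <- ifelse(table$flags[[f]], "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop flagged rows from a QuantTable
#'
#' Removes proteins marked as contaminant, decoy, or identified only by a
#' modification site. Row order of the survivors is preserved and the
#' operation is idempotent.
#'
#' @param table A `QuantTable`.
#' @return A `QuantTable` restricted to unflagged rows.
#' @export
drop_flagged <- function(table) {
  keep <- rowSums(as.matrix(table$flags)) == 0
  subset_quant(table, keep)
}

subset_quant <- function(table, idx) {
  quant_table(table$ids[idx],
              table$intensities[idx, , drop = FALSE],
              table$msms[idx, , drop = FALSE],
              table$flags[idx, , drop = FALSE],
              table$design)
}

parse_interval <- function(txt, what = "interval") {
  m <- regmatches(txt, regexec("^([0-9]+)-([0-9]+)$", txt))[[1L]]
  if (length(m) != 3L) stop("malformed ", what, ": '", txt, "'")
  iv <- c(as.integer(m[2L]), as.integer(m[3L]))
  if (iv[2L] < iv[1L]) stop(what, " end precedes start: '", txt, "'")
  iv
}

parse_tm_field <- function(txt) {
  txt <- trimws(txt)
  if (is.na(txt) || txt == "") return(matrix(integer(), 0, 2,
                                             dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  segs <- t(vapply(parts, parse_interval, integer(2), what = "TM segment"))
  dimnames(segs) <- list(NULL, c("start", "end"))
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  if (nrow(segs) > 1L && any(segs[-1L, "start"] <= segs[-nrow(segs), "end"]))
    stop("overlapping TM segments: '", txt, "'")
  segs
}

#' Construct a per-protein annotation record
#'
#' Holds imported transmembrane-segment and signal-peptide predictions
#' (e.g. from TMHMM / SignalP runs), category memberships and optional
#' literature localization flags. Coordinates are 1-based inclusive.
#'
#' @param protein_id Accession.
#' @param sequence Optional amino-acid string.
#' @param tm_segments Integer matrix with columns start, end; sorted,
#'   non-overlapping.
#' @param has_signal_peptide Logical.
#' @param sp_region Optional c(start, end); must start at residue 1.
#' @param categories Character vector of category labels.
#' @param literature_imp,literature_luminal Optional logical literature
#'   evidence flags used to resolve ambiguous single-TM/signal-peptide
#'   calls.
#' @return An object of class `ProteinAnnotation`.
#' @export
protein_annotation <- function(protein_id, sequence = NA_character_,
                               tm_segments = NULL,
                               has_signal_peptide = FALSE, sp_region = NULL,
                               categories = character(),
                               literature_imp = NA,
                               literature_luminal = NA) {
  if (is.null(tm_segments))
    tm_segments <- matrix(integer(), 0, 2,
                          dimnames = list(NULL, c("start", "end")))
  tm_segments <- matrix(as.integer(tm_segments), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  if (nrow(tm_segments) > 1L) {
    tm_segments <- tm_segments[order(tm_segments[, 1L]), , drop = FALSE]
    if (any(tm_segments[-1L, 1L] <= tm_segments[-nrow(tm_segments), 2L]))
      stop("overlapping TM segments for ", protein_id)
  }
  if (any(tm_segments[, 2L] < tm_segments[, 1L]))
    stop("TM segment end precedes start for ", protein_id)
  if (!is.na(sequence) && nrow(tm_segments) > 0L &&
      max(tm_segments[, 2L]) > nchar(sequence))
    stop("TM segment outside sequence for ", protein_id)
  if (!is.null(sp_region)) {
    if (sp_region[1L] != 1L)
      stop("signal-peptide region must start at residue 1 for ", protein_id)
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 tm_segments = tm_segments,
                 has_signal_peptide = isTRUE(has_signal_peptide),
                 sp_region = sp_region,
                 categories = unique(categories),
                 literature_imp = literature_imp,
                 literature_luminal = literature_luminal),
            class = "ProteinAnnotation")
}

#' Read a protein annotation table
#'
#' Tab-delimited columns: `protein_id`, `tm_segments` (intervals encoded
#' `start-end`, semicolon-separated, empty for none), `signal_peptide`
#' (0/1), and optionally `sp_region` (`start-end`), `categories`
#' (comma-separated), `literature_imp`, `literature_luminal` (0/1, empty
#' for unknown).
#'
#' @param path Path to the annotation file.
#' @param sequences Optional named character vector of sequences (from
#'   [read_fasta_seqs()]) attached to matching records.
#' @return Named list of [protein_annotation()] records.
#' @export
read_annotations <- function(path, sequences = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"protein_id" %in% names(tab))
    stop("annotation file must have a 'protein_id' column")
  get <- function(col, i, default = "") {
    if (col %in% names(tab)) tab[[col]][i] else default
  }
  as_flag <- function(x, default = NA) {
    if (is.na(x) || x == "") default else x %in% c("1", "TRUE", "+")
  }
  ann <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$protein_id[i]
    spr_txt <- trimws(get("sp_region", i))
    spr <- if (!is.na(spr_txt) && nzchar(spr_txt))
      parse_interval(spr_txt, "sp_region") else NULL
    cats <- trimws(strsplit(get("categories", i), ",", fixed = TRUE)[[1L]])
    protein_annotation(
      protein_id = id,
      sequence = if (!is.null(sequences) && id %in% names(sequences))
        sequences[[id]] else NA_character_,
      tm_segments = parse_tm_field(get("tm_segments", i)),
      has_signal_peptide = as_flag(get("signal_peptide", i), FALSE),
      sp_region = spr,
      categories = cats[nzchar(cats)],
      literature_imp = as_flag(get("literature_imp", i)),
      literature_luminal = as_flag(get("literature_luminal", i)))
  })
  names(ann) <- tab$protein_id
  if (anyDuplicated(names(ann))) stop("duplicate protein_id in annotations")
  ann
}

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of each header.
#' Sequences are upper-cased; residues outside the 20 standard amino
#' acids are kept but reported via a message.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, accession to sequence.
#' @export
read_fasta_seqs <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate accession in FASTA: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  odd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(odd))
    message(sum(odd), " sequence(s) contain non-standard residues: ",
            paste(utils::head(ids[odd], 5), collapse = ", "))
  seqs
}
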