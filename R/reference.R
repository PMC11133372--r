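## Clone reference construction: parent scFv inserts plus one-by-one alanine
## scans of the five epitope-contact residues of each parent.
##
## The shipped DNA inserts are synthetic placeholders: real variable-region
## sequences are not required because clone assignment uses only the
## amino-acid window over the mutated region, which must (a) carry the named
## residues at the named protein positions and (b) be unique per clone.

## Shared 3' flank mimicking the Gly/Ser linker the reverse primer anneals to.
.insert_flank3 <- "GGTGGAGGCGGTTCAGGCGGAGGTGGCTCTGGCGGTGGCGGAT"

.alanine_codons <- c("GCA", "GCC", "GCG", "GCT")

#' Parent scFv panel (synthetic inserts)
#'
#' Four parent query antibodies: the pertuzumab-derived scFv (Per), the
#' trastuzumab-derived scFv (Tra), and two non-binders of the displayed
#' antigen (Dac, daclizumab-derived; Niv, nivolumab-derived). Each record
#' carries a synthetic DNA insert whose reading frame starts
#' `frame_offset` bases into the insert and encodes a 15-residue
#' amino-acid window; `window_offset` is the protein position (1-based
#' numbering of the full scFv) of the first window residue, so that the
#' Per window spans residues 48-62 (epitope contacts N52-G56) and the Tra
#' window spans residues 97-111 (contacts G101-Y105).
#'
#' @return A data frame with one row per parent clone.
#' @export
parent_scfv_panel <- function() {
  windows <- c(
    Per = "TYNMNPNSGGSTSYA",  # residues 48-62; 52-56 = N P N S G
    Tra = "SRWGGDGFYAMDYWG",  # residues 97-111; 101-105 = G D G F Y
    Dac = "SGYRMHWIKQRPGQG",
    Niv = "NTGSHWLEQAPGKGL"
  )
  data.frame(
    clone_id = names(windows),
    lineage = c("pertuzumab", "trastuzumab", "none", "none"),
    blocked_epitope = c("HER2-ECD2", "HER2-ECD4", NA_character_, NA_character_),
    kd_qab = c(1, 1, Inf, Inf),
    dna_insert = paste0("G", reverse_translate(unname(windows)), .insert_flank3),
    window_offset = c(48L, 97L, 1L, 1L),
    frame_offset = 1L,
    stringsAsFactors = FALSE
  )
}

#' Alanine-scan mutation table for the HER2 panel
#'
#' One row per single-alanine mutant: five consecutive epitope-contact
#' residues of each parent replaced by alanine one-by-one, with the frozen
#' antigen dissociation constant assigned to each mutant.
#'
#' @return Data frame with columns `parent`, `position` (1-based protein
#'   numbering), `original`, `replacement`, `kd_qab`.
#' @export
her2_mutation_table <- function() {
  data.frame(
    parent = rep(c("Per", "Tra"), each = 5L),
    position = c(52:56, 101:105),
    original = c("N", "P", "N", "S", "G", "G", "D", "G", "F", "Y"),
    replacement = "A",
    kd_qab = c(60, 2, 5, 12, 20,    # Per-N52A .. Per-G56A
               12, 2, 5, 20, 40),   # Tra-G101A .. Tra-Y105A
    stringsAsFactors = FALSE
  )
}

#' Build a clone reference from parents and an alanine-mutation table
#'
#' For each mutation the parent's insert is edited by the minimal codon change
#' producing the alanine substitution (the alanine codon closest in Hamming
#' distance to the original codon; ties broken alphabetically), and the
#' amino-acid window is re-derived by translation. The stated original residue
#' is checked against the parent sequence; a mismatch is an error.
#'
#' @param parents Data frame as returned by [parent_scfv_panel()].
#' @param mutations Data frame as returned by [her2_mutation_table()].
#' @param window_codons Number of codons in the assignment window.
#' @return A `clone_reference` data frame: `clone_id`, `lineage`,
#'   `blocked_epitope`, `kd_qab` (nM; `Inf` marks an antigen non-binder),
#'   `dna_insert`, `aa_window`, `window_offset`, `frame_offset`.
#' @export
build_clone_reference <- function(parents = parent_scfv_panel(),
                                  mutations = her2_mutation_table(),
                                  window_codons = 15L) {
  stopifnot(is.data.frame(parents), is.data.frame(mutations))
  parents$aa_window <- translate_dna(parents$dna_insert,
                                     frame = parents$frame_offset[1L] + 1L)
  parents$aa_window <- substr(parents$aa_window, 1L, window_codons)

  rows <- vector("list", nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    p <- parents[parents$clone_id == m$parent, , drop = FALSE]
    if (nrow(p) != 1L) stop("unknown parent clone: ", m$parent, call. = FALSE)
    ci <- m$position - p$window_offset + 1L   # codon index within the window
    if (ci < 1L || ci > window_codons) {
      stop("mutation position ", m$position, " outside the window of ",
           m$parent, call. = FALSE)
    }
    observed <- substr(p$aa_window, ci, ci)
    if (observed != m$original) {
      stop(sprintf(
        "mutation table inconsistent: %s position %d is '%s' in the parent, not '%s'",
        m$parent, m$position, observed, m$original), call. = FALSE)
    }
    base0 <- p$frame_offset + 3L * (ci - 1L)  # bases before the codon
    codon <- substr(p$dna_insert, base0 + 1L, base0 + 3L)
    if (m$replacement != "A") {
      stop("only alanine replacements are supported", call. = FALSE)
    }
    dist <- vapply(.alanine_codons, function(ac) {
      sum(strsplit(ac, "")[[1L]] != strsplit(codon, "")[[1L]])
    }, integer(1L))
    new_codon <- .alanine_codons[which.min(dist)]  # ties -> alphabetical order
    dna <- p$dna_insert
    substr(dna, base0 + 1L, base0 + 3L) <- new_codon
    row <- p
    row$clone_id <- sprintf("%s-%s%d%s", m$parent, m$original, m$position,
                            m$replacement)
    row$kd_qab <- m$kd_qab
    row$dna_insert <- dna
    row$aa_window <- substr(translate_dna(dna, frame = p$frame_offset + 1L),
                            1L, window_codons)
    rows[[i]] <- row
  }
  ref <- rbind(parents, do.call(rbind, rows))
  ref <- ref[order(ref$clone_id), , drop = FALSE]
  rownames(ref) <- NULL
  if (anyDuplicated(ref$clone_id)) stop("duplicate clone_id", call. = FALSE)
  if (anyDuplicated(ref$aa_window)) {
    stop("amino-acid windows are not unique across clones", call. = FALSE)
  }
  class(ref) <- c("clone_reference", "data.frame")
  ref
}

#' Library composition for the skewed 14-clone binning experiment
#'
#' Pre-sort clone frequencies of the shipped fixture: the pertuzumab lineage
#' and the non-binder Niv are abundant (Niv at 36%), the trastuzumab lineage
#' and Dac are rare, with Tra-G103A at 0.018%. Frequencies sum to 1.
#'
#' @return Named numeric vector of fractions.
#' @export
binning_library_frequencies <- function() {
  f <- c(
    Niv = 0.36,
    Per = 0.11, `Per-N52A` = 0.08, `Per-P53A` = 0.08, `Per-N54A` = 0.08,
    `Per-S55A` = 0.08, `Per-G56A` = 0.08,
    Tra = 0.04, `Tra-D102A` = 0.025, `Tra-G101A` = 0.025,
    `Tra-F104A` = 0.01, `Tra-Y105A` = 0.00982, `Tra-G103A` = 0.00018,
    Dac = 0.02
  )
  stopifnot(abs(sum(f) - 1) < 1e-9)
  f
}

#' The shipped 14-clone HER2 reference
#'
#' Builds the full panel (two parents, ten alanine mutants, two antigen
#' non-binders) and attaches library frequencies.
#'
#' @param frequencies Named vector of library fractions (must cover every
#'   clone and sum to 1), or `NULL` to attach uniform frequencies.
#' @return A `clone_reference` data frame with a `library_frequency` column.
#' @export
her2_scfv_reference <- function(frequencies = binning_library_frequencies()) {
  ref <- build_clone_reference()
  if (is.null(frequencies)) {
    frequencies <- stats::setNames(rep(1 / nrow(ref), nrow(ref)), ref$clone_id)
  }
  if (!setequal(names(frequencies), ref$clone_id)) {
    stop("`frequencies` must name every clone in the reference", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("library frequencies must sum to 1", call. = FALSE)
  }
  ref$library_frequency <- as.numeric(frequencies[ref$clone_id])
  ref
}

#' Reference antibody panel
#'
#' Fluorescent reference antibodies probing the two HER2 epitopes:
#' pertuzumab (extracellular domain II, AF647 channel) and trastuzumab
#' (extracellular domain IV, AF488 channel).
#'
#' @param concentration Staining concentration in nM (recycled over rAbs).
#' @param kd_rab rAb-antigen dissociation constant in nM.
#' @return Data frame with columns `rab_id`, `epitope_id`, `concentration`,
#'   `kd_rab`, `channel`.
#' @export
rab_panel <- function(concentration = 0.1, kd_rab = 1) {
  data.frame(
    rab_id = c("pertuzumab", "trastuzumab"),
    epitope_id = c("HER2-ECD2", "HER2-ECD4"),
    concentration = rep_len(concentration, 2L),
    kd_rab = rep_len(kd_rab, 2L),
    channel = c("AF647", "AF488"),
    stringsAsFactors = FALSE
  )
}

#' Write / read a clone reference
#'
#' The TSV clone table is the authoritative on-disk form (it carries every
#' field); a DNA FASTA of the inserts is written alongside for use with
#' external tools.
#'
#' @param reference A `clone_reference` data frame.
#' @param tsv Path of the clone table TSV.
#' @param fasta Optional path of a DNA FASTA of the inserts (`NULL` to skip).
#' @return `write_clone_reference()` returns `tsv` invisibly;
#'   `read_clone_reference()` returns a `clone_reference`.
#' @export
write_clone_reference <- function(reference, tsv, fasta = NULL) {
  utils::write.table(as.data.frame(reference), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", reference$clone_id),
                               reference$dna_insert)), fasta)
  }
  invisible(tsv)
}

#' @rdname write_clone_reference
#' @export
read_clone_reference <- function(tsv) {
  ref <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  needed <- c("clone_id", "lineage", "blocked_epitope", "kd_qab",
              "dna_insert", "aa_window", "frame_offset")
  missing <- setdiff(needed, names(ref))
  if (length(missing)) {
    stop("clone table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(ref) <- c("clone_reference", "data.frame")
  ref
}
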