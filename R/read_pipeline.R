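## Read processing: sliding-window quality trimming, primer-match retention,
## barcode demultiplexing, translation, exact-window clone assignment.
##
## The trimmer re-implements the published sliding-window operator with the
## cited parameters (window 20, mean quality 20, minimum length 50):
## scanning 5'->3', the read is cut immediately before the first base of the
## first full-length window whose mean quality falls below the floor; reads
## shorter than the window are judged as a single window of their full
## length; trimmed reads shorter than `min_len` are dropped.

## Kept length of each read after sliding-window trimming.
trim_lengths <- function(quality, window, min_mean_q) {
  n <- length(quality)
  if (n == 0L) return(integer(0L))
  lens <- nchar(quality)
  out <- integer(n)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    q <- matrix(utf8ToInt(paste(quality[sel], collapse = "")) - 33L,
                nrow = L)
    if (L < window) {
      out[sel] <- ifelse(colMeans(q) < min_mean_q, 0L, L)
      next
    }
    cum <- q
    if (L >= 2L) for (j in 2:L) cum[j, ] <- cum[j - 1L, ] + q[j, ]
    n_win <- L - window + 1L
    cut <- rep.int(L, length(sel))
    # scan windows from the last to the first so `cut` ends at the FIRST
    # failing window's start (0 kept bases before window 1, etc.)
    for (i in n_win:1) {
      lo <- if (i == 1L) 0L else cum[i - 1L, ]
      fail <- (cum[i + window - 1L, ] - lo) / window < min_mean_q
      cut[fail] <- i - 1L
    }
    out[sel] <- cut
  }
  out
}

#' Sliding-window quality filter
#'
#' @param reads A `read_set` data frame.
#' @param window Window length in bases.
#' @param min_mean_q Minimum window mean Phred quality.
#' @param min_len Minimum retained read length after trimming.
#' @return A `read_set` of retained (possibly trimmed) reads, with attribute
#'   `"n_dropped"` (dropping is a normal outcome, tallied in QC).
#' @export
quality_filter <- function(reads, window = 20L, min_mean_q = 20,
                           min_len = 50L) {
  stopifnot(window >= 1L)
  keep_len <- trim_lengths(reads$quality, window, min_mean_q)
  keep <- keep_len >= min_len
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, keep_len[keep])
  out$quality <- substr(out$quality, 1L, keep_len[keep])
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Primer matching and barcode demultiplexing
#'
#' A read is primer-matched when the forward primer occurs at the offset
#' equal to the barcode length with at most `max_primer_mismatch`
#' substitutions. The barcode (first `barcode_length` bases) is then matched
#' exactly against the design's sample barcodes; failure of either step is a
#' normal outcome tallied separately.
#'
#' @param reads A `read_set`.
#' @param design An [amplicon_design()].
#' @param max_primer_mismatch Allowed substitutions in the primer.
#' @return Data frame with `read_id`, `primer_matched` (logical) and
#'   `sample_id` (`NA` when unassigned).
#' @export
demux_and_match <- function(reads, design, max_primer_mismatch = 0L) {
  stopifnot(inherits(design, "amplicon_design"))
  bl <- design$barcode_length
  primer <- design$fwd_primer
  pl <- nchar(primer)
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(read_id = character(0L), primer_matched = logical(0L),
                      sample_id = character(0L), stringsAsFactors = FALSE))
  }
  region <- substr(reads$sequence, bl + 1L, bl + pl)
  long_enough <- nchar(reads$sequence) >= bl + pl
  if (max_primer_mismatch == 0L) {
    matched <- long_enough & region == primer
  } else {
    mism <- integer(n)
    for (j in seq_len(pl)) {
      mism <- mism + (substr(region, j, j) != substr(primer, j, j))
    }
    matched <- long_enough & mism <= max_primer_mismatch
  }
  bc2sample <- stats::setNames(names(design$sample_barcodes),
                               design$sample_barcodes)
  sample_id <- unname(bc2sample[substr(reads$sequence, 1L, bl)])
  sample_id[!matched] <- NA_character_
  data.frame(read_id = reads$read_id, primer_matched = matched,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Translate the assignment window and assign clones
#'
#' Extracts the in-frame segment starting `insert_frame_offset` bases after
#' the primer, translates it with the standard genetic code, and compares
#' the window residues by exact string equality against the reference
#' windows. Reads too short to cover the window, with ambiguous bases, or
#' with a stop codon inside the window are unassigned.
#'
#' @param reads A `read_set` (already primer-matched and demultiplexed).
#' @param design An [amplicon_design()].
#' @param reference A `clone_reference`.
#' @return Character vector of clone ids (`NA` = unassigned).
#' @export
translate_and_assign <- function(reads, design, reference) {
  stopifnot(inherits(design, "amplicon_design"))
  n <- nrow(reads)
  if (n == 0L) return(character(0L))
  start <- design$barcode_length + nchar(design$fwd_primer) +
    design$insert_frame_offset + 1L
  span <- 3L * design$aa_window_codons
  out <- rep(NA_character_, n)
  covered <- nchar(reads$sequence) >= start + span - 1L
  seg <- substr(reads$sequence[covered], start, start + span - 1L)
  clean <- !grepl("[^ACGT]", seg)
  aa <- rep(NA_character_, length(seg))
  aa[clean] <- translate_fixed(seg[clean], design$aa_window_codons)
  aa[!is.na(aa) & grepl("[*X]", aa)] <- NA_character_
  out[covered] <- reference$clone_id[match(aa, reference$aa_window)]
  out
}

#' Process a sequencing run into per-sample clone count tables
#'
#' Applies quality filtering, primer matching, barcode demultiplexing and
#' clone assignment to every read, and returns one `count_table` per sample
#' with the QC tally chain
#' `reads_assigned <= reads_demuxed <= reads_primer_matched <=
#' reads_after_quality <= reads_in`
#' (`reads_in` through `reads_primer_matched` are run-level tallies;
#' `reads_demuxed`/`reads_assigned` are per sample). The chain invariant is
#' asserted on every run.
#'
#' @param fastq Path to a FASTQ file (plain or gzip) or a `read_set`.
#' @param design An [amplicon_design()].
#' @param reference A `clone_reference`.
#' @param samples Sample ids to report (default: all in the design).
#' @param window,min_mean_q,min_len Quality-filter parameters.
#' @param max_primer_mismatch Allowed primer substitutions.
#' @return Named list of `count_table` objects (one per sample), with a
#'   `"qc_global"` attribute holding the run-level tallies.
#' @export
process_run <- function(fastq, design, reference,
                        samples = names(design$sample_barcodes),
                        window = 20L, min_mean_q = 20, min_len = 50L,
                        max_primer_mismatch = 0L) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  stopifnot(is.data.frame(reads))
  n_in <- nrow(reads)
  kept <- quality_filter(reads, window = window, min_mean_q = min_mean_q,
                         min_len = min_len)
  n_quality <- nrow(kept)
  dm <- demux_and_match(kept, design, max_primer_mismatch = max_primer_mismatch)
  n_primer <- sum(dm$primer_matched)
  assignable <- !is.na(dm$sample_id)
  clone <- rep(NA_character_, n_quality)
  clone[assignable] <- translate_and_assign(kept[assignable, , drop = FALSE],
                                            design, reference)
  qc_global <- c(reads_in = n_in, reads_after_quality = n_quality,
                 reads_primer_matched = n_primer)
  clones <- reference$clone_id
  tables <- lapply(samples, function(s) {
    in_sample <- !is.na(dm$sample_id) & dm$sample_id == s
    assigned <- in_sample & !is.na(clone)
    counts <- table(factor(clone[assigned], levels = clones))
    ct <- list(
      sample_id = s,
      counts = stats::setNames(as.integer(counts), clones),
      qc = c(qc_global,
             reads_demuxed = sum(in_sample),
             reads_assigned = sum(assigned))
    )
    class(ct) <- "count_table"
    validate_count_table(ct)
    ct
  })
  names(tables) <- samples
  attr(tables, "qc_global") <- qc_global
  tables
}

validate_count_table <- function(ct) {
  qc <- ct$qc
  chain <- c(qc[["reads_assigned"]], qc[["reads_demuxed"]],
             qc[["reads_primer_matched"]], qc[["reads_after_quality"]],
             qc[["reads_in"]])
  if (is.unsorted(chain)) {
    stop("QC tally chain violated for sample ", ct$sample_id, call. = FALSE)
  }
  if (sum(ct$counts) != qc[["reads_assigned"]]) {
    stop("count/QC mismatch for sample ", ct$sample_id, call. = FALSE)
  }
  invisible(ct)
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> sample:", x$sample_id, "\n")
  cat("  QC:", paste(names(x$qc), x$qc, sep = "=", collapse = ", "), "\n")
  top <- sort(x$counts, decreasing = TRUE)
  top <- top[top > 0]
  cat("  assigned clones:", length(top), "; top:",
      paste(utils::head(names(top), 5L), utils::head(top, 5L),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a count table (and optionally its QC tallies)
#'
#' @param ct A `count_table` or named list of them.
#' @param path TSV output path (columns `sample_id`, `clone_id`, `count`).
#' @param qc_path Optional JSON path for the QC tallies.
#' @export
write_count_table <- function(ct, path, qc_path = NULL) {
  cts <- if (inherits(ct, "count_table")) list(ct) else ct
  df <- do.call(rbind, lapply(cts, function(x) {
    data.frame(sample_id = x$sample_id, clone_id = names(x$counts),
               count = unname(x$counts), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(qc_path)) {
    qc <- lapply(cts, function(x) as.list(x$qc))
    names(qc) <- vapply(cts, `[[`, "", "sample_id")
    jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a count table TSV written by [write_count_table()]
#'
#' @param path TSV path.
#' @param sample_id Sample to extract (default: the single sample present).
#' @return A `count_table` (QC tallies reconstructed from the counts alone).
#' @export
read_count_table <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    ids <- unique(df$sample_id)
    if (length(ids) != 1L) {
      stop("file holds several samples; supply `sample_id`", call. = FALSE)
    }
    sample_id <- ids
  }
  df <- df[df$sample_id == sample_id, , drop = FALSE]
  total <- sum(df$count)
  ct <- list(sample_id = sample_id,
             counts = stats::setNames(as.integer(df$count), df$clone_id),
             qc = c(reads_in = total, reads_after_quality = total,
                    reads_primer_matched = total, reads_demuxed = total,
                    reads_assigned = total))
  class(ct) <- "count_table"
  ct
}
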