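## Single-end amplicon read architecture:
##   [6-bp sample barcode][nested forward primer][clone insert ...]
## truncated to the read length, with iid substitution errors and per-base
## qualities drawn around a position-dependent profile (Phred+33 on disk).

.barcode_pool <- c(
  "AACCGG", "CCTTAA", "GGAATT", "TTGGCC", "ACACGT", "GTGTCA",
  "CAGTCA", "TCATGC", "AGGCTA", "GTCCAT", "TGACCT", "CATGGA"
)

.fwd_primer_default <- "TGGGTAAGACAAGCTCCAGG"
.rev_primer_default <- "CCTTGTCCCCAATAGTC"

#' Default per-position quality profile
#'
#' High-quality head (Q35) with a linearly decaying tail starting at 80% of
#' the read length and reaching Q5 at the final base, so that the
#' sliding-window trimmer engages on the tail of typical reads.
#'
#' @param read_length Read length in bases.
#' @return Integer vector of expected Phred scores.
#' @export
default_quality_profile <- function(read_length) {
  stopifnot(read_length >= 1L)
  q <- rep(35, read_length)
  tail_start <- floor(0.8 * read_length) + 1L
  if (tail_start <= read_length) {
    q[tail_start:read_length] <-
      round(seq(35, 5, length.out = read_length - tail_start + 1L))
  }
  as.integer(q)
}

#' Amplicon design
#'
#' Describes the read architecture: sample barcodes, primers, read length,
#' reading-frame offset of the insert, assignment-window span (in codons)
#' and the sequencing error/quality model.
#'
#' @param samples Character vector of sample ids; barcodes are taken in
#'   order from an internal pool unless `sample_barcodes` is given.
#' @param sample_barcodes Named character vector (sample id -> 6-mer),
#'   overriding `samples`.
#' @param fwd_primer,rev_primer Nested PCR primers (the reverse primer is
#'   carried for completeness; reads are forward single-end).
#' @param read_length Read length in bases.
#' @param barcode_length Barcode length (bases).
#' @param insert_frame_offset Bases from the primer end to the first full
#'   codon of the insert.
#' @param aa_window_codons Codons in the clone-assignment window.
#' @param per_base_error_rate iid substitution error probability per base.
#' @param quality_profile Per-position expected Phred scores
#'   (length `read_length`).
#' @return List of class `amplicon_design`.
#' @export
amplicon_design <- function(samples = "library",
                            sample_barcodes = NULL,
                            fwd_primer = .fwd_primer_default,
                            rev_primer = .rev_primer_default,
                            read_length = 110L,
                            barcode_length = 6L,
                            insert_frame_offset = 1L,
                            aa_window_codons = 15L,
                            per_base_error_rate = 0.001,
                            quality_profile = default_quality_profile(read_length)) {
  if (is.null(sample_barcodes)) {
    if (length(samples) > length(.barcode_pool)) {
      stop("not enough barcodes in the internal pool; supply `sample_barcodes`",
           call. = FALSE)
    }
    sample_barcodes <- stats::setNames(.barcode_pool[seq_along(samples)], samples)
  }
  if (anyDuplicated(sample_barcodes) || anyDuplicated(names(sample_barcodes))) {
    stop("sample barcodes and sample ids must be unique", call. = FALSE)
  }
  if (any(nchar(sample_barcodes) != barcode_length) ||
      any(grepl("[^ACGT]", sample_barcodes))) {
    stop("barcodes must be uppercase ACGT of length ", barcode_length,
         call. = FALSE)
  }
  if (per_base_error_rate < 0 || per_base_error_rate >= 1) {
    stop("`per_base_error_rate` must be in [0, 1)", call. = FALSE)
  }
  min_len <- barcode_length + nchar(fwd_primer) + insert_frame_offset +
    3L * aa_window_codons
  if (read_length < min_len) {
    stop("read_length must be at least ", min_len,
         " to cover barcode, primer and assignment window", call. = FALSE)
  }
  if (length(quality_profile) != read_length) {
    stop("`quality_profile` must have length `read_length`", call. = FALSE)
  }
  design <- list(
    sample_barcodes = sample_barcodes,
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    read_length = as.integer(read_length),
    barcode_length = as.integer(barcode_length),
    insert_frame_offset = as.integer(insert_frame_offset),
    aa_window_codons = as.integer(aa_window_codons),
    per_base_error_rate = per_base_error_rate,
    quality_profile = as.integer(quality_profile)
  )
  class(design) <- "amplicon_design"
  design
}

#' Write / read an amplicon design as YAML
#'
#' @param design An `amplicon_design`.
#' @param path File path.
#' @export
write_design_yaml <- function(design, path) {
  x <- unclass(design)
  x$sample_barcodes <- as.list(x$sample_barcodes)  # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  amplicon_design(
    sample_barcodes = unlist(x$sample_barcodes),
    fwd_primer = x$fwd_primer, rev_primer = x$rev_primer,
    read_length = x$read_length, barcode_length = x$barcode_length,
    insert_frame_offset = x$insert_frame_offset,
    aa_window_codons = x$aa_window_codons,
    per_base_error_rate = x$per_base_error_rate,
    quality_profile = unlist(x$quality_profile)
  )
}

## Inject iid substitution errors into equal-length sequences.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  k <- stats::rbinom(length(seqs), L, rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L, k[i])
    s <- seqs[i]
    for (p in pos) {
      orig <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, orig), 1L)
    }
    seqs[i] <- s
  }
  seqs
}

#' Generate single-end amplicon reads
#'
#' Draws one clone per read multinomially from `freqs`, builds
#' `barcode + fwd_primer + insert` truncated to the read length, applies iid
#' substitution errors, and draws per-base qualities around the design's
#' quality profile (Gaussian jitter, sd 3, clamped to Phred 2-41).
#'
#' @param freqs Named clone fractions summing to 1.
#' @param design An [amplicon_design()].
#' @param reference A `clone_reference` covering the named clones.
#' @param sample_id Sample whose barcode prefixes the reads.
#' @param n_reads Number of reads.
#' @param seed Integer seed (or `NULL`).
#' @return A `read_set` data frame (`read_id`, `sequence`, `quality`) with a
#'   `"true_counts"` attribute holding the generating clone draw. Read ids
#'   encode `sample:index:clone` as simulator ground truth.
#' @export
generate_reads <- function(freqs, design, reference, sample_id, n_reads,
                           seed = NULL) {
  stopifnot(inherits(design, "amplicon_design"))
  if (!is.numeric(n_reads) || length(n_reads) != 1L || n_reads < 0) {
    stop("`n_reads` must be a non-negative integer", call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  if (!sample_id %in% names(design$sample_barcodes)) {
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop("clone frequencies must sum to 1", call. = FALSE)
  }
  miss <- setdiff(names(freqs), reference$clone_id)
  if (length(miss)) {
    stop("clones not in reference: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (n_reads == 0L) {
    out <- data.frame(read_id = character(0L), sequence = character(0L),
                      quality = character(0L), stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    attr(out, "true_counts") <- stats::setNames(integer(length(freqs)),
                                                names(freqs))
    return(out)
  }
  bc <- design$sample_barcodes[[sample_id]]
  inserts <- reference$dna_insert[match(names(freqs), reference$clone_id)]
  templates <- substr(paste0(bc, design$fwd_primer, inserts),
                      1L, design$read_length)
  with_seed(seed, {
    idx <- sample.int(length(freqs), n_reads, replace = TRUE, prob = freqs)
    seqs <- inject_errors(templates[idx], design$per_base_error_rate)
    L <- nchar(seqs[1L])
    q <- round(rep(design$quality_profile[seq_len(L)], n_reads) +
                 stats::rnorm(as.double(n_reads) * L, 0, 3))
    q <- pmin(pmax(q, 2L), 41L)
    qraw <- matrix(as.raw(q + 33L), nrow = L)
    quals <- vapply(seq_len(n_reads), function(i) rawToChar(qraw[, i]),
                    character(1L))
    out <- data.frame(
      read_id = sprintf("%s:%d:%s", sample_id, seq_len(n_reads),
                        names(freqs)[idx]),
      sequence = seqs, quality = quals, stringsAsFactors = FALSE
    )
    class(out) <- c("read_set", "data.frame")
    attr(out, "true_counts") <- stats::setNames(
      tabulate(idx, nbins = length(freqs)), names(freqs))
    out
  })
}

#' Write / read FASTQ (Phred+33)
#'
#' Plain or gzip-compressed (by `.gz` extension). The reader validates the
#' 4-line record structure and errors naming the offending record.
#'
#' @param reads A `read_set` data frame.
#' @param path File path (`.gz` for compressed output).
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a
#'   `read_set`.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    out <- data.frame(read_id = character(0L), sequence = character(0L),
                      quality = character(0L), stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "' at record ", bad[1L],
         " (", hdr[bad[1L]], ")", call. = FALSE)
  }
  out <- data.frame(read_id = substring(hdr, 2L), sequence = seqs,
                    quality = quals, stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}
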