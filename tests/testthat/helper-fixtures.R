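# Fixtures are built in code at test time; nothing is stored on disk.

ref14 <- her2_scfv_reference()

per_lineage <- c("Per", "Per-N52A", "Per-P53A", "Per-N54A", "Per-S55A",
                 "Per-G56A")
tra_lineage <- c("Tra", "Tra-G101A", "Tra-D102A", "Tra-G103A", "Tra-F104A",
                 "Tra-Y105A")

one_clone <- function(clone_id, reference = ref14) {
  out <- reference[reference$clone_id == clone_id, , drop = FALSE]
  out$library_frequency <- 1
  out
}

# A read_set built from explicit sequences and per-base Phred scores.
make_reads <- function(sequences, phred) {
  if (is.numeric(phred)) phred <- list(phred)
  quals <- vapply(seq_along(sequences), function(i) {
    q <- phred[[min(i, length(phred))]]
    q <- rep_len(q, nchar(sequences[i]))
    rawToChar(as.raw(q + 33L))
  }, character(1L))
  out <- data.frame(read_id = paste0("r", seq_along(sequences)),
                    sequence = sequences, quality = quals,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

# Hand-built cell events with one fluorescence channel.
make_events <- function(fluor, clone_id = "c1", channel = "AF647") {
  n <- length(fluor)
  ev <- data.frame(clone_id = rep_len(clone_id, n),
                   A = rep(1, n), Q = rep(1, n), stringsAsFactors = FALSE)
  ev[[channel]] <- fluor
  ev
}

count_table_from <- function(counts, sample_id = "s") {
  total <- sum(counts)
  ct <- list(sample_id = sample_id,
             counts = counts,
             qc = c(reads_in = total, reads_after_quality = total,
                    reads_primer_matched = total, reads_demuxed = total,
                    reads_assigned = total))
  class(ct) <- "count_table"
  ct
}
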