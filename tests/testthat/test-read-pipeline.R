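pipe_design <- amplicon_design(samples = c("s1", "s2"))
prefix_for <- function(sample, design = pipe_design) {
  paste0(design$sample_barcodes[[sample]], design$fwd_primer)
}

test_that("sliding-window trimming matches the hand-computed oracle", {
  # 150 bases of Q30: no window fails, read unchanged
  clean <- make_reads(strrep("A", 150), rep(30, 150))
  out <- quality_filter(clean)
  expect_equal(nrow(out), 1L)
  expect_equal(nchar(out$sequence), 150L)
  expect_equal(attr(out, "n_dropped"), 0L)

  # 80 x Q30 then 40 x Q2: a 20-base window keeps mean >= 20 only while it
  # holds >= 13 Q30 bases, so the first failing window starts at 0-based
  # index 68 -> 68 bases kept, retained (>= 50)
  r80 <- make_reads(strrep("A", 120), c(rep(30, 80), rep(2, 40)))
  out80 <- quality_filter(r80)
  expect_equal(nchar(out80$sequence), 68L)
  expect_equal(nchar(out80$quality), 68L)

  # 60 x Q30 then 90 x Q2: first failing window starts at index 48,
  # trimmed length 48 < 50 -> dropped
  r60 <- make_reads(strrep("A", 150), c(rep(30, 60), rep(2, 90)))
  out60 <- quality_filter(r60)
  expect_equal(nrow(out60), 0L)
  expect_equal(attr(out60, "n_dropped"), 1L)

  # 40 x Q30: no failing window but below the length floor
  r40 <- make_reads(strrep("A", 40), rep(30, 40))
  expect_equal(nrow(quality_filter(r40)), 0L)

  # shorter than one window: judged as a single full-length window
  r10 <- make_reads(strrep("A", 10), rep(5, 10))
  expect_equal(nrow(quality_filter(r10, min_len = 5)), 0L)
  r10ok <- make_reads(strrep("A", 10), rep(30, 10))
  expect_equal(nchar(quality_filter(r10ok, min_len = 5)$sequence), 10L)
})

test_that("primer matching and barcode demultiplexing behave at boundaries", {
  ins <- strrep("ACGT", 25)
  good <- make_reads(paste0(prefix_for("s1"), ins), rep(35, 126))
  dm <- demux_and_match(good, pipe_design)
  expect_true(dm$primer_matched)
  expect_equal(dm$sample_id, "s1")

  # one substitution in the primer: rejected at 0 mismatches, kept at 1
  seq1 <- paste0(prefix_for("s2"), ins)
  substr(seq1, 10, 10) <- if (substr(seq1, 10, 10) == "A") "C" else "A"
  one_mm <- make_reads(seq1, rep(35, 126))
  expect_false(demux_and_match(one_mm, pipe_design)$primer_matched)
  dm1 <- demux_and_match(one_mm, pipe_design, max_primer_mismatch = 1)
  expect_true(dm1$primer_matched)
  expect_equal(dm1$sample_id, "s2")

  # unknown barcode with a perfect primer: matched but unassigned
  unk <- make_reads(paste0("AAAAAA", pipe_design$fwd_primer, ins), rep(35, 126))
  dmu <- demux_and_match(unk, pipe_design)
  expect_true(dmu$primer_matched)
  expect_true(is.na(dmu$sample_id))
})

test_that("window translation assigns clones exactly or not at all", {
  per <- ref14[ref14$clone_id == "Per", ]
  reads <- make_reads(paste0(prefix_for("s1"), per$dna_insert), rep(35, 115))
  expect_equal(translate_and_assign(reads, pipe_design, ref14), "Per")

  # a window matching no reference is unassigned
  alien <- per$dna_insert
  substr(alien, 5, 5) <- "C"  # TAC -> CAC: Y49H inside the window
  miss <- make_reads(paste0(prefix_for("s1"), alien), rep(35, 115))
  expect_true(is.na(translate_and_assign(miss, pipe_design, ref14)))

  # ambiguous base inside the window is unassigned
  ambig <- per$dna_insert
  substr(ambig, 10, 10) <- "N"
  ra <- make_reads(paste0(prefix_for("s1"), ambig), rep(35, 115))
  expect_true(is.na(translate_and_assign(ra, pipe_design, ref14)))

  # too short to cover the window is unassigned
  short <- make_reads(substr(paste0(prefix_for("s1"), per$dna_insert), 1, 60),
                      rep(35, 60))
  expect_true(is.na(translate_and_assign(short, pipe_design, ref14)))
})

test_that("an error-free run recovers the generated counts exactly", {
  flatq <- amplicon_design(samples = c("s1", "s2"), per_base_error_rate = 0,
                           quality_profile = rep(35L, 110L))
  freqs <- stats::setNames(ref14$library_frequency, ref14$clone_id)
  reads <- generate_reads(freqs, flatq, ref14, "s1", 5000, seed = 21)
  tables <- process_run(reads, flatq, ref14)
  expect_equal(tables$s1$counts, attr(reads, "true_counts")[names(tables$s1$counts)])
  expect_equal(tables$s1$qc[["reads_assigned"]], 5000L)
  expect_equal(sum(tables$s2$counts), 0L)
})

test_that("per-sample totals equal the per-barcode generated counts", {
  flatq <- amplicon_design(samples = c("s1", "s2"), per_base_error_rate = 0,
                           quality_profile = rep(35L, 110L))
  freqs <- stats::setNames(ref14$library_frequency, ref14$clone_id)
  r1 <- generate_reads(freqs, flatq, ref14, "s1", 1500, seed = 22)
  r2 <- generate_reads(freqs, flatq, ref14, "s2", 700, seed = 23)
  pooled <- rbind(r1, r2)
  class(pooled) <- c("read_set", "data.frame")
  tables <- process_run(pooled, flatq, ref14)
  expect_equal(tables$s1$qc[["reads_demuxed"]], 1500L)
  expect_equal(tables$s2$qc[["reads_demuxed"]], 700L)
  expect_equal(sum(tables$s1$counts), 1500L)
  expect_equal(sum(tables$s2$counts), 700L)
})

test_that("an empty FASTQ yields empty tables with zero tallies", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0L), path)
  tables <- process_run(path, pipe_design, ref14)
  for (s in c("s1", "s2")) {
    expect_equal(sum(tables[[s]]$counts), 0L)
    expect_true(all(tables[[s]]$qc == 0L))
  }
})

test_that("QC tallies form a monotone chain on a realistic noisy run", {
  freqs <- stats::setNames(ref14$library_frequency, ref14$clone_id)
  design <- amplicon_design(samples = c("s1", "s2"),
                            per_base_error_rate = 0.001)
  reads <- generate_reads(freqs, design, ref14, "s2", 4000, seed = 27)
  tables <- process_run(reads, design, ref14)
  qc <- tables$s2$qc
  expect_true(qc[["reads_assigned"]] <= qc[["reads_demuxed"]])
  expect_true(qc[["reads_demuxed"]] <= qc[["reads_primer_matched"]])
  expect_true(qc[["reads_primer_matched"]] <= qc[["reads_after_quality"]])
  expect_true(qc[["reads_after_quality"]] <= qc[["reads_in"]])
  expect_equal(sum(tables$s2$counts), qc[["reads_assigned"]])
  # losses stay near the binomial expectation for ~71 error-sensitive bases
  expect_gt(qc[["reads_assigned"]] / qc[["reads_in"]], 0.999^71 - 0.05)
})

test_that("sequencing errors rarely misassign reads between clones", {
  design <- amplicon_design(samples = "s1", per_base_error_rate = 0.001,
                            quality_profile = rep(35L, 110L))
  freqs <- stats::setNames(ref14$library_frequency, ref14$clone_id)
  reads <- generate_reads(freqs, design, ref14, "s1", 2e4, seed = 33)
  assigned <- translate_and_assign(reads, design, ref14)
  truth <- sub("^s1:\\d+:", "", reads$read_id)
  ok <- !is.na(assigned)
  # among assigned reads, essentially all carry their true clone label
  expect_gte(mean(assigned[ok] == truth[ok]), 0.99)
  # and the unassigned fraction is consistent with ~45 error-prone bases
  expect_lt(mean(!ok), 0.1)
})

test_that("count tables round-trip through TSV and QC JSON is written", {
  freqs <- stats::setNames(ref14$library_frequency, ref14$clone_id)
  design <- amplicon_design(samples = "s1", per_base_error_rate = 0,
                            quality_profile = rep(35L, 110L))
  reads <- generate_reads(freqs, design, ref14, "s1", 1000, seed = 3)
  tables <- process_run(reads, design, ref14)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  qcj <- withr::local_tempfile(fileext = ".json")
  write_count_table(tables, tsv, qc_path = qcj)
  back <- read_count_table(tsv, "s1")
  expect_equal(back$counts[sort(names(back$counts))],
               tables$s1$counts[sort(names(tables$s1$counts))])
  qc <- jsonlite::read_json(qcj)
  expect_equal(qc$s1$reads_assigned, 1000L)
})
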