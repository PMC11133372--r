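## End-to-end in-silico binning experiment:
## simulate -> gate/sort -> amplicon sequencing -> read pipeline ->
## enrichment -> bin classification.

#' Configuration for the 14-clone binning simulation
#'
#' The frozen study conditions of the shipped fixture experiment: the
#' calibrated single-cell model (see [sim_config()]) at the library scale.
#'
#' @param n_cells Cells per staining aliquot.
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
binning_config <- function(n_cells = 3e5, seed = NULL) {
  sim_config(n_cells = n_cells, seed = seed)
}

#' Run a full in-silico epitope-binning experiment
#'
#' For each rAb, a staining aliquot of the library is simulated, gated
#' automatically, and its rAb-non-binding population sorted. Barcoded
#' amplicon reads are generated from an unsorted library aliquot and from
#' each sorted pool, pooled into one run, and processed back into count
#' tables; enrichment against the library sample is normalised to the
#' negative-control clone and clones are classified into epitope bins.
#'
#' @param reference `clone_reference` with `library_frequency` (default:
#'   the shipped 14-clone HER2 panel).
#' @param rabs rAb panel data frame (default: pertuzumab + trastuzumab at
#'   `rab_concentration` nM).
#' @param rab_concentration Staining concentration in nM used when `rabs`
#'   is not supplied.
#' @param config `sim_config` for the cell-level simulation.
#' @param n_reads Reads generated per sample.
#' @param negative_control_id Negative-control clone (anchors relative
#'   enrichment at 1).
#' @param threshold Relative-enrichment threshold for bin membership.
#' @param min_count Minimum sorted-sample read count for bin membership.
#' @param design Optional [amplicon_design()]; defaults to one with a
#'   `library` sample plus one per rAb.
#' @param seed Integer seed driving every stochastic step.
#' @return A `binning_run` list: `percent_negative` and `thresholds` per
#'   rAb, `count_tables`, `enrichment` (per-rAb `enrichment_table`s),
#'   `bins` (a `bin_result`), and the `design`/`reference` used.
#' @export
run_binning_experiment <- function(reference = her2_scfv_reference(),
                                   rabs = rab_panel(rab_concentration),
                                   rab_concentration = 0.1,
                                   config = binning_config(),
                                   n_reads = 1e5,
                                   negative_control_id = "Niv",
                                   threshold = 3,
                                   min_count = 10L,
                                   design = NULL,
                                   seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!negative_control_id %in% reference$clone_id) {
    stop("negative control '", negative_control_id,
         "' is not in the reference", call. = FALSE)
  }
  samples <- c("library", rabs$rab_id)
  if (is.null(design)) design <- amplicon_design(samples = samples)

  ## unsorted library aliquot (cell-level multinomial draw)
  lib_cells <- with_seed(child_seed(seed, 1L), {
    stats::setNames(as.integer(
      stats::rmultinom(1L, config$n_cells, reference$library_frequency)),
      reference$clone_id)
  })

  percent_negative <- numeric(0L)
  thresholds <- numeric(0L)
  sorted_cells <- list()
  for (i in seq_len(nrow(rabs))) {
    r <- rabs[i, , drop = FALSE]
    cfg <- config
    cfg$seed <- child_seed(seed, 10L + i)
    events <- simulate_cell_events(cfg, reference, r)
    sorted <- gate_and_sort(events, r$channel, "auto", cfg)
    percent_negative[r$rab_id] <- sorted$percent_negative
    thresholds[r$rab_id] <- sorted$threshold
    counts <- stats::setNames(integer(nrow(reference)), reference$clone_id)
    counts[names(sorted$counts)] <- sorted$counts
    sorted_cells[[r$rab_id]] <- counts
  }

  pools <- c(list(library = lib_cells), sorted_cells)
  reads <- do.call(rbind, lapply(seq_along(pools), function(k) {
    generate_reads(pools[[k]] / sum(pools[[k]]), design, reference,
                   sample_id = samples[k], n_reads = n_reads,
                   seed = child_seed(seed, 100L + k))
  }))
  class(reads) <- c("read_set", "data.frame")

  count_tables <- process_run(reads, design, reference, samples = samples)
  enrichment <- lapply(stats::setNames(rabs$rab_id, rabs$rab_id), function(r) {
    compute_enrichment(count_tables$library, count_tables[[r]],
                       negative_control_id = negative_control_id)
  })
  bins <- classify_bins(enrichment, threshold = threshold,
                        min_count = min_count)

  out <- list(
    percent_negative = percent_negative,
    thresholds = thresholds,
    library_cells = lib_cells,
    sorted_cells = sorted_cells,
    count_tables = count_tables,
    enrichment = enrichment,
    bins = bins,
    design = design,
    reference = reference,
    seed = seed
  )
  class(out) <- "binning_run"
  out
}

#' @export
print.binning_run <- function(x, ...) {
  cat("<binning_run> seed", x$seed, "\n")
  for (r in names(x$percent_negative)) {
    cat(sprintf("  %s: %.1f%% rAb(-) (gate %.1f a.u.)\n", r,
                x$percent_negative[[r]], x$thresholds[[r]]))
  }
  print(x$bins)
  invisible(x)
}

#' Percent rAb-non-binding cells for a single displayed clone
#'
#' Simulates cells all displaying one clone under the given configuration,
#' stains with one rAb and reads the percent of events below the automatic
#' gate — the in-silico analogue of a single-clone sensitivity measurement.
#'
#' @param clone_id Clone to display.
#' @param rab One-row rAb panel (default: pertuzumab at `concentration` nM).
#' @param concentration Staining concentration in nM used when `rab` is not
#'   supplied.
#' @param reference `clone_reference` holding the clone.
#' @param config `sim_config` (default: the frozen [sensitivity_config()]).
#' @param seed Integer seed.
#' @return List with `percent_negative`, `threshold` and the `events`.
#' @export
percent_rab_negative <- function(clone_id,
                                 rab = rab_panel(concentration)[1L, ],
                                 concentration = 0.1,
                                 reference = her2_scfv_reference(),
                                 config = sensitivity_config(),
                                 seed = 1L) {
  clone <- reference[reference$clone_id == clone_id, , drop = FALSE]
  if (nrow(clone) != 1L) stop("unknown clone: ", clone_id, call. = FALSE)
  clone$library_frequency <- 1
  cfg <- config
  cfg$seed <- seed
  events <- simulate_cell_events(cfg, clone, rab)
  g <- gate_and_sort(events, rab$channel, "auto", cfg)
  list(percent_negative = g$percent_negative, threshold = g$threshold,
       events = events)
}
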