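## Single-cell competitive binding model.
##
## Each reference antibody (rAb) binds its epitope under single-site
## mass-action equilibrium; distinct epitopes are independent sites. A
## displayed query antibody (qAb) competes only on its own blocked epitope,
## entering the isotherm as an effective cis concentration C_q = alpha * Q
## (nM) with affinity K_q. For rAb r on epitope e, the bound fraction is
##
##   p_r = x_r / (1 + sum_{r' on e} x_{r'} + b_e * C_q / K_q),
##
## with x_r = concentration_r / kd_r and b_e = 1 iff e is the clone's
## blocked epitope (antigen non-binders never compete).

#' Equilibrium rAb occupancy fractions for one clone
#'
#' @param clone One clone: a one-row `clone_reference` data frame or a list
#'   with `blocked_epitope` and `kd_qab` (nM; `Inf` or `NA` = non-binder).
#' @param rabs Reference-antibody panel (see [rab_panel()]).
#' @param qab_copies Displayed qAb copies on the cell (molecules, >= 0).
#' @param alpha Effective cis concentration per displayed copy (nM/molecule).
#' @return Named vector of bound fractions in `[0, 1]`, one per `rab_id`.
#' @examples
#' ref <- her2_scfv_reference()
#' rab_occupancy_fraction(ref[ref$clone_id == "Dac", ], rab_panel(1), 0, 1e-3)
#' @export
rab_occupancy_fraction <- function(clone, rabs, qab_copies, alpha) {
  if (is.data.frame(clone)) {
    stopifnot(nrow(clone) == 1L)
    clone <- as.list(clone)
  }
  assert_scalar_number(qab_copies, "qab_copies", nonneg = TRUE)
  assert_scalar_number(alpha, "alpha", positive = TRUE)
  if (any(rabs$concentration < 0)) {
    stop("rAb concentrations must be non-negative", call. = FALSE)
  }
  if (any(rabs$kd_rab <= 0)) stop("kd_rab must be > 0", call. = FALSE)
  kd_q <- clone$kd_qab
  if (is.null(kd_q) || is.na(kd_q)) kd_q <- Inf
  if (kd_q <= 0) stop("kd_qab must be > 0", call. = FALSE)

  x <- rabs$concentration / rabs$kd_rab
  sum_x <- stats::ave(x, rabs$epitope_id, FUN = sum)
  blocks <- !is.na(clone$blocked_epitope) &
    rabs$epitope_id == clone$blocked_epitope & is.finite(kd_q)
  cq_term <- ifelse(blocks, alpha * qab_copies / kd_q, 0)
  p <- x / (1 + sum_x + cq_term)
  stats::setNames(p, rabs$rab_id)
}

## Vectorised occupancy over cells: returns an n_cells x n_rabs matrix.
## blocked: per-cell blocked epitope (NA = none); kd_q, Q: per-cell vectors.
occupancy_matrix <- function(blocked, kd_q, Q, rabs, alpha) {
  n <- length(Q)
  x <- rabs$concentration / rabs$kd_rab
  sum_x <- stats::ave(x, rabs$epitope_id, FUN = sum)
  cq <- alpha * Q / kd_q            # 0 when kd_q = Inf
  cq[!is.finite(cq)] <- 0
  p <- matrix(0, n, nrow(rabs), dimnames = list(NULL, rabs$rab_id))
  for (j in seq_len(nrow(rabs))) {
    b <- !is.na(blocked) & blocked == rabs$epitope_id[j]
    p[, j] <- x[j] / (1 + sum_x[j] + ifelse(b, cq, 0))
  }
  p
}

#' Simulation configuration
#'
#' Houses the free parameters of the single-cell simulator. Antigen copies A
#' and displayed qAb copies Q are drawn independently per cell from
#' log-normal distributions specified by log10 medians and log10 standard
#' deviations. Fluorescence in the channel of rAb r is
#' `gain * A * p_r + noise`, clipped at zero, with additive Gaussian noise.
#'
#' The defaults are the package's frozen calibrated configuration (see the
#' methods vignette for the calibration rationale).
#'
#' @param n_cells Number of cells to simulate.
#' @param log10_a_median,log10_a_sd log10 median and sd of antigen copies/cell.
#' @param log10_q_median,log10_q_sd log10 median and sd of qAb copies/cell.
#' @param alpha Effective cis concentration per displayed qAb copy
#'   (nM/molecule).
#' @param gain Fluorescence units per rAb-bound antigen molecule.
#' @param noise_sd Additive background noise sd (a.u.).
#' @param antigen_negative_fraction Fraction of cells with silenced antigen
#'   expression (`A = 0`). Such cells fall into the rAb(-) gate regardless
#'   of the displayed clone and set the floor sort rate of non-blocking
#'   clones — the false-positive mechanism of antigen-low cells that the
#'   platform is known to exhibit.
#' @param q_gate Quantile of the background-only fluorescence distribution
#'   used by the automatic gate, in (0, 1).
#' @param n_background Number of background-only events simulated when
#'   placing the automatic gate.
#' @param seed Integer seed (or `NULL`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1e5,
                       log10_a_median = 5, log10_a_sd = 0.7,
                       log10_q_median = 5, log10_q_sd = 0.7,
                       alpha = 1e-3,
                       gain = 0.41,
                       noise_sd = 20,
                       antigen_negative_fraction = 0.005,
                       q_gate = 0.995,
                       n_background = 1e5,
                       seed = NULL) {
  assert_scalar_number(n_cells, "n_cells", nonneg = TRUE)
  for (nm in c("log10_a_sd", "log10_q_sd", "alpha", "gain", "n_background")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_number(antigen_negative_fraction, "antigen_negative_fraction",
                       nonneg = TRUE)
  if (antigen_negative_fraction >= 1) {
    stop("`antigen_negative_fraction` must be < 1", call. = FALSE)
  }
  assert_scalar_number(q_gate, "q_gate")
  if (q_gate <= 0 || q_gate >= 1) stop("`q_gate` must be in (0, 1)", call. = FALSE)
  cfg <- list(
    n_cells = as.integer(n_cells),
    log10_a_median = log10_a_median, log10_a_sd = log10_a_sd,
    log10_q_median = log10_q_median, log10_q_sd = log10_q_sd,
    alpha = alpha, gain = gain, noise_sd = noise_sd,
    antigen_negative_fraction = antigen_negative_fraction,
    q_gate = q_gate, n_background = as.integer(n_background), seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Frozen configuration for single-clone sensitivity runs
#'
#' The calibrated configuration used for affinity-sensitivity experiments:
#' a single displayed clone at the stated rAb concentration, percent
#' rAb-non-binding read off the automatic gate. Calibrated once against the
#' wild-type pertuzumab-lineage benchmark, then frozen (see vignette).
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sensitivity_config <- function(n_cells = 1e5, seed = NULL) {
  sim_config(n_cells = n_cells, seed = seed)
}

#' Simulate cell events
#'
#' Assigns clones multinomially by `library_frequency`, draws per-cell
#' antigen and qAb copies log-normally, computes equilibrium rAb occupancy
#' and per-channel fluorescence. When several rAbs share a channel their
#' signals add.
#'
#' @param config A [sim_config()].
#' @param library `clone_reference` with a `library_frequency` column (a
#'   single-clone data frame may omit it).
#' @param rabs rAb panel data frame.
#' @param seed Seed overriding `config$seed`.
#' @return Data frame with `clone_id`, `A`, `Q` and one column per channel.
#' @export
simulate_cell_events <- function(config, library, rabs, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(library))
  n <- config$n_cells
  if (n > 0L && nrow(library) == 0L) {
    stop("cannot simulate cells from an empty library", call. = FALSE)
  }
  freq <- library$library_frequency %||% rep(1 / nrow(library), nrow(library))
  if (abs(sum(freq) - 1) > 1e-8) {
    stop("library frequencies must sum to 1", call. = FALSE)
  }
  channels <- unique(rabs$channel)
  if (n == 0L) {
    out <- data.frame(clone_id = character(0L), A = numeric(0L), Q = numeric(0L))
    for (ch in channels) out[[ch]] <- numeric(0L)
    return(out)
  }
  with_seed(seed, {
    idx <- sample.int(nrow(library), n, replace = TRUE, prob = freq)
    A <- 10^stats::rnorm(n, config$log10_a_median, config$log10_a_sd)
    Q <- 10^stats::rnorm(n, config$log10_q_median, config$log10_q_sd)
    f0 <- config$antigen_negative_fraction %||% 0
    if (f0 > 0) A[stats::runif(n) < f0] <- 0
    p <- occupancy_matrix(library$blocked_epitope[idx], library$kd_qab[idx],
                          Q, rabs, config$alpha)
    out <- data.frame(clone_id = library$clone_id[idx], A = A, Q = Q,
                      stringsAsFactors = FALSE)
    for (ch in channels) {
      signal <- rowSums(p[, rabs$channel == ch, drop = FALSE]) * config$gain * A
      out[[ch]] <- pmax(signal + stats::rnorm(n, 0, config$noise_sd), 0)
    }
    out
  })
}

#' Gate on one channel and sort the rAb-non-binding population
#'
#' An event is rAb(-) iff its fluorescence in `channel` is below the
#' threshold. `threshold = "auto"` places the gate at the `q_gate` quantile
#' of a background-only simulation (noise only, zero antigen signal) under
#' the same configuration, reproducibly from `config$seed`.
#'
#' @param events Cell events from [simulate_cell_events()].
#' @param channel Channel name.
#' @param threshold Numeric threshold in a.u., or `"auto"`.
#' @param config The `sim_config` (required for `"auto"`).
#' @return List with `threshold`, `percent_negative`, `counts` (named integer
#'   clone counts of the sorted rAb(-) population) and `negatives` (the
#'   sorted events).
#' @export
gate_and_sort <- function(events, channel, threshold = "auto", config = NULL) {
  if (!channel %in% names(events)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  if (identical(threshold, "auto")) {
    if (nrow(events) == 0L) {
      stop("automatic thresholding needs a non-empty event set", call. = FALSE)
    }
    stopifnot(inherits(config, "sim_config"))
    threshold <- with_seed(child_seed(config$seed %||% 0, 104729), {
      bg <- pmax(stats::rnorm(config$n_background, 0, config$noise_sd), 0)
      stats::quantile(bg, config$q_gate, names = FALSE)
    })
  }
  assert_scalar_number(threshold, "threshold")
  neg <- events[[channel]] < threshold
  counts <- table(factor(events$clone_id[neg],
                         levels = sort(unique(events$clone_id))))
  list(
    threshold = threshold,
    percent_negative = if (nrow(events)) 100 * mean(neg) else NA_real_,
    counts = stats::setNames(as.integer(counts), names(counts)),
    negatives = events[neg, , drop = FALSE]
  )
}

#' Quadrant percentages for a dual-rAb staining
#'
#' Partitions events by two channel thresholds into the four quadrants
#' (x-/y-, x-/y+, x+/y-, x+/y+); "negative" means below the threshold.
#'
#' @param events Cell events.
#' @param channel_x,channel_y Channel names.
#' @param thresh_x,thresh_y Numeric thresholds (a.u.).
#' @return Named numeric vector `neg_neg`, `neg_pos`, `pos_neg`, `pos_pos`
#'   of percentages summing to 100.
#' @export
quadrant_percentages <- function(events, channel_x, channel_y,
                                 thresh_x, thresh_y) {
  if (nrow(events) == 0L) stop("no events to partition", call. = FALSE)
  for (ch in c(channel_x, channel_y)) {
    if (!ch %in% names(events)) stop("unknown channel: ", ch, call. = FALSE)
  }
  nx <- events[[channel_x]] < thresh_x
  ny <- events[[channel_y]] < thresh_y
  n <- nrow(events)
  100 * c(neg_neg = sum(nx & ny), neg_pos = sum(nx & !ny),
          pos_neg = sum(!nx & ny), pos_pos = sum(!nx & !ny)) / n
}

#' Write cell events as TSV
#'
#' @param events Cell-event data frame.
#' @param path Output path.
#' @export
write_cell_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
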