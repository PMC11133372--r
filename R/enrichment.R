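## Enrichment statistics and epitope-bin classification.
##
## occupancy:            clone count / total assigned count of the sample
## enrichment ratio ER:  sorted-sample occupancy / library occupancy
## relative enrichment:  ER normalised so the negative control equals 1
## bin membership:       relative enrichment strictly greater than the
##                       threshold (default 3), with a minimum sorted read
##                       count guarding against single-cell shot noise.

#' Clone occupancies of a count table
#'
#' @param counts A `count_table` or named numeric vector of counts.
#' @return Named fractions summing to 1 (clones absent from the sample get 0).
#' @export
compute_occupancy <- function(counts) {
  x <- if (inherits(counts, "count_table")) counts$counts else counts
  if (!is.numeric(x) || is.null(names(x))) {
    stop("`counts` must be a count_table or a named numeric vector",
         call. = FALSE)
  }
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(x)
  if (total <= 0) stop("no assigned reads: total count is zero", call. = FALSE)
  x / total
}

#' Enrichment table of a sorted sample against the library
#'
#' Computes occupancies, enrichment ratios and negative-control-normalised
#' relative enrichment. With `pseudocount` p > 0, occupancies are
#' `(count + p) / (total + p * n_clones)`. Clones with zero library
#' occupancy (and zero pseudocount) cannot be given an enrichment ratio;
#' they are reported with `NA` and listed in the `"excluded"` attribute.
#'
#' @param library,sorted `count_table`s (or named count vectors) of the
#'   pre-sort library sample and the sorted sample.
#' @param negative_control_id Clone anchoring the relative enrichment at 1;
#'   must have nonzero occupancy in both samples.
#' @param pseudocount Pseudocount p >= 0.
#' @return An `enrichment_table` data frame (rows in lexicographic clone
#'   order): `clone_id`, `count_library`, `count_sorted`,
#'   `occupancy_library`, `occupancy_sorted`, `enrichment_ratio`,
#'   `relative_enrichment`.
#' @export
compute_enrichment <- function(library, sorted, negative_control_id,
                               pseudocount = 0) {
  lib <- if (inherits(library, "count_table")) library$counts else library
  srt <- if (inherits(sorted, "count_table")) sorted$counts else sorted
  clones <- sort(union(names(lib), names(srt)))
  lib <- stats::setNames(as.numeric(lib[clones]), clones)
  srt <- stats::setNames(as.numeric(srt[clones]), clones)
  lib[is.na(lib)] <- 0
  srt[is.na(srt)] <- 0
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  if (!negative_control_id %in% clones) {
    stop("negative control '", negative_control_id,
         "' is absent from the samples", call. = FALSE)
  }
  p <- pseudocount
  occ_l <- (lib + p) / (sum(lib) + p * length(clones))
  occ_s <- (srt + p) / (sum(srt) + p * length(clones))
  if (occ_l[negative_control_id] == 0 || occ_s[negative_control_id] == 0) {
    stop("negative control '", negative_control_id,
         "' has zero occupancy; cannot anchor relative enrichment",
         call. = FALSE)
  }
  er <- ifelse(occ_l > 0, occ_s / occ_l, NA_real_)
  rer <- er / er[[negative_control_id]]
  out <- data.frame(
    clone_id = clones,
    count_library = unname(lib), count_sorted = unname(srt),
    occupancy_library = unname(occ_l), occupancy_sorted = unname(occ_s),
    enrichment_ratio = unname(er), relative_enrichment = unname(rer),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "negative_control_id") <- negative_control_id
  attr(out, "pseudocount") <- p
  attr(out, "excluded") <- clones[occ_l == 0]
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Classify clones into epitope bins
#'
#' A clone belongs to the bin of rAb r iff its relative enrichment in the
#' r-sorted sample is strictly greater than `threshold` and it has at least
#' `min_count` assigned reads in that sorted sample (the read floor protects
#' very rare clones against single-sorted-cell shot noise). Clones enriched
#' under no rAb are labelled `"ungrouped"`; multi-bin membership is
#' representable and reported.
#'
#' @param tables Named list of `enrichment_table`s, one per rAb; all must
#'   cover the same clone set.
#' @param threshold Relative-enrichment threshold (strict inequality).
#' @param min_count Minimum assigned sorted-sample reads for membership.
#' @return A `bin_result` list: `assignments` (data frame `clone_id`,
#'   `bins`, `n_bins`), `bins` (rAb -> member clones), `ungrouped`.
#' @export
classify_bins <- function(tables, threshold = 3, min_count = 10L) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            !is.null(names(tables)))
  clone_sets <- lapply(tables, function(t) sort(t$clone_id))
  for (i in seq_along(clone_sets)) {
    if (!identical(clone_sets[[i]], clone_sets[[1L]])) {
      stop("enrichment tables cover inconsistent clone sets", call. = FALSE)
    }
  }
  clones <- clone_sets[[1L]]
  member <- vapply(tables, function(t) {
    t <- t[match(clones, t$clone_id), ]
    !is.na(t$relative_enrichment) & t$relative_enrichment > threshold &
      t$count_sorted >= min_count
  }, logical(length(clones)))
  member <- matrix(member, nrow = length(clones),
                   dimnames = list(clones, names(tables)))
  bins_per_clone <- apply(member, 1L, function(m) names(tables)[m],
                          simplify = FALSE)
  assignments <- data.frame(
    clone_id = clones,
    bins = vapply(bins_per_clone, function(b) {
      if (length(b)) paste(b, collapse = ",") else "ungrouped"
    }, character(1L)),
    n_bins = vapply(bins_per_clone, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  out <- list(
    assignments = assignments,
    bins = lapply(stats::setNames(names(tables), names(tables)),
                  function(r) clones[member[, r]]),
    ungrouped = clones[rowSums(member) == 0L],
    threshold = threshold, min_count = min_count
  )
  class(out) <- "bin_result"
  out
}

#' @export
print.bin_result <- function(x, ...) {
  cat("<bin_result> threshold >", x$threshold, "\n")
  for (r in names(x$bins)) {
    cat(sprintf("  %s bin (%d): %s\n", r, length(x$bins[[r]]),
                paste(x$bins[[r]], collapse = ", ")))
  }
  cat(sprintf("  ungrouped (%d): %s\n", length(x$ungrouped),
              paste(x$ungrouped, collapse = ", ")))
  invisible(x)
}

#' Detectable pool size implied by the rarest enriched clone
#'
#' The reciprocal of the smallest library occupancy among substantially
#' enriched clones, floored to an integer: the platform resolved one clone
#' from a pool of at least this many equally rare species.
#'
#' @param library_occupancies Named library fractions (> 0).
#' @param enriched Character vector of substantially enriched clone ids.
#' @return Integer pool size.
#' @examples
#' pool_size_capability(c(A = 0.5, B = 0.25), c("A", "B"))  # 4
#' @export
pool_size_capability <- function(library_occupancies, enriched) {
  if (length(enriched) == 0L) {
    stop("pool size is undefined for an empty enriched set", call. = FALSE)
  }
  miss <- setdiff(enriched, names(library_occupancies))
  if (length(miss)) {
    stop("no library occupancy for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  occ <- library_occupancies[enriched]
  if (any(occ <= 0)) stop("occupancies must be > 0", call. = FALSE)
  as.integer(floor(1 / min(occ)))
}

#' Write an enrichment table / bin result
#'
#' @param x An `enrichment_table` (TSV) or `bin_result` (JSON).
#' @param path Output path.
#' @export
write_enrichment_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
write_bin_result <- function(x, path) {
  jsonlite::write_json(
    list(threshold = x$threshold, min_count = x$min_count, bins = x$bins,
         ungrouped = x$ungrouped),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
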