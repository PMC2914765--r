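# Evaluation metrics: switch error rate for phasing, pooled false-negative /
# false-positive rates for IBD detection.

#' Switch error rate of an inferred phase
#'
#' Compares the relative phase between consecutive heterozygous loci of each
#' sample against the truth: with phase bits `y` (0 = A on the left
#' autosome), the relative phase coefficients are `z_i = y_i xor y_{i+1}`,
#' and a comparison is wrong when the inferred and true coefficients differ.
#' Homozygous and missing loci are excluded, and the measure is invariant
#' under a global swap of either sample's autosomes. Truth and inferred
#' panels must carry identical genotypes.
#'
#' @param truth,inferred `phased_panel`s over the same samples and loci.
#' @param samples Sample ids or indices to evaluate (default: all).
#' @param pooled If `TRUE`, return a single pooled row; otherwise one row
#'   per sample.
#' @return A tibble with columns `sample` (unless pooled), `n_het_pairs`,
#'   `n_incorrect`, `rate` (percent).
#' @export
switch_error_rate <- function(truth, inferred, samples = NULL,
                              pooled = FALSE) {
  stopifnot(inherits(truth, "phased_panel"), inherits(inferred, "phased_panel"))
  ids <- rownames(truth$calls)
  if (is.null(samples)) samples <- ids
  if (is.numeric(samples)) samples <- ids[samples]
  gt <- collapse_phase(truth)$calls
  gi <- collapse_phase(inferred)$calls
  rows <- lapply(samples, function(sm) {
    if (!isTRUE(all.equal(gt[sm, ], gi[sm, ])))
      stop("genotype mismatch between truth and inferred for sample ", sm)
    het <- which(gt[sm, ] == 1L)
    if (length(het) < 2L)
      return(tibble::tibble(sample = sm, n_het_pairs = 0L,
                            n_incorrect = 0L, rate = NA_real_))
    yt <- as.integer(truth$calls[sm, het] == 2L)
    yi <- as.integer(inferred$calls[sm, het] == 2L)
    zt <- xor(yt[-length(yt)], yt[-1L])
    zi <- xor(yi[-length(yi)], yi[-1L])
    bad <- sum(zt != zi)
    tibble::tibble(sample = sm, n_het_pairs = length(zt),
                   n_incorrect = bad, rate = 100 * bad / length(zt))
  })
  out <- dplyr::bind_rows(rows)
  if (pooled) {
    tot <- sum(out$n_het_pairs); bad <- sum(out$n_incorrect)
    tibble::tibble(n_het_pairs = tot, n_incorrect = bad,
                   rate = if (tot > 0) 100 * bad / tot else NA_real_)
  } else out
}

#' Convert segments to a per-locus detection matrix
#'
#' @param segments A segment tibble (0-based half-open `start`/`end`).
#' @param n_loci Panel size.
#' @param pairs Two-column matrix of sample ids defining the row order.
#' @return Logical matrix, pairs by loci.
#' @export
segments_to_loci <- function(segments, n_loci, pairs) {
  pairs <- as.matrix(pairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rk <- key(pairs[, 1], pairs[, 2])
  out <- matrix(FALSE, nrow(pairs), n_loci)
  if (nrow(segments) == 0) { attr(out, "pairs") <- pairs; return(out) }
  sk <- key(segments$sample_a, segments$sample_b)
  ri <- match(sk, rk)
  if (anyNA(ri)) stop("segments contain pairs not listed in `pairs`")
  for (r in seq_len(nrow(segments)))
    out[ri[r], (segments$start[r] + 1L):segments$end[r]] <- TRUE
  attr(out, "pairs") <- pairs
  out
}

#' IBD detection accuracy against ground truth
#'
#' Pooled over all pairs and loci: the false-negative percentage is the
#' share of truth-IBD (pair, locus) combinations the detector missed, and
#' the false-positive percentage is the number of detected combinations
#' that are not truth-IBD, *also expressed relative to the total number of
#' truth-IBD combinations* — so it can legitimately exceed 100% when truth
#' IBD is scarce.
#'
#' @param truth,detected Logical pair-by-locus matrices (same shape), e.g.
#'   from [truth_ibd_matrix()] and [segments_to_loci()].
#' @return A tibble with `n_truth`, `n_detected`, `fn_pct`, `fp_pct`.
#' @export
ibd_accuracy <- function(truth, detected) {
  stopifnot(identical(dim(truth), dim(detected)))
  n_truth <- sum(truth)
  if (n_truth == 0) {
    warning("no truth-IBD loci; rates undefined")
    return(tibble::tibble(n_truth = 0L, n_detected = sum(detected),
                          fn_pct = NA_real_, fp_pct = NA_real_))
  }
  fn <- sum(truth & !detected)
  fp <- sum(detected & !truth)
  tibble::tibble(n_truth = n_truth, n_detected = sum(detected),
                 fn_pct = 100 * fn / n_truth, fp_pct = 100 * fp / n_truth)
}
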