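#' @keywords internal
"_PACKAGE"

#' @useDynLib ibdphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils combn head read.table tail
NULL

# Internal call encodings.
# Unordered genotype codes: 0 = AA, 1 = AB, 2 = BB, NA = missing.
# Phased (ordered) codes:   0 = AA, 1 = AB (A on left), 2 = BA, 3 = BB, NA.
GENO_CALLS <- c("AA", "AB", "BB")
PHASED_CALLS <- c("AA", "AB", "BA", "BB")

#' Locus table constructor
#'
#' Builds the per-locus annotation table shared by genotype and phased
#' panels: physical position, genetic position (centimorgans) and the
#' frequency `p` of allele A (identified with the VCF REF allele; `q = 1 - p`).
#'
#' @param n_loci Number of loci.
#' @param chrom Chromosome labels (recycled).
#' @param pos Physical positions (1-based bp).
#' @param cm Genetic positions in centimorgans; must be non-decreasing.
#' @param p Frequency of allele A per locus, in `[0, 1]`, or `NA` if unknown.
#' @return A tibble with columns `chrom`, `pos`, `cm`, `p`, `monomorphic`.
#' @export
locus_table <- function(n_loci, chrom = "1", pos = seq_len(n_loci),
                        cm = NULL, p = NA_real_) {
  if (is.null(cm)) cm <- pos * 1e-6 # 1 cM / Mb default map
  stopifnot(length(pos) == n_loci, length(cm) == n_loci)
  if (any(diff(cm) < 0)) stop("genetic positions `cm` must be non-decreasing")
  p <- rep_len(as.numeric(p), n_loci)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("`p` must lie in [0, 1]")
  tibble::tibble(
    chrom = rep_len(as.character(chrom), n_loci),
    pos = as.integer(pos), cm = as.numeric(cm), p = p,
    monomorphic = !is.na(p) & (p <= 0 | p >= 1)
  )
}

encode_calls <- function(calls, levels) {
  if (is.character(calls)) {
    m <- matrix(match(calls, levels) - 1L, nrow = nrow(calls),
                dimnames = dimnames(calls))
    bad <- !is.na(calls) & is.na(m) & calls != "" & calls != ".."
    if (any(bad)) stop("unrecognised call(s): ",
                       paste(unique(calls[bad]), collapse = ", "))
    m
  } else {
    storage.mode(calls) <- "integer"
    if (any(calls < 0 | calls >= length(levels), na.rm = TRUE))
      stop("call codes out of range")
    calls
  }
}

#' Genotype panel
#'
#' A panel of unordered biallelic genotype calls, samples by loci. Calls are
#' `AA`, `AB`, `BB` or missing. Allele frequencies are either supplied via
#' `loci` or estimated from the calls (see [compute_allele_freqs()]).
#'
#' @param calls A samples-by-loci matrix, either character (`"AA"`, `"AB"`,
#'   `"BB"`, `NA`) or integer codes (0, 1, 2, `NA`). Row names are sample ids.
#' @param loci Optional locus table from [locus_table()].
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(calls, loci = NULL) {
  calls <- encode_calls(as.matrix(calls), GENO_CALLS)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- locus_table(ncol(calls))
  stopifnot(nrow(loci) == ncol(calls))
  x <- structure(list(calls = calls, loci = loci), class = "geno_panel")
  if (all(is.na(loci$p))) x$loci <- compute_allele_freqs(x)
  x
}

#' Phased genotype panel
#'
#' Like [geno_panel()] but with ordered heterozygous calls: `AB` means allele
#' A sits on the "left" autosome, `BA` on the right. The left/right labels
#' are arbitrary but consistent along the chromosome, which is what gives
#' relative phase between consecutive heterozygous loci its meaning.
#'
#' @param calls Samples-by-loci matrix of `AA`/`AB`/`BA`/`BB`/`NA` (or codes
#'   0..3).
#' @param loci Optional locus table.
#' @param phase_known Logical matrix (same shape) marking calls whose phase
#'   was actually observed; unphased input (e.g. "/" VCF genotypes) is stored
#'   as `AB` with `phase_known = FALSE`.
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(calls, loci = NULL, phase_known = NULL) {
  calls <- encode_calls(as.matrix(calls), PHASED_CALLS)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- locus_table(ncol(calls))
  stopifnot(nrow(loci) == ncol(calls))
  if (is.null(phase_known))
    phase_known <- matrix(TRUE, nrow(calls), ncol(calls))
  stopifnot(identical(dim(phase_known), dim(calls)))
  dimnames(phase_known) <- dimnames(calls)
  x <- structure(list(calls = calls, loci = loci, phase_known = phase_known),
                 class = "phased_panel")
  if (all(is.na(loci$p))) x$loci <- compute_allele_freqs(x)
  x
}

#' @exportS3Method base::print
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d samples x %d loci (%.3g%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @exportS3Method base::print
print.phased_panel <- function(x, ...) {
  cat(sprintf(
    "<phased_panel> %d samples x %d loci (%.3g%% missing, %.3g%% phase known)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls)),
    100 * mean(x$phase_known)))
  invisible(x)
}

#' Sample identifiers of a panel
#' @param x A `geno_panel` or `phased_panel`.
#' @return Character vector of sample ids.
#' @export
samples <- function(x) rownames(x$calls)

#' Number of loci in a panel
#' @param x A `geno_panel` or `phased_panel`.
#' @export
n_loci <- function(x) ncol(x$calls)

#' Collapse a phased panel to its unordered genotypes
#'
#' `AB` and `BA` both collapse to the heterozygous genotype, so the result is
#' invariant under any re-phasing of the input.
#'
#' @param x A `phased_panel`.
#' @return A `geno_panel` with the same samples, loci and frequencies.
#' @export
collapse_phase <- function(x) {
  stopifnot(inherits(x, "phased_panel"))
  g <- matrix(c(0L, 1L, 1L, 2L)[x$calls + 1L], nrow = nrow(x$calls),
              dimnames = dimnames(x$calls))
  structure(list(calls = g, loci = x$loci), class = "geno_panel")
}

#' Estimate allele frequencies from calls
#'
#' `p = (2 * #AA + #het) / (2 * #non-missing)` per locus. Monomorphic loci
#' (`p` of 0 or 1) and all-missing loci are flagged and masked from HMM
#' emission computations rather than clamped.
#'
#' @param x A `geno_panel` or `phased_panel`.
#' @return The panel's locus table with `p` and `monomorphic` filled in.
#' @export
compute_allele_freqs <- function(x) {
  g <- if (inherits(x, "phased_panel")) collapse_phase(x)$calls else x$calls
  n_a <- colSums(2L * (g == 0L) + (g == 1L), na.rm = TRUE)
  n_tot <- 2L * colSums(!is.na(g))
  p <- ifelse(n_tot > 0, n_a / n_tot, NA_real_)
  loci <- x$loci
  loci$p <- p
  loci$monomorphic <- is.na(p) | p <= 0 | p >= 1
  loci
}

#' Heterozygous locus indices of one sample
#'
#' @param x A panel.
#' @param sample Sample id or index.
#' @return Integer vector of 1-based locus indices at which the sample is
#'   heterozygous, in increasing order.
#' @export
het_loci <- function(x, sample) {
  calls <- x$calls[sample, ]
  if (inherits(x, "phased_panel")) which(calls == 1L | calls == 2L)
  else which(calls == 1L)
}

#' Build phased calls from two haplotype allele vectors
#'
#' @param left,right Allele vectors for the left and right autosome; 0/1
#'   integers (0 = A) or characters `"A"`/`"B"`.
#' @return Integer phased call codes (one per locus).
#' @export
haplotypes_to_phased <- function(left, right) {
  to_int <- function(h) if (is.character(h)) match(h, c("A", "B")) - 1L else as.integer(h)
  l <- to_int(left); r <- to_int(right)
  stopifnot(length(l) == length(r), all(l %in% c(0L, 1L, NA)), all(r %in% c(0L, 1L, NA)))
  2L * l + r
}

#' Extract the two haplotypes of a sample from a phased panel
#'
#' @param x A `phased_panel`.
#' @param sample Sample id or index.
#' @return A list with integer allele vectors `left` and `right` (0 = A,
#'   1 = B, `NA` missing).
#' @export
sample_haplotypes <- function(x, sample) {
  stopifnot(inherits(x, "phased_panel"))
  cc <- x$calls[sample, ]
  list(left = cc %/% 2L, right = cc %% 2L)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.geno_panel <- function(x, ...) {
  tibble::tibble(
    sample = rep(samples(x), times = n_loci(x)),
    locus = rep(seq_len(n_loci(x)), each = nrow(x$calls)),
    call = GENO_CALLS[as.vector(x$calls) + 1L]
  )
}

#' @export
as_tibble.phased_panel <- function(x, ...) {
  tibble::tibble(
    sample = rep(samples(x), times = n_loci(x)),
    locus = rep(seq_len(n_loci(x)), each = nrow(x$calls)),
    call = PHASED_CALLS[as.vector(x$calls) + 1L],
    phase_known = as.vector(x$phase_known)
  )
}
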