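# Two-stage Wright-Fisher simulator with recombination and founder-ancestry
# tracking. Stage 1 evolves a large random-mating pool of haplotypes to
# build up realistic relatedness; stage 2 takes a subsample of haplotypes as
# the founders of a small interbred family and evolves them for a few more
# generations. Every stage-2 haplotype carries, per locus, the identity of
# the family founder it descends from, which defines ground-truth pairwise
# IBD: a locus is truth-IBD for two samples when some haplotype of each
# descends from the same family founder there.

#' Simulation configuration
#'
#' @param n Family size (stage 2 has `2n` haplotypes, paired into `n`
#'   diploid samples).
#' @param L Genetic length of the simulated segment, centimorgans.
#' @param s Number of SNPs; default `30 * L` (an Affymetrix-100k-like
#'   density of 30 SNPs/cM).
#' @param N Large-population diploid size: stage 1 has `2N` haplotypes.
#'   Must satisfy `2n <= 2N`.
#' @param T_gens Stage-1 generations.
#' @param t_gens Stage-2 (family) generations.
#' @param founder_freq Range of the uniform distribution founder allele
#'   frequencies are drawn from.
#' @param ld_copy Per-locus probability that a founder haplotype copies its
#'   allele from a template haplotype instead of drawing it independently;
#'   0 (default) gives linkage equilibrium among founders, values near 1
#'   emulate block LD.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 50, L = 10, s = NULL, N = 400, T_gens = 10,
                       t_gens = 4, founder_freq = c(0.05, 0.95),
                       ld_copy = 0) {
  if (is.null(s)) s <- max(2L, as.integer(round(30 * L)))
  stopifnot(n >= 1, L >= 0, s >= 1, N >= 1, T_gens >= 0, t_gens >= 0,
            2 * n <= 2 * N, ld_copy >= 0, ld_copy <= 1,
            length(founder_freq) == 2, founder_freq[1] <= founder_freq[2],
            founder_freq[1] >= 0, founder_freq[2] <= 1)
  structure(list(n = n, L = L, s = as.integer(s), N = N, T_gens = T_gens,
                 t_gens = t_gens, founder_freq = founder_freq,
                 ld_copy = ld_copy), class = "sim_config")
}

#' Generate founder haplotypes
#'
#' Draws per-locus allele frequencies from the configured uniform range and
#' then `2N` binary haplotypes (0 = A, 1 = B). With `ld_copy > 0`,
#' haplotypes after the first copy each allele from a previously generated
#' template with that probability (a simple Markov copying scheme that
#' induces allelic association along the chromosome).
#'
#' @param cfg A [sim_config()].
#' @return A list with the haplotype matrix `H` (`2N` x `s`), the generating
#'   frequencies `p` (of allele A), and the genetic map `cm`.
#' @export
generate_founders <- function(cfg) {
  s <- cfg$s
  p <- runif(s, cfg$founder_freq[1], cfg$founder_freq[2])
  cm <- sort(runif(s, 0, cfg$L))
  nh <- 2L * cfg$N
  H <- matrix(0L, nh, s)
  H[1, ] <- as.integer(runif(s) >= p)
  for (i in seq_len(nh)[-1]) {
    fresh <- as.integer(runif(s) >= p)
    if (cfg$ld_copy > 0) {
      tmpl <- H[sample.int(i - 1L, 1L), ]
      copy <- runif(s) < cfg$ld_copy
      H[i, ] <- ifelse(copy, tmpl, fresh)
    } else H[i, ] <- fresh
  }
  list(H = H, p = p, cm = cm)
}

# one meiosis: recombine two parent haplotype rows; returns per-locus
# logical mask (TRUE = take parent 1)
meiosis_mask <- function(cm, L) {
  ncx <- rpois(1L, L / 100) # Haldane: Poisson crossovers, no interference
  if (ncx == 0L) return(rep(TRUE, length(cm)))
  cx <- sort(runif(ncx, 0, L))
  seg <- findInterval(cm, cx) # 0..ncx: which inter-crossover segment
  seg %% 2L == 0L
}

#' One Wright-Fisher generation with recombination
#'
#' Each offspring haplotype is a recombinant of two uniformly chosen parent
#' haplotypes (random mating with replacement, selfing allowed): the
#' crossover count is Poisson with mean `L/100` and crossover positions are
#' uniform in genetic distance. Founder-ancestry rows are spliced with the
#' same breakpoints.
#'
#' @param H Parent haplotype matrix (haplotypes x loci).
#' @param cm Genetic positions (cM) of the loci.
#' @param L Segment genetic length in cM.
#' @param anc Optional ancestry matrix parallel to `H` (founder id per
#'   locus).
#' @param n_off Number of offspring haplotypes (default: population size
#'   unchanged).
#' @return A list with the offspring `H` and (if given) `anc`.
#' @export
wright_fisher_generation <- function(H, cm, L, anc = NULL,
                                     n_off = nrow(H)) {
  nh <- nrow(H)
  H2 <- matrix(0L, n_off, ncol(H))
  A2 <- if (!is.null(anc)) matrix(0L, n_off, ncol(H)) else NULL
  for (k in seq_len(n_off)) {
    par <- sample.int(nh, 2L, replace = TRUE)
    mask <- meiosis_mask(cm, L)
    H2[k, ] <- ifelse(mask, H[par[1L], ], H[par[2L], ])
    if (!is.null(anc))
      A2[k, ] <- ifelse(mask, anc[par[1L], ], anc[par[2L], ])
  }
  list(H = H2, anc = A2)
}

#' Simulate a large interbred family
#'
#' Stage 1 evolves `2N` haplotypes for `T_gens` generations; `2n` of the
#' resulting haplotypes are then taken as family founders (each its own
#' ancestry source) and evolved as a closed population of size `2n` for
#' `t_gens` generations; the final haplotypes are paired into `n` diploid
#' samples. Genotypes are the collapsed truth haplotypes, and the locus
#' table carries allele frequencies computed from the emitted genotypes.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed for reproducibility (optional).
#' @return An object of class `family_sim`: a list with `haplotypes`
#'   (truth `phased_panel`), `genotypes` (`geno_panel`), `ancestry`
#'   (`2n` x `s` founder-id matrix, rows ordered left/right per sample),
#'   `trace` (ancestry intervals as a tibble), `loci`, and `config`.
#' @export
simulate_family <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fo <- generate_founders(cfg)
  H <- fo$H
  for (g in seq_len(cfg$T_gens))
    H <- wright_fisher_generation(H, fo$cm, cfg$L)$H
  pick <- sample.int(nrow(H), 2L * cfg$n)
  H <- H[pick, , drop = FALSE]
  anc <- matrix(rep(seq_len(2L * cfg$n), cfg$s), ncol = cfg$s)
  for (g in seq_len(cfg$t_gens)) {
    st <- wright_fisher_generation(H, fo$cm, cfg$L, anc)
    H <- st$H; anc <- st$anc
  }
  ids <- sprintf("S%03d", seq_len(cfg$n))
  left <- H[2L * seq_len(cfg$n) - 1L, , drop = FALSE]
  right <- H[2L * seq_len(cfg$n), , drop = FALSE]
  calls <- left * 2L + right # phased codes
  rownames(calls) <- ids
  loci <- locus_table(cfg$s, pos = seq_len(cfg$s), cm = fo$cm, p = fo$p)
  loci$monomorphic <- loci$p <= 0 | loci$p >= 1
  hap <- phased_panel(calls, loci)
  hap$loci <- compute_allele_freqs(hap) # realised frequencies for the HMMs
  structure(list(
    haplotypes = hap,
    genotypes = collapse_phase(hap),
    ancestry = anc,
    trace = ancestry_trace(anc, ids),
    loci = hap$loci,
    generating_p = fo$p,
    config = cfg
  ), class = "family_sim")
}

ancestry_trace <- function(anc, ids) {
  rows <- lapply(seq_len(nrow(anc)), function(h) {
    r <- rle(anc[h, ])
    ends <- cumsum(r$lengths)
    tibble::tibble(
      sample = ids[(h + 1L) %/% 2L],
      side = if (h %% 2L == 1L) "left" else "right",
      start = ends - r$lengths, end = ends, # 0-based half-open
      founder = r$values
    )
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method base::print
print.family_sim <- function(x, ...) {
  cat(sprintf("<family_sim> n=%d samples, s=%d loci, L=%g cM, t=%d family generations\n",
              x$config$n, x$config$s, x$config$L, x$config$t_gens))
  invisible(x)
}

#' Ground-truth IBD status for a sample pair
#'
#' A locus is truth-IBD for a pair when some haplotype of one sample and
#' some haplotype of the other descend from the same stage-2 family founder
#' at that locus. Founder haplotypes are distinct ancestry sources by
#' construction, so sharing between founders themselves is never counted.
#'
#' @param sim A `family_sim`.
#' @param sample_a,sample_b Sample ids or indices.
#' @return A list with the per-locus logical vector `ibd` and a tibble
#'   `segments` of maximal truth-IBD runs (0-based half-open).
#' @export
truth_ibd <- function(sim, sample_a, sample_b) {
  ids <- samples(sim$haplotypes)
  ia <- if (is.character(sample_a)) match(sample_a, ids) else sample_a
  ib <- if (is.character(sample_b)) match(sample_b, ids) else sample_b
  a1 <- sim$ancestry[2L * ia - 1L, ]; a2 <- sim$ancestry[2L * ia, ]
  b1 <- sim$ancestry[2L * ib - 1L, ]; b2 <- sim$ancestry[2L * ib, ]
  ibd <- (a1 == b1) | (a1 == b2) | (a2 == b1) | (a2 == b2)
  r <- rle(ibd)
  ends <- cumsum(r$lengths)
  keep <- which(r$values)
  segs <- tibble::tibble(
    sample_a = ids[ia], sample_b = ids[ib],
    start = (ends - r$lengths)[keep], end = ends[keep]
  )
  list(ibd = ibd, segments = segs)
}

#' Truth-IBD per-locus matrix for all pairs
#'
#' @param sim A `family_sim`.
#' @param pairs Optional two-column matrix of sample indices; default all
#'   unordered pairs.
#' @return Logical matrix, one row per pair, one column per locus, with the
#'   pair indices as attributes `pairs`.
#' @export
truth_ibd_matrix <- function(sim, pairs = NULL) {
  n <- sim$config$n
  if (is.null(pairs)) pairs <- t(combn(n, 2))
  out <- matrix(FALSE, nrow(pairs), sim$config$s)
  for (k in seq_len(nrow(pairs)))
    out[k, ] <- truth_ibd(sim, pairs[k, 1], pairs[k, 2])$ibd
  attr(out, "pairs") <- pairs
  out
}

#' Mean pairwise truth-IBD fraction
#'
#' The fraction of (pair, locus) combinations that are truth-IBD; in larger
#' families this decreases because average relatedness is lower.
#'
#' @param sim A `family_sim`.
#' @return A single number in `[0, 1]`.
#' @export
truth_ibd_fraction <- function(sim) mean(truth_ibd_matrix(sim))
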