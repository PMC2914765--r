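#' HMM parameters for IBD detection
#'
#' Bundles the tunable parameters of both detection models. The chance of
#' entering or leaving an IBD state between adjacent loci is
#' `epsilon = 2^-delta`; larger `delta` makes transitions costlier, so only
#' longer stretches of IBD-compatible evidence are decoded as IBD (the
#' minimum detectable segment length grows roughly linearly with `delta`).
#' `gamma` caps, in bits, the per-locus evidence an incompatible observation
#' can contribute against IBD, which is what keeps single genotyping errors
#' from splitting segments. `lam` and `mu` are the phased model's autosome
#' switch weights for samples 1 and 2: at every locus where a sample's next
#' observation is heterozygous, the shared segment may jump to the homologous
#' autosome with that weight. `lam = mu = 0` trusts the phase completely;
#' `lam = mu = 1/2` treats it as uninformative and reproduces the genotype
#' model exactly.
#'
#' @param delta Transition cost; `epsilon = 2^-delta`. Positive.
#' @param gamma Incompatibility evidence cap, bits. Positive.
#' @param lam,mu Switch weights in `[0, 1/2]`.
#' @param gamma_discount Discount mode for the phased emissions: `"all"`,
#'   `"incompat"`, or `"none"` (see [emission_phased()]).
#' @param init_genotype Initial distribution over (NO, IBD).
#' @param init_phased Initial distribution over (NO, LL, LR, RL, RR). The
#'   default puts 1/2 on NO and 1/8 on each IBD state, the projection
#'   compatible with the genotype model's (1/2, 1/2).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(delta = 40, gamma = 8, lam = 0.25, mu = 0.25,
                       gamma_discount = c("all", "incompat", "none"),
                       init_genotype = c(0.5, 0.5),
                       init_phased = c(0.5, rep(0.125, 4))) {
  gamma_discount <- match.arg(gamma_discount)
  stopifnot(delta > 0, gamma > 0,
            lam >= 0, lam <= 0.5, mu >= 0, mu <= 0.5,
            length(init_genotype) == 2, all(init_genotype >= 0),
            length(init_phased) == 5, all(init_phased >= 0))
  structure(list(
    delta = delta, eps = 2^-delta, gamma = gamma, lam = lam, mu = mu,
    gamma_discount = gamma_discount,
    init_genotype = init_genotype / sum(init_genotype),
    init_phased = init_phased / sum(init_phased)
  ), class = "hmm_params")
}

#' @exportS3Method base::print
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> delta=%g (eps=2^-%g), gamma=%g, lambda=%g, mu=%g, discount=%s\n",
              x$delta, x$delta, x$gamma, x$lam, x$mu, x$gamma_discount))
  invisible(x)
}

#' Two-state transition matrix of the genotype model
#'
#' Symmetric chain: switch between NO IBD and IBD with probability `eps`,
#' stay with `1 - eps`.
#'
#' @param eps Transition probability in (0, 1).
#' @return A 2x2 row-stochastic matrix with dimnames `NO`/`IBD`.
#' @export
transition_genotype <- function(eps) {
  stopifnot(eps > 0, eps < 1)
  matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2, byrow = TRUE,
         dimnames = list(c("NO", "IBD"), c("NO", "IBD")))
}

#' Five-state transition matrix of the phased model
#'
#' From NO the chain enters each IBD state with `eps/4`; from any IBD state
#' it returns to NO with `eps`. The remaining mass `1 - eps` within the IBD
#' states is redistributed by autosome switches that are only allowed when
#' the *next* observation is heterozygous for the corresponding sample:
#' sample 1's haplotype may switch (LL<->RL, LR<->RR) with weight `lam` when
#' `het_1`, sample 2's (LL<->LR, RL<->RR) with weight `mu` when `het_2`, and
#' when both are heterozygous the two switches act independently (double
#' switch `lam*mu`, single switches `lam*(1-mu)` and `(1-lam)*mu`). With
#' `lam = mu = 0` all four matrices coincide and no switching is allowed.
#'
#' @param het_1,het_2 Is the next observation heterozygous for sample 1 / 2?
#' @param eps Transition probability in (0, 1).
#' @param lam,mu Switch weights in `[0, 1/2]`.
#' @return A 5x5 row-stochastic matrix (states NO, LL, LR, RL, RR).
#' @export
transition_phased <- function(het_1, het_2, eps, lam = 0.25, mu = 0.25) {
  stopifnot(eps > 0, eps < 1, lam >= 0, lam <= 0.5, mu >= 0, mu <= 0.5)
  l <- if (het_1) lam else 0
  m <- if (het_2) mu else 0
  M <- matrix(0, 5, 5, dimnames = list(PHASED_STATES, PHASED_STATES))
  M[1, ] <- c(1 - eps, rep(eps / 4, 4))
  # IBD states indexed by (autosome of sample 1, autosome of sample 2)
  for (a in 0:1) for (b in 0:1) {
    from <- 2L + 2L * a + b # LL, LR, RL, RR
    M[from, 1] <- eps
    M[from, 2L + 2L * a + b] <- (1 - eps) * (1 - l) * (1 - m)
    M[from, 2L + 2L * (1 - a) + b] <- (1 - eps) * l * (1 - m)
    M[from, 2L + 2L * a + (1 - b)] <- (1 - eps) * (1 - l) * m
    M[from, 2L + 2L * (1 - a) + (1 - b)] <- (1 - eps) * l * m
  }
  M
}

# the four phased transition templates indexed by code = 1 + het1 + 2*het2
phased_trans_templates <- function(params) {
  lapply(0:3, function(k) transition_phased(k %% 2 == 1, k >= 2,
                                            params$eps, params$lam, params$mu))
}

# per-locus emission tables, with masked (monomorphic / unknown-p) loci
# made uninformative
geno_emis_array <- function(loci, params) {
  s <- nrow(loci)
  E <- array(1, dim = c(6, 2, s))
  ok <- which(!loci$monomorphic & !is.na(loci$p))
  for (i in ok) E[, , i] <- geno_table(loci$p[i], params$gamma, TRUE)
  E
}

phased_emis_array <- function(loci, params) {
  s <- nrow(loci)
  E <- array(1, dim = c(16, 5, s))
  ok <- which(!loci$monomorphic & !is.na(loci$p))
  for (i in ok) E[, , i] <- phased_table(loci$p[i], params$gamma,
                                         params$gamma_discount)
  E
}

haplo_emis_array <- function(loci, params) {
  s <- nrow(loci)
  E <- array(1, dim = c(3, 2, s))
  ok <- which(!loci$monomorphic & !is.na(loci$p))
  for (i in ok) E[, , i] <- haplo_table(loci$p[i], params$gamma, TRUE)
  E
}

# s x K emission matrix for one pair given class codes (NA = missing)
pair_emis <- function(E, cls) {
  s <- length(cls); K <- dim(E)[2]
  out <- matrix(1, s, K)
  ok <- which(!is.na(cls))
  for (k in seq_len(K)) out[ok, k] <- E[cbind(cls[ok], k, ok)]
  out
}

new_ibd_posterior <- function(post, model, pair, loglik, cm) {
  colnames(post) <- if (ncol(post) == 5) PHASED_STATES else c("NO", "IBD")
  structure(list(posterior = post, model = model, pair = pair,
                 loglik = loglik, cm = cm), class = "ibd_posterior")
}

#' @exportS3Method base::print
print.ibd_posterior <- function(x, ...) {
  cat(sprintf("<ibd_posterior> %s model, pair %s-%s, %d loci, P(IBD) mean %.3f\n",
              x$model, x$pair[1], x$pair[2], nrow(x$posterior),
              mean(ibd_probability(x))))
  invisible(x)
}

#' Per-locus probability of being IBD
#'
#' For the genotype and haplotype models this is the posterior of the IBD
#' state; for the phased model it is the summed posterior of the four IBD
#' states.
#'
#' @param x An `ibd_posterior`.
#' @return Numeric vector, one probability per locus.
#' @export
ibd_probability <- function(x) {
  if (x$model == "phased") rowSums(x$posterior[, 2:5, drop = FALSE])
  else x$posterior[, 2]
}

#' Posterior IBD state probabilities for one sample pair
#'
#' Runs scaled forward-backward decoding of the genotype-emission HMM (on a
#' `geno_panel`) or the phased-genotype-emission HMM (on a `phased_panel`)
#' for one pair of samples, returning exact per-locus posteriors.
#'
#' @param panel A `geno_panel` or `phased_panel`.
#' @param sample_a,sample_b Sample ids or indices.
#' @param params An [hmm_params()] object.
#' @param model `"genotype"` or `"phased"`; defaults to the model matching
#'   the panel class (a `phased_panel` can also be decoded with the genotype
#'   model, which collapses it first).
#' @return An `ibd_posterior` object.
#' @export
pair_posterior <- function(panel, sample_a, sample_b, params = hmm_params(),
                           model = NULL) {
  if (is.null(model))
    model <- if (inherits(panel, "phased_panel")) "phased" else "genotype"
  if (model == "genotype" && inherits(panel, "phased_panel"))
    panel <- collapse_phase(panel)
  if (model == "phased" && !inherits(panel, "phased_panel"))
    stop("phased model needs a phased_panel")
  loci <- panel$loci
  g1 <- panel$calls[sample_a, ]
  g2 <- panel$calls[sample_b, ]
  if (model == "genotype") {
    E <- geno_emis_array(loci, params)
    cls <- ifelse(is.na(g1) | is.na(g2), NA_integer_,
                  GENO_PAIR_CLASS[cbind(g1 + 1L, g2 + 1L)])
    emis <- pair_emis(E, cls)
    fb <- .fb_cpp(params$init_genotype, emis,
                  list(transition_genotype(params$eps)),
                  rep(1L, max(0L, length(cls) - 1L)))
  } else {
    E <- phased_emis_array(loci, params)
    cls <- ifelse(is.na(g1) | is.na(g2), NA_integer_, 4L * g1 + g2 + 1L)
    emis <- pair_emis(E, cls)
    het1 <- !is.na(g1) & (g1 == 1L | g1 == 2L)
    het2 <- !is.na(g2) & (g2 == 1L | g2 == 2L)
    code <- 1L + het1 + 2L * het2
    fb <- .fb_cpp(params$init_phased, emis, phased_trans_templates(params),
                  code[-1L])
  }
  new_ibd_posterior(fb$posterior, model,
                    c(rownames(panel$calls)[sample_a][1],
                      rownames(panel$calls)[sample_b][1]),
                    fb$loglik, loci$cm)
}

#' Posterior IBD probabilities for a pair of haplotypes
#'
#' The two-state haplotype-emission HMM, for the case where the actual
#' haplotypes of the two (haploid) sequences are observed.
#'
#' @param h1,h2 Allele vectors (0/1 or `"A"`/`"B"`, `NA` missing).
#' @param loci A locus table with valid `p` (see [locus_table()]).
#' @param params An [hmm_params()].
#' @return An `ibd_posterior` with model `"haplotype"`.
#' @export
haplotype_posterior <- function(h1, h2, loci, params = hmm_params()) {
  to_int <- function(h) if (is.character(h)) match(h, c("A", "B")) - 1L else as.integer(h)
  h1 <- to_int(h1); h2 <- to_int(h2)
  stopifnot(length(h1) == length(h2), length(h1) == nrow(loci))
  E <- haplo_emis_array(loci, params)
  cls <- ifelse(is.na(h1) | is.na(h2), NA_integer_, h1 + h2 + 1L)
  emis <- pair_emis(E, cls)
  fb <- .fb_cpp(params$init_genotype, emis,
                list(transition_genotype(params$eps)),
                rep(1L, max(0L, length(cls) - 1L)))
  new_ibd_posterior(fb$posterior, "haplotype", c("hap1", "hap2"),
                    fb$loglik, loci$cm)
}

segments_from_ibd <- function(p_ibd, labels, cm, pair, model) {
  ibd <- p_ibd > 0.5 # strict: ties decode as NOT IBD
  r <- rle(ibd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L)
    return(tibble::tibble(sample_a = character(), sample_b = character(),
                          start = integer(), end = integer(),
                          start_cm = numeric(), end_cm = numeric(),
                          n_loci = integer(), state = character(),
                          mean_posterior = numeric()))
  st <- starts[keep]; en <- ends[keep]
  lab <- vapply(seq_along(keep), function(k) {
    if (model == "phased") {
      counts <- tabulate(labels[st[k]:en[k]], nbins = 4L)
      PHASED_STATES[1L + which.max(counts)]
    } else "IBD"
  }, character(1))
  mp <- vapply(seq_along(keep), function(k) mean(p_ibd[st[k]:en[k]]), numeric(1))
  tibble::tibble(
    sample_a = pair[1], sample_b = pair[2],
    start = st - 1L, end = en, # 0-based half-open [start, end)
    start_cm = cm[st], end_cm = cm[en],
    n_loci = en - st + 1L, state = lab, mean_posterior = mp
  )
}

#' Call IBD segments from a posterior
#'
#' A locus is labelled IBD when its posterior IBD probability strictly
#' exceeds 1/2 (ties decode as NOT IBD); maximal runs of IBD loci are merged
#' into half-open, 0-based `[start, end)` segments. For the phased model a
#' segment's state label is the majority per-locus argmax among the four IBD
#' states.
#'
#' @param x An `ibd_posterior`.
#' @return A tibble of segments with columns `sample_a`, `sample_b`,
#'   `start`, `end`, `start_cm`, `end_cm`, `n_loci`, `state`,
#'   `mean_posterior`.
#' @export
decode_segments <- function(x) {
  stopifnot(inherits(x, "ibd_posterior"))
  labels <- if (x$model == "phased")
    max.col(x$posterior[, 2:5, drop = FALSE], ties.method = "first")
  else rep(1L, nrow(x$posterior))
  segments_from_ibd(ibd_probability(x), labels, x$cm, x$pair, x$model)
}

#' Detect IBD segments across sample pairs
#'
#' Runs the chosen model's forward-backward decoding for every sample pair
#' (all unordered pairs by default) and returns all decoded segments.
#'
#' @param panel A `geno_panel` or `phased_panel`.
#' @param params An [hmm_params()].
#' @param model `"genotype"` or `"phased"` (default from the panel class).
#' @param pairs Optional two-column matrix/data frame of sample ids or
#'   indices; defaults to all pairs.
#' @return A tibble of segments as in [decode_segments()].
#' @export
detect_ibd <- function(panel, params = hmm_params(), model = NULL,
                       pairs = NULL) {
  if (is.null(model))
    model <- if (inherits(panel, "phased_panel")) "phased" else "genotype"
  if (model == "genotype" && inherits(panel, "phased_panel"))
    panel <- collapse_phase(panel)
  loci <- panel$loci
  n <- nrow(panel$calls)
  if (n < 2) stop("need at least two samples")
  if (sum(!loci$monomorphic & !is.na(loci$p)) == 0)
    stop("no usable polymorphic loci in the panel")
  if (is.null(pairs)) pairs <- t(combn(n, 2))
  idx <- function(v) if (is.character(v)) match(v, rownames(panel$calls)) else as.integer(v)
  pa <- idx(pairs[, 1]); pb <- idx(pairs[, 2])

  calls <- panel$calls
  ids <- rownames(calls)
  if (model == "genotype") {
    E <- geno_emis_array(loci, params)
    templates <- list(transition_genotype(params$eps))
    init <- params$init_genotype
  } else {
    E <- phased_emis_array(loci, params)
    templates <- phased_trans_templates(params)
    init <- params$init_phased
  }
  out <- vector("list", length(pa))
  for (k in seq_along(pa)) {
    g1 <- calls[pa[k], ]; g2 <- calls[pb[k], ]
    miss <- is.na(g1) | is.na(g2)
    if (model == "genotype") {
      cls <- ifelse(miss, NA_integer_, GENO_PAIR_CLASS[cbind(g1 + 1L, g2 + 1L)])
      code <- rep(1L, length(cls) - 1L)
    } else {
      cls <- ifelse(miss, NA_integer_, 4L * g1 + g2 + 1L)
      het1 <- !is.na(g1) & (g1 == 1L | g1 == 2L)
      het2 <- !is.na(g2) & (g2 == 1L | g2 == 2L)
      code <- (1L + het1 + 2L * het2)[-1L]
    }
    fb <- .fb_cpp(init, pair_emis(E, cls), templates, code)
    post <- fb$posterior
    if (model == "phased") {
      p_ibd <- rowSums(post[, 2:5, drop = FALSE])
      labels <- max.col(post[, 2:5, drop = FALSE], ties.method = "first")
    } else {
      p_ibd <- post[, 2]
      labels <- rep(1L, nrow(post))
    }
    out[[k]] <- segments_from_ibd(p_ibd, labels, loci$cm,
                                  c(ids[pa[k]], ids[pb[k]]), model)
  }
  dplyr::bind_rows(out)
}

#' Empirical check of the genotype/phased model equivalence
#'
#' At `lam = mu = 1/2` the phased model treats the phase as uninformative
#' and its summed IBD posterior must coincide exactly with the genotype
#' model's IBD posterior on the collapsed genotypes, for any phase
#' configuration of the same data. This function measures the maximal
#' per-locus discrepancy for one pair; it uses the `"incompat"` emission
#' discount, under which the equivalence is exact (discounting
#' phase-structural zeros would perturb it by order `2^-gamma`).
#'
#' @param panel A `phased_panel`.
#' @param sample_a,sample_b Sample ids or indices.
#' @param params An [hmm_params()]; `lam`, `mu` and `gamma_discount` are
#'   overridden.
#' @return Maximum over loci of |sum of phased IBD posteriors - genotype
#'   P(IBD)|.
#' @export
theorem1_check <- function(panel, sample_a, sample_b,
                           params = hmm_params()) {
  stopifnot(inherits(panel, "phased_panel"))
  p2 <- hmm_params(delta = params$delta, gamma = params$gamma,
                   lam = 0.5, mu = 0.5, gamma_discount = "incompat",
                   init_genotype = params$init_genotype,
                   init_phased = c(params$init_genotype[1],
                                   rep(params$init_genotype[2] / 4, 4)))
  ph <- pair_posterior(panel, sample_a, sample_b, p2, model = "phased")
  gt <- pair_posterior(collapse_phase(panel), sample_a, sample_b, p2,
                       model = "genotype")
  max(abs(ibd_probability(ph) - ibd_probability(gt)))
}
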