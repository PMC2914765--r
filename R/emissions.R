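# Emission models.
#
# All probabilities are functions of p, the population frequency of allele A
# at the locus (q = 1 - p). The genotype model emits one of the six unordered
# genotype pairs; the phased model emits one of the 16 ordered pairs; the
# haplotype model emits one of the three unordered allele pairs.
#
# Incompatible observations ({AA, BB} between the two samples) have true
# emission probability zero under IBD; to stay robust to genotyping error
# they are instead discounted to 2^-gamma times the NO-IBD probability, so
# that the per-locus log-evidence pro NO IBD is capped at exactly gamma bits.

GENO_PAIRS <- c("AA,AA", "AA,AB", "AA,BB", "AB,AB", "AB,BB", "BB,BB")
PHASED_STATES <- c("NO", "LL", "LR", "RL", "RR")

# unordered pair class (1..6) from two genotype codes 0..2
GENO_PAIR_CLASS <- matrix(c(1L, 2L, 3L,
                            2L, 4L, 5L,
                            3L, 5L, 6L), 3, 3, byrow = TRUE)

# 6 x 2 emission table for the genotype model at one p
geno_table <- function(p, gamma, discount = TRUE) {
  q <- 1 - p
  no <- c(p^4, 4 * p^3 * q, 2 * p^2 * q^2, 4 * p^2 * q^2, 4 * p * q^3, q^4)
  ibd <- c(p^3, 2 * p^2 * q, 0, p * q, 2 * p * q^2, q^3)
  if (discount) ibd[3] <- no[3] * 2^-gamma
  cbind(NO = no, IBD = ibd)
}

# 16 x 5 emission table for the phased model at one p.
# Rows ordered (g1, g2) with g1, g2 in AA, AB, BA, BB, i.e. row = 4*c1+c2+1.
# discount: "all" replaces every structural zero under an IBD state by the
# NO entry times 2^-gamma; "incompat" does so only for the genotype-
# incompatible rows (AA,BB)/(BB,AA), which preserves exact equivalence with
# the genotype model at lambda = mu = 1/2; "none" keeps literal zeros.
phased_table <- function(p, gamma, discount = c("all", "incompat", "none")) {
  discount <- match.arg(discount)
  q <- 1 - p
  no <- c(p^4, p^3 * q, p^3 * q, p^2 * q^2,
          p^3 * q, p^2 * q^2, p^2 * q^2, p * q^3,
          p^3 * q, p^2 * q^2, p^2 * q^2, p * q^3,
          p^2 * q^2, p * q^3, p * q^3, q^4)
  z <- 0
  ll <- c(p^3, p^2 * q, z, z,  p^2 * q, p * q^2, z, z,  z, z, p^2 * q, p * q^2,  z, z, p * q^2, q^3)
  lr <- c(p^3, z, p^2 * q, z,  p^2 * q, z, p * q^2, z,  z, p^2 * q, z, p * q^2,  z, p * q^2, z, q^3)
  rl <- c(p^3, p^2 * q, z, z,  z, z, p^2 * q, p * q^2,  p^2 * q, p * q^2, z, z,  z, z, p * q^2, q^3)
  rr <- c(p^3, z, p^2 * q, z,  z, p^2 * q, z, p * q^2,  p^2 * q, z, p * q^2, z,  z, p * q^2, z, q^3)
  tab <- cbind(NO = no, LL = ll, LR = lr, RL = rl, RR = rr)
  if (discount != "none") {
    rows <- if (discount == "all") seq_len(16) else c(4L, 13L)
    for (s in 2:5) {
      zero <- tab[rows, s] == 0
      tab[rows[zero], s] <- tab[rows[zero], 1] * 2^-gamma
    }
  }
  tab
}

# 3 x 2 emission table for the haplotype model ({A,A}, {A,B}, {B,B})
haplo_table <- function(p, gamma, discount = TRUE) {
  q <- 1 - p
  no <- c(p^2, 2 * p * q, q^2)
  ibd <- c(p, 0, q)
  if (discount) ibd[2] <- no[2] * 2^-gamma
  cbind(NO = no, IBD = ibd)
}

#' Genotype-model emission probabilities
#'
#' Emission probabilities of an unordered genotype pair under the two hidden
#' states NO IBD / IBD of the genotype-emission HMM. The incompatible pair
#' (one sample `AA`, the other `BB`) is impossible under IBD; with
#' `gamma_discount = TRUE` it instead emits `2^-gamma` times its NO-IBD
#' probability so the log-evidence against IBD is capped at `gamma` bits.
#' Any missing call is uninformative and emits probability 1 in both states.
#'
#' @param g1,g2 Genotype calls (`"AA"`, `"AB"`, `"BB"`, `NA`), vectorised.
#' @param p Frequency of allele A, in (0, 1); vectorised.
#' @param gamma Log-evidence cap for incompatible observations, in bits.
#' @param gamma_discount Apply the incompatibility discount?
#' @return A tibble with columns `p_no_ibd` and `p_ibd`.
#' @export
emission_genotype <- function(g1, g2, p, gamma = 8, gamma_discount = TRUE) {
  n <- max(length(g1), length(g2), length(p))
  g1 <- rep_len(match(g1, GENO_CALLS) - 1L, n)
  g2 <- rep_len(match(g2, GENO_CALLS) - 1L, n)
  p <- rep_len(p, n)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)")
  out <- matrix(1, n, 2)
  ok <- !is.na(g1) & !is.na(g2)
  if (any(ok)) {
    cls <- GENO_PAIR_CLASS[cbind(g1[ok] + 1L, g2[ok] + 1L)]
    tabs <- vapply(which(ok), function(i) {
      geno_table(p[i], gamma, gamma_discount)[GENO_PAIR_CLASS[g1[i] + 1L, g2[i] + 1L], ]
    }, numeric(2))
    out[ok, ] <- t(tabs)
  }
  tibble::tibble(p_no_ibd = out[, 1], p_ibd = out[, 2])
}

#' Phased-model emission probabilities
#'
#' Emission probability of an ordered phased-genotype pair under one of the
#' five hidden states (`NO`, `LL`, `LR`, `RL`, `RR`) of the phased-genotype
#' HMM. State `LL` means the left autosome of sample 1 shares a haplotype
#' IBD with the left autosome of sample 2, and so on.
#'
#' @param pg1,pg2 Phased calls (`"AA"`, `"AB"`, `"BA"`, `"BB"`, `NA`).
#' @param state One of `"NO"`, `"LL"`, `"LR"`, `"RL"`, `"RR"`.
#' @param p Frequency of allele A, in (0, 1).
#' @param gamma Log-evidence cap, in bits.
#' @param gamma_discount `"all"` discounts every structurally-zero IBD cell
#'   (robust default), `"incompat"` only genotype-incompatible observations,
#'   `"none"` keeps literal zeros.
#' @return Numeric vector of emission probabilities.
#' @export
emission_phased <- function(pg1, pg2, state, p, gamma = 8,
                            gamma_discount = c("all", "incompat", "none")) {
  gamma_discount <- match.arg(gamma_discount)
  n <- max(length(pg1), length(pg2), length(p), length(state))
  c1 <- rep_len(match(pg1, PHASED_CALLS) - 1L, n)
  c2 <- rep_len(match(pg2, PHASED_CALLS) - 1L, n)
  st <- rep_len(match(state, PHASED_STATES), n)
  p <- rep_len(p, n)
  if (anyNA(st)) stop("unknown state label")
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)")
  out <- rep(1, n)
  ok <- !is.na(c1) & !is.na(c2)
  out[ok] <- vapply(which(ok), function(i) {
    phased_table(p[i], gamma, gamma_discount)[4L * c1[i] + c2[i] + 1L, st[i]]
  }, numeric(1))
  out
}

#' Haplotype-model emission probabilities
#'
#' Two-state model for a pair of observed haplotypes: an unordered allele
#' pair emits `p^2 / 2pq / q^2` under NO IBD and `p / 0 / q` under IBD, the
#' mismatch `{A, B}` being discounted to `2pq * 2^-gamma` when
#' `gamma_discount` is on.
#'
#' @param a1,a2 Alleles (`"A"`/`"B"` or 0/1).
#' @param p Frequency of allele A.
#' @param gamma,gamma_discount As in [emission_genotype()].
#' @return A tibble with columns `p_no_ibd` and `p_ibd`.
#' @export
emission_haplotype <- function(a1, a2, p, gamma = 8, gamma_discount = TRUE) {
  to_int <- function(h) if (is.character(h)) match(h, c("A", "B")) - 1L else as.integer(h)
  n <- max(length(a1), length(a2), length(p))
  a1 <- rep_len(to_int(a1), n); a2 <- rep_len(to_int(a2), n); p <- rep_len(p, n)
  cls <- a1 + a2 + 1L # 1 = {A,A}, 2 = {A,B}, 3 = {B,B}
  out <- matrix(1, n, 2)
  ok <- !is.na(cls)
  out[ok, ] <- t(vapply(which(ok), function(i) {
    haplo_table(p[i], gamma, gamma_discount)[cls[i], ]
  }, numeric(2)))
  tibble::tibble(p_no_ibd = out[, 1], p_ibd = out[, 2])
}

#' Per-locus log-evidence pro NO IBD
#'
#' `lev_g` is `log2` of the genotype-model NO-IBD over IBD emission
#' probabilities; the incompatible pair `{AA, BB}` takes the capped value
#' `gamma` exactly. `lev_h` is the haplotype-model analogue, with the
#' mismatching pair `{A, B}` capped at `gamma`.
#'
#' @inheritParams emission_genotype
#' @return Numeric vector of log-evidences, in bits.
#' @export
lev_g <- function(g1, g2, p, gamma = 8) {
  e <- emission_genotype(g1, g2, p, gamma, gamma_discount = TRUE)
  log2(e$p_no_ibd / e$p_ibd)
}

#' @rdname lev_g
#' @inheritParams emission_haplotype
#' @export
lev_h <- function(a1, a2, p, gamma = 8) {
  e <- emission_haplotype(a1, a2, p, gamma, gamma_discount = TRUE)
  log2(e$p_no_ibd / e$p_ibd)
}

#' Moments of the accumulated log-evidence
#'
#' Exact mean, variance and standard deviation of the per-locus log-evidence
#' variables that drive IBD detectability: `Sigma_NO||IBD` is `lev_g`
#' averaged over genotype pairs drawn from the IBD state (the evidence pro
#' NO IBD collected while truly IBD), `Sigma_IBD||NO` is `-lev_g` under the
#' NO-IBD state, and `Omega_*` are the haplotype-model analogues using
#' `lev_h`. The mean-to-sd ratio of the Omega variables is markedly larger
#' in magnitude than that of the Sigma variables, which quantifies how much
#' easier IBD detection is with haplotype data than with genotype data.
#'
#' @param p Frequency of allele A, in (0, 1); vectorised.
#' @param gamma Log-evidence cap in bits.
#' @return A tibble with one row per (p, variable, condition): columns `p`,
#'   `model` (`"genotype"`/`"haplotype"`), `variable` (`"sigma"`/`"omega"`),
#'   `condition` (`"ibd_given_no"`, `"no_given_ibd"`), `mean`, `var`, `sd`.
#' @export
sigma_omega_moments <- function(p, gamma = 8) {
  one <- function(pp) {
    gt <- geno_table(pp, gamma, discount = FALSE)
    lg <- log2(geno_table(pp, gamma, TRUE)[, 1] / geno_table(pp, gamma, TRUE)[, 2])
    ht <- haplo_table(pp, gamma, discount = FALSE)
    lh <- log2(haplo_table(pp, gamma, TRUE)[, 1] / haplo_table(pp, gamma, TRUE)[, 2])
    mom <- function(x, w) {
      m <- sum(w * x); v <- sum(w * (x - m)^2)
      c(mean = m, var = v, sd = sqrt(v))
    }
    rows <- rbind(
      c(mom(-lg, gt[, "NO"])),  # Sigma_IBD||NO
      c(mom(lg, gt[, "IBD"])),  # Sigma_NO||IBD
      c(mom(-lh, ht[, "NO"])),  # Omega_IBD||NO
      c(mom(lh, ht[, "IBD"]))   # Omega_NO||IBD
    )
    tibble::tibble(
      p = pp,
      model = rep(c("genotype", "haplotype"), each = 2),
      variable = rep(c("sigma", "omega"), each = 2),
      condition = rep(c("ibd_given_no", "no_given_ibd"), 2),
      mean = rows[, "mean"], var = rows[, "var"], sd = rows[, "sd"]
    )
  }
  dplyr::bind_rows(lapply(p, one))
}
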