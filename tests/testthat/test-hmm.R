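test_that("transition matrices are row-stochastic and obey the switch rules", {
  set.seed(2)
  for (r in 1:20) {
    eps <- runif(1, 1e-12, 0.2)
    lam <- runif(1, 0, 0.5); mu <- runif(1, 0, 0.5)
    for (h1 in c(FALSE, TRUE)) for (h2 in c(FALSE, TRUE)) {
      M <- transition_phased(h1, h2, eps, lam, mu)
      expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
      expect_equal(unname(M[1, ]), c(1 - eps, rep(eps / 4, 4)))
      expect_equal(unname(M[2:5, 1]), rep(eps, 4))
    }
  }
  # no switching when lam = mu = 0: all four heterozygosity patterns coincide
  mats <- lapply(0:3, function(k)
    transition_phased(k %% 2 == 1, k >= 2, 0.01, 0, 0))
  for (k in 2:4) expect_identical(mats[[1]], mats[[k]])
  expect_equal(unname(diag(mats[[1]])[2:5]), rep(0.99, 4))
  # both heterozygous at lam = mu = 1/2: uniform over the four IBD states
  M <- transition_phased(TRUE, TRUE, 0.04, 0.5, 0.5)
  expect_equal(unname(M[2, 2:5]), rep(0.96 / 4, 4))
  # single switch weights: from LL, sample-1 het only moves mass to RL
  M <- transition_phased(TRUE, FALSE, 0.01, 0.3, 0.25)
  expect_equal(M["LL", "RL"], 0.99 * 0.3)
  expect_equal(M["LL", "LR"], 0)
  M <- transition_phased(FALSE, TRUE, 0.01, 0.3, 0.25)
  expect_equal(M["LL", "LR"], 0.99 * 0.25)
  expect_equal(M["RL", "RR"], 0.99 * 0.25)
})

test_that("single-locus posterior matches one-step Bayes", {
  p <- 0.5; gamma <- 8
  panel <- geno_panel(matrix(c("AA", "BB"), 2, 1), locus_table(1, p = p))
  post <- pair_posterior(panel, 1, 2, hmm_params(delta = 10, gamma = gamma))
  expected <- 2^-gamma / (1 + 2^-gamma) # uniform prior, likelihood ratio 2^-gamma
  expect_equal(unname(post$posterior[1, "IBD"]), expected, tolerance = 1e-12)
})

test_that("runs of incompatible observations drive P(IBD) down monotonically", {
  p_first <- sapply(1:8, function(k) {
    panel <- geno_panel(matrix(rep(c("AA", "BB"), k), nrow = 2),
                        locus_table(k, p = 0.5))
    post <- pair_posterior(panel, 1, 2, hmm_params(delta = 4, gamma = 2))
    post$posterior[1, "IBD"]
  })
  expect_true(all(diff(p_first) < 0))
})

test_that("forward-backward equals exhaustive path enumeration (genotype model)", {
  set.seed(11)
  params <- hmm_params(delta = 3, gamma = 4)
  for (T_ in c(1, 2, 5, 8, 10)) {
    ph <- random_phased_panel(2, T_)
    g <- collapse_phase(ph)
    post <- pair_posterior(g, 1, 2, params)$posterior
    emis <- pair_emis_genotype(g, 1, 2, params)
    oracle <- enum_posterior(params$init_genotype, emis,
                             list(transition_genotype(params$eps)),
                             rep(1L, max(0, T_ - 1)))
    expect_lt(max(abs(post - oracle)), 1e-10)
  }
})

test_that("forward-backward equals exhaustive path enumeration (phased model)", {
  set.seed(12)
  for (T_ in c(1, 3, 5, 6)) {
    for (rep in 1:2) {
      params <- hmm_params(delta = sample(2:6, 1), gamma = 4,
                           lam = runif(1, 0, 0.5), mu = runif(1, 0, 0.5))
      ph <- random_phased_panel(2, T_)
      post <- pair_posterior(ph, 1, 2, params)$posterior
      emis <- pair_emis_phased(ph, 1, 2, params)
      g1 <- ph$calls[1, ]; g2 <- ph$calls[2, ]
      code <- (1L + (g1 == 1L | g1 == 2L) + 2L * (g2 == 1L | g2 == 2L))[-1L]
      templates <- lapply(0:3, function(k)
        transition_phased(k %% 2 == 1, k >= 2, params$eps, params$lam, params$mu))
      oracle <- enum_posterior(params$init_phased, emis, templates, code)
      expect_lt(max(abs(post - oracle)), 1e-10)
    }
  }
})

test_that("posterior rows are normalised probability vectors", {
  set.seed(13)
  ph <- random_phased_panel(2, 150)
  post <- pair_posterior(ph, 1, 2, hmm_params(delta = 10))$posterior
  expect_lt(max(abs(rowSums(post) - 1)), 1e-12)
  expect_true(all(post >= 0))
})

test_that("segment decoding merges maximal runs and treats ties as NOT IBD", {
  mk <- function(p_ibd) {
    post <- cbind(NO = 1 - p_ibd, IBD = p_ibd)
    structure(list(posterior = post, model = "genotype", pair = c("a", "b"),
                   loglik = 0, cm = seq_along(p_ibd) * 0.1),
              class = "ibd_posterior")
  }
  segs <- decode_segments(mk(c(0.9, 0.9, 0.2, 0.8)))
  expect_equal(segs$start, c(0L, 3L))
  expect_equal(segs$end, c(2L, 4L))
  expect_equal(segs$mean_posterior, c(0.9, 0.8))
  expect_equal(nrow(decode_segments(mk(rep(0.4, 5)))), 0)
  expect_equal(nrow(decode_segments(mk(c(0.5, 0.5)))), 0)
})

test_that("phased-model equivalence to the genotype model at lam = mu = 1/2", {
  set.seed(14)
  params <- hmm_params(delta = 8, gamma = 8)
  for (r in 1:10) {
    ph <- random_phased_panel(2, 100)
    expect_lt(theorem1_check(ph, 1, 2, params), 1e-9)
  }
  # invariance under arbitrary re-phasing of the same genotypes
  ph <- random_phased_panel(2, 120)
  g_ref <- collapse_phase(ph)$calls
  for (r in 1:3) {
    for (i in 1:2) {
      y <- get_phase(ph, i)
      ph <- apply_phase(ph, i, as.integer(runif(length(y)) < 0.5))
    }
    expect_identical(collapse_phase(ph)$calls, g_ref)
    expect_lt(theorem1_check(ph, 1, 2, params), 1e-9)
  }
  # away from 1/2 the two models genuinely differ
  p25 <- hmm_params(delta = 8, gamma = 8, lam = 0.25, mu = 0.25,
                    gamma_discount = "incompat")
  pp <- pair_posterior(ph, 1, 2, p25)
  pg <- pair_posterior(collapse_phase(ph), 1, 2, p25)
  expect_gt(max(abs(ibd_probability(pp) - ibd_probability(pg))), 1e-6)
})

test_that("raising delta suppresses short segments, never conjures new ones", {
  # higher transition cost lengthens the minimum detectable segment: strong
  # segments persist (their boundaries may extend), short ones drop out, and
  # no segment appears in a region that carried none at a lower delta
  sim <- tiny_family(seed = 21)
  for (pr in list(c(1, 2), c(3, 7), c(2, 5))) {
    segs <- lapply(c(4, 8, 14), function(d)
      decode_segments(pair_posterior(sim$genotypes, pr[1], pr[2],
                                     hmm_params(delta = d))))
    for (k in 2:3) {
      expect_lte(nrow(segs[[k]]), nrow(segs[[k - 1]]))
      if (nrow(segs[[k]]) > 0) {
        overlaps <- vapply(seq_len(nrow(segs[[k]])), function(r)
          any(segs[[k]]$start[r] < segs[[k - 1]]$end &
              segs[[k]]$end[r] > segs[[k - 1]]$start), logical(1))
        expect_true(all(overlaps))
      }
    }
    if (nrow(segs[[1]]) > 0 && nrow(segs[[2]]) > 0)
      expect_gte(min(segs[[2]]$n_loci), min(segs[[1]]$n_loci))
  }
})

test_that("with trusted phase (lam = mu = 0) the phased model reduces to the haplotype model", {
  set.seed(31)
  s <- 300
  p <- runif(s, 0.1, 0.9)
  loci <- locus_table(s, cm = seq_len(s) * 0.03, p = p)
  draw <- function() as.integer(runif(s) >= p)
  shared <- draw()
  h1l <- draw(); h2l <- draw()
  h1l[101:200] <- shared[101:200] # one truly shared left-left segment
  h2l[101:200] <- shared[101:200]
  ph <- phased_panel(rbind(haplotypes_to_phased(h1l, draw()),
                           haplotypes_to_phased(h2l, draw())), loci)
  params <- hmm_params(delta = 10, gamma = 8, lam = 0, mu = 0)
  ibd_ph <- ibd_probability(pair_posterior(ph, 1, 2, params)) > 0.5
  ibd_hap <- ibd_probability(haplotype_posterior(h1l, h2l, loci, params)) > 0.5
  # transition into IBD differs by the eps/4 split, so allow boundary loci
  expect_gt(mean(ibd_ph == ibd_hap), 0.98)
  expect_gt(mean(ibd_hap[101:200]), 0.9)
  expect_gt(mean(ibd_ph[101:200]), 0.9)
})

test_that("missing observations and monomorphic loci are uninformative", {
  calls <- matrix(c("AA", "BB", NA,
                    "BB", "BB", "AB"), 2, 3, byrow = TRUE)
  panel <- geno_panel(calls, locus_table(3, p = c(0.5, 1, 0.5)))
  post <- pair_posterior(panel, 1, 2, hmm_params(delta = 5, gamma = 3))
  # locus 2 (monomorphic) and locus 3 (missing) emit 1 in both states; the
  # posterior there is driven purely by the chain and locus 1's evidence
  expect_true(all(post$posterior[, "IBD"] < 0.5))
  single <- geno_panel(matrix(c(NA, "AA"), 2, 1), locus_table(1, p = 0.4))
  post1 <- pair_posterior(single, 1, 2, hmm_params())
  expect_equal(unname(post1$posterior[1, ]), c(0.5, 0.5))
})
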