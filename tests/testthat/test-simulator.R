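test_that("simulation is deterministic given a seed", {
  cfg <- sim_config(n = 6, L = 4, s = 50, N = 30, T_gens = 2, t_gens = 2)
  a <- simulate_family(cfg, seed = 123)
  b <- simulate_family(cfg, seed = 123)
  expect_identical(a$haplotypes$calls, b$haplotypes$calls)
  expect_identical(a$ancestry, b$ancestry)
  expect_identical(a$loci, b$loci)
})

test_that("genotypes are exactly the collapsed truth haplotypes", {
  sim <- tiny_family(seed = 1)
  expect_identical(sim$genotypes$calls, collapse_phase(sim$haplotypes)$calls)
})

test_that("ancestry intervals partition the chromosome", {
  sim <- tiny_family(seed = 2)
  s <- sim$config$s
  for (grp in split(sim$trace, paste(sim$trace$sample, sim$trace$side))) {
    grp <- grp[order(grp$start), ]
    expect_equal(grp$start[1], 0)
    expect_equal(grp$end[nrow(grp)], s)
    if (nrow(grp) > 1) expect_equal(grp$start[-1], grp$end[-nrow(grp)])
  }
  # with t = 0 every haplotype is a single founder block
  sim0 <- simulate_family(sim_config(n = 5, L = 5, s = 40, N = 30,
                                     T_gens = 1, t_gens = 0), seed = 3)
  expect_equal(nrow(sim0$trace), 10)
  expect_equal(sort(sim0$trace$founder), 1:10)
})

test_that("zero genetic length means no recombination", {
  H <- matrix(sample(0:1, 8 * 20, replace = TRUE), 8, 20)
  off <- wright_fisher_generation(H, cm = rep(0, 20), L = 0)$H
  for (k in seq_len(nrow(off)))
    expect_true(any(apply(H, 1, identical, off[k, ])))
})

test_that("crossover counts are Poisson with mean L/100", {
  set.seed(17)
  L <- 10; cm <- sort(runif(400, 0, L))
  switches <- replicate(10000, {
    mask <- ibdphase:::meiosis_mask(cm, L)
    sum(diff(mask) != 0)
  })
  # switches undercount crossovers only when two land in one marker gap
  expect_lt(abs(mean(switches) - L / 100), 4 * sqrt(L / 100 / 10000) + 0.002)
})

test_that("allele-frequency drift behaves like Wright-Fisher", {
  set.seed(18)
  # fixation probability of an allele equals its starting frequency
  fixed_b <- replicate(300, {
    H <- matrix(as.integer(runif(8) < 0.5), 8, 1)
    start <- mean(H)
    for (g in 1:200) {
      H <- wright_fisher_generation(H, cm = 0, L = 0)$H
      m <- mean(H)
      if (m == 0 || m == 1) break
    }
    c(start, mean(H))
  })
  started_half <- fixed_b[1, ] == 0.5
  expect_gt(sum(started_half), 50)
  frac <- mean(fixed_b[2, started_half])
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(sum(started_half)))
})

test_that("founders are in linkage equilibrium unless LD copying is on", {
  set.seed(19)
  fo <- generate_founders(sim_config(n = 50, L = 10, s = 200, N = 400))
  r2 <- sapply(1:199, function(l) suppressWarnings(cor(fo$H[, l], fo$H[, l + 1]))^2)
  expect_lt(mean(r2, na.rm = TRUE), 0.01)
  fo_ld <- generate_founders(sim_config(n = 50, L = 10, s = 200, N = 400,
                                        ld_copy = 0.9))
  r2_ld <- sapply(1:199, function(l)
    suppressWarnings(cor(fo_ld$H[, l], fo_ld$H[, l + 1]))^2)
  expect_gt(mean(r2_ld, na.rm = TRUE), 5 * mean(r2, na.rm = TRUE))
})

test_that("truth IBD follows founder ancestry", {
  sim <- tiny_family(seed = 4)
  # a sample against itself shares everywhere
  expect_true(all(truth_ibd(sim, 1, 1)$ibd))
  # hand-built traces: parent carries founders 1,2; child inherits a splice
  # of them -> IBD everywhere; an unrelated pair with disjoint founders -> none
  anc <- rbind(c(1, 1, 1, 1), c(2, 2, 2, 2),   # parent
               c(1, 1, 2, 2), c(3, 3, 3, 3),   # child
               c(4, 4, 4, 4), c(5, 5, 5, 5))   # unrelated
  fake <- structure(list(
    ancestry = anc,
    haplotypes = phased_panel(matrix(0L, 3, 4,
                                     dimnames = list(c("P", "C", "U"), NULL)),
                              locus_table(4, p = 0.5)),
    config = sim_config(n = 3, L = 1, s = 4, N = 5, T_gens = 0, t_gens = 0)
  ), class = "family_sim")
  pc <- truth_ibd(fake, "P", "C")
  expect_true(all(pc$ibd))
  expect_equal(pc$segments$start, 0L)
  expect_equal(pc$segments$end, 4L)
  expect_false(any(truth_ibd(fake, "P", "U")$ibd))
})
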