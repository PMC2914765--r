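# Link semantics: a source homozygous for the same allele class at both
# linked loci votes +1 (target's heterozygous alleles on the same autosome);
# different classes vote -1.

test_that("links are collected per Algorithm 1 with the satisfied/unsatisfied sign", {
  seg <- tibble::tibble(sample_a = "T", sample_b = "S", start = 0L, end = 5L)
  # source homozygous for DIFFERENT alleles at the two linked loci: with the
  # target's het alleles currently both on the left the link is unsatisfied
  tgt <- c("AB", "AA", "BB", "AB", "AA")
  src_diff <- c("AA", "AA", "AB", "BB", "AA") # hom at linked loci 1 and 4
  panel <- phased_panel(rbind(T = tgt, S = src_diff),
                        locus_table(5, p = 0.5))
  links <- collect_links(panel, seg)
  expect_equal(nrow(links$T$links), 1)
  expect_equal(links$T$links$value, -1L)
  expect_equal(links$T$het_loci, c(1L, 4L))
  y0 <- get_phase(panel, "T") # both het alleles on the left: c(0, 0)
  expect_equal(phase_objective(y0, links$T), -1L) # Figure-4 style: unsatisfied
  expect_equal(phase_objective(c(0L, 1L), links$T), 1L) # re-phased: satisfied
  # source homozygous for the SAME allele: the same phase satisfies the link
  src_same <- c("AA", "AA", "AB", "AA", "AA")
  panel2 <- phased_panel(rbind(T = tgt, S = src_same), locus_table(5, p = 0.5))
  links2 <- collect_links(panel2, seg)
  expect_equal(links2$T$links$value, 1L)
  expect_equal(phase_objective(y0, links2$T), 1L)
})

test_that("links join only consecutive qualifying loci and both roles are scanned", {
  seg <- tibble::tibble(sample_a = "A", sample_b = "B", start = 0L, end = 6L)
  a <- c("AB", "AB", "AB", "AA", "AB", "BB")
  b <- c("AA", "AB", "BB", "AB", "AA", "AB")
  panel <- phased_panel(rbind(A = a, B = b), locus_table(6, p = 0.5))
  links <- collect_links(panel, seg)
  # A is het at 1,2,3,5; B hom at 1,3,5 -> consecutive qualifying pairs
  # (1,3) and (3,5) in locus space = ordinals (1,3) and (3,4); locus 2 is
  # skipped because B is heterozygous there
  expect_equal(links$A$links$i, c(1L, 3L))
  expect_equal(links$A$links$j, c(3L, 4L))
  # roles swapped: B is het at 2,4,6; A hom at 4 and 6 only -> one link
  expect_equal(nrow(links$B$links), 1)
  expect_equal(links$B$links$i, 2L)
  expect_equal(links$B$links$j, 3L)
  # a segment where the target has < 2 qualifying loci contributes nothing
  seg2 <- tibble::tibble(sample_a = "A", sample_b = "B", start = 0L, end = 2L)
  links2 <- collect_links(panel, seg2)
  expect_equal(nrow(links2$A$links), 0)
  expect_error(collect_links(panel, tibble::tibble(
    sample_a = "A", sample_b = "B", start = 0L, end = 9L)), "bounds")
})

test_that("the objective counts satisfied minus unsatisfied links", {
  lk <- make_links(3, i = c(1, 2), j = c(2, 3), value = c(2, -1))
  expect_equal(phase_objective(c(0, 0, 0), lk), 1L)
  lk1 <- make_links(2, 1, 2, 1)
  expect_equal(phase_objective(c(0, 0), lk1), 1L)
  expect_equal(phase_objective(c(0, 1), lk1), -1L)
  # global flip invariance
  set.seed(5)
  for (r in 1:10) {
    lk <- random_links(10, 8)
    y <- sample(0:1, 10, replace = TRUE)
    expect_equal(phase_objective(y, lk), phase_objective(1L - y, lk))
  }
})

test_that("signed link bookkeeping agrees with the direct objective", {
  set.seed(6)
  for (r in 1:20) {
    m <- sample(5:15, 1)
    lk <- random_links(m, m)
    y <- sample(0:1, m, replace = TRUE)
    z <- as.integer(xor(y[-m], y[-1]))
    expect_equal(sum(ibdphase:::link_signs(lk$links, z)),
                 phase_objective(y, lk))
  }
})

test_that("the sliding-window search never decreases the objective and terminates", {
  set.seed(7)
  for (r in 1:25) {
    m <- sample(6:20, 1)
    lk <- random_links(m, sample(3:(2 * m), 1))
    y0 <- sample(0:1, m, replace = TRUE)
    res <- update_phase(y0, lk, s = sample(1:5, 1))
    expect_gte(res$objective, phase_objective(y0, lk))
    expect_equal(phase_objective(res$y, lk), res$objective)
    # a fixed point: re-running changes nothing
    res2 <- update_phase(res$y, lk, s = 4)
    expect_equal(res2$objective, res$objective)
  }
  # already-satisfied links leave the phase untouched
  lk <- make_links(4, i = c(1, 2), j = c(2, 4), value = c(1, 2))
  res <- update_phase(c(0L, 0L, 0L, 0L), lk, s = 3)
  expect_identical(res$y, c(0L, 0L, 0L, 0L))
})

test_that("a sample linked consistently to several others is phased to satisfy all links", {
  # five samples; the centre one is IBD with all four, each contributing a
  # link; the unique compatible configuration satisfies every link
  ctr <- c("AB", "AB", "AB", "AB")
  s1 <- c("AA", "AA", "AB", "AB") # hom A/A at loci 1,2 -> +1 on (1,2)
  s2 <- c("AB", "AA", "BB", "AB") # hom A/B at loci 2,3 -> -1 on (2,3)
  s3 <- c("AB", "AB", "BB", "BB") # hom B/B at loci 3,4 -> +1 on (3,4)
  s4 <- c("BB", "AB", "AB", "AA") # hom B/A at loci 1,4 -> -1 on (1,4)
  panel <- phased_panel(rbind(C = ctr, S1 = s1, S2 = s2, S3 = s3, S4 = s4),
                        locus_table(4, p = 0.5))
  segs <- tibble::tibble(sample_a = "C", sample_b = c("S1", "S2", "S3", "S4"),
                         start = 0L, end = 4L)
  links <- collect_links(panel, segs)
  expect_equal(nrow(links$C$links), 4)
  res <- update_phase(get_phase(panel, "C"), links$C, s = 4)
  expect_equal(res$objective, sum(abs(links$C$links$value)))
  # the configuration is the unique one (up to global flip): y = (0,0,1,1)
  expect_true(identical(res$y, c(0L, 0L, 1L, 1L)) ||
              identical(res$y, c(1L, 1L, 0L, 0L)))
})

test_that("brute force handles degenerate link matrices", {
  empty <- make_links(5, integer(), integer(), integer())
  expect_equal(brute_force_phase(empty)$objective, 0L)
  single <- make_links(6, 2, 5, 3)
  expect_equal(brute_force_phase(single)$objective, 3L)
  big <- make_links(25, 1, 2, 1)
  expect_error(brute_force_phase(big), "m <= 20")
})

test_that("chain-structured instances are solved to optimality", {
  set.seed(8)
  for (r in 1:20) {
    m <- 12
    lk <- make_links(m, i = 1:(m - 1), j = 2:m,
                     value = sample(c(-2L, -1L, 1L, 2L), m - 1, replace = TRUE))
    bf <- brute_force_phase(lk)
    up <- update_phase(sample(0:1, m, replace = TRUE), lk, s = 4)
    expect_equal(up$objective, bf$objective)
  }
})
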