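# Shared fixtures and independent oracles.

# Exhaustive path-enumeration posterior: sums the joint probability of every
# hidden-state path, independent of the forward-backward recursion. Emission
# matrix rows are loci, columns states; `trans` is a list of transition
# templates indexed per step by `code`.
enum_posterior <- function(init, emis, trans, code) {
  T_ <- nrow(emis)
  K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  pr <- init[paths[, 1]] * emis[cbind(1L, paths[, 1])]
  if (T_ > 1) for (t in seq_len(T_ - 1)) {
    A <- trans[[code[t]]]
    pr <- pr * A[cbind(paths[, t], paths[, t + 1])] *
      emis[cbind(t + 1L, paths[, t + 1])]
  }
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    post[t, k] <- sum(pr[paths[, t] == k])
  post / rowSums(post)
}

# random phased panel with HWE calls at random frequencies
random_phased_panel <- function(n_samples, s, p = NULL) {
  if (is.null(p)) p <- runif(s, 0.05, 0.95)
  calls <- matrix(0L, n_samples, s)
  for (i in seq_len(n_samples)) {
    left <- as.integer(runif(s) >= p)
    right <- as.integer(runif(s) >= p)
    calls[i, ] <- 2L * left + right
  }
  rownames(calls) <- sprintf("S%03d", seq_len(n_samples))
  phased_panel(calls, locus_table(s, cm = seq_len(s) * 0.05, p = p))
}

# emission matrix for one pair via the exported vectorised emission
# functions (independent of the internal per-locus array path)
pair_emis_genotype <- function(panel, a, b, params) {
  g <- ibdphase:::GENO_CALLS
  g1 <- g[panel$calls[a, ] + 1L]
  g2 <- g[panel$calls[b, ] + 1L]
  e <- emission_genotype(g1, g2, panel$loci$p, params$gamma)
  cbind(e$p_no_ibd, e$p_ibd)
}

pair_emis_phased <- function(panel, a, b, params) {
  pc <- ibdphase:::PHASED_CALLS
  g1 <- pc[panel$calls[a, ] + 1L]
  g2 <- pc[panel$calls[b, ] + 1L]
  e <- sapply(c("NO", "LL", "LR", "RL", "RR"), function(st)
    emission_phased(g1, g2, st, panel$loci$p, params$gamma,
                    params$gamma_discount))
  matrix(e, ncol = 5)
}

# link_matrix built directly from a triplet table (for optimizer tests)
make_links <- function(m, i, j, value) {
  ibdphase:::new_link_matrix("t", seq_len(m),
                             tibble::tibble(i = as.integer(i),
                                            j = as.integer(j),
                                            value = as.integer(value)))
}

random_links <- function(m, n_links, max_span = 4) {
  i <- sample.int(m - 1L, n_links, replace = TRUE)
  j <- pmin(m, i + sample.int(max_span, n_links, replace = TRUE))
  v <- sample(c(-2L, -1L, 1L, 2L), n_links, replace = TRUE)
  tr <- stats::aggregate(value ~ i + j, data.frame(i = i, j = j, value = v), sum)
  tr <- tr[tr$value != 0, ]
  make_links(m, tr$i, tr$j, tr$value)
}

# 1-sample phased panel from two haplotype strings like "AABBA"
panel_from_haps <- function(left, right, p = 0.5, id = "X") {
  l <- strsplit(left, "")[[1]]
  r <- strsplit(right, "")[[1]]
  calls <- matrix(haplotypes_to_phased(l, r), 1, dimnames = list(id, NULL))
  phased_panel(calls, locus_table(length(l), p = p))
}

# small family simulation reused across tests
tiny_family <- function(seed = 42, n = 8, L = 5, s = 100) {
  simulate_family(sim_config(n = n, L = L, s = s, N = 50, T_gens = 3,
                             t_gens = 2), seed = seed)
}

all_pairs_ids <- function(panel) {
  ids <- samples(panel)
  prs <- t(combn(length(ids), 2))
  cbind(ids[prs[, 1]], ids[prs[, 2]])
}
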