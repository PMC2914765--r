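# Phase inference from IBD segments.
#
# A "link" joins two heterozygous loci of a target sample that fall inside
# an IBD segment with a source sample homozygous at both, with no such locus
# in between. If the source is homozygous for the *same* allele at the two
# loci, the shared haplotype carries that allele at both, so the target's
# heterozygous alleles must sit on the same autosome (equal phase bits); if
# for *different* alleles, they must sit on opposite autosomes. Links are
# stored as +1 / -1 votes in a sparse matrix over the target's heterozygous
# loci; the objective counts satisfied minus unsatisfied links and is
# maximised by a sliding-window local search over the relative phase
# coefficients z_i = y_i xor y_{i+1} (a special instance of MAX 2-SAT).

new_link_matrix <- function(sample, het, links) {
  structure(list(sample = sample, het_loci = het,
                 links = links), class = "link_matrix")
}

#' @exportS3Method base::print
print.link_matrix <- function(x, ...) {
  cat(sprintf("<link_matrix> sample %s: %d het loci, %d links (|value| sum %d)\n",
              x$sample, length(x$het_loci), nrow(x$links),
              sum(abs(x$links$value))))
  invisible(x)
}

#' Sparse link matrix as a Matrix object
#' @param x A `link_matrix`.
#' @return An upper-triangular sparse matrix over het-locus ordinals.
#' @export
as_sparse <- function(x) {
  m <- length(x$het_loci)
  Matrix::sparseMatrix(i = x$links$i, j = x$links$j, x = x$links$value,
                       dims = c(m, m))
}

#' Collect phase links from IBD segments
#'
#' For every segment and both role assignments (each sample of the pair in
#' turn as phasing target, the other as source), scans the loci inside the
#' segment where the target is heterozygous and the source homozygous, and
#' records one link per consecutive such pair: `+1` if the source genotype
#' class (AA vs BB) is equal at the two loci, `-1` otherwise. Link indices
#' `(i, j)` are ordinals into the target's full heterozygous-locus list.
#'
#' @param panel A `phased_panel` (only genotype classes are used here, so
#'   the current phase does not influence the collected links).
#' @param segments A segment tibble as produced by [detect_ibd()], decoded
#'   against the same panel.
#' @return A named list of `link_matrix` objects, one per sample.
#' @export
collect_links <- function(panel, segments) {
  calls <- if (inherits(panel, "phased_panel")) collapse_phase(panel)$calls
           else panel$calls
  ids <- rownames(calls)
  s <- ncol(calls)
  if (nrow(segments) > 0 &&
      (min(segments$start) < 0 || max(segments$end) > s))
    stop("segment indices out of panel bounds")
  het <- calls == 1L
  hom <- !is.na(calls) & (calls == 0L | calls == 2L)
  hets <- lapply(seq_along(ids), function(i) which(het[i, ]))
  ord <- matrix(NA_integer_, length(ids), s)
  for (i in seq_along(ids))
    ord[i, hets[[i]]] <- seq_along(hets[[i]])

  trip <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) trip[[i]] <- list()
  add_links <- function(target, source, rng) {
    cand <- rng[het[target, rng] & hom[source, rng]]
    if (length(cand) < 2L) return()
    cls <- calls[source, cand]
    k <- length(cand)
    trip[[target]][[length(trip[[target]]) + 1L]] <<- data.frame(
      i = ord[target, cand[-k]],
      j = ord[target, cand[-1L]],
      value = ifelse(cls[-k] == cls[-1L], 1L, -1L)
    )
  }
  if (nrow(segments) > 0) {
    sa <- match(segments$sample_a, ids)
    sb <- match(segments$sample_b, ids)
    for (r in seq_len(nrow(segments))) {
      rng <- (segments$start[r] + 1L):segments$end[r] # to 1-based inclusive
      add_links(sa[r], sb[r], rng)
      add_links(sb[r], sa[r], rng) # swap target and source, repeat once
    }
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- if (length(trip[[i]])) do.call(rbind, trip[[i]])
          else data.frame(i = integer(), j = integer(), value = integer())
    agg <- if (nrow(tr)) stats::aggregate(value ~ i + j, tr, sum) else tr
    agg <- agg[agg$value != 0L, , drop = FALSE]
    agg <- agg[order(agg$i, agg$j), , drop = FALSE]
    out[[i]] <- new_link_matrix(ids[i], hets[[i]],
                                tibble::as_tibble(agg))
  }
  stats::setNames(out, ids)
}

#' Satisfied-minus-unsatisfied link objective
#'
#' For a phase vector `y` over the target's heterozygous loci (0 = AB,
#' 1 = BA), the objective is the sum over nonzero links of
#' `L(i, j) * (+1 if y_i = y_j else -1)`: the number of links the phase
#' configuration satisfies minus the number it leaves unsatisfied. It is
#' invariant under a global flip of `y` (swapping the two autosomes).
#'
#' @param y Binary phase vector, one entry per heterozygous locus.
#' @param link A `link_matrix`.
#' @return Integer objective value.
#' @export
phase_objective <- function(y, link) {
  stopifnot(length(y) == length(link$het_loci))
  L <- link$links
  if (nrow(L) == 0L) return(0L)
  sum(L$value * ifelse(y[L$i] == y[L$j], 1L, -1L))
}

# per-link signed contributions given relative-phase coefficients z
link_signs <- function(L, z) {
  if (nrow(L) == 0L) return(integer())
  cz <- c(0L, cumsum(z))
  par <- (cz[L$j] - cz[L$i]) %% 2L # parity of z over the link span [i, j-1]
  as.integer(L$value * (1L - 2L * par))
}

#' Sliding-window phase update
#'
#' Local search over relative phase coefficients `z_i = y_i xor y_{i+1}`:
#' for every window of up to `s + 1` consecutive coefficients starting at
#' each position, all flip patterns that include the first coefficient are
#' tested, and a pattern is applied whenever it strictly increases the
#' number of satisfied links; sweeps repeat until a full pass makes no
#' change. The objective is integer-valued and strictly increases with
#' every accepted move, so the search terminates at a window-local optimum.
#'
#' @param y Binary phase vector over the target's heterozygous loci.
#' @param link A `link_matrix` for the same sample.
#' @param s Window length (number of coefficients beyond the first tested
#'   jointly); default 4.
#' @return A list with the updated `y`, the final `objective`, and the
#'   number of `sweeps` performed.
#' @export
update_phase <- function(y, link, s = 4) {
  stopifnot(s >= 1, length(y) == length(link$het_loci))
  m <- length(y)
  L <- link$links
  if (m < 2L || nrow(L) == 0L)
    return(list(y = y, objective = phase_objective(y, link), sweeps = 0L))
  z <- as.integer(xor(y[-m], y[-1L]))
  S <- link_signs(L, z)
  # links covering each z position
  span_len <- L$j - L$i
  pos <- sequence(span_len) + rep(L$i, span_len) - 1L
  lidx <- rep(seq_len(nrow(L)), span_len)
  pos2links <- split(lidx, factor(pos, levels = seq_len(m - 1L)))
  # flip patterns: subsets of the s trailing offsets, first position fixed in
  patterns <- lapply(seq_len(2^s) - 1L,
                     function(b) c(0L, which(bitwAnd(b, 2^(0:(s - 1))) > 0L)))
  sweeps <- 0L
  repeat {
    flag <- FALSE
    sweeps <- sweeps + 1L
    for (w in seq_len(m - 1L)) {
      for (pat in patterns) {
        flip <- w + pat
        flip <- flip[flip <= m - 1L]
        aff <- unlist(pos2links[flip], use.names = FALSE)
        if (length(aff) == 0L) next
        cnt <- tabulate(aff, nbins = nrow(L))
        odd <- which(cnt %% 2L == 1L)
        if (length(odd) && sum(S[odd]) < 0L) {
          z[flip] <- 1L - z[flip]
          S[odd] <- -S[odd]
          flag <- TRUE
        }
      }
    }
    if (!flag) break
  }
  y_new <- as.integer(cumsum(c(y[1L], z)) %% 2L)
  list(y = y_new, objective = sum(S), sweeps = sweeps)
}

#' Exhaustive phase optimum
#'
#' Brute-force maximisation of the link objective over all `2^(m-1)`
#' relative-phase configurations (the global flip symmetry fixes `y_1 = 0`).
#' Test oracle for [update_phase()]; refuses more than 20 heterozygous loci.
#'
#' @param link A `link_matrix`.
#' @return A list with the optimal `y` and `objective`.
#' @export
brute_force_phase <- function(link) {
  m <- length(link$het_loci)
  if (m > 20L) stop("brute force limited to m <= 20 heterozygous loci")
  L <- link$links
  if (m < 2L || nrow(L) == 0L)
    return(list(y = rep(0L, m), objective = 0L))
  nz <- m - 1L
  configs <- as.matrix(expand.grid(rep(list(0:1), nz)))
  obj <- rep(0L, nrow(configs))
  for (r in seq_len(nrow(L))) {
    cols <- L$i[r]:(L$j[r] - 1L)
    par <- rowSums(configs[, cols, drop = FALSE]) %% 2L
    obj <- obj + L$value[r] * (1L - 2L * par)
  }
  best <- which.max(obj)
  z <- configs[best, ]
  list(y = as.integer(cumsum(c(0L, z)) %% 2L), objective = as.integer(obj[best]))
}

#' Read or set the phase vector of one sample
#'
#' The phase vector has one bit per heterozygous locus: 0 for AB (allele A
#' on the left autosome), 1 for BA.
#'
#' @param panel A `phased_panel`.
#' @param sample Sample id or index.
#' @return `get_phase()`: integer 0/1 vector. `apply_phase()`: the panel
#'   with the sample's heterozygous calls re-phased (and marked
#'   phase-known).
#' @export
get_phase <- function(panel, sample) {
  stopifnot(inherits(panel, "phased_panel"))
  cc <- panel$calls[sample, het_loci(panel, sample)]
  as.integer(cc == 2L)
}

#' @rdname get_phase
#' @param y Binary phase vector over the sample's heterozygous loci.
#' @export
apply_phase <- function(panel, sample, y) {
  stopifnot(inherits(panel, "phased_panel"))
  het <- het_loci(panel, sample)
  stopifnot(length(y) == length(het))
  panel$calls[sample, het] <- 1L + as.integer(y)
  panel$phase_known[sample, het] <- TRUE
  panel
}

#' Serialise link matrices to a sparse triplet text file
#'
#' One row per nonzero link: `target i j value`, tab-separated.
#'
#' @param links A list of `link_matrix` objects (from [collect_links()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  rows <- dplyr::bind_rows(lapply(links, function(l)
    dplyr::mutate(l$links, target = l$sample, .before = 1)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
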