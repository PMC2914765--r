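# Readers and writers for the standard exchange formats: VCF (phased or
# unphased GT), a plain tabular matrix format, and the IBD segment table.
#
# VCF conventions: allele A is identified with REF and allele B with ALT
# (the emission formulas are symmetric in p and q, so no major/minor
# reordering is performed); the genetic position is carried in the INFO
# field as CM= and the allele-A frequency as PA=. Phase is taken from the
# GT separator: "|" ordered, "/" unordered (stored as AB with
# phase_known = FALSE).

GT_TO_CODE <- c("0|0" = 0L, "0|1" = 1L, "1|0" = 2L, "1|1" = 3L,
                "0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 3L)

#' Read a phased panel from a VCF file
#'
#' Reads biallelic SNP records with GT fields through `vcfR`. Pipe-phased
#' genotypes become ordered calls (`0|1` is AB, `1|0` is BA); slash
#' genotypes become phase-unknown calls; `./.` is missing. Multi-allelic
#' records are skipped with a warning. The INFO keys `CM` (genetic
#' position, centimorgans) and `PA` (frequency of the REF allele) are used
#' when present; otherwise `cm` defaults to POS * 1e-6 and frequencies are
#' computed from the calls.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return A `phased_panel`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v@fix <- v@fix[!multi, , drop = FALSE]
    v@gt <- v@gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  s <- nrow(gt)
  gt[gt %in% c("./.", ".|.", ".")] <- NA
  codes <- matrix(GT_TO_CODE[gt], nrow = s)
  bad <- which(!is.na(gt) & is.na(codes), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed GT '%s' at %s:%s sample %s",
                 gt[bad[1, 1], bad[1, 2]], fix[bad[1, 1], "CHROM"],
                 fix[bad[1, 1], "POS"], ids[bad[1, 2]]))
  pk <- matrix(grepl("|", gt, fixed = TRUE), nrow = s)
  info_num <- function(key) {
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", key, "=[^;]+"), fix[, "INFO"]))
    out <- rep(NA_real_, s)
    hit <- lengths(regmatches(fix[, "INFO"],
                              gregexpr(paste0("(^|;)", key, "="), fix[, "INFO"]))) > 0
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
    out
  }
  cm <- info_num("CM")
  pa <- info_num("PA")
  pos <- as.integer(fix[, "POS"])
  if (all(is.na(cm))) cm <- pos * 1e-6
  loci <- locus_table(s, chrom = fix[, "CHROM"], pos = pos, cm = cm, p = pa)
  calls <- t(codes)
  rownames(calls) <- ids
  phased_panel(calls, loci, phase_known = t(pk))
}

#' Write a phased panel to VCF
#'
#' Emits an uncompressed VCF 4.2 file with symbolic alleles REF=A, ALT=B,
#' the genetic map and allele-A frequency in INFO (`CM=`, `PA=`, printed
#' with full double precision so that read/write round-trips are exact),
#' and GT separators chosen from the panel's `phase_known` mask.
#'
#' @param panel A `phased_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  loci <- panel$loci
  s <- nrow(loci)
  ids <- rownames(panel$calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in centimorgans\">",
    "##INFO=<ID=PA,Number=1,Type=Float,Description=\"Frequency of the REF (A) allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  phased_gt <- c("0|0", "0|1", "1|0", "1|1")
  unphased_gt <- c("0/0", "0/1", "0/1", "1/1")
  gt_mat <- matrix("./.", nrow(panel$calls), s)
  known <- !is.na(panel$calls) & panel$phase_known
  unk <- !is.na(panel$calls) & !panel$phase_known
  gt_mat[known] <- phased_gt[panel$calls[known] + 1L]
  gt_mat[unk] <- unphased_gt[panel$calls[unk] + 1L]
  miss_phased <- is.na(panel$calls) & panel$phase_known
  gt_mat[miss_phased] <- ".|."
  info <- sprintf("CM=%.17g;PA=%.17g", loci$cm, loci$p)
  info[is.na(loci$p)] <- sprintf("CM=%.17g", loci$cm[is.na(loci$p)])
  body <- paste(loci$chrom, loci$pos, sprintf("snp%d", seq_len(s)),
                "A", "B", ".", ".", info, "GT",
                apply(gt_mat, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the tabular matrix format
#'
#' A plain text format with a header row `chrom pos cM p <sample ids>` and
#' one row per locus; calls are `AA`, `AB`, `BA`, `BB` or `..` for missing.
#'
#' @param path File path.
#' @return `read_tabular()`: a `phased_panel`; `write_tabular()`: `path`,
#'   invisibly.
#' @export
read_tabular <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  stopifnot(length(hdr) > 4, identical(hdr[1:4], c("chrom", "pos", "cM", "p")))
  d <- read.table(path, header = FALSE, skip = 1L,
                  colClasses = c("character", "integer", "numeric",
                                 "character", rep("character", length(hdr) - 4)))
  p <- suppressWarnings(as.numeric(d[[4]]))
  calls <- t(as.matrix(d[, -(1:4), drop = FALSE]))
  calls[calls == ".."] <- NA
  rownames(calls) <- hdr[-(1:4)]
  loci <- locus_table(nrow(d), chrom = d[[1]], pos = d[[2]], cm = d[[3]], p = p)
  phased_panel(calls, loci)
}

#' @rdname read_tabular
#' @param panel A `phased_panel`.
#' @export
write_tabular <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  loci <- panel$loci
  calls <- matrix(PHASED_CALLS[panel$calls + 1L], nrow(panel$calls))
  calls[is.na(calls)] <- ".."
  lines <- c(
    paste(c("chrom", "pos", "cM", "p", rownames(panel$calls)), collapse = "\t"),
    paste(loci$chrom, loci$pos, sprintf("%.17g", loci$cm),
          sprintf("%.17g", loci$p), apply(calls, 2, paste, collapse = "\t"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an IBD segment table written by [write_segments()]
#'
#' @param path Segment file.
#' @return A segment tibble with the columns of [decode_segments()] (minus
#'   `n_loci`, which is recomputed).
#' @export
read_segments <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "integer",
                                 "integer", "numeric", "numeric",
                                 "character", "numeric"))
  tibble::tibble(
    sample_a = d$sample_a, sample_b = d$sample_b,
    start = d$start_idx, end = d$end_idx,
    start_cm = d$start_pos, end_cm = d$end_pos,
    n_loci = d$end_idx - d$start_idx,
    state = d$state, mean_posterior = d$mean_posterior
  )
}

#' Write an IBD segment table
#'
#' Tab-separated columns `sample_a sample_b start_idx end_idx start_pos
#' end_pos state mean_posterior`; locus indices are 0-based half-open,
#' positions in centimorgans.
#'
#' @param segments A segment tibble from [detect_ibd()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    sample_a = segments$sample_a, sample_b = segments$sample_b,
    start_idx = segments$start, end_idx = segments$end,
    start_pos = segments$start_cm, end_pos = segments$end_cm,
    state = segments$state, mean_posterior = segments$mean_posterior
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
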