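# PWM construction and promoter scanning.
#
# Scores are standard log-likelihood ratios: for motif position i and base b,
# llr[b,i] = log( p(b,i) / q(b) ) with p the pseudocount-smoothed column
# frequency and q the background. A candidate site's score is the sum of the
# llr terms of its bases; the scanner keeps windows whose score strictly
# exceeds min_fraction * max_score.

#' Convert a count matrix to a log-likelihood-ratio PWM
#'
#' Column counts are smoothed with an additive pseudocount, converted to
#' frequencies, divided by the background distribution and logged:
#' `llr[b,i] = log((counts[b,i] + pc) / (total_i + 4 pc) / q(b))`.
#'
#' @param pfm A `pfm` object (see [read_jaspar_pfm()]).
#' @param background Background base probabilities, a positive length-4
#'   vector in A,C,G,T order summing to 1. Default uniform; see
#'   [estimate_background()] to estimate one from intergenic sequence.
#' @param pseudocount Additive smoothing per matrix cell; must be > 0 so the
#'   llr stays finite.
#' @param log_base Base of the logarithm (default 2).
#' @param min_fraction Fraction of the maximum score a window must exceed to
#'   be reported by [scan_promoters()] (default 0.66).
#' @return A `pwm` object: list with `motif_id`, `tf_name`, `llr` (4 x L),
#'   `background`, `pseudocount`, `log_base`, `max_score`, `min_score`,
#'   `min_fraction`, `length`.
#' @export
build_pwm <- function(pfm, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 1, log_base = 2, min_fraction = 0.66) {
  stopifnot(inherits(pfm, "pfm"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0))
    stop("background must be positive over A,C,G,T")
  if (abs(sum(background) - 1) > 1e-12) stop("background must sum to 1")

  counts <- pfm$counts
  p <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  llr <- log(sweep(p, 1L, background, "/"), base = log_base)
  structure(list(
    motif_id = pfm$motif_id, tf_name = pfm$tf_name, llr = llr,
    background = background, pseudocount = pseudocount, log_base = log_base,
    max_score = sum(apply(llr, 2L, max)),
    min_score = sum(apply(llr, 2L, min)),
    min_fraction = min_fraction, length = ncol(llr)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "PWM %s (%s): %d positions, max score %.4f, report cutoff > %.4f\n",
    x$motif_id, x$tf_name, x$length, x$max_score,
    x$min_fraction * x$max_score))
  invisible(x)
}

# integer codes 1..4 for A,C,G,T; NA otherwise (N etc.)
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1L]], DNA_BASES)
}

#' Score L-mers against a PWM
#'
#' @param pwm A `pwm` object.
#' @param lmer Character vector of sequences, each of the motif length.
#' @return Numeric scores; `NA` for any sequence containing a non-ACGT base
#'   (callers skip such windows).
#' @export
score_window <- function(pwm, lmer) {
  stopifnot(inherits(pwm, "pwm"))
  L <- pwm$length
  if (any(nchar(lmer) != L)) stop("sequence length must equal motif length ", L)
  vapply(lmer, function(s) {
    code <- encode_dna(s)
    if (anyNA(code)) return(NA_real_)
    sum(pwm$llr[cbind(code, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}

# score every forward-strand window of an encoded sequence; NA where the
# window touches a non-ACGT base
score_all_windows <- function(llr, code) {
  L <- ncol(llr); n <- length(code)
  if (n < L) return(numeric(0))
  m <- n - L + 1L
  sc <- numeric(m)
  for (j in seq_len(L)) {
    v <- llr[, j][code[j:(m + j - 1L)]]
    sc <- sc + v   # NA propagates through windows containing N
  }
  sc
}

#' Scan promoters for binding sites
#'
#' Slides the PWM over every promoter (both strands by default) and reports
#' every window whose score strictly exceeds
#' `min_fraction * max_score`. Overlapping and nested matches are all kept.
#' Positions follow the TSS = +1 convention: the TSS base is +1, the base
#' before it -1, there is no position 0; `position` is the 5'-most base of
#' the match **on the promoter's forward strand**, and `matched_sequence` is
#' read on the matching strand.
#'
#' @param pwm A `pwm` object.
#' @param promoters A [promoter_set()].
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return A `data.table` of binding sites: `gene_id`, `motif_id`,
#'   `position`, `strand`, `matched_sequence`, `score`.
#' @export
scan_promoters <- function(pwm, promoters, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"), inherits(promoters, "promoter_set"))
  if (nrow(promoters) == 0L) stop("promoter set is empty")
  L <- pwm$length
  cutoff <- pwm$min_fraction * pwm$max_score
  res <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$sequence[i]
    n <- nchar(s)
    if (n < L) {
      warning("promoter ", promoters$gene_id[i], " shorter than motif; skipped")
      next
    }
    code <- encode_dna(s)
    off <- promoters$tss_offset[i]
    fw <- score_all_windows(pwm$llr, code)
    keep <- which(!is.na(fw) & fw > cutoff)
    parts <- list()
    if (length(keep)) {
      parts[[1L]] <- data.table(
        start = keep, strand = "+",
        matched_sequence = substring(s, keep, keep + L - 1L),
        score = fw[keep])
    }
    if (both_strands) {
      rc <- revcomp(s)
      rv <- score_all_windows(pwm$llr, encode_dna(rc))
      keep <- which(!is.na(rv) & rv > cutoff)
      if (length(keep)) {
        # start position of the match on the forward axis
        fstart <- n - (keep + L - 1L) + 1L
        parts[[length(parts) + 1L]] <- data.table(
          start = fstart, strand = "-",
          matched_sequence = substring(rc, keep, keep + L - 1L),
          score = rv[keep])
      }
    }
    if (length(parts)) {
      dt <- rbindlist(parts)
      dt[, `:=`(gene_id = promoters$gene_id[i], motif_id = pwm$motif_id,
                position = tss_relative(start, off))]
      res[[i]] <- dt[, .(gene_id, motif_id, position, strand,
                         matched_sequence, score)]
    }
  }
  out <- rbindlist(res)
  if (nrow(out) == 0L)
    out <- data.table(gene_id = character(), motif_id = character(),
                      position = integer(), strand = character(),
                      matched_sequence = character(), score = numeric())
  setorderv(out, c("gene_id", "position", "strand"))
  out[]
}

# 1-based promoter index -> TSS-relative coordinate (TSS = +1, no 0)
tss_relative <- function(idx, tss_offset) {
  ifelse(idx >= tss_offset, idx - tss_offset + 1L, idx - tss_offset)
}

# inverse: TSS-relative coordinate -> 1-based promoter index
tss_to_index <- function(pos, tss_offset) {
  ifelse(pos > 0L, pos + tss_offset - 1L, pos + tss_offset)
}

#' Percentile score threshold over a site pool
#'
#' Sorts sites by decreasing score and takes the score at rank
#' `ceiling(top_fraction * n)` as cutoff; every site scoring at least the
#' cutoff qualifies, so ties at the cutoff are included.
#'
#' @param sites A site table from [scan_promoters()] (typically the
#'   genome-wide pool).
#' @param top_fraction Fraction in (0, 1].
#' @return A `score_threshold`: list with `top_fraction` and `cutoff_score`.
#' @export
percentile_threshold <- function(sites, top_fraction) {
  if (NROW(sites) == 0L) stop("cannot take a percentile of an empty site list")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  sc <- sort(sites$score, decreasing = TRUE)
  cutoff <- sc[ceiling(top_fraction * length(sc))]
  structure(list(top_fraction = top_fraction, cutoff_score = cutoff),
            class = "score_threshold")
}

#' Genes carrying a minimum number of qualifying sites
#'
#' @param sites A site table from [scan_promoters()].
#' @param threshold Optional `score_threshold`; if supplied only sites with
#'   `score >= cutoff_score` count.
#' @param min_sites Minimum qualifying sites per gene (k >= 1).
#' @return List with `genes` (character vector of gene IDs with at least
#'   `min_sites` qualifying sites) and `counts` (`data.table` of per-gene
#'   qualifying-site counts, all genes with >= 1 such site).
#' @export
genes_with_min_sites <- function(sites, threshold = NULL, min_sites = 1L) {
  if (min_sites < 1L) stop("min_sites must be >= 1")
  dt <- as.data.table(sites)
  if (!is.null(threshold)) {
    stopifnot(inherits(threshold, "score_threshold"))
    dt <- dt[score >= threshold$cutoff_score]
  }
  counts <- dt[, .(n_sites = .N), by = gene_id]
  setorderv(counts, "gene_id")
  list(genes = counts[n_sites >= min_sites, gene_id], counts = counts[])
}

#' Overlapping site pairs between two site sets
#'
#' Two sites in the same gene overlap when their occupied intervals
#' (`position` .. `position + L - 1` on the TSS = +1 axis, either strand)
#' intersect.
#'
#' @param sites_a,sites_b Site tables sharing the gene universe and position
#'   convention.
#' @return A `data.table` of overlapping pairs with the positions, strands
#'   and motifs of both members.
#' @export
site_overlap <- function(sites_a, sites_b) {
  a <- as.data.table(sites_a); b <- as.data.table(sites_b)
  empty <- data.table(gene_id = character(),
                      position_a = integer(), strand_a = character(),
                      motif_a = character(), position_b = integer(),
                      strand_b = character(), motif_b = character())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  # linearize the TSS=+1 axis (no 0) so interval arithmetic works
  lin <- function(p) ifelse(p > 0L, p - 1L, p)
  a[, `:=`(s = lin(position), e = lin(position) + nchar(matched_sequence) - 1L)]
  b[, `:=`(s = lin(position), e = lin(position) + nchar(matched_sequence) - 1L)]
  out <- a[b, on = .(gene_id), allow.cartesian = TRUE, nomatch = NULL][
    s <= i.e & i.s <= e]
  if (nrow(out) == 0L) return(empty)
  out[, .(gene_id, position_a = position, strand_a = strand,
          motif_a = motif_id, position_b = i.position, strand_b = i.strand,
          motif_b = i.motif_id)]
}

#' Estimate background base frequencies
#'
#' Mononucleotide frequencies over A,C,G,T (N ignored), e.g. from intergenic
#' sequence, for use as [build_pwm()] background.
#'
#' @param x FASTA path, `DNAStringSet`, named character vector of sequences,
#'   or a [promoter_set()].
#' @return Named probability vector over A,C,G,T.
#' @export
estimate_background <- function(x) {
  seqs <- if (inherits(x, "promoter_set")) x$sequence else load_genome(x)
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                      levels = DNA_BASES))
  n <- sum(tab)
  if (n == 0L) stop("no A/C/G/T bases found")
  as.vector(tab) / n -> p
  setNames(p, DNA_BASES)
}
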