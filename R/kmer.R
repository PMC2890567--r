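# Over-represented / conserved oligonucleotide analysis.
#
# Counting convention (used consistently for n_g(w), N(w) and the trials
# denominator N_g): greedy left-to-right non-self-overlapping occurrences,
# both strands. The reverse-strand count of w equals the greedy count of
# revcomp(w) on the forward strand (maximal sets of non-overlapping
# equal-length intervals have the same size in either scan direction), and
# a palindromic word is counted once per strand. Windows containing N are
# skipped and excluded from N_g.
#
# Statistics: with f(w) the pooled frequency N(w) / sum_g N_g within a GC
# class, a promoter g over-represents w when P(X >= n_g(w)) < alpha for
# X ~ Binomial(N_g, f(w)). S(w) is the set of such genes.

#' Split promoters at the median GC content
#'
#' GC fraction is computed over non-N bases; promoters strictly above the
#' cohort median go to the `rich` class, the rest to `poor`. All-N promoters
#' are excluded with a warning. The two classes are analyzed independently
#' downstream.
#'
#' @param promoters A [promoter_set()] with at least two promoters.
#' @return List with `rich`, `poor` (promoter sets), `median` (the GC
#'   threshold) and `gc` (named per-gene GC fractions).
#' @export
split_by_median_gc <- function(promoters) {
  stopifnot(inherits(promoters, "promoter_set"))
  if (nrow(promoters) < 2L) stop("need at least two promoters to split")
  gc <- gc_content(promoters$sequence)
  allN <- is.na(gc)
  if (any(allN)) {
    warning("excluding all-N promoter(s): ",
            paste(promoters$gene_id[allN], collapse = ", "))
    promoters <- promoters[!allN]
    gc <- gc[!allN]
  }
  med <- median(gc)
  rich <- promoters[gc > med]
  poor <- promoters[gc <= med]
  for (cls in list(rich, poor))
    setattr(cls, "class", c("promoter_set", "data.table", "data.frame"))
  if (nrow(rich) == 0L)
    warning("GC-rich class is empty (all promoters at or below the median)")
  list(rich = rich, poor = poor, median = med,
       gc = setNames(gc, promoters$gene_id))
}

#' GC fraction of sequences
#'
#' @param x Character vector of DNA sequences (N ignored; all-N gives `NA`).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(x) {
  x <- toupper(x)
  gc <- nchar(gsub("[^GC]", "", x))
  acgt <- nchar(gsub("[^ACGT]", "", x))
  ifelse(acgt == 0L, NA_real_, gc / acgt)
}

#' Count non-overlapping occurrences of a word
#'
#' Greedy left-to-right non-self-overlapping matches of `w` on the forward
#' strand, plus (when `both_strands`) the same count on the reverse
#' complement strand. `w` must be over A,C,G,T, so windows containing N can
#' never match.
#'
#' @param w Word (A,C,G,T).
#' @param sequence Subject sequence.
#' @param both_strands Count the reverse strand too (default `TRUE`).
#' @return Integer count.
#' @export
count_nonoverlapping <- function(w, sequence, both_strands = TRUE) {
  w <- toupper(w); sequence <- toupper(sequence)
  if (grepl("[^ACGT]", w)) stop("word must be over A,C,G,T")
  if (nchar(w) > nchar(sequence)) stop("word longer than sequence")
  n_fixed <- function(pat, subj) {
    m <- gregexpr(pat, subj, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  cnt <- n_fixed(w, sequence)
  if (both_strands) cnt <- cnt + n_fixed(revcomp(w), sequence)
  cnt
}

# greedy non-overlap count from sorted start positions
greedy_from_starts <- function(starts, k) {
  cur <- -Inf; cnt <- 0L
  for (p in starts) if (p > cur) { cnt <- cnt + 1L; cur <- p + k - 1L }
  cnt
}

# Per-gene word-count table for one word length: forward-strand greedy
# counts combined into both-strand counts, plus the per-gene number of valid
# (N-free) windows.
kmer_count_table <- function(promoters, k, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"))
  genes <- promoters$gene_id
  parts <- vector("list", length(genes))
  n_valid <- integer(length(genes))
  for (i in seq_along(genes)) {
    s <- promoters$sequence[i]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    words <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", words, fixed = TRUE)
    n_valid[i] <- sum(ok)
    if (!any(ok)) next
    parts[[i]] <- data.table(gene_id = genes[i], word = words[ok],
                             start = starts[ok])
  }
  occ <- rbindlist(parts)
  if (nrow(occ) == 0L) {
    counts <- data.table(gene_id = character(), word = character(),
                         count = integer())
  } else {
    # greedy resolution is only needed where successive hits self-overlap
    fwd <- occ[, {
      if (.N == 1L || all(diff(start) >= k)) .(count = .N)
      else .(count = greedy_from_starts(start, k))
    }, by = .(gene_id, word)]
    if (both_strands) {
      rev <- copy(fwd)[, word := revcomp(word)]
      counts <- rbindlist(list(fwd, rev))[, .(count = sum(count)),
                                          by = .(gene_id, word)]
    } else counts <- fwd
  }
  trials <- data.table(gene_id = genes,
                       N_g = (if (both_strands) 2L else 1L) * n_valid)
  list(counts = counts, trials = trials)
}

#' Binomial over-representation of one word in a promoter class
#'
#' @param promoters A [promoter_set()] — one GC class.
#' @param w The word (5-9 nt typical; any A,C,G,T word accepted).
#' @param alpha Per-gene significance level for membership in `S_w`
#'   (default 0.01).
#' @param both_strands Count both strands (default `TRUE`).
#' @return An `oligo_stats` list: `word`, `k`, `N_w` (class-wide count),
#'   `f_w` (pooled frequency), `per_gene` (`data.table` of `gene_id`, `n_g`,
#'   `N_g`, `p_g`), and `S_w` (gene IDs with `p_g < alpha`).
#' @export
oligo_stats <- function(promoters, w, alpha = 0.01, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"), nrow(promoters) > 0L)
  w <- toupper(w)
  k <- nchar(w)
  n_g <- vapply(promoters$sequence, function(s)
    count_nonoverlapping(w, s, both_strands), integer(1), USE.NAMES = FALSE)
  tab <- kmer_count_table(promoters, k, both_strands)$trials
  N_g <- tab$N_g
  N_w <- sum(n_g)
  f_w <- if (sum(N_g) > 0) N_w / sum(N_g) else 0
  p_g <- binom_tail(n_g, N_g, f_w)
  per_gene <- data.table(gene_id = promoters$gene_id, n_g = n_g,
                         N_g = N_g, p_g = p_g)
  structure(list(word = w, k = k, N_w = N_w, f_w = f_w, per_gene = per_gene,
                 S_w = per_gene[p_g < alpha, gene_id], alpha = alpha),
            class = "oligo_stats")
}

# P(X >= n) for X ~ Binomial(N, f); 1 when n = 0 or f = 0
binom_tail <- function(n, N, f) {
  p <- rep(1, length(n))
  pos <- n > 0 & f > 0
  p[pos] <- pbinom(n[pos] - 1, N[pos], f, lower.tail = FALSE)
  p
}

#' Enumerate over-represented oligonucleotides in a promoter class
#'
#' Scores every word of each length in `k_range` that occurs in the class
#' (absent words cannot be over-represented) under the binomial model and
#' collects the words with a non-empty over-representing gene set. A word
#' and its reverse complement are distinct entries.
#'
#' @param promoters A [promoter_set()] — one GC class.
#' @param k_range Word lengths, default `5:9`; lengths above 9 are rejected.
#' @param alpha Per-gene significance level (default 0.01).
#' @param both_strands Count both strands (default `TRUE`).
#' @return An `oligo_overrep` list: `memberships` (`data.table` of `word`,
#'   `k`, `gene_id`, `n_g`, `N_g`, `p_g` for all significant gene/word
#'   pairs), `words` (per-word summary: `word`, `k`, `N_w`, `f_w`,
#'   `n_genes`), `n_tests` (genes x words examined, for calibration checks),
#'   `genes` (the class gene universe), `alpha`, `k_range`.
#' @export
enumerate_overrepresented <- function(promoters, k_range = 5:9, alpha = 0.01,
                                      both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"))
  if (any(k_range > 9L)) stop("word lengths above 9 are not supported")
  if (any(k_range < 1L)) stop("word lengths must be >= 1")
  genes <- promoters$gene_id
  if (nrow(promoters) == 0L)
    return(structure(list(memberships = data.table(), words = data.table(),
                          n_tests = 0, genes = character(), alpha = alpha,
                          k_range = k_range), class = "oligo_overrep"))
  mem <- list(); summ <- list(); n_tests <- 0
  for (k in k_range) {
    tabs <- kmer_count_table(promoters, k, both_strands)
    counts <- tabs$counts
    if (nrow(counts) == 0L) next
    trials <- tabs$trials
    tot_trials <- sum(trials$N_g)
    word_tot <- counts[, .(N_w = sum(count)), by = word]
    word_tot[, f_w := N_w / tot_trials]
    n_tests <- n_tests + nrow(word_tot) * length(genes)
    counts <- counts[trials, on = "gene_id", nomatch = NULL]
    counts <- counts[word_tot, on = "word", nomatch = NULL]
    counts[, p_g := pbinom(count - 1L, N_g, f_w, lower.tail = FALSE)]
    sig <- counts[p_g < alpha]
    if (nrow(sig)) {
      mem[[length(mem) + 1L]] <- sig[, .(word, k = k, gene_id, n_g = count,
                                         N_g, p_g)]
      ws <- sig[, .(n_genes = .N), by = word]
      ws <- ws[word_tot, on = "word", nomatch = NULL][n_genes > 0]
      summ[[length(summ) + 1L]] <- ws[, .(word, k = k, N_w, f_w, n_genes)]
    }
  }
  memberships <- if (length(mem)) rbindlist(mem) else
    data.table(word = character(), k = integer(), gene_id = character(),
               n_g = integer(), N_g = integer(), p_g = numeric())
  words <- if (length(summ)) rbindlist(summ) else
    data.table(word = character(), k = integer(), N_w = integer(),
               f_w = numeric(), n_genes = integer())
  setorderv(memberships, c("word", "gene_id"))
  setorderv(words, c("k", "word"))
  structure(list(memberships = memberships, words = words, n_tests = n_tests,
                 genes = genes, alpha = alpha, k_range = k_range),
            class = "oligo_overrep")
}

#' @export
print.oligo_overrep <- function(x, ...) {
  cat(sprintf(
    "over-represented oligos: %d word(s) (k in %s) over %d genes, alpha %.3g\n",
    nrow(x$words), paste(range(x$k_range), collapse = "-"),
    length(x$genes), x$alpha))
  invisible(x)
}

#' The over-representing gene set S(w) of a word
#'
#' @param overrep An `oligo_overrep` object.
#' @param w Word.
#' @return Character vector of gene IDs (possibly empty).
#' @export
oligo_set <- function(overrep, w) {
  stopifnot(inherits(overrep, "oligo_overrep"))
  overrep$memberships[word == toupper(w), gene_id]
}

#' Conservation of over-representation across orthologs
#'
#' Tests whether the genes over-representing a word in two species share
#' more one-to-one orthologs than chance: over the universe of ortholog
#' pairs, a 2x2 of membership of the species-1 gene in `S_h` against
#' membership of its partner in `S_m`, one-sided Fisher.
#'
#' @param S_h,S_m Gene-ID vectors (over-representing sets in each species).
#' @param orthology An `orthology_map` (see [read_orthology()]).
#' @return List with `overlap` (pairs in both sets), `p_value`, and the 2x2
#'   counts.
#' @export
conserved_overrepresentation <- function(S_h, S_m, orthology) {
  stopifnot(inherits(orthology, "orthology_map") || is.data.frame(orthology))
  if (nrow(orthology) == 0L)
    return(list(overlap = 0L, p_value = 1, a = 0L, b = 0L, c = 0L, d = 0L))
  in_h <- orthology$gene1 %in% S_h
  in_m <- orthology$gene2 %in% S_m
  a <- sum(in_h & in_m); b <- sum(in_h & !in_m)
  c <- sum(!in_h & in_m); d <- sum(!in_h & !in_m)
  ft <- fisher_exact(a, b, c, d, alternative = "greater")
  list(overlap = a, p_value = ft$p_value, a = a, b = b, c = c, d = d)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' FDR control under arbitrary dependence: with `m` tests and
#' `c(m) = sum_{i=1..m} 1/i`, the adjusted value of the i-th smallest p is
#' `min_{j >= i} ( m c(m) p_(j) / j )`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
by_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ranked <- p[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Conservation table over all tested words
#'
#' Runs [conserved_overrepresentation()] for every word over-represented in
#' either species (a word absent from one species has an empty set there and
#' p = 1), adjusts the p-values jointly with [by_fdr()] — one family across
#' all word lengths — and flags words with `q < fdr` as conserved.
#'
#' @param overrep_1,overrep_2 `oligo_overrep` objects for the two species;
#'   each may also be a list of objects (e.g. both GC classes), in which
#'   case the species' gene sets `S(w)` are unions over the classes.
#' @param orthology An `orthology_map` with species-1 IDs in `gene1`.
#' @param fdr Conservation FDR threshold (default 0.1).
#' @return A `data.table`: `word`, `k`, `overlap`, `p_value`, `q_value`,
#'   `conserved`.
#' @export
conservation_table <- function(overrep_1, overrep_2, orthology, fdr = 0.1) {
  pool <- function(x) {
    if (inherits(x, "oligo_overrep")) x <- list(x)
    stopifnot(all(vapply(x, inherits, logical(1), "oligo_overrep")))
    rbindlist(lapply(x, `[[`, "memberships"))
  }
  mem1 <- pool(overrep_1); mem2 <- pool(overrep_2)
  words <- unique(rbind(mem1[, .(word, k)], mem2[, .(word, k)]))
  if (nrow(words) == 0L)
    return(data.table(word = character(), k = integer(), overlap = integer(),
                      p_value = numeric(), q_value = numeric(),
                      conserved = logical()))
  m1 <- lapply(split(mem1$gene_id, mem1$word), unique)
  m2 <- lapply(split(mem2$gene_id, mem2$word), unique)
  res <- lapply(seq_len(nrow(words)), function(i) {
    w <- words$word[i]
    cr <- conserved_overrepresentation(m1[[w]], m2[[w]], orthology)
    data.table(word = w, k = words$k[i], overlap = cr$overlap,
               p_value = cr$p_value)
  })
  out <- rbindlist(res)
  out[, q_value := by_fdr(p_value)]
  out[, conserved := q_value < fdr]
  setorderv(out, c("q_value", "word"))
  out[]
}

#' Enrichment of oligo target sets in a regulated gene subset
#'
#' For each over-represented word, a one-sided Fisher test of membership in
#' `S(w)` against membership in the regulated subset over the supplied gene
#' universe. Words with p below `alpha` are ranked by p and the top `top_n`
#' returned.
#'
#' @param overrep An `oligo_overrep` object (or a list of them, e.g. both GC
#'   classes; memberships are pooled).
#' @param regulated_subset Gene IDs (e.g. the down-regulated genes).
#' @param universe Gene-ID universe (default: the union of the class gene
#'   sets in `overrep`).
#' @param alpha Reporting cutoff on the Fisher p (default 0.05).
#' @param top_n Rows returned after ranking (default 10).
#' @param conservation Optional [conservation_table()] output used to set
#'   the `conserved` flag.
#' @param annotations Optional named list from [annotate_oligos()] mapping
#'   word -> TF names for the `tf` column.
#' @return A `data.table`: `word`, `conserved`, `tf`, `target_gene_count`
#'   (`|S(w)` intersect regulated`|`), `p_value`, ranked by `p_value`.
#' @export
regulated_enrichment <- function(overrep, regulated_subset, universe = NULL,
                                 alpha = 0.05, top_n = 10L,
                                 conservation = NULL, annotations = NULL) {
  if (inherits(overrep, "oligo_overrep")) overrep <- list(overrep)
  mem <- rbindlist(lapply(overrep, `[[`, "memberships"))
  if (is.null(universe))
    universe <- unique(unlist(lapply(overrep, `[[`, "genes")))
  regulated_subset <- intersect(regulated_subset, universe)
  if (length(setdiff(regulated_subset, universe)))
    stop("regulated subset must lie within the universe")
  empty <- data.table(word = character(), conserved = logical(),
                      tf = character(), target_gene_count = integer(),
                      p_value = numeric())
  if (nrow(mem) == 0L || length(regulated_subset) == 0L) return(empty)
  n_reg <- length(regulated_subset)
  n_univ <- length(universe)
  sets <- mem[gene_id %in% universe, .(genes = list(gene_id)), by = word]
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    S <- sets$genes[[i]]
    a <- sum(S %in% regulated_subset)
    b <- length(S) - a
    ft <- fisher_exact(a, b, n_reg - a, (n_univ - n_reg) - b,
                       alternative = "greater")
    data.table(word = sets$word[i], target_gene_count = a,
               p_value = ft$p_value)
  })
  out <- rbindlist(rows)[p_value < alpha]
  if (nrow(out) == 0L) return(empty)
  setorderv(out, c("p_value", "word"))
  out <- head(out, top_n)
  out[, conserved := FALSE]
  if (!is.null(conservation) && nrow(conservation))
    out[conservation, conserved := i.conserved, on = "word"]
  out[, tf := ""]
  if (!is.null(annotations)) {
    hit <- intersect(out$word, names(annotations))
    for (w in hit)
      out[word == w, tf := paste(annotations[[w]], collapse = ", ")]
  }
  out[, .(word, conserved, tf, target_gene_count, p_value)]
}
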