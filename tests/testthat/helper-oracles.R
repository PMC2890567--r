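# Independent reference implementations and tiny fixture builders used
# across the suite. These stay deliberately naive: they are the oracles the
# fast paths are checked against.

# naive window-by-window scanner: scores every L-mer of every promoter on
# both strands and keeps windows strictly above frac * max_score
oracle_scan <- function(pwm, promoters, both_strands = TRUE) {
  L <- pwm$length
  cutoff <- pwm$min_fraction * pwm$max_score
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$sequence[i]
    off <- promoters$tss_offset[i]
    n <- nchar(s)
    if (n < L) next
    for (st in seq_len(n - L + 1L)) {
      win <- substr(s, st, st + L - 1L)
      pos <- if (st >= off) st - off + 1L else st - off
      sc <- suppressWarnings(score_window(pwm, win))
      if (!is.na(sc) && sc > cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[i], position = pos, strand = "+",
          matched_sequence = win, score = sc)
      if (both_strands) {
        rcw <- cismap::revcomp(win)
        sc <- suppressWarnings(score_window(pwm, rcw))
        if (!is.na(sc) && sc > cutoff)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = promoters$gene_id[i], position = pos, strand = "-",
            matched_sequence = rcw, score = sc)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), position = integer(),
                      strand = character(), matched_sequence = character(),
                      score = numeric())
  out[order(out$gene_id, out$position, out$strand), ]
}

# full enumeration Fisher (one-sided greater) for small margins
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; s <- a + c
  support <- max(0, s - n):min(s, m)
  probs <- exp(lchoose(m, support) + lchoose(n, s - support) - lchoose(m + n, s))
  sum(probs[support >= a])
}

# greedy non-overlapping count by explicit walk
oracle_nonoverlap <- function(w, s) {
  k <- nchar(w); n <- nchar(s); i <- 1L; cnt <- 0L
  while (i <= n - k + 1L) {
    if (substr(s, i, i + k - 1L) == w) { cnt <- cnt + 1L; i <- i + k }
    else i <- i + 1L
  }
  cnt
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a sharply informative 9-mer test matrix (consensus GCCCGCGGG-like)
test_pfm <- function() {
  pfm_from_sites(c("GCCCGCGGG", "GCCCGGGGG", "GCCGGCGGG", "GCCCGCGGC",
                   "GCCCACGGG", "GCCTGCGGG", "GCCCGCAGG", "GCCCGCGGG",
                   "GCCCGTGGG", "ACCCGCGGG"),
                 motif_id = "TEST9", tf_name = "test")
}

extdata <- function(f) system.file("extdata", f, package = "cismap")

# reported TFAP2A sites fixture (distinct 9-mers with published scores)
reported_sites <- function() {
  read.delim(extdata("tfap2a_reported_sites.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

tfap2a_pfm <- function() read_jaspar_pfm(extdata("MA0003_TFAP2A_synthetic.pfm"))
sp1_pfm <- function() read_jaspar_pfm(extdata("MA0079_SP1_synthetic.pfm"))
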