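test_that("build_pwm implements the smoothed log-likelihood ratio", {
  # uniform counts + uniform background -> llr identically 0
  flat <- matrix(25, 4, 3, dimnames = list(c("A","C","G","T"), NULL))
  pfm <- structure(list(motif_id = "FLAT", tf_name = "", counts = flat),
                   class = "pfm")
  pwm <- build_pwm(pfm)
  expect_equal(unname(pwm$llr), matrix(0, 4, 3))
  expect_equal(pwm$max_score, 0)

  # hand evaluation: A=100, C=G=T=0 per column, pc 1, log2, uniform q
  mat <- matrix(0, 4, 3, dimnames = list(c("A","C","G","T"), NULL))
  mat["A", ] <- 100
  pfm <- structure(list(motif_id = "AAA", tf_name = "", counts = mat),
                   class = "pfm")
  pwm <- build_pwm(pfm)
  expect_equal(unname(pwm$llr["A", 1]), log2((101 / 104) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$llr["A", 1]), 1.9578, tolerance = 1e-4)
  expect_equal(pwm$max_score, 3 * log2((101 / 104) / 0.25), tolerance = 1e-12)
  expect_equal(pwm$max_score, 5.8735, tolerance = 1e-4)

  expect_error(build_pwm(pfm, pseudocount = 0), "pseudocount")
  expect_error(build_pwm(pfm, background = c(A = 1, C = 0, G = 0, T = 0)),
               "positive")
})

test_that("max_score equals the brute-force maximum over all L-mers", {
  set.seed(7)
  for (L in c(2L, 3L, 4L)) {
    counts <- matrix(sample(0:20, 4 * L, replace = TRUE), 4, L,
                     dimnames = list(c("A","C","G","T"), NULL))
    counts[, colSums(counts) == 0] <- 1
    pwm <- build_pwm(structure(list(motif_id = "R", tf_name = "",
                                    counts = counts), class = "pfm"))
    lmers <- do.call(paste0, expand.grid(rep(list(c("A","C","G","T")), L)))
    expect_equal(pwm$max_score, max(score_window(pwm, lmers)),
                 tolerance = 1e-12)
  }
})

test_that("score_window is deterministic, additive, and NA on N", {
  pwm <- build_pwm(test_pfm())
  expect_equal(score_window(pwm, "GCCCGCGGG"),
               score_window(pwm, "GCCCGCGGG"))
  expect_true(is.na(score_window(pwm, "GCCCNCGGG")))
  expect_error(score_window(pwm, "GCCC"), "length")
  # duplicate-sequence consistency across genes falls out of determinism
  ps <- promoter_set(c("g1", "g2"),
                     c(paste0("TTTTT", "GCCCGCGGG", "TTTTT"),
                       paste0("AAAAA", "GCCCGCGGG", "AAAAA")),
                     tss_offset = 10L)
  sites <- scan_promoters(pwm, ps)
  sc <- sites[sites$matched_sequence == "GCCCGCGGG", ]$score
  expect_true(length(sc) >= 2L)
  expect_equal(length(unique(sc)), 1L)
})

test_that("scan_promoters equals the exhaustive oracle on random promoters", {
  set.seed(11)
  pwm <- build_pwm(test_pfm())
  ps <- promoter_set(sprintf("g%02d", 1:12),
                     vapply(runif(12, 0.35, 0.65), function(gc)
                       random_seq(sample(60:200, 1), gc), character(1)),
                     tss_offset = 31L)
  # plant the consensus in a few promoters so hits certainly exist
  for (i in c(2L, 5L)) {
    s <- ps$sequence[i]
    ps$sequence[i] <- paste0(substr(s, 1, 20), "GCCCGCGGG",
                             substr(s, 30, nchar(s)))
  }
  got <- scan_promoters(pwm, ps)
  want <- oracle_scan(pwm, ps)
  expect_gt(nrow(want), 0L)
  expect_equal(as.data.frame(got[, c("gene_id", "position", "strand",
                                     "matched_sequence", "score")]),
               want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a planted site is reported at its planted TSS-relative position", {
  pwm <- build_pwm(test_pfm())
  flank_l <- strrep("AT", 25)           # AT-rich flanks score far below 0
  flank_r <- strrep("TA", 25)
  ps <- promoter_set("gene", paste0(flank_l, "GCCCGCGGG", flank_r),
                     tss_offset = 60L)
  sites <- scan_promoters(pwm, ps)
  fwd <- sites[sites$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$position, 51L - 60L)   # promoter index 51, upstream of TSS
  expect_equal(fwd$matched_sequence, "GCCCGCGGG")

  # reverse complement of the whole promoter: same score, strand flipped
  rc <- promoter_set("gene", revcomp(ps$sequence), tss_offset = 60L)
  rsites <- scan_promoters(pwm, rc)
  rev <- rsites[rsites$strand == "-", ]
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$matched_sequence, fwd$matched_sequence)
})

test_that("strand symmetry: multiset of scores is invariant under revcomp", {
  set.seed(13)
  pwm <- build_pwm(tfap2a_pfm())
  ps <- promoter_set(sprintf("g%d", 1:6),
                     vapply(rep(0.6, 6), function(gc) random_seq(300, gc),
                            character(1)), tss_offset = 271L)
  a <- scan_promoters(pwm, ps)
  rc <- promoter_set(ps$gene_id, revcomp(ps$sequence), tss_offset = 271L)
  b <- scan_promoters(pwm, rc)
  expect_equal(sort(a$score), sort(b$score), tolerance = 1e-12)
})

test_that("degenerate uniform matrix yields no sites", {
  flat <- matrix(10, 4, 5, dimnames = list(c("A","C","G","T"), NULL))
  pwm <- build_pwm(structure(list(motif_id = "F", tf_name = "",
                                  counts = flat), class = "pfm"))
  ps <- promoter_set("g", random_seq(100), tss_offset = 91L)
  expect_equal(nrow(scan_promoters(pwm, ps)), 0L)
})

test_that("percentile thresholds follow the ceiling-rank rule with ties", {
  sites <- data.frame(gene_id = "g", score = 10:1)
  thr <- percentile_threshold(sites, 0.2)
  expect_equal(thr$cutoff_score, 9)
  expect_equal(sum(sites$score >= thr$cutoff_score), 2L)

  thr <- percentile_threshold(sites, 1.0)
  expect_equal(thr$cutoff_score, 1)

  tied <- data.frame(score = rep(5, 7))
  thr <- percentile_threshold(tied, 0.1)
  expect_equal(sum(tied$score >= thr$cutoff_score), 7L)

  expect_error(percentile_threshold(sites[0, ], 0.2), "empty")
  expect_error(percentile_threshold(sites, 0), "top_fraction")
})

test_that("genes_with_min_sites matches a brute-force recount", {
  set.seed(17)
  sites <- data.frame(gene_id = sample(sprintf("g%d", 1:8), 60, replace = TRUE),
                      score = runif(60))
  thr <- percentile_threshold(sites, 0.5)
  got <- genes_with_min_sites(sites, thr, min_sites = 2L)
  qual <- sites[sites$score >= thr$cutoff_score, ]
  recount <- table(qual$gene_id)
  expect_setequal(got$genes, names(recount)[recount >= 2])
  expect_equal(got$counts$n_sites[match(names(recount), got$counts$gene_id)],
               as.integer(recount))
  expect_equal(genes_with_min_sites(sites[0, ], min_sites = 1L)$genes,
               character(0))
})

test_that("threshold gene sets nest and counts are monotone in k", {
  set.seed(19)
  pwm <- build_pwm(tfap2a_pfm())
  ps <- promoter_set(sprintf("g%d", 1:20),
                     vapply(rep(0.62, 20), function(gc) random_seq(400, gc),
                            character(1)), tss_offset = 361L)
  sites <- scan_promoters(pwm, ps)
  expect_gt(nrow(sites), 10L)
  gs <- lapply(c(0.1, 0.2, 0.3), function(f)
    genes_with_min_sites(sites, percentile_threshold(sites, f), 1L)$genes)
  expect_true(all(gs[[1]] %in% gs[[2]]))
  expect_true(all(gs[[2]] %in% gs[[3]]))
  ks <- vapply(1:4, function(k)
    length(genes_with_min_sites(sites, min_sites = k)$genes), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("site_overlap finds one-base-shifted sites and is symmetric", {
  mk <- function(pos, strand = "+")
    data.frame(gene_id = "g", motif_id = "m", position = pos,
               strand = strand, matched_sequence = strrep("G", 9),
               score = 1)
  expect_equal(nrow(site_overlap(mk(-64L), mk(-63L))), 1L)
  expect_equal(nrow(site_overlap(mk(-900L), mk(50L))), 0L)
  # spanning the (no-0) TSS: -3 covers -3..+6, +5 covers +5..+13
  expect_equal(nrow(site_overlap(mk(-3L), mk(5L))), 1L)

  set.seed(23)
  a <- do.call(rbind, lapply(sample(-50:50, 8), mk))
  b <- do.call(rbind, lapply(sample(-50:50, 8), mk))
  ab <- site_overlap(a, b); ba <- site_overlap(b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$position_a, ab$position_b),
                  paste(ba$position_b, ba$position_a))
})

test_that("estimate_background recovers composition", {
  ps <- promoter_set("g", strrep("ACGG", 1000), tss_offset = 1L)
  bg <- estimate_background(ps)
  expect_equal(unname(bg), c(0.25, 0.25, 0.5, 0), tolerance = 1e-12)
})
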