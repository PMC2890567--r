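test_that("GC split at the median partitions the cohort", {
  ps <- promoter_set(sprintf("g%d", 1:4),
                     c(paste0(strrep("A", 7), strrep("G", 3)),   # 0.3
                       paste0(strrep("A", 6), strrep("G", 4)),   # 0.4
                       paste0(strrep("A", 4), strrep("G", 6)),   # 0.6
                       paste0(strrep("A", 3), strrep("G", 7))),  # 0.7
                     tss_offset = 9L)
  sp <- split_by_median_gc(ps)
  expect_equal(sp$median, 0.5)
  expect_setequal(sp$rich$gene_id, c("g3", "g4"))
  expect_setequal(sp$poor$gene_id, c("g1", "g2"))
  expect_setequal(c(sp$rich$gene_id, sp$poor$gene_id), ps$gene_id)

  same <- promoter_set(c("a", "b"), rep(strrep("ACGT", 5), 2), tss_offset = 19L)
  expect_warning(sp2 <- split_by_median_gc(same), "empty")
  expect_equal(nrow(sp2$rich), 0L)
  expect_equal(nrow(sp2$poor), 2L)

  withN <- promoter_set(c("a", "b", "n"),
                        c(strrep("ACGT", 5), strrep("GGCC", 5),
                          strrep("N", 20)), tss_offset = 19L)
  expect_warning(sp3 <- split_by_median_gc(withN), "all-N")
  expect_equal(nrow(sp3$rich) + nrow(sp3$poor), 2L)
})

test_that("non-overlapping counting is greedy left-to-right per strand", {
  expect_equal(count_nonoverlapping("AAAAA", strrep("A", 9),
                                    both_strands = FALSE), 1L)
  expect_equal(count_nonoverlapping("AAAAA", strrep("A", 10),
                                    both_strands = FALSE), 2L)
  expect_equal(count_nonoverlapping("CGCGC", strrep("T", 30),
                                    both_strands = FALSE), 0L)
  # both strands: reverse-strand hits are revcomp occurrences on the forward
  expect_equal(count_nonoverlapping("AAAAA", strrep("A", 10)), 2L)
  expect_equal(count_nonoverlapping("TTTTT", strrep("A", 10)), 2L)
  expect_equal(count_nonoverlapping("ACGTT", "ACGTTAACGT"), 2L)
  # palindromic words count once per strand (documented double count)
  expect_equal(count_nonoverlapping("ACGT", "ACGTACGT"), 4L)

  set.seed(47)
  for (i in 1:25) {
    s <- random_seq(120, 0.5)
    w <- substr(random_seq(20, 0.5), 1, sample(3:6, 1))
    expect_equal(count_nonoverlapping(w, s, both_strands = FALSE),
                 oracle_nonoverlap(w, s))
    expect_equal(count_nonoverlapping(w, s),
                 oracle_nonoverlap(w, s) + oracle_nonoverlap(revcomp(w), s))
  }
})

test_that("counts bound: nonoverlap <= overlap <= windows", {
  set.seed(53)
  for (i in 1:10) {
    s <- random_seq(80, 0.7)
    w <- substr(s, 11, 15)
    non <- count_nonoverlapping(w, s, both_strands = FALSE)
    starts <- seq_len(nchar(s) - nchar(w) + 1L)
    over <- sum(substring(s, starts, starts + nchar(w) - 1L) == w)
    expect_lte(non, over)
    expect_lte(over, nchar(s) - nchar(w) + 1L)
  }
})

test_that("binomial tail matches direct summation and the worked example", {
  # n=2, N=10, f=0.1: P(X>=2) = 1 - 0.9^10 - 10*0.1*0.9^9
  stats <- oligo_stats(promoter_set("g", strrep("ACGT", 10), tss_offset = 1L),
                       "ACGTA")  # any word; we test the tail helper via p_g
  p <- 1 - 0.9^10 - 10 * 0.1 * 0.9^9
  expect_equal(pbinom(1, 10, 0.1, lower.tail = FALSE), p, tolerance = 1e-12)
  expect_equal(p, 0.2639, tolerance = 1e-4)

  set.seed(59)
  for (i in 1:30) {
    N <- sample(10:10000, 1); f <- runif(1, 1e-4, 0.2)
    n <- sample(0:min(N, 12), 1)
    direct <- sum(dbinom(n:N, N, f))
    got <- if (n == 0) 1 else pbinom(n - 1, N, f, lower.tail = FALSE)
    expect_equal(got, direct, tolerance = 1e-12)
  }
})

test_that("oligo_stats computes f(w), N_g and S(w) per the model", {
  set.seed(61)
  # pooled f(w) includes the planted copies, so the cohort must be large
  # enough to keep the per-gene expectation well below the planted count
  ps <- promoter_set(sprintf("g%02d", 1:20),
                     vapply(rep(0.5, 20), function(gc) random_seq(60, gc),
                            character(1)), tss_offset = 55L)
  for (i in 1:2)
    ps$sequence[i] <- paste0("CGGGCCGGGCCGGGCCGGGCCGGGC",
                             substr(ps$sequence[i], 26, 60))
  st <- oligo_stats(ps, "CGGGC", alpha = 0.01)
  expect_equal(st$N_w, sum(st$per_gene$n_g))
  expect_equal(st$f_w, st$N_w / sum(st$per_gene$N_g))
  expect_equal(st$per_gene$N_g, rep(2L * (60L - 5L + 1L), 20L))
  expect_true(all(c("g01", "g02") %in% st$S_w))
  expect_true(all(st$per_gene$p_g > 0 & st$per_gene$p_g <= 1))
  # n_g = 0 -> p = 1
  none <- oligo_stats(promoter_set("g", strrep("A", 40), tss_offset = 1L),
                      "CGCGC")
  expect_equal(none$per_gene$p_g, 1)
  expect_length(none$S_w, 0L)
})

test_that("N-containing windows are excluded from trials and counts", {
  ps <- promoter_set("g", paste0(strrep("A", 10), "NN", strrep("A", 10)),
                     tss_offset = 1L)
  st <- oligo_stats(ps, "AAAAA")
  # valid 5-windows: 18 total starts, those touching the Ns drop out
  expect_equal(st$per_gene$N_g, 2L * (18L - 6L))
  expect_equal(st$per_gene$n_g, 4L)   # 2 per strand in the two A-runs
})

test_that("enumerate_overrepresented recovers planted words, controls error", {
  set.seed(67)
  ps <- promoter_set(sprintf("g%03d", 1:100),
                     vapply(rep(0.5, 100), function(gc) random_seq(300, gc),
                            character(1)), tss_offset = 271L)
  targets <- sprintf("g%03d", 1:10)
  for (i in 1:10) {
    s <- ps$sequence[i]
    at <- seq(10, by = 25, length.out = 5)
    for (a in at) s <- paste0(substr(s, 1, a - 1), "CGGGC",
                              substr(s, a + 5, nchar(s)))
    ps$sequence[i] <- s
  }
  ov <- enumerate_overrepresented(ps, k_range = 5L, alpha = 0.01)
  expect_true("CGGGC" %in% ov$words$word)
  S <- oligo_set(ov, "CGGGC")
  expect_gte(sum(targets %in% S), 9L)
  # every reported membership is below alpha and implies occurrence
  expect_true(all(ov$memberships$p_g < 0.01))
  expect_true(all(ov$memberships$n_g >= 1L))
  expect_error(enumerate_overrepresented(ps, k_range = 10L), "not supported")
  empty <- enumerate_overrepresented(ps[0], k_range = 5L)
  expect_equal(nrow(empty$words), 0L)
})

test_that("per-gene type-I rate on null cohorts stays near alpha", {
  rates <- vapply(1:5, function(seed) {
    set.seed(100 + seed)
    ps <- promoter_set(sprintf("g%02d", 1:25),
                       vapply(rep(0.5, 25), function(gc) random_seq(250, gc),
                              character(1)), tss_offset = 226L)
    ov <- enumerate_overrepresented(ps, k_range = 5L, alpha = 0.01)
    nrow(ov$memberships) / ov$n_tests
  }, numeric(1))
  expect_lte(mean(rates), 0.015)
})

test_that("class permutation invariance: gene order does not change stats", {
  set.seed(71)
  ps <- promoter_set(sprintf("g%d", 1:12),
                     vapply(rep(0.5, 12), function(gc) random_seq(150, gc),
                            character(1)), tss_offset = 136L)
  ov1 <- enumerate_overrepresented(ps, k_range = 5L)
  perm <- ps[sample(12)]
  data.table::setattr(perm, "class", class(ps))
  ov2 <- enumerate_overrepresented(perm, k_range = 5L)
  m1 <- ov1$memberships[order(word, gene_id)]
  m2 <- ov2$memberships[order(word, gene_id)]
  expect_equal(m1, m2)
})

test_that("by_fdr implements Benjamini-Yekutieli and matches p.adjust", {
  expect_equal(by_fdr(0.05), 0.05)
  # two p-values, c(2) = 1.5: raw = 2*1.5*c(0.01, 0.04)/c(1, 2)
  expect_equal(by_fdr(c(0.01, 0.04)), c(0.03, 0.06), tolerance = 1e-12)
  expect_error(by_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(73)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(by_fdr(p), stats::p.adjust(p, method = "BY"),
                 tolerance = 1e-12)
  }
})

test_that("conserved_overrepresentation scores ortholog-set overlap", {
  orth <- orthology_map(sprintf("h%d", 1:50), sprintf("m%d", 1:50))
  none <- conserved_overrepresentation(character(0), character(0), orth)
  expect_equal(none$overlap, 0L)
  expect_equal(none$p_value, 1)

  S_h <- sprintf("h%d", 1:8)
  S_m <- sprintf("m%d", 1:8)
  hit <- conserved_overrepresentation(S_h, S_m, orth)
  expect_equal(hit$overlap, 8L)
  expect_lt(hit$p_value, 1e-8)
  # permuting partners destroys the signal (in distribution)
  set.seed(79)
  perm_p <- vapply(1:20, function(i) {
    po <- orthology_map(orth$gene1, sample(orth$gene2))
    conserved_overrepresentation(S_h, S_m, po)$p_value
  }, numeric(1))
  expect_gte(mean(perm_p > 0.05), 0.9)

  empty <- conserved_overrepresentation(S_h, S_m, orthology_map(character(0),
                                                                character(0)))
  expect_equal(empty$p_value, 1)
})

test_that("regulated_enrichment ranks by recomputed Fisher p", {
  set.seed(83)
  ps <- promoter_set(sprintf("g%03d", 1:100),
                     vapply(rep(0.5, 100), function(gc) random_seq(200, gc),
                            character(1)), tss_offset = 181L)
  down <- sprintf("g%03d", 1:12)
  for (i in 1:12) {   # plant in the "down" set
    s <- ps$sequence[i]
    for (a in c(10, 40, 70, 100, 130, 160))
      s <- paste0(substr(s, 1, a - 1), "GAGCC", substr(s, a + 5, nchar(s)))
    ps$sequence[i] <- s
  }
  ov <- enumerate_overrepresented(ps, k_range = 5L, alpha = 0.01)
  enr <- regulated_enrichment(ov, down, universe = ps$gene_id)
  expect_gt(nrow(enr), 0L)
  expect_equal(enr$word[1L], "GAGCC")
  expect_gte(enr$target_gene_count[1L], 9L)
  # ranking oracle: recompute each p independently
  for (i in seq_len(nrow(enr))) {
    S <- oligo_set(ov, enr$word[i])
    a <- length(intersect(S, down))
    p <- oracle_fisher_greater(a, length(S) - a, length(down) - a,
                               (100 - length(down)) - (length(S) - a))
    expect_equal(enr$p_value[i], p, tolerance = 1e-10)
  }
  expect_true(!is.unsorted(enr$p_value))

  disjoint <- regulated_enrichment(ov, setdiff(ps$gene_id, ov$memberships$gene_id),
                                   universe = ps$gene_id)
  expect_equal(nrow(disjoint), 0L)
})
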