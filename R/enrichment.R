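# Fisher exact enrichment of site-carrying genes in a regulated set.
#
# Contingency construction for the site-enrichment table: at minimum site
# count k and score threshold rho, the gene universe is the set of genes
# carrying >= k sites at ANY score; the 2x2 then crosses {regulated vs rest
# of universe} with {>= k sites at top-rho score vs not}, with the regulated
# genes removed from the "rest" column. This is the construction under which
# the published-count checks in the test-suite reproduce their p-values.

#' Fisher's exact test on a 2x2 table
#'
#' One-sided ("greater", the enrichment direction) p-values are computed
#' directly from the hypergeometric tail; two-sided p-values sum all tables
#' with point probability not exceeding the observed one (the usual
#' convention). The table is
#' \preformatted{ a  b
#'  c  d}
#' with `a` the doubly-positive cell.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `contingency_result`: list with the four counts, `odds_ratio`
#'   (`a d / b c`, `Inf` when `b c = 0` and the numerator is positive),
#'   `p_value` and `sidedness`.
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) stop("cell counts must be >= 0")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  if (sum(cells) == 0) stop("at least one margin must be positive")
  m <- a + b      # row-1 margin (white balls)
  n <- c + d      # row-2 margin (black balls)
  s <- a + c      # column-1 margin (draws)
  if (alternative == "greater") {
    p <- phyper(a - 1, m, n, s, lower.tail = FALSE)
  } else {
    support <- max(0, s - n):min(s, m)
    dens <- dhyper(support, m, n, s)
    p <- sum(dens[dens <= dhyper(a, m, n, s) * (1 + 1e-7)])
    p <- min(1, p)
  }
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(a = a, b = b, c = c, d = d, odds_ratio = or,
                 p_value = p, sidedness = alternative),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 [%d %d / %d %d]  OR = %.4g  p (%s) = %.4g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$sidedness, x$p_value))
  invisible(x)
}

#' Per-gene qualifying-site counts at several thresholds
#'
#' Builds the wide per-gene count table consumed by
#' [site_enrichment_table()]: one row per gene with at least one site at any
#' score, one column per threshold (label `all` plus `top<percent>` for each
#' requested fraction, cutoffs computed over the full site pool supplied).
#'
#' @param sites Genome-wide site table from [scan_promoters()].
#' @param top_fractions Percentile fractions, default `c(0.30, 0.20, 0.10)`.
#' @return A `data.table`: `gene_id`, `all`, then one count column per
#'   threshold label.
#' @export
per_gene_site_counts <- function(sites, top_fractions = c(0.30, 0.20, 0.10)) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) stop("empty site table")
  out <- sites[, .(all = .N), by = gene_id]
  for (f in top_fractions) {
    thr <- percentile_threshold(sites, f)
    lab <- threshold_label(f)
    cnt <- sites[score >= thr$cutoff_score, .(count = .N), by = gene_id]
    out[cnt, (lab) := i.count, on = "gene_id"]
    out[is.na(get(lab)), (lab) := 0L]
  }
  setorderv(out, "gene_id")
  out[]
}

threshold_label <- function(f) sprintf("top%d", as.integer(round(100 * f)))

#' Site-enrichment table over regulated genes
#'
#' For every combination of minimum site count `k` and score threshold rho,
#' reports the number of qualifying genes genome-wide and among regulated
#' genes, with a Fisher exact p-value for the enrichment (see the
#' construction note in the package source; `all`-threshold rows are the
#' baseline and carry no p-value).
#'
#' @param gene_counts Wide per-gene count table from
#'   [per_gene_site_counts()]; must cover every regulated gene that carries a
#'   site.
#' @param regulated A `regulated_genes` table or character vector of gene
#'   IDs; must be a subset of the promoter universe (genes absent from
#'   `gene_counts` are treated as zero-site genes only if
#'   `allow_missing = TRUE`).
#' @param top_fractions Threshold fractions matching the columns of
#'   `gene_counts`.
#' @param min_sites Integer vector of minimum site counts, default `c(1, 2)`.
#' @param alternative Sidedness passed to [fisher_exact()].
#' @param allow_missing Accept regulated genes with no row in `gene_counts`
#'   (zero sites) rather than erroring.
#' @return A `data.table` with columns `min_sites`, `threshold`,
#'   `genome_count`, `regulated_count`, `p_value`.
#' @export
site_enrichment_table <- function(gene_counts, regulated,
                                  top_fractions = c(0.30, 0.20, 0.10),
                                  min_sites = c(1L, 2L),
                                  alternative = "greater",
                                  allow_missing = TRUE) {
  gene_counts <- as.data.table(gene_counts)
  reg_ids <- if (inherits(regulated, "regulated_genes") ||
                 is.data.frame(regulated)) regulated$gene_id
             else as.character(regulated)
  missing <- setdiff(reg_ids, gene_counts$gene_id)
  if (length(missing) && !allow_missing)
    stop("regulated gene(s) absent from the count table: ",
         paste(missing, collapse = ", "))
  labels <- c("all", vapply(top_fractions, threshold_label, character(1)))
  if (!all(labels %in% names(gene_counts)))
    stop("gene_counts lacks threshold column(s): ",
         paste(setdiff(labels, names(gene_counts)), collapse = ", "))
  is_reg <- gene_counts$gene_id %in% reg_ids
  rows <- list()
  for (k in min_sites) {
    in_univ <- gene_counts$all >= k
    n_univ_reg <- sum(in_univ & is_reg)
    n_univ_gen <- sum(in_univ)
    rows[[length(rows) + 1L]] <- data.table(
      min_sites = k, threshold = "all", genome_count = n_univ_gen,
      regulated_count = n_univ_reg, p_value = NA_real_)
    for (f in top_fractions) {
      lab <- threshold_label(f)
      qual <- gene_counts[[lab]] >= k
      n_gen <- sum(in_univ & qual)
      n_reg <- sum(in_univ & qual & is_reg)
      # regulated genes excluded from the rest-of-genome column
      ft <- fisher_exact(n_reg, n_univ_reg - n_reg,
                         n_gen - n_reg,
                         (n_univ_gen - n_univ_reg) - (n_gen - n_reg),
                         alternative = alternative)
      rows[[length(rows) + 1L]] <- data.table(
        min_sites = k, threshold = lab, genome_count = n_gen,
        regulated_count = n_reg, p_value = ft$p_value)
    }
  }
  rbindlist(rows)[]
}

#' Distribution of genes by minimum site count
#'
#' For each minimum site count from 1 to the maximum observed, the number of
#' genes with at least that many qualifying sites and the percentage relative
#' to the universe of genes carrying at least one site at any score.
#'
#' @param per_gene_counts Integer vector of qualifying-site counts per gene
#'   (genes with zero qualifying sites may be included or omitted), or a
#'   `counts` table from [genes_with_min_sites()].
#' @param universe_size_any_site Number of genes with >= 1 site at any score
#'   (the percentage denominator).
#' @return A `data.table`: `min_sites`, `n`, `percent` (percent rounded to
#'   two decimals).
#' @export
site_count_distribution <- function(per_gene_counts, universe_size_any_site) {
  if (is.data.frame(per_gene_counts)) per_gene_counts <- per_gene_counts$n_sites
  per_gene_counts <- per_gene_counts[per_gene_counts > 0]
  if (length(per_gene_counts) > universe_size_any_site)
    stop("universe smaller than the number of site-carrying genes")
  kmax <- if (length(per_gene_counts)) max(per_gene_counts) else 0L
  ks <- seq_len(kmax)
  n <- vapply(ks, function(k) sum(per_gene_counts >= k), integer(1))
  data.table(min_sites = ks, n = n,
             percent = round(100 * n / universe_size_any_site, 2))
}

#' Split a gene subset by regulation direction
#'
#' @param regulated A `regulated_genes` table.
#' @param gene_subset Character vector of gene IDs; genes not in the
#'   regulated table are ignored.
#' @return List with `up` and `down` character vectors partitioning
#'   `intersect(gene_subset, regulated$gene_id)`.
#' @export
split_by_direction <- function(regulated, gene_subset) {
  stopifnot(is.data.frame(regulated))
  if (any(regulated$fold_change == 0))
    stop("fold_change of 0 cannot be assigned a direction")
  sub <- regulated[regulated$gene_id %in% gene_subset, ]
  list(up = sub$gene_id[sub$direction == "up"],
       down = sub$gene_id[sub$direction == "down"])
}
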