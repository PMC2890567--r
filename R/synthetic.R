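# Seeded two-species synthetic promoter cohorts with planted ground truth.
#
# Background model: each gene draws a GC content from a truncated normal,
# then bases are i.i.d. given GC (A and T at (1-gc)/2, C and G at gc/2) —
# the simplest model under which both the GC-median split and the binomial
# word model are well specified. Planted PWM sites are sampled from the
# matrix's smoothed column distributions and resampled until they clear the
# scanner's reporting cutoff, so planted truth is detectable by
# construction. Species 2 is generated independently except that planted
# content is copied into orthologs with a configurable probability.

#' Configuration for a synthetic cohort
#'
#' @param n_genes Number of genes per species.
#' @param promoter_length Promoter window length in nt (default 1000; the
#'   TSS sits so that one tenth of the window is downstream, mirroring a
#'   900/100 window at the default length).
#' @param gc_mean,gc_sd Mean and SD of the per-gene GC content (truncated to
#'   `[0.25, 0.75]`).
#' @param regulated_fraction Fraction of genes flagged regulated.
#' @param planted_pwm Optional `pfm`; sites are planted in regulated genes.
#' @param pwm_sites_per_regulated_gene Poisson mean for planted site counts
#'   per regulated gene.
#' @param planted_oligos List of entries `list(word=, n_targets=, copies=,
#'   from=)` planting `copies` non-overlapping copies of `word` into
#'   `n_targets` genes drawn from `from` (`"down"`, `"up"`, `"regulated"`,
#'   or `"any"`).
#' @param conservation_prob Probability that a target gene's planted content
#'   (per planted item group) is copied into its species-2 ortholog.
#' @param ortholog_drop_fraction,ortholog_permute_fraction Negative-control
#'   knobs: fraction of ortholog pairs dropped, and fraction whose partners
#'   are randomly permuted.
#' @param min_fraction Reporting cutoff fraction used when validating
#'   planted PWM sites (matches [build_pwm()]'s default).
#' @param seed Integer seed; all outputs are pure functions of the
#'   configuration including the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L, promoter_length = 1000L,
                             gc_mean = 0.5, gc_sd = 0.08,
                             regulated_fraction = 0.023,
                             planted_pwm = NULL,
                             pwm_sites_per_regulated_gene = 2,
                             planted_oligos = list(),
                             conservation_prob = 0.8,
                             ortholog_drop_fraction = 0,
                             ortholog_permute_fraction = 0,
                             min_fraction = 0.66,
                             seed = 1L) {
  stopifnot(n_genes >= 2L, promoter_length >= 20L,
            regulated_fraction > 0, regulated_fraction < 1,
            conservation_prob >= 0, conservation_prob <= 1,
            gc_sd >= 0, gc_mean > 0, gc_mean < 1)
  if (!is.null(planted_pwm)) {
    stopifnot(inherits(planted_pwm, "pfm"))
    if (ncol(planted_pwm$counts) >= promoter_length)
      stop("planted motif longer than the promoter")
  }
  for (po in planted_oligos) {
    stopifnot(!is.null(po$word), !is.null(po$n_targets), !is.null(po$copies))
    if (nchar(po$word) >= promoter_length)
      stop("planted oligo longer than the promoter")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    promoter_length = as.integer(promoter_length),
    gc_mean = gc_mean, gc_sd = gc_sd,
    regulated_fraction = regulated_fraction,
    planted_pwm = planted_pwm,
    pwm_sites_per_regulated_gene = pwm_sites_per_regulated_gene,
    planted_oligos = planted_oligos,
    conservation_prob = conservation_prob,
    ortholog_drop_fraction = ortholog_drop_fraction,
    ortholog_permute_fraction = ortholog_permute_fraction,
    min_fraction = min_fraction,
    seed = as.integer(seed)), class = "synthetic_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- pmin(pmax(x[bad], lo), hi); break }
  }
  x
}

random_promoter <- function(len, gc) {
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sample a site from the PFM's smoothed column distributions, resampling
# until it clears fraction*max of the PWM score (generator guarantee)
sample_pwm_site <- function(pwm_obj, pfm) {
  p <- sweep(pfm$counts + pwm_obj$pseudocount, 2L,
             colSums(pfm$counts) + 4 * pwm_obj$pseudocount, "/")
  cutoff <- pwm_obj$min_fraction * pwm_obj$max_score
  for (i in 1:10000) {
    site <- paste(vapply(seq_len(ncol(p)), function(j)
      sample(DNA_BASES, 1L, prob = p[, j]), character(1)), collapse = "")
    if (score_window(pwm_obj, site) > cutoff) return(site)
  }
  stop("could not sample a planted site above the score cutoff; ",
       "is the matrix nearly uniform?")
}

# pick a start for a width-w insert avoiding occupied intervals
place_insert <- function(len, width, occupied) {
  starts <- seq_len(len - width + 1L)
  if (nrow(occupied)) {
    ok <- rep(TRUE, length(starts))
    for (r in seq_len(nrow(occupied)))
      ok <- ok & (starts + width - 1L < occupied$s[r] | starts > occupied$e[r])
    starts <- starts[ok]
  }
  if (!length(starts))
    stop("planted content exceeds promoter capacity")
  if (length(starts) == 1L) starts else sample(starts, 1L)
}

splice <- function(s, at, insert) {
  paste0(substr(s, 1L, at - 1L), insert,
         substr(s, at + nchar(insert), nchar(s)))
}

#' Generate a synthetic two-species promoter cohort
#'
#' @param config A [synthetic_config()].
#' @return List with `promoters1`, `promoters2` ([promoter_set()]s),
#'   `orthology` (`orthology_map`, species-1 IDs `g...`, species-2 `m...`),
#'   `regulated` (`regulated_genes` for species 1), `truth` (list with
#'   `sites`: planted-item table carrying species, gene, type, label, start,
#'   end, strand, sequence, conserved flag; and `gc`: drawn GC values), and
#'   the `config` echo.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  len <- config$promoter_length
  downstream <- max(1L, as.integer(round(len / 10)))
  tss_off <- len - downstream + 1L
  g1 <- sprintf("g%05d", seq_len(n))
  g2 <- sprintf("m%05d", seq_len(n))

  gc1 <- rtrunc_norm(n, config$gc_mean, config$gc_sd, 0.25, 0.75)
  gc2 <- rtrunc_norm(n, config$gc_mean, config$gc_sd, 0.25, 0.75)
  seq1 <- vapply(gc1, random_promoter, character(1), len = len)
  seq2 <- vapply(gc2, random_promoter, character(1), len = len)

  n_reg <- max(1L, round(config$regulated_fraction * n))
  reg_idx <- sort(sample.int(n, n_reg))
  dir <- sample(c("up", "down"), n_reg, replace = TRUE)
  fc_mag <- round(1.5 + stats::rexp(n_reg, rate = 1), 2)
  regulated <- regulated_genes(g1[reg_idx],
                               ifelse(dir == "up", fc_mag, -fc_mag), dir)

  occupied <- lapply(seq_len(n), function(i) data.table(s = integer(),
                                                        e = integer()))
  truth_rows <- list()
  add_truth <- function(gene_i, type, label, at, strand, site, conserved) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.table(
      gene_id = g1[gene_i], ortholog = g2[gene_i], type = type,
      label = label, start = at, end = at + nchar(site) - 1L,
      strand = strand, sequence = site, conserved = conserved)
  }

  occupied2 <- lapply(seq_len(n), function(i) data.table(s = integer(),
                                                         e = integer()))

  if (!is.null(config$planted_pwm) &&
      config$pwm_sites_per_regulated_gene > 0) {
    pwm_obj <- build_pwm(config$planted_pwm,
                         min_fraction = config$min_fraction)
    for (i in reg_idx) {
      n_sites <- rpois(1L, config$pwm_sites_per_regulated_gene)
      if (n_sites == 0L) next
      keep <- runif(1) < config$conservation_prob
      for (s in seq_len(n_sites)) {
        site <- sample_pwm_site(pwm_obj, config$planted_pwm)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") site else revcomp(site)
        at <- place_insert(len, nchar(ins), occupied[[i]])
        seq1[i] <- splice(seq1[i], at, ins)
        occupied[[i]] <- rbind(occupied[[i]],
                               data.table(s = at, e = at + nchar(ins) - 1L))
        add_truth(i, "pwm", pwm_obj$motif_id, at, strand, site, keep)
        if (keep) {
          at2 <- place_insert(len, nchar(ins), occupied2[[i]])
          seq2[i] <- splice(seq2[i], at2, ins)
          occupied2[[i]] <- rbind(occupied2[[i]],
                                  data.table(s = at2,
                                             e = at2 + nchar(ins) - 1L))
        }
      }
    }
  }

  reg_dir <- setNames(dir, as.character(reg_idx))
  for (po in config$planted_oligos) {
    from <- if (is.null(po$from)) "any" else po$from
    pool <- switch(from,
      down = reg_idx[reg_dir[as.character(reg_idx)] == "down"],
      up = reg_idx[reg_dir[as.character(reg_idx)] == "up"],
      regulated = reg_idx,
      any = seq_len(n),
      stop("unknown 'from' in planted oligo: ", from))
    if (length(pool) < po$n_targets)
      stop("not enough genes in pool '", from, "' for oligo ", po$word)
    targets <- sort(sample(pool, po$n_targets))
    w <- toupper(po$word)
    for (i in targets) {
      keep <- runif(1) < config$conservation_prob
      for (cp in seq_len(po$copies)) {
        at <- place_insert(len, nchar(w), occupied[[i]])
        seq1[i] <- splice(seq1[i], at, w)
        occupied[[i]] <- rbind(occupied[[i]],
                               data.table(s = at, e = at + nchar(w) - 1L))
        add_truth(i, "oligo", w, at, "+", w, keep)
        if (keep) {
          at2 <- place_insert(len, nchar(w), occupied2[[i]])
          seq2[i] <- splice(seq2[i], at2, w)
          occupied2[[i]] <- rbind(occupied2[[i]],
                                  data.table(s = at2,
                                             e = at2 + nchar(w) - 1L))
        }
      }
    }
  }

  # orthology: identity pairing, optionally degraded for negative controls
  keep_pair <- rep(TRUE, n)
  if (config$ortholog_drop_fraction > 0)
    keep_pair[sample.int(n, round(config$ortholog_drop_fraction * n))] <- FALSE
  partner <- g2
  if (config$ortholog_permute_fraction > 0) {
    idx <- sample.int(n, max(2L, round(config$ortholog_permute_fraction * n)))
    partner[idx] <- partner[sample(idx)]
  }
  orth <- orthology_map(g1[keep_pair], partner[keep_pair])

  truth <- list(
    sites = if (length(truth_rows)) rbindlist(truth_rows) else
      data.table(gene_id = character(), ortholog = character(),
                 type = character(), label = character(), start = integer(),
                 end = integer(), strand = character(),
                 sequence = character(), conserved = logical()),
    gc = data.table(gene_id = c(g1, g2), gc = c(gc1, gc2)))

  list(promoters1 = promoter_set(g1, seq1, tss_off),
       promoters2 = promoter_set(g2, seq2, tss_off),
       orthology = orth, regulated = regulated, truth = truth,
       config = config)
}

#' Recovery of planted truth by the pipeline
#'
#' Compares scanner / word-route output against a cohort's truth table.
#' A planted PWM site counts as recovered when a reported site in the same
#' gene overlaps its interval on the same strand; a planted oligo counts as
#' recovered when its over-representing set covers the majority of its
#' target genes.
#'
#' @param cohort Output of [generate_cohort()].
#' @param sites Optional site table from [scan_promoters()] on
#'   `cohort$promoters1`.
#' @param overrep Optional `oligo_overrep` (or list of them) computed on
#'   species-1 promoters.
#' @return List with `pwm` (per-site logical `recovered`, plus `recall` and
#'   `precision` of reported sites against planted intervals) and `oligos`
#'   (per planted word: target coverage and `recovered` flag).
#' @export
truth_recovery_report <- function(cohort, sites = NULL, overrep = NULL) {
  truth <- cohort$truth$sites
  tss_off <- cohort$promoters1$tss_offset[1L]
  out <- list()
  if (!is.null(sites)) {
    planted <- truth[type == "pwm"]
    if (nrow(planted) == 0L) {
      out$pwm <- list(recall = NA_real_, precision = NA_real_,
                      n_reported = nrow(sites))
    } else {
      if (length(setdiff(planted$gene_id, cohort$promoters1$gene_id)))
        stop("truth and promoter gene universes disagree")
      st <- as.data.table(sites)
      st[, `:=`(s = tss_to_index(position, tss_off),
                e = tss_to_index(position, tss_off) +
                  nchar(matched_sequence) - 1L)]
      hit <- logical(nrow(planted))
      used <- rep(FALSE, nrow(st))
      for (i in seq_len(nrow(planted))) {
        cand <- which(st$gene_id == planted$gene_id[i] &
                        st$strand == planted$strand[i] &
                        st$s <= planted$end[i] & st$e >= planted$start[i])
        if (length(cand)) { hit[i] <- TRUE; used[cand] <- TRUE }
      }
      out$pwm <- list(recovered = hit, recall = mean(hit),
                      precision = if (nrow(st)) mean(used) else NA_real_,
                      n_reported = nrow(st))
    }
  }
  if (!is.null(overrep)) {
    if (inherits(overrep, "oligo_overrep")) overrep <- list(overrep)
    mem <- rbindlist(lapply(overrep, `[[`, "memberships"))
    planted <- truth[type == "oligo", .(targets = list(unique(gene_id))),
                     by = label]
    rows <- lapply(seq_len(nrow(planted)), function(i) {
      tg <- planted$targets[[i]]
      S <- mem[word == planted$label[i], gene_id]
      cov <- mean(tg %in% S)
      data.table(word = planted$label[i], n_targets = length(tg),
                 coverage = cov, recovered = cov > 0.5)
    })
    out$oligos <- if (length(rows)) rbindlist(rows) else
      data.table(word = character(), n_targets = integer(),
                 coverage = numeric(), recovered = logical())
  }
  out
}
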