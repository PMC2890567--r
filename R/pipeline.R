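# End-to-end orchestration: scan -> threshold -> enrich -> words ->
# conserve -> annotate -> co-localize, with a run manifest. Stages log one
# line each with input/output row counts; all randomness flows from the
# single config seed.

#' Assemble a pipeline run configuration
#'
#' Inputs may be in-memory objects or file paths (FASTA for promoters,
#' JASPAR flat for matrices, TSV for tables); paths are loaded at run time
#' by the matching reader.
#'
#' @param promoters Promoter set or FASTA path (species 1).
#' @param pfm Primary motif `pfm` or path.
#' @param out_dir Output directory (created if absent).
#' @param regulated Optional regulated-gene table or path.
#' @param sp1_pfm Optional second motif (GC-box style co-factor) or path.
#' @param promoters2,orthology Optional second species promoters and
#'   one-to-one orthology (objects or paths) enabling conservation
#'   filtering.
#' @param consensus Optional consensus library (object or path) for TF
#'   annotation of over-represented words.
#' @param background Background base probabilities for [build_pwm()].
#' @param min_fraction,top_fractions,min_sites Scanner cutoff fraction,
#'   percentile thresholds and minimum site counts (defaults 0.66,
#'   `c(0.30, 0.20, 0.10)`, `c(1, 2)`).
#' @param focus_fraction The threshold used for the site-count distribution
#'   and co-localization stages (default 0.20).
#' @param k_range,alpha_oligo,alpha_enrich,fdr Word route parameters
#'   (defaults 5:9, 0.01, 0.05, 0.1).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(promoters, pfm, out_dir,
                       regulated = NULL, sp1_pfm = NULL,
                       promoters2 = NULL, orthology = NULL, consensus = NULL,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       min_fraction = 0.66,
                       top_fractions = c(0.30, 0.20, 0.10),
                       min_sites = c(1L, 2L), focus_fraction = 0.20,
                       k_range = 5:9, alpha_oligo = 0.01,
                       alpha_enrich = 0.05, fdr = 0.1, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

resolve_input <- function(x, reader) {
  if (is.null(x)) NULL
  else if (is.character(x) && length(x) == 1L) reader(x)
  else x
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage its configuration enables and writes report tables
#' (tab-separated) plus a JSON run manifest into `out_dir`. Reruns with the
#' same inputs and configuration are bit-identical.
#'
#' Outputs: `sites.tsv` (all reported sites), `site_report.tsv` (gene /
#' sequence / score / TSS-relative position), `enrichment.tsv`,
#' `site_distribution.tsv`, `oligo_words_<class>.tsv`, `conservation.tsv`,
#' `oligo_enrichment_<direction>.tsv`, `sp1_colocalization.tsv`,
#' `manifest.json` — each only when its stage runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- list()
  written <- character(0)
  emit <- function(dt, file) {
    path <- file.path(config$out_dir, file)
    fwrite(dt, path, sep = "\t")
    written <<- c(written, path)
    path
  }

  promoters <- resolve_input(config$promoters, read_promoters)
  pfm <- resolve_input(config$pfm, read_jaspar_pfm)
  regulated <- resolve_input(config$regulated, read_regulated_genes)
  stage_log("load", "%d promoters, motif %s (%d nt)%s", nrow(promoters),
            pfm$motif_id, ncol(pfm$counts),
            if (is.null(regulated)) "" else
              sprintf(", %d regulated genes", nrow(regulated)))

  # ---- scan ----
  pwm <- build_pwm(pfm, background = config$background,
                   min_fraction = config$min_fraction)
  sites <- scan_promoters(pwm, promoters)
  out$pwm <- pwm; out$sites <- sites
  stage_log("scan", "%d sites above %.3f x max score", nrow(sites),
            config$min_fraction)
  emit(sites, "sites.tsv")
  emit(sites[, .(gene_id, sequence = matched_sequence, score,
                 position)], "site_report.tsv")

  # ---- threshold + enrichment ----
  if (nrow(sites)) {
    counts <- per_gene_site_counts(sites, config$top_fractions)
    out$gene_counts <- counts
    if (!is.null(regulated) && nrow(regulated)) {
      enr <- site_enrichment_table(counts, regulated,
                                   top_fractions = config$top_fractions,
                                   min_sites = config$min_sites)
      out$enrichment <- enr
      emit(enr, "enrichment.tsv")
      stage_log("enrich", "%d table rows", nrow(enr))
      lab <- threshold_label(config$focus_fraction)
      dist_g <- site_count_distribution(counts[[lab]], sum(counts$all >= 1L))
      reg_counts <- counts[gene_id %in% regulated$gene_id]
      dist_r <- site_count_distribution(reg_counts[[lab]],
                                        sum(reg_counts$all >= 1L))
      dist <- merge(dist_g, dist_r, by = "min_sites", all.x = TRUE,
                    suffixes = c("_genome", "_regulated"))
      out$distribution <- dist
      emit(dist, "site_distribution.tsv")
    } else {
      stage_log("enrich", "skipped: no regulated gene table")
    }
  }

  # ---- word route ----
  promoters2 <- resolve_input(config$promoters2, read_promoters)
  orthology <- resolve_input(config$orthology, read_orthology)
  consensus <- resolve_input(config$consensus, read_consensus_library)
  if (nrow(promoters) >= 2L) {
    classes1 <- split_by_median_gc(promoters)
    ov1 <- lapply(classes1[c("rich", "poor")], function(cls)
      if (nrow(cls)) enumerate_overrepresented(cls, config$k_range,
                                               config$alpha_oligo) else NULL)
    ov1 <- Filter(Negate(is.null), ov1)
    out$overrep1 <- ov1
    for (nm in names(ov1)) emit(ov1[[nm]]$words,
                                sprintf("oligo_words_%s.tsv", nm))
    stage_log("kmers", "%d over-represented word(s) across classes",
              sum(vapply(ov1, function(o) nrow(o$words), integer(1))))

    cons_tab <- NULL
    if (!is.null(promoters2) && !is.null(orthology) && nrow(orthology)) {
      classes2 <- split_by_median_gc(promoters2)
      ov2 <- lapply(classes2[c("rich", "poor")], function(cls)
        if (nrow(cls)) enumerate_overrepresented(cls, config$k_range,
                                                 config$alpha_oligo) else NULL)
      ov2 <- Filter(Negate(is.null), ov2)
      # per-species S(w) is the union over GC classes; one FDR family
      if (length(ov2)) {
        cons_tab <- conservation_table(unname(ov1), unname(ov2), orthology,
                                       fdr = config$fdr)
        out$conservation <- cons_tab
        emit(cons_tab, "conservation.tsv")
        stage_log("conserve", "%d word(s) conserved at FDR < %.2g",
                  sum(cons_tab$conserved), config$fdr)
      }
    }

    if (!is.null(regulated) && nrow(regulated)) {
      split_dir <- split_by_direction(regulated, regulated$gene_id)
      ann <- NULL
      all_words <- unique(unlist(lapply(ov1, function(o) o$words$word)))
      if (!is.null(consensus) && length(all_words))
        ann <- annotate_oligos(all_words, consensus)
      for (dname in c("down", "up")) {
        subset <- split_dir[[dname]]
        if (!length(subset)) next
        enr <- regulated_enrichment(unname(ov1), subset,
                                    universe = promoters$gene_id,
                                    alpha = config$alpha_enrich,
                                    conservation = cons_tab,
                                    annotations = ann)
        out[[paste0("oligo_enrichment_", dname)]] <- enr
        emit(enr, sprintf("oligo_enrichment_%s.tsv", dname))
        stage_log("annotate", "%s: %d enriched word(s)", dname, nrow(enr))
      }
    }
  }

  # ---- SP1-style co-factor colocalization ----
  sp1_pfm <- resolve_input(config$sp1_pfm, read_jaspar_pfm)
  if (!is.null(sp1_pfm) && !is.null(regulated) && nrow(sites)) {
    sp1_pwm <- build_pwm(sp1_pfm, background = config$background,
                         min_fraction = config$min_fraction)
    sp1_sites <- scan_promoters(sp1_pwm, promoters)
    out$sp1_sites <- sp1_sites
    if (nrow(sp1_sites)) {
      thr_sp1 <- percentile_threshold(sp1_sites, config$focus_fraction)
      thr_a <- percentile_threshold(sites, config$focus_fraction)
      down <- split_by_direction(regulated, regulated$gene_id)$down
      coloc <- sp1_colocalization(sites[score >= thr_a$cutoff_score],
                                  sp1_sites[score >= thr_sp1$cutoff_score],
                                  down)
      out$colocalization <- coloc
      emit(coloc$report, "sp1_colocalization.tsv")
      stage_log("colocalize",
                "%d gene(s) with co-factor sites, %d overlapping pair(s)",
                nrow(coloc$report), nrow(coloc$overlaps))
    }
  }

  # ---- manifest ----
  manifest <- list(
    package = "cismap",
    version = as.character(packageVersion("cismap")),
    seed = config$seed,
    parameters = list(min_fraction = config$min_fraction,
                      top_fractions = config$top_fractions,
                      min_sites = config$min_sites,
                      focus_fraction = config$focus_fraction,
                      k_range = config$k_range,
                      alpha_oligo = config$alpha_oligo,
                      alpha_enrich = config$alpha_enrich,
                      fdr = config$fdr,
                      background = as.list(config$background)),
    outputs = lapply(setNames(nm = basename(written)), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Co-localization of a co-factor's sites with the primary motif's sites
#'
#' Per gene of the subset that carries at least one (already thresholded)
#' co-factor site: its co-factor and primary site counts, plus the explicit
#' list of overlapping site pairs from [site_overlap()].
#'
#' @param sites_primary,sites_cofactor Thresholded site tables on the same
#'   promoter set (e.g. top-20% TFAP2A and SP1 sites).
#' @param gene_subset Genes to report on (e.g. the down-regulated set).
#' @return List with `report` (`gene_id`, `n_cofactor_sites`,
#'   `n_primary_sites`, `n_overlaps`) and `overlaps` (pair table).
#' @export
sp1_colocalization <- function(sites_primary, sites_cofactor, gene_subset) {
  sp <- as.data.table(sites_primary)[gene_id %in% gene_subset]
  sc <- as.data.table(sites_cofactor)[gene_id %in% gene_subset]
  ov <- site_overlap(sp, sc)
  carriers <- sc[, .(n_cofactor_sites = .N), by = gene_id]
  prim <- sp[, .(n_primary_sites = .N), by = gene_id]
  report <- merge(carriers, prim, by = "gene_id", all.x = TRUE)
  report[is.na(n_primary_sites), n_primary_sites := 0L]
  novl <- ov[, .(n_overlaps = .N), by = gene_id]
  report <- merge(report, novl, by = "gene_id", all.x = TRUE)
  report[is.na(n_overlaps), n_overlaps := 0L]
  setorderv(report, "gene_id")
  list(report = report[], overlaps = ov)
}
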