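# Readers and writers for the external formats the pipeline touches:
# JASPAR flat count matrices, promoter FASTA, BED-like TSS tables,
# orthology / regulated-gene / consensus-library TSVs.
#
# TSV dialect throughout: tab-separated, UTF-8, lines starting with "#"
# are comments.

DNA_BASES <- c("A", "C", "G", "T")

#' Read a JASPAR-style position frequency matrix
#'
#' Parses the JASPAR flat (`.pfm` / "jaspar") format: an optional header line
#' `>MOTIF_ID TF_NAME` followed by four rows of non-negative counts labelled
#' `A`, `C`, `G`, `T` (brackets around the numbers, as in JASPAR files, are
#' tolerated and ignored). Headerless four-row count files are accepted too.
#'
#' @param path Path to a JASPAR flat file.
#' @return An object of class `pfm`: a list with `motif_id`, `tf_name`, and
#'   `counts`, a 4 x L integer matrix with rownames `A,C,G,T`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty PFM file: ", path)

  motif_id <- tf_name <- ""
  if (startsWith(lines[1L], ">")) {
    hdr <- strsplit(sub("^>", "", lines[1L]), "[ \t]+")[[1L]]
    motif_id <- hdr[1L]
    if (length(hdr) > 1L) tf_name <- paste(hdr[-1L], collapse = " ")
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("PFM must contain 4 base rows (A,C,G,T)")

  rows <- lapply(lines[1:4], function(l) {
    base <- toupper(substr(l, 1L, 1L))
    nums <- regmatches(l, gregexpr("-?[0-9]+\\.?[0-9]*", l))[[1L]]
    list(base = base, counts = as.numeric(nums))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!identical(sort(bases), DNA_BASES)) {
    # headerless numeric-only files: assume canonical A,C,G,T order
    if (all(grepl("^[-0-9\\[\\]. \t]+$", lines[1:4]))) {
      bases <- DNA_BASES
    } else {
      stop("PFM rows must be labelled A, C, G, T (got: ",
           paste(bases, collapse = ","), ")")
    }
  }
  lens <- vapply(rows, function(r) length(r$counts), integer(1))
  if (length(unique(lens)) != 1L || lens[1L] < 1L)
    stop("PFM format error: rows have unequal lengths (",
         paste(lens, collapse = ","), ")")
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- bases
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(counts < 0)) stop("PFM format error: negative count")
  if (any(colSums(counts) <= 0)) stop("PFM format error: zero-total column")
  new_pfm(motif_id = motif_id, tf_name = tf_name, counts = counts)
}

new_pfm <- function(motif_id, tf_name, counts) {
  structure(list(motif_id = motif_id, tf_name = tf_name, counts = counts),
            class = "pfm")
}

#' Build a PFM from aligned site sequences
#'
#' Stacks equal-length DNA strings into a count matrix, one observation per
#' string. Useful for constructing stand-in matrices from published binding
#' site collections.
#'
#' @param sites Character vector of equal-length sequences over A,C,G,T.
#' @param motif_id,tf_name Identifier strings stored in the result.
#' @return A `pfm` object.
#' @export
pfm_from_sites <- function(sites, motif_id = "", tf_name = "") {
  stopifnot(length(sites) >= 1L)
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("site sequences must have equal length")
  mat <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites, ""))
  for (j in seq_len(L)) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- as.integer(tab)
  }
  if (any(colSums(mat) == 0)) stop("column with no A/C/G/T observations")
  new_pfm(motif_id, tf_name, mat)
}

#' Write a PFM in JASPAR flat format
#'
#' @param pfm A `pfm` object.
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s %s", pfm$motif_id, pfm$tf_name), con)
  for (b in DNA_BASES) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pfm$counts[b, ], trim = TRUE),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%s), %d positions\n", x$motif_id, x$tf_name,
              ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

# ---- promoter sets -------------------------------------------------------

#' Construct a promoter set
#'
#' A promoter set is a `data.table` (class `promoter_set`) with one row per
#' gene: `gene_id`, `sequence` (uppercase, over A,C,G,T,N), `tss_offset`
#' (1-based index of the TSS base within the sequence), `strand` (the gene's
#' genomic strand) and `truncated` (window clipped at a contig end and padded
#' with N).
#'
#' @param gene_id,sequence,tss_offset,strand,truncated Parallel vectors.
#' @return A `promoter_set`.
#' @export
promoter_set <- function(gene_id, sequence, tss_offset,
                         strand = "+", truncated = FALSE) {
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("non-ACGTN character in promoter sequence for ",
                     paste(gene_id[bad], collapse = ", "))
  dt <- data.table(gene_id = as.character(gene_id), sequence = sequence,
                   tss_offset = as.integer(tss_offset),
                   strand = rep_len(strand, length(gene_id)),
                   truncated = rep_len(truncated, length(gene_id)))
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene_id in promoter set")
  setattr(dt, "class", c("promoter_set", class(dt)))
  dt[]
}

#' Extract core promoter windows from a genome
#'
#' Takes, for every gene, the window `upstream` nt before to `downstream` nt
#' after the transcription start site of its **longest** transcript (the TSS
#' base itself is the first downstream base). For minus-strand genes the
#' window is reported on the reverse complement, so upstream is always 5' of
#' the TSS. Windows overrunning contig ends are padded with `N` and flagged
#' `truncated`.
#'
#' @param genome A named character vector, a `Biostrings::DNAStringSet`, or a
#'   path to a FASTA file.
#' @param tss_table A data.frame with columns `chrom`, `tss_pos` (1-based),
#'   `strand`, `gene_id`, `transcript_length`, and optionally
#'   `transcript_id`; or a path to a tab-separated file with those columns
#'   (headerless files are read positionally).
#' @param upstream,downstream Window extents in nt; their sum must be > 0.
#' @return A [promoter_set()] with one record per gene, window length
#'   `upstream + downstream`, and `tss_offset = upstream + 1`.
#' @details When a gene has several transcripts the one with maximal
#'   `transcript_length` is used; ties go to the lexicographically smallest
#'   `transcript_id` (or, without IDs, to the smallest `tss_pos`).
#' @export
extract_promoters <- function(genome, tss_table, upstream = 900L,
                              downstream = 100L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream + downstream <= 0L) stop("upstream + downstream must be > 0")
  if (upstream < 0L || downstream < 0L) stop("window extents must be >= 0")

  seqs <- load_genome(genome)
  tss <- load_tss_table(tss_table)

  # longest transcript per gene, deterministic tie-break
  setorderv(tss, c("gene_id", "transcript_length", "transcript_id", "tss_pos"),
            order = c(1L, -1L, 1L, 1L))
  tss <- tss[, head(.SD, 1L), by = gene_id]

  missing <- setdiff(tss$chrom, names(seqs))
  if (length(missing))
    stop("unknown chromosome(s) in TSS table: ", paste(missing, collapse = ", "))

  n <- nrow(tss)
  out_seq <- character(n); out_trunc <- logical(n)
  win <- upstream + downstream
  for (i in seq_len(n)) {
    chrom_seq <- seqs[[tss$chrom[i]]]
    clen <- nchar(chrom_seq)
    t <- tss$tss_pos[i]
    if (t < 1L || t > clen)
      stop("tss_pos out of chromosome bounds for gene ", tss$gene_id[i])
    if (tss$strand[i] == "+") {
      from <- t - upstream; to <- t + downstream - 1L
    } else {
      from <- t - downstream + 1L; to <- t + upstream
    }
    lo <- max(from, 1L); hi <- min(to, clen)
    core <- substr(chrom_seq, lo, hi)
    pad_l <- lo - from; pad_r <- to - hi
    s <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
    if (tss$strand[i] == "-") s <- revcomp(s)
    stopifnot(nchar(s) == win)
    out_seq[i] <- s
    out_trunc[i] <- pad_l > 0L || pad_r > 0L
  }
  promoter_set(tss$gene_id, out_seq, tss_offset = upstream + 1L,
               strand = tss$strand, truncated = out_trunc)
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(toupper(as.character(genome)), names(genome))
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("[ \t].*$", "", names(x))
    setNames(toupper(as.character(x)), names(x))
  } else if (is.character(genome) && !is.null(names(genome))) {
    toupper(genome)
  } else stop("genome must be a FASTA path, DNAStringSet, or named character vector")
}

load_tss_table <- function(tss_table) {
  if (is.character(tss_table) && length(tss_table) == 1L) {
    tss <- read_tsv_file(tss_table)
    if (!"chrom" %in% names(tss)) {
      nm <- c("chrom", "tss_pos", "strand", "gene_id", "transcript_length",
              "transcript_id")
      setnames(tss, names(tss), nm[seq_len(ncol(tss))])
    }
  } else tss <- as.data.table(tss_table)
  req <- c("chrom", "tss_pos", "strand", "gene_id", "transcript_length")
  if (!all(req %in% names(tss)))
    stop("TSS table needs columns: ", paste(req, collapse = ", "))
  if (!"transcript_id" %in% names(tss)) tss[, transcript_id := ""]
  tss[, `:=`(chrom = as.character(chrom), tss_pos = as.integer(tss_pos),
             strand = as.character(strand), gene_id = as.character(gene_id),
             transcript_length = as.numeric(transcript_length),
             transcript_id = as.character(transcript_id))]
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss
}

#' Write a promoter set as FASTA
#'
#' Record metadata (TSS offset, gene strand, truncation flag) is carried in
#' the description line, so [read_promoters()] round-trips the object.
#'
#' @param promoters A [promoter_set()].
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @export
write_promoters <- function(promoters, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    writeLines(sprintf(">%s tss_offset=%d strand=%s truncated=%d",
                       promoters$gene_id[i], promoters$tss_offset[i],
                       promoters$strand[i], as.integer(promoters$truncated[i])),
               con)
    s <- promoters$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read promoters from FASTA
#'
#' Inverse of [write_promoters()]. Plain FASTA without the metadata fields is
#' accepted: `tss_offset` then defaults to `default_upstream + 1`.
#'
#' @param path FASTA path.
#' @param default_upstream Assumed upstream extent for plain FASTA input.
#' @return A [promoter_set()].
#' @export
read_promoters <- function(path, default_upstream = 900L) {
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  ids <- sub("[ \t].*$", "", desc)
  get_field <- function(field, default) {
    m <- regmatches(desc, regexpr(paste0(field, "=[^ \t]+"), desc))
    out <- rep(default, length(desc))
    hit <- grepl(paste0(field, "="), desc)
    out[hit] <- sub(paste0(field, "="), "", regmatches(desc, regexpr(
      paste0(field, "=[^ \t]+"), desc)))
    out
  }
  offs <- suppressWarnings(as.integer(get_field("tss_offset",
                                                default_upstream + 1L)))
  offs[is.na(offs)] <- default_upstream + 1L
  strands <- get_field("strand", "+")
  trunc <- get_field("truncated", "0") == "1"
  promoter_set(ids, as.character(x), offs, strands, trunc)
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, lengths %s, %d truncated\n",
              nrow(x), paste(range(nchar(x$sequence)), collapse = "-"),
              sum(x$truncated)))
  invisible(x)
}

# ---- simple TSV tables ---------------------------------------------------

read_tsv_file <- function(path, header = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.table())
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = header,
        data.table = TRUE, na.strings = NULL, showProgress = FALSE)
}

#' Read a one-to-one orthology map
#'
#' Two-column tab-separated file of orthologous gene ID pairs (species 1,
#' species 2). Any gene appearing in more than one pair violates the
#' one-to-one requirement and **all** of its pairs are dropped; the number of
#' dropped pairs is reported with a message.
#'
#' @param path TSV path.
#' @return A `data.table` with columns `gene1`, `gene2`, class
#'   `orthology_map`.
#' @export
read_orthology <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    warning("empty orthology file: ", path)
    return(orthology_map(character(), character()))
  }
  dt <- read_tsv_file(path, header = FALSE)
  if (nrow(dt) == 0L) {
    warning("empty orthology file: ", path)
    return(orthology_map(character(), character()))
  }
  if (ncol(dt) < 2L) stop("orthology table needs two columns")
  orthology_map(as.character(dt[[1L]]), as.character(dt[[2L]]))
}

#' Construct a one-to-one orthology map
#'
#' @param gene1,gene2 Parallel gene ID vectors; pairs breaking one-to-one-ness
#'   are removed entirely (see [read_orthology()]).
#' @return An `orthology_map` data.table.
#' @export
orthology_map <- function(gene1, gene2) {
  dt <- data.table(gene1 = as.character(gene1), gene2 = as.character(gene2))
  dup1 <- dt$gene1 %in% dt$gene1[duplicated(dt$gene1)]
  dup2 <- dt$gene2 %in% dt$gene2[duplicated(dt$gene2)]
  drop <- dup1 | dup2
  if (any(drop))
    message(sum(drop), " orthology pair(s) dropped (not one-to-one)")
  dt <- dt[!drop]
  setattr(dt, "class", c("orthology_map", class(dt)))
  dt[]
}

#' Read a regulated-gene table
#'
#' Three tab-separated columns: `gene_id`, `fold_change` (signed), and
#' `direction` (`up`/`down`). Directions must agree with the fold-change
#' sign, gene IDs must be unique, and a fold change of exactly zero is
#' rejected (no direction can be assigned).
#'
#' @param path TSV path (a header row naming the columns is optional).
#' @return A `data.table` of class `regulated_genes`.
#' @export
read_regulated_genes <- function(path) {
  dt <- read_tsv_file(path)
  if (!"gene_id" %in% names(dt))
    setnames(dt, names(dt)[1:3], c("gene_id", "fold_change", "direction"))
  regulated_genes(dt$gene_id, as.numeric(dt$fold_change),
                  as.character(dt$direction))
}

#' Construct a regulated-gene table
#'
#' @param gene_id,fold_change,direction Parallel vectors; see
#'   [read_regulated_genes()].
#' @return A `regulated_genes` data.table.
#' @export
regulated_genes <- function(gene_id, fold_change, direction) {
  dt <- data.table(gene_id = as.character(gene_id),
                   fold_change = as.numeric(fold_change),
                   direction = tolower(as.character(direction)))
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene_id in regulated table")
  if (!all(dt$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  if (any(dt$fold_change == 0)) stop("fold_change of 0 cannot carry a direction")
  mismatch <- (dt$fold_change > 0) != (dt$direction == "up")
  if (any(mismatch))
    stop("direction inconsistent with fold_change sign for: ",
         paste(dt$gene_id[mismatch], collapse = ", "))
  setattr(dt, "class", c("regulated_genes", class(dt)))
  dt[]
}

#' Read a transcription-factor consensus library
#'
#' Two tab-separated columns: TF name and an IUPAC consensus string
#' (letters A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#'
#' @param path TSV path.
#' @return A `data.table` with columns `tf`, `consensus`.
#' @export
read_consensus_library <- function(path) {
  dt <- read_tsv_file(path, header = FALSE)
  if (ncol(dt) < 2L) stop("consensus library needs two columns")
  setnames(dt, 1:2, c("tf", "consensus"))
  dt[, consensus := toupper(as.character(consensus))]
  bad <- !nzchar(dt$consensus) | grepl("[^ACGTRYSWKMBDHVN]", dt$consensus)
  if (any(bad)) stop("invalid IUPAC consensus for: ",
                     paste(dt$tf[bad], collapse = ", "))
  dt[, .(tf = as.character(tf), consensus)]
}

#' Reverse complement
#'
#' @param x Character vector of DNA strings (A,C,G,T,N and IUPAC codes).
#' @return Reverse complement of each string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
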