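# IUPAC consensus matching: associate over-represented oligos with known
# transcription-factor consensus strings. Two degenerate letters are
# compatible when their base sets intersect; an oligo matches a consensus
# when the shorter string is fully contained, position-by-position
# compatibly, within the longer at some offset (no overhangs), on either
# strand of the oligo.

#' The 15-letter IUPAC DNA alphabet
#'
#' Named list mapping each IUPAC letter to its base set.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_ALPHABET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# 15 x 15 compatibility lookup, computed once at load
iupac_compat_matrix <- local({
  letters <- names(IUPAC_ALPHABET)
  m <- matrix(FALSE, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (x in letters) for (y in letters)
    m[x, y] <- length(intersect(IUPAC_ALPHABET[[x]], IUPAC_ALPHABET[[y]])) > 0L
  m
})

#' Are two IUPAC letters compatible?
#'
#' Compatible means their base sets intersect, e.g. `G` and `R` (= A/G) are,
#' `A` and `Y` (= C/T) are not.
#'
#' @param x,y Single IUPAC letters (vectorized, recycled).
#' @return Logical vector.
#' @export
iupac_compatible <- function(x, y) {
  x <- toupper(x); y <- toupper(y)
  bad <- setdiff(unique(c(x, y)), names(IUPAC_ALPHABET))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  iupac_compat_matrix[cbind(x, y)]
}

# does `short` sit IUPAC-compatibly inside `long` at some offset?
contained_compatibly <- function(short, long) {
  ns <- nchar(short); nl <- nchar(long)
  s <- strsplit(short, "")[[1L]]
  l <- strsplit(long, "")[[1L]]
  for (off in 0:(nl - ns)) {
    if (all(iupac_compat_matrix[cbind(s, l[(off + 1L):(off + ns)])]))
      return(TRUE)
  }
  FALSE
}

#' Match an oligo against a TF consensus
#'
#' TRUE when the shorter of the two strings is entirely contained,
#' position-by-position IUPAC-compatibly, within the longer at some offset
#' ("full overlap"; overhangs are rejected). With `both_strands` the reverse
#' complement of the oligo is tried as well.
#'
#' @param oligo DNA/IUPAC string.
#' @param consensus A consensus IUPAC string, or a row of the library from
#'   [read_consensus_library()].
#' @param both_strands Also try the oligo's reverse complement (default
#'   `TRUE`).
#' @return Logical.
#' @export
match_oligo_to_consensus <- function(oligo, consensus, both_strands = TRUE) {
  if (is.list(consensus) || is.data.frame(consensus))
    consensus <- consensus$consensus
  oligo <- toupper(oligo); consensus <- toupper(consensus)
  stopifnot(nchar(oligo) >= 1L, nchar(consensus) >= 1L)
  pair_match <- function(o) {
    if (nchar(o) <= nchar(consensus)) contained_compatibly(o, consensus)
    else contained_compatibly(consensus, o)
  }
  if (pair_match(oligo)) return(TRUE)
  if (both_strands && pair_match(revcomp(oligo))) return(TRUE)
  FALSE
}

#' Annotate oligos with matching transcription factors
#'
#' @param oligos Character vector of words.
#' @param library A consensus library (`tf`, `consensus` columns; see
#'   [read_consensus_library()]).
#' @param both_strands Match either strand of each oligo (default `TRUE`).
#' @return Named list mapping each oligo to the (possibly empty) character
#'   vector of matching TF names, in library order.
#' @export
annotate_oligos <- function(oligos, library, both_strands = TRUE) {
  stopifnot(is.data.frame(library), nrow(library) >= 1L)
  oligos <- toupper(oligos)
  out <- lapply(oligos, function(w) {
    hits <- vapply(seq_len(nrow(library)), function(i)
      match_oligo_to_consensus(w, library$consensus[i], both_strands),
      logical(1))
    library$tf[hits]
  })
  names(out) <- oligos
  out
}
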