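# Nucleotide-sequence primitives shared by all higher modules.
#
# Conventions used throughout the package:
#   * coordinates are 0-based, half-open [start, end)
#   * sequences are uppercase-normalized on input; lowercase is folded
#   * stored sequences carry no IUPAC ambiguity codes -- ambiguity is allowed
#     only in motif patterns (PAMs, enzyme recognition sites)

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

# IUPAC nucleotide codes -> the set of DNA bases each matches
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalize and validate a nucleotide sequence
#'
#' Folds lowercase to uppercase and checks every residue against the strict
#' (unambiguous) DNA or RNA alphabet. Ambiguity codes are rejected here;
#' they are only legal inside motif patterns.
#'
#' @param x Character scalar.
#' @param kind `"dna"` or `"rna"`.
#' @param what Label used in error messages.
#' @return The validated, uppercased sequence.
#' @keywords internal
normalize_seq <- function(x, kind = c("dna", "rna"), what = "sequence") {
  kind <- match.arg(kind)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (!nzchar(x)) return(x)
  pattern <- if (kind == "dna") "[^ACGT]" else "[^ACGU]"
  bad <- regexpr(pattern, x)
  if (bad != -1L) {
    stop(sprintf(
      "invalid %s character '%s' at position %d (0-based) in %s",
      toupper(kind), substr(x, bad, bad), bad - 1L, what
    ), call. = FALSE)
  }
  x
}

#' Does a sequence look like RNA?
#' @keywords internal
is_rna_seq <- function(x) grepl("U", toupper(x), fixed = TRUE)

#' Reverse complement of a DNA or RNA sequence
#'
#' Watson-Crick reverse complement (A<->T or A<->U, C<->G, order reversed).
#' The kind (DNA vs RNA) is inferred from the presence of U unless given.
#'
#' @param x Character scalar, unambiguous DNA or RNA. `""` returns `""`.
#' @param kind `"auto"` (default), `"dna"` or `"rna"`.
#' @return Character scalar of the same kind and length.
#' @examples
#' reverse_complement("AAAACC")  # "GGTTTT"
#' @export
reverse_complement <- function(x, kind = c("auto", "dna", "rna")) {
  kind <- match.arg(kind)
  if (kind == "auto") kind <- if (is_rna_seq(x)) "rna" else "dna"
  x <- normalize_seq(x, kind)
  if (!nzchar(x)) return(x)
  comp <- if (kind == "dna") chartr("ACGT", "TGCA", x) else
    chartr("ACGU", "UGCA", x)
  # reverse via raw bytes: fast for the short sequences this package handles
  rawToChar(rev(charToRaw(comp)))
}

#' Transcribe a DNA sequence into RNA
#'
#' The input is interpreted as the sense (coding) strand of the transcript,
#' so transcription is simply T -> U.
#'
#' @param x Character scalar, unambiguous DNA.
#' @return Character scalar, RNA.
#' @examples
#' transcribe("TTAA")  # "UUAA"
#' @export
transcribe <- function(x) {
  if (is_rna_seq(x)) {
    stop("transcribe() expects DNA input; sequence already contains U",
         call. = FALSE)
  }
  x <- normalize_seq(x, "dna")
  chartr("T", "U", x)
}

#' Reverse complement of an IUPAC pattern (ambiguity codes allowed)
#' @keywords internal
iupac_reverse_complement <- function(motif) {
  motif <- validate_motif(motif)
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", motif),
                     "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Validate an IUPAC motif pattern
#' @keywords internal
validate_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("motif must be a non-empty character string", call. = FALSE)
  }
  motif <- toupper(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at position %d (0-based) in motif",
                 chars[bad[1L]], bad[1L] - 1L), call. = FALSE)
  }
  motif
}

#' Find all occurrences of an IUPAC motif on one or both strands
#'
#' Scans a DNA sequence for an IUPAC-degenerate motif. Minus-strand hits are
#' intervals whose reverse complement matches the motif; their coordinates
#' are reported on the plus strand. Overlapping hits are all reported. A
#' palindromic motif hitting the same interval on both strands is reported
#' once, with `strand = "+"` (one physical site is one site).
#'
#' @param x Character scalar, unambiguous DNA (the subject).
#' @param motif Character scalar over IUPAC codes (e.g. `"NGG"`, `"GCTCTTC"`).
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return A data frame with columns `start` (0-based), `end` (exclusive) and
#'   `strand` (`"+"`/`"-"`), sorted by `start` with plus before minus at equal
#'   start. A motif longer than the subject yields zero rows, not an error.
#' @examples
#' find_sites("GAAGAGC", "GCTCTTC")  # one minus-strand hit at [0,7)
#' @export
find_sites <- function(x, motif, strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  motif <- validate_motif(motif)
  x <- normalize_seq(x, "dna")
  hits_df <- function(start, strand) {
    # lightweight data.frame construction: this sits on a hot path
    structure(list(start = start, end = start + nchar(motif),
                   strand = strand),
              class = "data.frame",
              row.names = if (length(start)) c(NA_integer_, -length(start))
                          else integer())
  }
  if (nchar(motif) > nchar(x) || !nzchar(x)) {
    return(hits_df(integer(), character()))
  }

  # IUPAC motif -> regex; a lookahead reports overlapping matches too
  to_regex <- function(m) {
    paste(vapply(strsplit(m, "", fixed = TRUE)[[1L]], function(ch) {
      bases <- IUPAC_CODES[[ch]]
      if (length(bases) == 1L) bases else
        paste0("[", paste(bases, collapse = ""), "]")
    }, character(1)), collapse = "")
  }
  scan_one <- function(pattern) {
    m <- gregexpr(sprintf("(?=%s)", to_regex(pattern)), x, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m) - 1L
  }

  plus <- if (strands %in% c("both", "plus")) scan_one(motif) else integer()
  minus <- if (strands %in% c("both", "minus"))
    scan_one(iupac_reverse_complement(motif)) else integer()
  if (strands == "both" && length(minus)) {
    # palindromic motif: drop minus hits duplicating a plus interval
    minus <- minus[!minus %in% plus]
  }
  starts <- c(plus, minus)
  strand <- rep(c("+", "-"), c(length(plus), length(minus)))
  ord <- order(starts, match(strand, c("+", "-")))
  hits_df(starts[ord], strand[ord])
}
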