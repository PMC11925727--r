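# Independent brute-force oracles. These deliberately share no code with
# the package internals: per-position loops and character tables instead of
# regex or vectorized scans.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(ORACLE_COMP[ch])), collapse = "")
}

oracle_match_at <- function(seq_chars, motif_chars, pos) {
  # does the motif match the sequence at 0-based position `pos`?
  for (j in seq_along(motif_chars)) {
    if (!seq_chars[pos + j] %in% ORACLE_IUPAC[[motif_chars[j]]]) return(FALSE)
  }
  TRUE
}

# position-by-position scan on both strands; same reporting conventions as
# find_sites (plus-strand coordinates, palindromic dedup, sort order)
oracle_find_sites <- function(x, motif, strands = "both") {
  seq_chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  rc_chars <- strsplit(oracle_revcomp_iupac(motif), "", fixed = TRUE)[[1L]]
  k <- length(motif_chars)
  n <- length(seq_chars)
  rows <- list()
  if (n >= k) {
    for (a in 0:(n - k)) {
      plus_hit <- oracle_match_at(seq_chars, motif_chars, a)
      minus_hit <- oracle_match_at(seq_chars, rc_chars, a)
      if (strands %in% c("both", "plus") && plus_hit) {
        rows[[length(rows) + 1L]] <- list(a, a + k, "+")
      }
      if (strands %in% c("both", "minus") && minus_hit) {
        if (!(strands == "both" && plus_hit)) {  # palindromic dedup
          rows[[length(rows) + 1L]] <- list(a, a + k, "-")
        }
      }
    }
  }
  df <- data.frame(start = vapply(rows, `[[`, numeric(1), 1),
                   end = vapply(rows, `[[`, numeric(1), 2),
                   strand = vapply(rows, `[[`, character(1), 3),
                   stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[order(df$start, match(df$strand, c("+", "-"))), , drop = FALSE]
}

oracle_revcomp_iupac <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  paste(rev(unname(comp[ch])), collapse = "")
}

# exhaustive position x strand enumeration of PAM-adjacent protospacers
# wholly inside the closed upstream window [tss - max_up, tss - min_up]
oracle_candidate_scan <- function(promoter, tss, cas, min_up = 75,
                                  max_up = 300, L = NULL) {
  if (is.null(L)) L <- if (cas == "spcas9") 20L else 23L
  chars <- strsplit(promoter, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pam <- if (cas == "spcas9") "NGG" else "TTTV"
  pam_chars <- strsplit(pam, "", fixed = TRUE)[[1L]]
  pk <- length(pam_chars)
  ok_window <- function(a, b) a >= tss - max_up && (b - 1) <= tss - min_up
  rows <- list()
  for (a in 0:(n - L)) {
    b <- a + L
    # plus strand: NGG 3' adjacent / TTTV 5' adjacent
    if (cas == "spcas9") {
      pam_at <- b
      pam_ok <- pam_at + pk <= n && oracle_match_at(chars, pam_chars, pam_at)
    } else {
      pam_at <- a - pk
      pam_ok <- pam_at >= 0 && oracle_match_at(chars, pam_chars, pam_at)
    }
    if (pam_ok && ok_window(a, b)) {
      rows[[length(rows) + 1L]] <- list(a, b, "+")
    }
    # minus strand: protospacer is the reverse complement of [a, b)
    if (cas == "spcas9") {
      pam_at <- a - pk  # 3' of the minus-strand protospacer
      rc_pam <- strsplit(oracle_revcomp_iupac(pam), "", fixed = TRUE)[[1L]]
      pam_ok <- pam_at >= 0 && oracle_match_at(chars, rc_pam, pam_at)
    } else {
      pam_at <- b
      rc_pam <- strsplit(oracle_revcomp_iupac(pam), "", fixed = TRUE)[[1L]]
      pam_ok <- pam_at + pk <= n && oracle_match_at(chars, rc_pam, pam_at)
    }
    if (pam_ok && ok_window(a, b)) {
      rows[[length(rows) + 1L]] <- list(a, b, "-")
    }
  }
  df <- data.frame(start = vapply(rows, `[[`, numeric(1), 1),
                   end = vapply(rows, `[[`, numeric(1), 2),
                   strand = vapply(rows, `[[`, character(1), 3),
                   stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[order(df$start, match(df$strand, c("+", "-"))), , drop = FALSE]
}

# independent positional-arithmetic cutter for a blunt linear duplex:
# returns spans and overhang lengths expected from digest()
oracle_digest_linear <- function(seq, recognition, off_top, off_bottom) {
  sites <- oracle_find_sites(seq, recognition, "both")
  cuts <- data.frame(pt = integer(), pb = integer())
  for (i in seq_len(nrow(sites))) {
    if (sites$strand[i] == "+") {
      cuts <- rbind(cuts, data.frame(pt = sites$end[i] + off_top,
                                     pb = sites$end[i] + off_bottom))
    } else {
      cuts <- rbind(cuts, data.frame(pt = sites$start[i] - off_bottom,
                                     pb = sites$start[i] - off_top))
    }
  }
  cuts <- cuts[order(cuts$pt), , drop = FALSE]
  n <- nchar(seq)
  pts <- c(0L, cuts$pt, n)
  pbs <- c(0L, cuts$pb, n)
  out <- list()
  for (i in seq_len(length(pts) - 1L)) {
    out[[i]] <- list(
      seq = substr(seq, pts[i] + 1L, pbs[i + 1L]),
      left_len = pbs[i] - pts[i],
      right_len = pbs[i + 1L] - pts[i + 1L])
  }
  out
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a quick two-guide array used by several test files
two_guide_array <- function(registry = default_registry()) {
  build_array(list(
    spacer("TTGACCTTAAGGCCAATAGGTCA", "lbcas12a", "guide_cas12a"),
    spacer("GACCTTAAGGCCAATAGGTT", "spcas9", "guide_cas9")
  ), registry)
}
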