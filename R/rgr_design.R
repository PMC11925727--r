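# RGR cassette design: the 6-nt hammerhead stem rule, cassette and
# multiplex-array construction, directional cloning arms, domestication
# checks, and CRISPRa candidate-spacer enumeration upstream of a TSS.

SPACER_LEN_BOUNDS <- c(min = 18L, max = 25L)
DEFAULT_SPACER_LEN <- c(spcas9 = 20L, lbcas12a = 23L)

#' Construct a spacer
#'
#' A spacer is the target-matching segment of a guide, tagged with the Cas
#' system that will use it: SpCas9 guides are spacer-first (spacer +
#' scaffold), LbCas12a guides are repeat-first (direct repeat + spacer).
#'
#' @param sequence DNA string, default length bounds 18-25 nt.
#' @param cas `"spcas9"` or `"lbcas12a"`.
#' @param label Unique identifier used to track the guide through arrays,
#'   transcripts and cleavage products.
#' @param len_bounds Length-2 integer vector of allowed spacer lengths.
#' @return A `spacer` object.
#' @export
spacer <- function(sequence, cas = c("spcas9", "lbcas12a"), label,
                   len_bounds = SPACER_LEN_BOUNDS) {
  cas <- match.arg(cas)
  sequence <- normalize_seq(sequence, "dna", what = "spacer sequence")
  n <- nchar(sequence)
  if (n < len_bounds[[1]] || n > len_bounds[[2]]) {
    stop(sprintf("spacer '%s': length %d outside allowed bounds [%d, %d]",
                 label, n, len_bounds[[1]], len_bounds[[2]]), call. = FALSE)
  }
  if (missing(label) || !nzchar(label)) {
    stop("spacer label must be a non-empty string", call. = FALSE)
  }
  structure(list(sequence = sequence, cas = cas, label = label),
            class = "spacer")
}

#' @export
print.spacer <- function(x, ...) {
  cat(sprintf("spacer %s [%s] %s (%d nt)\n", x$label, x$cas, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Design the 6-nt hammerhead stem for a guide body
#'
#' The hammerhead ribozyme's first six nucleotides must base-pair with the
#' six nucleotides immediately following its 3' end, so the stem is the
#' reverse complement of that downstream hexamer.
#'
#' @param downstream_six DNA string of length exactly 6: the first six
#'   nucleotides of the guide body that follows the ribozyme.
#' @return The 6-nt stem (DNA).
#' @examples
#' design_stem("GAAACC")  # "GGTTTC"
#' @export
design_stem <- function(downstream_six) {
  downstream_six <- normalize_seq(downstream_six, "dna",
                                  what = "downstream hexamer")
  if (nchar(downstream_six) != 6L) {
    stop(sprintf("stem design needs exactly 6 nt, got %d",
                 nchar(downstream_six)), call. = FALSE)
  }
  reverse_complement(downstream_six)
}

#' Build one RGR cassette from a spacer
#'
#' Composes hammerhead ribozyme + guide body + HDV ribozyme. The guide body
#' is `spacer + scaffold` for SpCas9 and `direct_repeat + spacer` for
#' LbCas12a. The stem rule is applied positionally: the hammerhead's first
#' six nucleotides are the reverse complement of the first six nucleotides
#' of whatever immediately follows its 3' end -- the spacer for SpCas9, the
#' direct repeat for LbCas12a.
#'
#' If the spacer itself contains a registered enzyme's recognition site a
#' domestication warning is raised (and recorded on the cassette); it only
#' becomes fatal at [add_cloning_arms()].
#'
#' @param sp A [spacer()].
#' @param registry A `part_registry` (defaults to the bundled one).
#' @param part_names Optional named list selecting parts by name when a role
#'   has several (`hh_template`, `hdv`, `cas9_scaffold`,
#'   `cas12a_direct_repeat`).
#' @return An `rgr_cassette` with fields `spacer`, `stem`, `hh`,
#'   `guide_body`, `hdv`, `full_sequence` and 0-based half-open `boundaries`.
#' @export
build_rgr <- function(sp, registry = default_registry(), part_names = list()) {
  stopifnot(inherits(sp, "spacer"), inherits(registry, "part_registry"))
  pick <- function(role) get_part(registry, role, part_names[[role]])
  hh_template <- pick("hh_template")$sequence
  hdv <- pick("hdv")$sequence
  guide_body <- switch(sp$cas,
    spcas9 = paste0(sp$sequence, pick("cas9_scaffold")$sequence),
    lbcas12a = paste0(pick("cas12a_direct_repeat")$sequence, sp$sequence)
  )
  stem <- design_stem(substr(guide_body, 1L, 6L))
  hh <- paste0(stem, substring(hh_template, 7L))
  full <- paste0(hh, guide_body, hdv)
  boundaries <- list(
    hh = c(0L, nchar(hh)),
    guide_body = c(nchar(hh), nchar(hh) + nchar(guide_body)),
    hdv = c(nchar(hh) + nchar(guide_body), nchar(full))
  )
  domestication <- domesticate_check(sp$sequence, registry$enzymes)
  if (nrow(domestication)) {
    warning(sprintf(
      "spacer '%s' contains %d type IIS recognition site(s) (%s); %s",
      sp$label, nrow(domestication),
      paste(unique(domestication$enzyme), collapse = ", "),
      "assembly with that enzyme will fail at add_cloning_arms()"),
      call. = FALSE)
  }
  structure(list(spacer = sp, stem = stem, hh = hh, guide_body = guide_body,
                 hdv = hdv, full_sequence = full, boundaries = boundaries,
                 domestication = domestication),
            class = "rgr_cassette")
}

#' @export
print.rgr_cassette <- function(x, ...) {
  cat(sprintf("RGR cassette '%s' [%s], %d nt\n", x$spacer$label,
              x$spacer$cas, nchar(x$full_sequence)))
  cat(sprintf("  stem %s | HH %d nt | guide body %d nt | HDV %d nt\n",
              x$stem, nchar(x$hh), nchar(x$guide_body), nchar(x$hdv)))
  invisible(x)
}

#' Build a multiplex array of RGR cassettes
#'
#' Cassettes are built independently per spacer and concatenated in input
#' order, releasing one guide each after ribozyme self-cleavage of the
#' shared transcript. The default inter-cassette linker is empty (direct
#' HDV-to-HH abutment).
#'
#' @param spacers List of [spacer()] objects with unique labels.
#' @param registry A `part_registry`.
#' @param linker DNA string inserted between consecutive cassettes.
#' @param part_names Passed to [build_rgr()].
#' @return A `multiplex_array`.
#' @export
build_array <- function(spacers, registry = default_registry(), linker = "",
                        part_names = list()) {
  if (inherits(spacers, "spacer")) spacers <- list(spacers)
  if (length(spacers) == 0L) {
    stop("build_array() needs at least one spacer", call. = FALSE)
  }
  labels <- vapply(spacers, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate spacer labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (nzchar(linker)) linker <- normalize_seq(linker, "dna", what = "linker")
  cassettes <- lapply(spacers, build_rgr, registry = registry,
                      part_names = part_names)
  full <- paste(vapply(cassettes, `[[`, character(1), "full_sequence"),
                collapse = linker)
  structure(list(cassettes = cassettes, linker = linker,
                 full_sequence = full),
            class = "multiplex_array")
}

#' @export
print.multiplex_array <- function(x, ...) {
  cat(sprintf("multiplex_array: %d cassette(s), %d nt total%s\n",
              length(x$cassettes), nchar(x$full_sequence),
              if (nzchar(x$linker))
                sprintf(", %d-nt linker", nchar(x$linker)) else ""))
  for (cs in x$cassettes) {
    cat(sprintf("  %s [%s] %d nt\n", cs$spacer$label, cs$spacer$cas,
                nchar(cs$full_sequence)))
  }
  invisible(x)
}

#' Scan a sequence for internal type IIS recognition sites
#'
#' Golden Gate assembly requires the insert interior to be free of the
#' enzyme's recognition site on either strand ("domestication"); internal
#' sites would shatter the fragment during the one-pot digestion.
#'
#' @param x DNA string.
#' @param enzymes A list of `rgr_enzyme` objects (e.g. `registry$enzymes`),
#'   or a single `rgr_enzyme`.
#' @return Data frame with columns `enzyme`, `start`, `end`, `strand`;
#'   zero rows means the sequence is clean.
#' @export
domesticate_check <- function(x, enzymes) {
  if (inherits(enzymes, "rgr_enzyme")) enzymes <- list(enzymes)
  out <- list()
  seen <- character()
  x <- toupper(x)
  for (e in enzymes) {
    # isoschizomers (same recognition site) are reported once
    if (e$recognition %in% seen) next
    seen <- c(seen, e$recognition)
    # fast pre-screen for literal (unambiguous) recognition sequences
    if (!grepl("[^ACGT]", e$recognition) &&
        !grepl(e$recognition, x, fixed = TRUE) &&
        !grepl(reverse_complement(e$recognition), x, fixed = TRUE)) next
    hits <- find_sites(x, e$recognition, "both")
    if (nrow(hits)) {
      hits$enzyme <- e$name
      out[[length(out) + 1L]] <- hits[, c("enzyme", "start", "end", "strand")]
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$enzyme), , drop = FALSE]
    rownames(res) <- NULL
    res
  } else {
    data.frame(enzyme = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  }
}

#' Attach directional type IIS cloning arms to an array
#'
#' Flanks the array with inward-pointing recognition sites so that
#' digestion releases exactly one insert whose 5' overhangs are the
#' configured directional pair, with no recognition site left on the
#' insert. Overhang sequences are given (and reported) as the plus-strand
#' sequence of the overhang window.
#'
#' @param array A `multiplex_array` (or a single `rgr_cassette`).
#' @param enzyme An `rgr_enzyme`.
#' @param overhangs Character vector `c(o5, o3)` of length
#'   `enzyme$overhang_len` each.
#' @param spacer_nt DNA string placed between the recognition site and the
#'   cut window on each side; defaults to `"A"` repeated `cut_offset_top`
#'   times.
#' @return A `cloned_fragment` containing the arm-bearing linear duplex
#'   (`$ds`), the arms, and the design metadata.
#' @export
add_cloning_arms <- function(array, enzyme, overhangs,
                             spacer_nt = NULL) {
  if (inherits(array, "rgr_cassette")) {
    array <- structure(list(cassettes = list(array), linker = "",
                            full_sequence = array$full_sequence),
                       class = "multiplex_array")
  }
  stopifnot(inherits(array, "multiplex_array"),
            inherits(enzyme, "rgr_enzyme"))
  overhangs <- toupper(overhangs)
  if (length(overhangs) != 2L ||
      any(nchar(overhangs) != enzyme$overhang_len)) {
    stop(sprintf("overhang pair must be two %d-nt sequences for %s",
                 enzyme$overhang_len, enzyme$name), call. = FALSE)
  }
  internal <- domesticate_check(array$full_sequence, list(enzyme))
  if (nrow(internal)) {
    stop(sprintf(
      "array contains %d internal %s recognition site(s) at plus-strand %s",
      nrow(internal), enzyme$name,
      paste(sprintf("[%d,%d)/%s", internal$start, internal$end,
                    internal$strand), collapse = ", ")), call. = FALSE)
  }
  if (is.null(spacer_nt)) {
    spacer_nt <- strrep("A", enzyme$cut_offset_top)
  } else {
    spacer_nt <- normalize_seq(spacer_nt, "dna", what = "spacer_nt")
    if (nchar(spacer_nt) != enzyme$cut_offset_top) {
      stop(sprintf("spacer_nt must be %d nt for %s",
                   enzyme$cut_offset_top, enzyme$name), call. = FALSE)
    }
  }
  arm5 <- paste0(enzyme$recognition, spacer_nt, overhangs[[1]])
  arm3 <- paste0(overhangs[[2]], spacer_nt,
                 reverse_complement(enzyme$recognition))
  top <- paste0(arm5, array$full_sequence, arm3)
  frag <- ds_fragment(top, id = "armed_insert")
  # the arms themselves must contribute exactly the two intended sites
  sites <- find_sites(top, enzyme$recognition, "both")
  if (nrow(sites) != 2L) {
    stop(sprintf(
      "arm construction created %d %s site(s) instead of 2; choose a %s",
      nrow(sites), enzyme$name,
      "different spacer_nt or overhang pair"), call. = FALSE)
  }
  structure(list(array = array, enzyme = enzyme,
                 overhangs = overhangs, arm5 = arm5, arm3 = arm3,
                 ds = frag),
            class = "cloned_fragment")
}

#' @export
print.cloned_fragment <- function(x, ...) {
  cat(sprintf(
    "cloned_fragment: %d-cassette array + %s arms, overhangs %s/%s, %d nt\n",
    length(x$array$cassettes), x$enzyme$name,
    x$overhangs[[1]], x$overhangs[[2]], nchar(x$ds$seq)))
  invisible(x)
}

#' CRISPRa target window upstream of a TSS
#'
#' @param min_upstream,max_upstream Window bounds in bp upstream of the
#'   transcription start site; defaults 75 and 300. Both bounds inclusive:
#'   the whole protospacer must lie within `[tss - max_upstream,
#'   tss - min_upstream]` in plus-strand coordinates.
#' @return A `target_window`.
#' @export
target_window <- function(min_upstream = 75L, max_upstream = 300L) {
  min_upstream <- as.integer(min_upstream)
  max_upstream <- as.integer(max_upstream)
  if (!(min_upstream > 0L && min_upstream < max_upstream)) {
    stop("require 0 < min_upstream < max_upstream", call. = FALSE)
  }
  structure(list(min_upstream = min_upstream, max_upstream = max_upstream),
            class = "target_window")
}

#' Enumerate CRISPRa candidate spacers in a promoter window
#'
#' Finds every protospacer (on both strands) with a correctly placed PAM --
#' NGG 3'-adjacent for SpCas9, TTTV 5'-adjacent for LbCas12a, PAM excluded
#' from the spacer -- whose protospacer lies entirely within the window
#' upstream of the TSS. A base at plus-strand index `p` is `tss - p` bp
#' upstream of the TSS, so the window constraint is
#' `start >= tss - max_upstream` and `end - 1 <= tss - min_upstream`
#' (both bounds inclusive).
#'
#' @param promoter DNA string (plus strand, 5'->3').
#' @param tss 0-based index of the transcription start site on `promoter`.
#' @param cas `"spcas9"` or `"lbcas12a"`.
#' @param window A [target_window()].
#' @param spacer_len Protospacer length; defaults to 20 (SpCas9) or
#'   23 (LbCas12a).
#' @return Data frame sorted by plus-strand `start` (plus before minus at
#'   equal start) with columns `label`, `sequence` (the spacer, always read
#'   5'->3' on the targeted strand), `cas`, `start`, `end` (0-based
#'   half-open protospacer interval on the plus strand), `strand`, `pam`
#'   (as read on the protospacer strand) and `dist_to_tss` (bp from the
#'   TSS-proximal protospacer end to the TSS).
#' @export
find_candidate_spacers <- function(promoter, tss,
                                   cas = c("spcas9", "lbcas12a"),
                                   window = target_window(),
                                   spacer_len = NULL) {
  cas <- match.arg(cas)
  stopifnot(inherits(window, "target_window"))
  promoter <- normalize_seq(promoter, "dna", what = "promoter")
  n <- nchar(promoter)
  tss <- as.integer(tss)
  if (is.na(tss) || tss < 0L || tss > n) {
    stop(sprintf("tss %d out of range [0, %d]", tss, n), call. = FALSE)
  }
  if (is.null(spacer_len)) spacer_len <- DEFAULT_SPACER_LEN[[cas]]
  spacer_len <- as.integer(spacer_len)

  empty <- data.frame(label = character(), sequence = character(),
                      cas = character(), start = integer(), end = integer(),
                      strand = character(), pam = character(),
                      dist_to_tss = integer(), stringsAsFactors = FALSE)
  if (tss < window$max_upstream) {
    warning(sprintf(
      "window extends %d bp upstream but only %d bp precede the TSS; %s",
      window$max_upstream, tss, "returning no candidates"), call. = FALSE)
    return(empty)
  }

  lo <- tss - window$max_upstream   # smallest allowed protospacer start
  hi <- tss - window$min_upstream   # largest allowed protospacer last base
  sub <- function(a, b) substr(promoter, a + 1L, b)  # [a, b) 0-based

  rows <- list()
  push <- function(a, b, strand, pam) {
    if (a < 0L || b > n) return(invisible())
    if (a < lo || (b - 1L) > hi) return(invisible())
    seqp <- sub(a, b)
    if (strand == "-") seqp <- reverse_complement(seqp)
    rows[[length(rows) + 1L]] <<- data.frame(
      label = sprintf("%s_%s%d", cas, ifelse(strand == "+", "p", "m"), a),
      sequence = seqp, cas = cas, start = a, end = b, strand = strand,
      pam = pam, dist_to_tss = tss - (b - 1L), stringsAsFactors = FALSE)
  }

  if (cas == "spcas9") {
    for (i in seq_len(nrow(h <- find_sites(promoter, "NGG", "plus")))) {
      a <- h$start[i] - spacer_len          # PAM 3' of protospacer
      push(a, h$start[i], "+", sub(h$start[i], h$end[i]))
    }
    for (i in seq_len(nrow(h <- find_sites(promoter, "NGG", "minus")))) {
      push(h$end[i], h$end[i] + spacer_len, "-",
           reverse_complement(sub(h$start[i], h$end[i])))
    }
  } else {
    for (i in seq_len(nrow(h <- find_sites(promoter, "TTTV", "plus")))) {
      push(h$end[i], h$end[i] + spacer_len, "+",  # PAM 5' of protospacer
           sub(h$start[i], h$end[i]))
    }
    for (i in seq_len(nrow(h <- find_sites(promoter, "TTTV", "minus")))) {
      push(h$start[i] - spacer_len, h$start[i], "-",
           reverse_complement(sub(h$start[i], h$end[i])))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read spacers from a plain-text table or FASTA file
#'
#' Plain-text format: one spacer per line, whitespace-separated fields
#' `label sequence cas`; lines starting with `#` are ignored. FASTA format:
#' the record id is the label and the description must contain a
#' `cas=spcas9` or `cas=lbcas12a` tag.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"table"` or `"fasta"`.
#' @return List of [spacer()] objects.
#' @export
read_spacers <- function(path, format = c("auto", "table", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "table"
  }
  if (format == "fasta") {
    recs <- read_fasta(path)
    out <- vector("list", nrow(recs))
    for (i in seq_len(nrow(recs))) {
      m <- regmatches(recs$description[i],
                      regexpr("cas=(spcas9|lbcas12a)", recs$description[i]))
      if (!length(m)) {
        stop(sprintf("FASTA record '%s' lacks a cas=spcas9|lbcas12a tag",
                     recs$id[i]), call. = FALSE)
      }
      out[[i]] <- spacer(recs$sequence[i], sub("^cas=", "", m),
                         label = recs$id[i])
    }
    return(out)
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    f <- strsplit(l, "[ \t]+")[[1L]]
    if (length(f) != 3L) {
      stop("expected 3 fields (label sequence cas), got: ", l, call. = FALSE)
    }
    spacer(f[2L], f[3L], label = f[1L])
  })
}

#' Write candidate spacers as a BED file
#'
#' 0-based half-open intervals on the promoter sequence, with the spacer
#' label as name and the TSS distance as score.
#'
#' @param candidates Output of [find_candidate_spacers()].
#' @param path Output BED path.
#' @param chrom Sequence name placed in column 1 (default `"promoter"`).
#' @return `path`, invisibly.
#' @export
spacers_to_bed <- function(candidates, path, chrom = "promoter") {
  bed <- data.frame(chrom = chrom,
                    start = candidates$start, end = candidates$end,
                    name = candidates$label, score = candidates$dist_to_tss,
                    strand = candidates$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
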