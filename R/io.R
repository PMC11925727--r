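# File formats and helpers: FASTA in/out (via Biostrings), a minimal
# GenBank flat-file writer/reader for annotated records, synthetic fixture
# generation, and the illumination-dose calculator for pulsed blue-light
# regimes.

#' Read a (multi-record) FASTA file
#'
#' Lowercase residues are folded to uppercase (with a message noting the
#' normalization).
#'
#' @param path Input FASTA path.
#' @return Data frame with columns `id`, `description` (the header text
#'   after the id, `""` if none) and `sequence`; zero rows for an empty
#'   file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("read_fasta: lowercase residues folded to uppercase")
    seqs <- toupper(seqs)
  }
  headers <- names(set)
  ids <- sub("[ \t].*$", "", headers)
  descs <- ifelse(grepl("[ \t]", headers),
                  sub("^[^ \t]+[ \t]+", "", headers), "")
  data.frame(id = ids, description = descs, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data frame with `id`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]), or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc),
                       paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

FEATURE_TYPES <- c("ribozyme", "spacer", "scaffold", "direct_repeat",
                   "enzyme_site", "arm", "orf")

#' Construct an annotated sequence record
#'
#' @param id Record identifier.
#' @param sequence DNA string.
#' @param features Data frame with columns `label`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`) and `type` (one of ribozyme,
#'   spacer, scaffold, direct_repeat, enzyme_site, arm, orf).
#' @return An `annotated_record`.
#' @export
annotated_record <- function(id, sequence, features = NULL) {
  sequence <- normalize_seq(sequence, "dna", what = "record sequence")
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character(),
                           type = character(), stringsAsFactors = FALSE)
  }
  needed <- c("label", "start", "end", "strand", "type")
  if (!all(needed %in% names(features))) {
    stop("features need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  n <- nchar(sequence)
  bad <- which(features$start < 0L | features$end > n |
                 features$start >= features$end)
  if (length(bad)) {
    stop(sprintf("feature '%s' interval [%d,%d) out of bounds for %d-nt record",
                 features$label[bad[1L]], features$start[bad[1L]],
                 features$end[bad[1L]], n), call. = FALSE)
  }
  bad_type <- setdiff(unique(features$type), FEATURE_TYPES)
  if (length(bad_type)) {
    stop("unknown feature type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "annotated_record")
}

#' Write an annotated record as a GenBank flat file
#'
#' Minimal standards-conforming output: LOCUS line, FEATURES table
#' (`misc_feature` entries with `/label` and `/note="type"` qualifiers,
#' 1-based inclusive coordinates, `complement(..)` for minus-strand
#' features) and ORIGIN block. [read_genbank()] restores the record
#' exactly; files from other software are not guaranteed to parse.
#'
#' @param record An [annotated_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "annotated_record"))
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
                     record$id, n, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])  # 1-based inclusive
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     misc_feature    %s", loc), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    writeLines(sprintf("                     /note=\"%s\"", f$type[i]), con)
  }
  writeLines("ORIGIN", con)
  for (a in seq(1L, n, by = 60L)) {
    chunk <- substr(record$sequence, a, min(a + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", a, paste(tolower(blocks), collapse = " ")),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path Input path.
#' @return An [annotated_record()]; GenBank 1-based inclusive locations are
#'   converted back to 0-based half-open intervals.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  id <- sub("^LOCUS +([^ ]+).*$", "\\1", lines[grepl("^LOCUS", lines)][1L])
  feats <- list()
  i <- 1L
  while (i <= length(lines)) {
    l <- lines[i]
    if (grepl("^ {5}misc_feature", l)) {
      loc <- trimws(sub("^ {5}misc_feature +", "", l))
      strand <- if (startsWith(loc, "complement(")) "-" else "+"
      loc <- gsub("complement\\(|\\)", "", loc)
      ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
      label <- sub('^.*/label="([^"]*)".*$', "\\1", lines[i + 1L])
      type <- sub('^.*/note="([^"]*)".*$', "\\1", lines[i + 2L])
      feats[[length(feats) + 1L]] <- data.frame(
        label = label, start = ab[1L] - 1L, end = ab[2L], strand = strand,
        type = type, stringsAsFactors = FALSE)
      i <- i + 3L
      next
    }
    i <- i + 1L
  }
  origin <- which(grepl("^ORIGIN", lines))
  stop_at <- which(lines == "//")
  seq_lines <- lines[(origin + 1L):(stop_at - 1L)]
  sequence <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  annotated_record(id, sequence, features)
}

#' Convert an RGR cassette to an annotated record
#'
#' @param cassette An `rgr_cassette`.
#' @return An [annotated_record()] with ribozyme, spacer and
#'   scaffold/direct-repeat features.
#' @export
cassette_to_record <- function(cassette) {
  stopifnot(inherits(cassette, "rgr_cassette"))
  b <- cassette$boundaries
  sp_len <- nchar(cassette$spacer$sequence)
  gb <- b$guide_body
  if (cassette$spacer$cas == "spcas9") {
    spacer_iv <- c(gb[1L], gb[1L] + sp_len)
    const_iv <- c(gb[1L] + sp_len, gb[2L])
    const_type <- "scaffold"
  } else {
    const_iv <- c(gb[1L], gb[2L] - sp_len)
    spacer_iv <- c(gb[2L] - sp_len, gb[2L])
    const_type <- "direct_repeat"
  }
  features <- data.frame(
    label = c("HH_ribozyme", "spacer",
              if (const_type == "scaffold") "sgRNA_scaffold" else
                "direct_repeat", "HDV_ribozyme"),
    start = c(b$hh[1L], spacer_iv[1L], const_iv[1L], b$hdv[1L]),
    end = c(b$hh[2L], spacer_iv[2L], const_iv[2L], b$hdv[2L]),
    strand = "+",
    type = c("ribozyme", "spacer", const_type, "ribozyme"),
    stringsAsFactors = FALSE)
  features <- features[order(features$start), ]
  annotated_record(cassette$spacer$label, cassette$full_sequence, features)
}

#' A pulsed-illumination regime
#'
#' @param intensity_mW_cm2 Irradiance in mW/cm^2.
#' @param on_s,off_s Pulse ON and OFF durations in seconds
#'   (`on_s + off_s > 0`; `off_s = 0` is continuous illumination).
#' @param duration_h Total regime duration in hours.
#' @param wavelength_nm Informational; default 470 (blue).
#' @return An `illumination_regime`.
#' @export
illumination_regime <- function(intensity_mW_cm2, on_s, off_s, duration_h,
                                wavelength_nm = 470) {
  vals <- c(intensity_mW_cm2 = intensity_mW_cm2, on_s = on_s,
            duration_h = duration_h, wavelength_nm = wavelength_nm)
  if (any(!is.finite(vals)) || any(vals <= 0) ||
      !is.finite(off_s) || off_s < 0) {
    stop("illumination regime fields must be positive (off_s may be 0)",
         call. = FALSE)
  }
  structure(list(intensity_mW_cm2 = intensity_mW_cm2, on_s = on_s,
                 off_s = off_s, duration_h = duration_h,
                 wavelength_nm = wavelength_nm),
            class = "illumination_regime")
}

#' Duty cycle, on-time and fluence of an illumination regime
#'
#' `duty = on / (on + off)`; `total_on_s = duty * duration`;
#' `fluence_J_cm2 = intensity(mW/cm^2) * total_on_s / 1000`.
#'
#' @param regime An [illumination_regime()].
#' @return List with `duty_cycle` (fraction), `total_on_s` (seconds) and
#'   `fluence_J_cm2` (J/cm^2).
#' @examples
#' # 1 mW/cm^2, 20 s ON / 40 s OFF for 1 h: duty 1/3, fluence 1.2 J/cm^2
#' illumination_dose(illumination_regime(1, 20, 40, 1))
#' @export
illumination_dose <- function(regime) {
  stopifnot(inherits(regime, "illumination_regime"))
  duty <- regime$on_s / (regime$on_s + regime$off_s)
  total_on_s <- duty * regime$duration_h * 3600
  fluence <- regime$intensity_mW_cm2 * total_on_s / 1000
  list(duty_cycle = duty, total_on_s = total_on_s, fluence_J_cm2 = fluence)
}
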