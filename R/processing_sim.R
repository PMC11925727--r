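# Transcript model and ribozyme self-cleavage simulation: the in-silico
# counterpart of light-induced Pol II transcription of an (optional
# reporter ORF +) RGR array, followed by hammerhead/HDV excision of the
# guides. Cleavage chemistry is reduced to exact junction cuts: the
# hammerhead cleaves at its own 3' boundary (leaving the guide's exact 5'
# end) and HDV at its own 5' boundary (leaving the guide's exact 3' end).
# The hammerhead byproduct therefore retains the stem; the guide does not.

#' Assemble the transcript model for an RGR array
#'
#' Concatenates (optional upstream ORF) + array + (optional trailer),
#' transcribes it, and records the two cleavage sites each cassette
#' contributes: the hammerhead site at the HH/guide-body boundary and the
#' HDV site at the guide-body/HDV boundary.
#'
#' @param array A `multiplex_array` (or single `rgr_cassette`).
#' @param upstream_orf Optional DNA string 5' of the array (e.g. a reporter
#'   ORF expressed from the same transcript).
#' @param trailer Optional DNA string 3' of the array.
#' @return A `transcript_model` with fields `rna`, `cleavage_sites` (data
#'   frame with 0-based RNA position, site type and cassette label) and the
#'   input components.
#' @export
assemble_transcript <- function(array, upstream_orf = NULL, trailer = NULL) {
  if (inherits(array, "rgr_cassette")) {
    array <- structure(list(cassettes = list(array), linker = "",
                            full_sequence = array$full_sequence),
                       class = "multiplex_array")
  }
  stopifnot(inherits(array, "multiplex_array"))
  if (length(array$cassettes) == 0L) {
    stop("transcript needs a non-empty array", call. = FALSE)
  }
  upstream_orf <- if (is.null(upstream_orf)) "" else
    normalize_seq(upstream_orf, "dna", what = "upstream_orf")
  trailer <- if (is.null(trailer)) "" else
    normalize_seq(trailer, "dna", what = "trailer")

  dna <- paste0(upstream_orf, array$full_sequence, trailer)
  offset <- nchar(upstream_orf)
  sites <- list()
  for (cs in array$cassettes) {
    b <- cs$boundaries
    sites[[length(sites) + 1L]] <- data.frame(
      pos = offset + b$guide_body[[1]], type = "hh",
      label = cs$spacer$label, stringsAsFactors = FALSE)
    sites[[length(sites) + 1L]] <- data.frame(
      pos = offset + b$guide_body[[2]], type = "hdv",
      label = cs$spacer$label, stringsAsFactors = FALSE)
    offset <- offset + nchar(cs$full_sequence) + nchar(array$linker)
  }
  sites <- do.call(rbind, sites)
  stopifnot(all(diff(sites$pos) > 0L))
  structure(list(rna = transcribe(dna), dna = dna, array = array,
                 upstream_orf = upstream_orf, trailer = trailer,
                 cleavage_sites = sites),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model: %d nt RNA, %d cassette(s), %d cleavage sites\n",
              nchar(x$rna), length(x$array$cassettes),
              nrow(x$cleavage_sites)))
  invisible(x)
}

#' Simulate ribozyme self-cleavage of a transcript
#'
#' Cuts the RNA at the selected cleavage sites and labels the resulting
#' fragments. With complete cleavage every site is cut, yielding `2n + 1`
#' fragments for `n` cassettes; a fragment is a released `guide` exactly
#' when it spans one cassette's HH-site-to-HDV-site interval. Partial
#' processing is modeled combinatorially via per-site flags, not
#' kinetically.
#'
#' @param transcript A `transcript_model`.
#' @param efficiency `"complete"` (cut every site) or a logical vector of
#'   per-site flags, one per row of `transcript$cleavage_sites` in order.
#' @return A `cleavage_products` data frame with columns `sequence` (RNA),
#'   `role` (`upstream_byproduct`, `guide`, `inter_byproduct`,
#'   `downstream_byproduct`), `source_label` (cassette label for guides,
#'   `"-"` otherwise), `start` and `end` (0-based on the transcript).
#' @export
simulate_cleavage <- function(transcript, efficiency = "complete") {
  stopifnot(inherits(transcript, "transcript_model"))
  sites <- transcript$cleavage_sites
  if (identical(efficiency, "complete")) {
    flags <- rep(TRUE, nrow(sites))
  } else {
    flags <- as.logical(efficiency)
    if (length(flags) != nrow(sites) || anyNA(flags)) {
      stop(sprintf("efficiency flags must be 'complete' or %d logicals",
                   nrow(sites)), call. = FALSE)
    }
  }
  n <- nchar(transcript$rna)
  cuts <- sites$pos[flags]
  bounds <- unique(c(0L, cuts, n))

  # guide intervals: [hh site, hdv site) per cassette, cut on both sides
  hh <- sites[sites$type == "hh", ]
  hdv <- sites[sites$type == "hdv", ]
  guide_iv <- data.frame(start = hh$pos, end = hdv$pos, label = hh$label)

  out <- list()
  nfrag <- length(bounds) - 1L
  for (i in seq_len(nfrag)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    gi <- which(guide_iv$start == a & guide_iv$end == b)
    if (length(gi) == 1L) {
      role <- "guide"; lab <- guide_iv$label[gi]
    } else {
      role <- if (i == 1L) "upstream_byproduct"
        else if (i == nfrag) "downstream_byproduct"
        else "inter_byproduct"
      lab <- "-"
    }
    out[[i]] <- data.frame(
      sequence = substr(transcript$rna, a + 1L, b),
      role = role, source_label = lab, start = a, end = b,
      stringsAsFactors = FALSE)
  }
  products <- do.call(rbind, out)
  class(products) <- c("cleavage_products", class(products))
  products
}

#' Extract released guides from cleavage products
#'
#' @param products Output of [simulate_cleavage()].
#' @return Data frame `label`, `rna` with the guide-role fragments in
#'   transcript order. For complete cleavage of an array built from spacers
#'   s1..sn, guide i equals `transcribe(guide_body(si))`.
#' @export
released_guides <- function(products) {
  stopifnot(inherits(products, "cleavage_products"))
  g <- products[products$role == "guide", , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  data.frame(label = g$source_label, rna = g$sequence,
             stringsAsFactors = FALSE)
}

#' Write cleavage products to FASTA
#'
#' One record per fragment; the description line carries role and source
#' cassette label.
#'
#' @param products Output of [simulate_cleavage()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
products_to_fasta <- function(products, path) {
  stopifnot(inherits(products, "cleavage_products"))
  set <- Biostrings::RNAStringSet(products$sequence)
  names(set) <- sprintf("fragment_%02d role=%s label=%s",
                        seq_len(nrow(products)), products$role,
                        products$source_label)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
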