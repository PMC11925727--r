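# Synthetic fixture generation: random spacers, destination vectors with
# type IIS dropout cassettes, and a promoter with planted PAMs at known
# window positions. Everything is generated programmatically (rejection
# sampling where a sequence must be free of enzyme sites), deterministic
# for a given seed.

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

# random DNA free of every registered enzyme's recognition site
random_domesticated <- function(n, enzymes, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (nrow(domesticate_check(s, enzymes)) == 0L) return(s)
  }
  stop("could not sample an enzyme-site-free sequence of length ", n,
       call. = FALSE)
}

# random DNA with suppressed PAM background: no GG, CC, TTT or AAA runs,
# so NGG and TTTV PAMs occur only where planted
random_pam_poor <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    excl <- character()
    if (i > 1L) {
      prev <- out[i - 1L]
      if (prev == "G") excl <- c(excl, "G")
      if (prev == "C") excl <- c(excl, "C")
    }
    if (i > 2L) {
      if (out[i - 1L] == "T" && out[i - 2L] == "T") excl <- c(excl, "T")
      if (out[i - 1L] == "A" && out[i - 2L] == "A") excl <- c(excl, "A")
    }
    out[i] <- sample(setdiff(DNA_ALPHABET, excl), 1L)
  }
  paste(out, collapse = "")
}

splice_in <- function(seq, at, insert) {
  # overwrite seq at 0-based position `at` with `insert`
  paste0(substr(seq, 1L, at), insert,
         substring(seq, at + nchar(insert) + 1L))
}

# circular destination vector: backbone + [o5 window | gap | site> dropout
# <site | gap | o3 window], sites pointing outward so digestion leaves the
# backbone with the directional overhang pair
make_dropout_vector <- function(vector_len, enzyme, overhangs, all_enzymes,
                                id, max_tries = 50L) {
  off_top <- enzyme$cut_offset_top
  fixed_len <- 2L * enzyme$overhang_len + 2L * off_top +
    2L * nchar(enzyme$recognition)
  core_len <- 60L
  backbone_len <- vector_len - fixed_len - core_len
  if (backbone_len < 100L) {
    stop(sprintf("vector_len %d too short for a %d-nt dropout cassette",
                 vector_len, fixed_len + core_len), call. = FALSE)
  }
  filler <- strrep("A", off_top)
  for (i in seq_len(max_tries)) {
    backbone <- random_domesticated(backbone_len, all_enzymes)
    core <- random_domesticated(core_len, all_enzymes)
    top <- paste0(backbone,
                  overhangs[[1]], filler,
                  reverse_complement(enzyme$recognition),
                  core,
                  enzyme$recognition, filler,
                  overhangs[[2]])
    # junctions must not create extra sites anywhere on the circle
    if (count_sites(top, enzyme, circular = TRUE) == 2L) {
      return(ds_fragment(top, topology = "circular", id = id))
    }
  }
  stop("could not construct a clean dropout vector", call. = FALSE)
}

#' Generate a reproducible synthetic fixture bundle
#'
#' Produces random spacers for both Cas systems (rejection-sampled free of
#' registered enzyme sites), synthetic circular destination vectors with an
#' outward-facing SapI dropout and a BbsI variant (digestion leaves the
#' backbone carrying the registry's directional overhang pairs), and a
#' 1 kb promoter with PAM-poor background and one planted SpCas9 (AGG) and
#' one planted LbCas12a (TTTA) protospacer at known positions inside the
#' 75-300 bp window upstream of the declared TSS.
#'
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param n_spacers Number of spacers (alternating Cas systems).
#' @param vector_len Total length of each destination vector.
#' @param promoter_len Promoter length (default 1000; TSS at
#'   `promoter_len - 50`).
#' @param registry A `part_registry`.
#' @return A `fixture_bundle` list: `spacers`, `vector_sapi`,
#'   `vector_bbsi`, `promoter` (list with `sequence`, `tss` and a `planted`
#'   data frame of the expected candidate hits).
#' @export
generate_fixtures <- function(seed, n_spacers = 4L, vector_len = 2500L,
                              promoter_len = 1000L,
                              registry = default_registry()) {
  set.seed(as.integer(seed))
  enzymes <- registry$enzymes

  cas_cycle <- rep(c("spcas9", "lbcas12a"), length.out = n_spacers)
  spacers <- lapply(seq_len(n_spacers), function(i) {
    len <- DEFAULT_SPACER_LEN[[cas_cycle[i]]]
    spacer(random_domesticated(len, enzymes), cas_cycle[i],
           label = sprintf("sp%02d_%s", i, cas_cycle[i]))
  })

  vector_sapi <- make_dropout_vector(
    vector_len, get_enzyme(registry, "SapI"),
    registry$overhang_sets[["sapi_pair"]]$overhangs, enzymes, "vector_sapi")
  vector_bbsi <- make_dropout_vector(
    vector_len, get_enzyme(registry, "BbsI"),
    registry$overhang_sets[["bbsi_pair"]]$overhangs, enzymes, "vector_bbsi")

  tss <- promoter_len - 50L
  background <- random_pam_poor(promoter_len)
  # SpCas9 plant: 20-nt protospacer with proximal end 100 bp upstream,
  # AGG PAM immediately 3'
  b9 <- tss - 100L + 1L
  a9 <- b9 - 20L
  plant9 <- paste0(random_pam_poor(20L), "AGG")
  promoter <- splice_in(background, a9, plant9)
  # LbCas12a plant: TTTA PAM immediately 5' of a 23-nt protospacer whose
  # distal end sits 250 bp upstream
  a12 <- tss - 250L
  plant12 <- paste0("TTTA", random_pam_poor(23L))
  promoter <- splice_in(promoter, a12 - 4L, plant12)
  planted <- data.frame(
    cas = c("spcas9", "lbcas12a"),
    start = c(a9, a12),
    end = c(b9, a12 + 23L),
    strand = "+",
    pam = c("AGG", "TTTA"),
    stringsAsFactors = FALSE)

  structure(list(spacers = spacers, vector_sapi = vector_sapi,
                 vector_bbsi = vector_bbsi,
                 promoter = list(sequence = promoter, tss = tss,
                                 planted = planted),
                 seed = as.integer(seed)),
            class = "fixture_bundle")
}

#' Write a fixture bundle to a directory
#'
#' Writes `spacers.tsv` (label/sequence/cas), `vector_sapi.fasta`,
#' `vector_bbsi.fasta` and `promoter.fasta` (TSS recorded in the
#' description line).
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- bundle$spacers
  utils::write.table(
    data.frame(label = vapply(sp, `[[`, character(1), "label"),
               sequence = vapply(sp, `[[`, character(1), "sequence"),
               cas = vapply(sp, `[[`, character(1), "cas")),
    file.path(dir, "spacers.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_fasta(data.frame(id = "vector_sapi", description = "topology=circular",
                         sequence = bundle$vector_sapi$seq),
              file.path(dir, "vector_sapi.fasta"))
  write_fasta(data.frame(id = "vector_bbsi", description = "topology=circular",
                         sequence = bundle$vector_bbsi$seq),
              file.path(dir, "vector_bbsi.fasta"))
  write_fasta(data.frame(id = "promoter",
                         description = sprintf("tss=%d", bundle$promoter$tss),
                         sequence = bundle$promoter$sequence),
              file.path(dir, "promoter.fasta"))
  invisible(dir)
}
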