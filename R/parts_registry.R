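# Part registry: the biologically fixed-but-configurable sequences and
# enzyme definitions the designer composes. Parts are configuration data,
# not code constants: the shipped defaults are the minimal hammerhead and
# genomic HDV ribozyme of the RGR literature plus the canonical SpCas9
# sgRNA scaffold and LbCas12a direct repeat. Replace them (via a YAML
# registry file) with your construct's exact part sequences for bit-exact
# output against a particular vector system.

PART_ROLES <- c("hh_template", "hdv", "cas9_scaffold",
                "cas12a_direct_repeat", "vector_arm")
REQUIRED_ROLES <- c("hh_template", "hdv", "cas9_scaffold",
                    "cas12a_direct_repeat")
STEM_PLACEHOLDER <- "NNNNNN"

default_registry_data <- function() {
  list(
    parts = list(
      list(name = "hh_minimal", role = "hh_template",
           # 6-nt placeholder stem + minimal hammerhead catalytic core
           sequence = "NNNNNNCTGATGAGTCCGTGAGGACGAAACGAGTAAGCTCGTC"),
      list(name = "hdv_genomic", role = "hdv",
           sequence = paste0("GGCCGGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGG",
                             "CAACATGCTTCGGCATGGCGAATGGGAC")),
      list(name = "sp_sgrna_scaffold", role = "cas9_scaffold",
           sequence = paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCG",
                             "TTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC")),
      list(name = "lb_direct_repeat", role = "cas12a_direct_repeat",
           sequence = "TAATTTCTACTAAGTGTAGAT")
    ),
    enzymes = list(
      list(name = "SapI", recognition = "GCTCTTC",
           cut_offset_top = 1L, cut_offset_bottom = 4L),
      # LguI is an isoschizomer of SapI
      list(name = "LguI", recognition = "GCTCTTC",
           cut_offset_top = 1L, cut_offset_bottom = 4L),
      list(name = "BbsI", recognition = "GAAGAC",
           cut_offset_top = 2L, cut_offset_bottom = 6L)
    ),
    overhang_sets = list(
      list(name = "sapi_pair", overhangs = c("AAT", "GCA")),
      list(name = "bbsi_pair", overhangs = c("AATG", "GCAA"))
    )
  )
}

new_part <- function(name, role, sequence) {
  if (!is.character(name) || !nzchar(name)) {
    stop("part name must be a non-empty string", call. = FALSE)
  }
  if (!role %in% PART_ROLES) {
    stop(sprintf("part '%s': unknown role '%s' (expected one of %s)",
                 name, role, paste(PART_ROLES, collapse = ", ")),
         call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (role == "hh_template") {
    if (!startsWith(sequence, STEM_PLACEHOLDER)) {
      stop(sprintf("part '%s': hh_template placeholder missing (sequence %s",
                   name, "must begin with 'NNNNNN')"), call. = FALSE)
    }
    body <- substring(sequence, 7L)
    normalize_seq(body, "dna", what = sprintf("part '%s' body", name))
    if (grepl("N", body, fixed = TRUE)) {
      stop(sprintf("part '%s': placeholder characters outside the 6-nt stem",
                   name), call. = FALSE)
    }
  } else {
    normalize_seq(sequence, "dna", what = sprintf("part '%s'", name))
  }
  structure(list(name = name, role = role, sequence = sequence),
            class = "rgr_part")
}

new_enzyme <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- validate_motif(recognition)
  cut_offset_top <- as.integer(cut_offset_top)
  cut_offset_bottom <- as.integer(cut_offset_bottom)
  if (is.na(cut_offset_top) || is.na(cut_offset_bottom) ||
      cut_offset_top < 0L) {
    stop(sprintf("enzyme '%s': cut offsets must be non-negative integers",
                 name), call. = FALSE)
  }
  overhang_len <- cut_offset_bottom - cut_offset_top
  if (overhang_len <= 0L) {
    stop(sprintf(paste0(
      "enzyme '%s': cut_offset_bottom must exceed cut_offset_top ",
      "(only 5'-overhang type IIS enzymes are supported)"), name),
      call. = FALSE)
  }
  if (identical(toupper(recognition), iupac_reverse_complement(recognition))) {
    stop(sprintf(paste0(
      "enzyme '%s': recognition site is palindromic; a type IIS enzyme ",
      "must recognize an asymmetric site"), name), call. = FALSE)
  }
  structure(list(name = name, recognition = toupper(recognition),
                 cut_offset_top = cut_offset_top,
                 cut_offset_bottom = cut_offset_bottom,
                 overhang_len = overhang_len),
            class = "rgr_enzyme")
}

new_overhang_set <- function(name, overhangs) {
  overhangs <- toupper(overhangs)
  for (o in overhangs) normalize_seq(o, "dna", what = sprintf(
    "overhang '%s' in set '%s'", o, name))
  if (anyDuplicated(overhangs)) {
    stop(sprintf("overhang set '%s': overhangs not distinct", name),
         call. = FALSE)
  }
  selfc <- vapply(overhangs, function(o) identical(o, reverse_complement(o)),
                  logical(1))
  if (any(selfc)) {
    stop(sprintf(
      "overhang set '%s': overhang '%s' is self-complementary and cannot %s",
      name, overhangs[which(selfc)[1L]], "enforce directional insertion"),
      call. = FALSE)
  }
  structure(list(name = name, overhangs = overhangs),
            class = "rgr_overhang_set")
}

build_registry <- function(data) {
  parts <- list()
  for (p in data$parts) {
    part <- new_part(p$name, p$role, p$sequence)
    parts[[part$name]] <- part
  }
  enzymes <- list()
  for (e in data$enzymes) {
    enz <- new_enzyme(e$name, e$recognition,
                      e$cut_offset_top, e$cut_offset_bottom)
    enzymes[[enz$name]] <- enz
  }
  sets <- list()
  for (s in data$overhang_sets) {
    os <- new_overhang_set(s$name, s$overhangs)
    sets[[os$name]] <- os
  }
  reg <- structure(list(parts = parts, enzymes = enzymes,
                        overhang_sets = sets),
                   class = "part_registry")
  roles <- vapply(reg$parts, `[[`, character(1), "role")
  missing <- setdiff(REQUIRED_ROLES, roles)
  if (length(missing)) {
    stop("registry is missing parts for role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reg
}

#' The bundled default part registry
#'
#' Minimal hammerhead ribozyme template (6-nt `NNNNNN` stem placeholder +
#' catalytic core), genomic HDV ribozyme, canonical SpCas9 sgRNA scaffold,
#' LbCas12a direct repeat, SapI/LguI and BbsI enzyme definitions, and two
#' directional overhang pairs. These are documented stand-in defaults for
#' the parts any particular RGR vector system fixes; override them with
#' [load_registry()] for bit-exact output against your own vectors.
#'
#' @return A `part_registry` object.
#' @export
default_registry <- function() {
  build_registry(default_registry_data())
}

#' Load a part registry from a YAML file
#'
#' The file holds three optional top-level keys -- `parts`, `enzymes`,
#' `overhang_sets` -- each a list of records (see the bundled example at
#' `system.file("extdata", "default_registry.yaml", package = "rgrtools")`).
#' User entries are merged over the bundled defaults: an entry with the same
#' name replaces the default, new names are added. Every registry invariant
#' is checked at load time; violations raise an error naming the offending
#' part or enzyme and the rule.
#'
#' @param path Path to a YAML registry file, or `NULL` for the defaults.
#' @param merge_defaults Merge user entries over the bundled defaults
#'   (default `TRUE`); if `FALSE` the file must be self-contained.
#' @return A validated `part_registry`.
#' @export
load_registry <- function(path = NULL, merge_defaults = TRUE) {
  if (is.null(path)) return(default_registry())
  if (!file.exists(path)) stop("registry file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user) || length(user) == 0L) {
    stop("registry file is empty: ", path, call. = FALSE)
  }
  bad <- setdiff(names(user), c("parts", "enzymes", "overhang_sets"))
  if (length(bad)) {
    stop("unknown registry section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data <- if (merge_defaults) default_registry_data() else
    list(parts = list(), enzymes = list(), overhang_sets = list())
  for (section in c("parts", "enzymes", "overhang_sets")) {
    for (rec in user[[section]]) {
      if (is.null(rec$name)) {
        stop("registry record in '", section, "' lacks a name", call. = FALSE)
      }
      existing <- vapply(data[[section]], `[[`, character(1), "name")
      i <- match(rec$name, existing)
      if (is.na(i)) {
        data[[section]] <- c(data[[section]], list(rec))
      } else {
        data[[section]][[i]] <- utils::modifyList(data[[section]][[i]], rec)
      }
    }
  }
  build_registry(data)
}

#' Save a registry to a YAML file
#'
#' Writes the registry in the same schema [load_registry()] reads, so a
#' save/load round trip preserves the logical content.
#'
#' @param registry A `part_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  stopifnot(inherits(registry, "part_registry"))
  data <- list(
    parts = lapply(unname(registry$parts), function(p)
      list(name = p$name, role = p$role, sequence = p$sequence)),
    enzymes = lapply(unname(registry$enzymes), function(e)
      list(name = e$name, recognition = e$recognition,
           cut_offset_top = e$cut_offset_top,
           cut_offset_bottom = e$cut_offset_bottom)),
    overhang_sets = lapply(unname(registry$overhang_sets), function(s)
      list(name = s$name, overhangs = as.list(s$overhangs)))
  )
  yaml::write_yaml(data, path)
  invisible(path)
}

#' Fetch a part by role (and optionally name)
#'
#' @param registry A `part_registry`.
#' @param role One of `hh_template`, `hdv`, `cas9_scaffold`,
#'   `cas12a_direct_repeat`, `vector_arm`.
#' @param name Optional part name; required when several parts share the role.
#' @return An `rgr_part`.
#' @export
get_part <- function(registry, role, name = NULL) {
  stopifnot(inherits(registry, "part_registry"))
  if (!role %in% PART_ROLES) {
    stop("unknown part role: ", role, call. = FALSE)
  }
  candidates <- Filter(function(p) p$role == role, registry$parts)
  if (!is.null(name)) {
    hit <- candidates[[name]]
    if (is.null(hit)) {
      stop(sprintf("no part named '%s' with role '%s'", name, role),
           call. = FALSE)
    }
    return(hit)
  }
  if (length(candidates) == 0L) {
    stop("no part registered for role: ", role, call. = FALSE)
  }
  if (length(candidates) > 1L) {
    stop(sprintf(
      "role '%s' has %d parts (%s); pass `name` to disambiguate",
      role, length(candidates),
      paste(names(candidates), collapse = ", ")), call. = FALSE)
  }
  candidates[[1L]]
}

#' Fetch an enzyme definition by name
#' @param registry A `part_registry`.
#' @param name Enzyme name (e.g. `"SapI"`, `"BbsI"`).
#' @return An `rgr_enzyme`.
#' @export
get_enzyme <- function(registry, name) {
  stopifnot(inherits(registry, "part_registry"))
  enz <- registry$enzymes[[name]]
  if (is.null(enz)) stop("no enzyme named '", name, "' in registry",
                         call. = FALSE)
  enz
}

#' Validate a registry and report violations
#'
#' Re-checks every structural invariant and additionally cross-checks
#' domestication of the parts themselves: no part other than a vector arm
#' may contain any registered enzyme's recognition site (on either strand),
#' since such a site would fragment the part during Golden Gate assembly.
#' The `NNNNNN` stem placeholder of the hammerhead template is excluded
#' from the scan.
#'
#' @param registry A `part_registry`.
#' @return A data frame of violations with columns `scope`, `name`, `rule`
#'   and `detail`; zero rows means the registry is valid.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "part_registry"))
  v <- list()
  add <- function(scope, name, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(
      scope = scope, name = name, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }
  roles <- vapply(registry$parts, `[[`, character(1), "role")
  for (r in REQUIRED_ROLES) {
    if (!r %in% roles) add("registry", r, "role_missing",
                           sprintf("no part with role '%s'", r))
  }
  for (p in registry$parts) {
    if (p$role == "hh_template" && !startsWith(p$sequence, STEM_PLACEHOLDER))
      add("part", p$name, "placeholder_missing",
          "hh_template must begin with 'NNNNNN'")
    scan_seq <- if (p$role == "hh_template")
      substring(p$sequence, 7L) else p$sequence
    if (p$role != "vector_arm") {
      # isoschizomers share a recognition site; one violation per site
      hits <- domesticate_check(scan_seq, registry$enzymes)
      for (i in seq_len(nrow(hits))) {
        add("part", p$name, "internal_enzyme_site",
            sprintf("%s site at [%d,%d) strand %s", hits$enzyme[i],
                    hits$start[i], hits$end[i], hits$strand[i]))
      }
    }
  }
  for (s in registry$overhang_sets) {
    if (anyDuplicated(s$overhangs))
      add("overhang_set", s$name, "overhangs_not_distinct",
          paste(s$overhangs, collapse = ","))
    for (o in s$overhangs) {
      if (identical(o, reverse_complement(o)))
        add("overhang_set", s$name, "self_complementary_overhang", o)
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(scope = character(), name = character(),
               rule = character(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Export registry parts to FASTA
#'
#' One record per part; the description carries the role.
#'
#' @param registry A `part_registry`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
registry_to_fasta <- function(registry, path) {
  stopifnot(inherits(registry, "part_registry"))
  ids <- vapply(registry$parts, `[[`, character(1), "name")
  seqs <- vapply(registry$parts, `[[`, character(1), "sequence")
  roles <- vapply(registry$parts, `[[`, character(1), "role")
  # the placeholder is not DNA; exported verbatim as IUPAC N's
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- paste(ids, paste0("role=", roles))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.part_registry <- function(x, ...) {
  cat("part_registry:", length(x$parts), "parts,",
      length(x$enzymes), "enzymes,",
      length(x$overhang_sets), "overhang sets\n")
  for (p in x$parts) {
    cat(sprintf("  part %-22s %-22s %4d nt\n", p$name, p$role,
                nchar(p$sequence)))
  }
  for (e in x$enzymes) {
    cat(sprintf("  enzyme %-8s %s cut %d/%d (%d-nt 5' overhang)\n",
                e$name, e$recognition, e$cut_offset_top,
                e$cut_offset_bottom, e$overhang_len))
  }
  invisible(x)
}
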