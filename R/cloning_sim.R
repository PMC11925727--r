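# In-silico type IIS digestion and sticky-end ligation (Golden Gate).
#
# Double-stranded fragments use a span representation: `seq` is the
# plus-strand sequence of the full span covered by either strand;
# `left_len` bases at the left end are single-stranded on the TOP strand
# (a 5' overhang, since type IIS enzymes modeled here leave 5' extensions)
# and `right_len` bases at the right end are single-stranded on the BOTTOM
# strand (also a 5' overhang; its bases appear in `seq` as the plus-strand
# window of the cut). Two fragments produced by one cut therefore both
# carry the cut window in their spans -- one keeps the top strand of the
# window, the other the bottom. Blunt ends have length-0 overhangs;
# circular fragments have none.

#' Construct a double-stranded DNA fragment
#'
#' @param seq Plus-strand sequence of the full span (5'->3').
#' @param left_len,right_len Lengths of the 5' single-stranded overhangs at
#'   the left (top strand) and right (bottom strand) ends; 0 = blunt.
#' @param topology `"linear"` or `"circular"`; circular fragments must be
#'   blunt-ended (they have no ends).
#' @param id Optional identifier used in assembly diagnostics.
#' @return A `ds_fragment`.
#' @export
ds_fragment <- function(seq, left_len = 0L, right_len = 0L,
                        topology = c("linear", "circular"), id = NULL) {
  topology <- match.arg(topology)
  seq <- normalize_seq(seq, "dna", what = "fragment sequence")
  left_len <- as.integer(left_len); right_len <- as.integer(right_len)
  if (left_len < 0L || right_len < 0L ||
      left_len + right_len > nchar(seq)) {
    stop("overhang lengths out of range for fragment", call. = FALSE)
  }
  if (topology == "circular" && (left_len > 0L || right_len > 0L)) {
    stop("circular fragments cannot carry overhangs", call. = FALSE)
  }
  structure(list(seq = seq, left_len = left_len, right_len = right_len,
                 topology = topology, id = id),
            class = "ds_fragment")
}

#' @export
print.ds_fragment <- function(x, ...) {
  cat(sprintf("ds_fragment%s: %d nt, %s, overhangs %s/%s\n",
              if (!is.null(x$id)) paste0(" '", x$id, "'") else "",
              nchar(x$seq), x$topology,
              if (x$left_len) fragment_overhangs(x)$left else "blunt",
              if (x$right_len) fragment_overhangs(x)$right else "blunt"))
  invisible(x)
}

#' Overhang sequences of a fragment
#'
#' Both overhangs are reported as the plus-strand sequence of the overhang
#' window (5'->3' on the top strand); the right overhang's physical
#' single strand is the bottom-strand reverse complement of the reported
#' window.
#'
#' @param frag A `ds_fragment`.
#' @return List with `left` and `right` window sequences (`""` if blunt).
#' @export
fragment_overhangs <- function(frag) {
  stopifnot(inherits(frag, "ds_fragment"))
  n <- nchar(frag$seq)
  list(left = substr(frag$seq, 1L, frag$left_len),
       right = substr(frag$seq, n - frag$right_len + 1L, n))
}

# substring of a circular sequence, 0-based [a, b), b may exceed length
circ_sub <- function(x, a, b) {
  n <- nchar(x)
  a_mod <- a %% n
  substr(paste0(x, x), a_mod + 1L, a_mod + (b - a))
}

# all cut pairs (pt, pb) implied by an enzyme on a plus-strand sequence;
# for circular sequences the scan covers origin-spanning sites
enzyme_cuts <- function(seq, enzyme, circular = FALSE) {
  scan_seq <- if (circular) paste0(seq, seq) else seq
  hits <- find_sites(scan_seq, enzyme$recognition, "both")
  if (circular) hits <- hits[hits$start < nchar(seq), , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(pt = integer(), pb = integer(), site_start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  pt <- ifelse(hits$strand == "+",
               hits$end + enzyme$cut_offset_top,
               hits$start - enzyme$cut_offset_bottom)
  pb <- ifelse(hits$strand == "+",
               hits$end + enzyme$cut_offset_bottom,
               hits$start - enzyme$cut_offset_top)
  data.frame(pt = as.integer(pt), pb = as.integer(pb),
             site_start = hits$start, strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Digest a fragment with a type IIS enzyme
#'
#' Cuts at every recognition site on both strands, using the enzyme's
#' top/bottom cut offsets downstream of the site in the site's own
#' orientation. A linear fragment with k internal cuts yields k + 1
#' fragments; a circular one with k cuts yields k linear fragments.
#' Fragments are returned 5'->3' in plus-strand order of their spans.
#'
#' @param frag A `ds_fragment`.
#' @param enzyme An `rgr_enzyme`.
#' @return List of `ds_fragment`s (the input, unchanged, if no sites).
#' @export
digest <- function(frag, enzyme) {
  stopifnot(inherits(frag, "ds_fragment"), inherits(enzyme, "rgr_enzyme"))
  n <- nchar(frag$seq)
  circular <- frag$topology == "circular"
  cuts <- enzyme_cuts(frag$seq, enzyme, circular = circular)
  if (!nrow(cuts)) return(list(frag))

  mk_id <- function(i) {
    if (is.null(frag$id)) sprintf("fragment_%d", i) else
      sprintf("%s.%d", frag$id, i)
  }

  if (!circular) {
    bad <- which(cuts$pt < 0L | cuts$pb > n)
    if (length(bad)) {
      stop(sprintf(
        "%s site at plus-strand position %d cuts outside the fragment",
        enzyme$name, cuts$site_start[bad[1L]]), call. = FALSE)
    }
    cuts <- cuts[order(cuts$pt), , drop = FALSE]
    # fragment ends behave like pre-existing cuts
    pts <- c(0L, cuts$pt, n - frag$right_len)
    pbs <- c(frag$left_len, cuts$pb, n)
    out <- vector("list", length(pts) - 1L)
    for (i in seq_along(out)) {
      out[[i]] <- ds_fragment(
        substr(frag$seq, pts[i] + 1L, pbs[i + 1L]),
        left_len = pbs[i] - pts[i],
        right_len = pbs[i + 1L] - pts[i + 1L],
        topology = "linear", id = mk_id(i))
    }
    return(out)
  }

  # circular: k cuts -> k fragments, cyclically paired
  cuts$pt_mod <- cuts$pt %% n
  cuts$pb_mod <- cuts$pt_mod + (cuts$pb - cuts$pt)
  cuts <- cuts[order(cuts$pt_mod), , drop = FALSE]
  k <- nrow(cuts)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    a <- cuts$pt_mod[i]
    b <- cuts$pb_mod[j] + if (j <= i) n else 0L
    out[[i]] <- ds_fragment(
      circ_sub(frag$seq, a, b),
      left_len = cuts$pb_mod[i] - cuts$pt_mod[i],
      right_len = cuts$pb_mod[j] - cuts$pt_mod[j],
      topology = "linear", id = mk_id(i))
  }
  out
}

# reverse-complement a fragment (swap strands and ends)
flip_fragment <- function(frag) {
  ds_fragment(reverse_complement(frag$seq),
              left_len = frag$right_len, right_len = frag$left_len,
              topology = frag$topology,
              id = if (is.null(frag$id)) NULL else paste0(frag$id, "'"))
}

# can X's right end ligate to Y's left end? (5' overhangs anneal when the
# two fragments share the plus-strand cut window)
ends_join <- function(x, y) {
  k <- x$right_len
  k > 0L && k == y$left_len &&
    identical(fragment_overhangs(x)$right, fragment_overhangs(y)$left)
}

canonical_circle <- function(seq) {
  rotations <- function(s) {
    n <- nchar(s)
    d <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
  }
  min(c(rotations(seq), rotations(reverse_complement(seq))))
}

#' Ligate fragments into circular constructs
#'
#' Joins ends whose 5' overhangs are Watson-Crick complementary (blunt ends
#' never ligate; near-cognate mismatch ligation is not modeled) and
#' exhaustively explores the junction graph, each physical fragment used at
#' most once per construct and in either orientation. All distinct circular
#' closures are returned; identity is the lexicographically smallest
#' rotation over both strands, so a circle and its mirror traversal count
#' once.
#'
#' @param fragments List of linear `ds_fragment`s (circular inputs are
#'   passed through to `leftovers`).
#' @param max_states Search-state cap guarding against pathological
#'   overhang sets (default 10000); exceeding it is an error.
#' @return An `assembly_result`: `constructs` (list of circular
#'   `ds_fragment`s, deterministic order), `diagnostics` (per-junction data
#'   frame) and `leftovers` (fragments in no construct).
#' @export
ligate <- function(fragments, max_states = 10000L) {
  if (inherits(fragments, "ds_fragment")) fragments <- list(fragments)
  if (length(fragments) == 0L) {
    stop("ligate() needs at least one fragment", call. = FALSE)
  }
  for (f in fragments) stopifnot(inherits(f, "ds_fragment"))
  ids <- vapply(seq_along(fragments), function(i) {
    if (is.null(fragments[[i]]$id)) sprintf("fragment_%d", i) else
      fragments[[i]]$id
  }, character(1))
  linear <- vapply(fragments, function(f) f$topology == "linear", logical(1))

  # oriented views: [[i]][[orient]] with orient 1 = "+", 2 = "-"
  oriented <- lapply(fragments, function(f) list(f, flip_fragment(f)))
  states <- 0L
  found <- list()

  close_chain <- function(chain) {
    # chain: data.frame(idx, orient); build circle sequence + diagnostics
    frs <- lapply(seq_len(nrow(chain)), function(i)
      oriented[[chain$idx[i]]][[chain$orient[i]]])
    segs <- vapply(seq_along(frs), function(i) {
      f <- frs[[i]]
      substring(f$seq, f$left_len + 1L)  # drop window shared with previous
    }, character(1))
    first <- frs[[1L]]
    total <- paste0(substr(first$seq, 1L, first$left_len),
                    paste(segs, collapse = ""))
    k <- first$left_len  # closing window counted twice
    circ <- substr(total, 1L, nchar(total) - k)
    junctions <- do.call(rbind, lapply(seq_along(frs), function(i) {
      j <- if (i == length(frs)) 1L else i + 1L
      data.frame(
        from_id = ids[chain$idx[i]],
        from_orient = c("+", "-")[chain$orient[i]],
        to_id = ids[chain$idx[j]],
        to_orient = c("+", "-")[chain$orient[j]],
        overhang = fragment_overhangs(frs[[i]])$right,
        stringsAsFactors = FALSE)
    }))
    list(circ = circ, canonical = canonical_circle(circ),
         members = chain$idx, junctions = junctions)
  }

  extend <- function(chain, used) {
    states <<- states + 1L
    if (states > max_states) {
      stop(sprintf(
        "ligation junction-graph exploration exceeded %d states; %s",
        max_states, "the overhang set is pathological"), call. = FALSE)
    }
    last <- oriented[[chain$idx[nrow(chain)]]][[chain$orient[nrow(chain)]]]
    first <- oriented[[chain$idx[1L]]][[chain$orient[1L]]]
    if (ends_join(last, first)) {
      found[[length(found) + 1L]] <<- close_chain(chain)
    }
    start_idx <- chain$idx[1L]
    for (i in which(linear)) {
      if (i <= start_idx || used[i]) next  # min-index start canonicalizes
      for (o in 1:2) {
        cand <- oriented[[i]][[o]]
        if (ends_join(last, cand)) {
          used[i] <- TRUE
          extend(rbind(chain, data.frame(idx = i, orient = o)), used)
          used[i] <- FALSE
        }
      }
    }
  }

  for (s in which(linear)) {
    used <- logical(length(fragments)); used[s] <- TRUE
    extend(data.frame(idx = s, orient = 1L), used)
  }

  # de-duplicate by canonical sequence, deterministic order
  if (length(found)) {
    canon <- vapply(found, `[[`, character(1), "canonical")
    keep <- !duplicated(canon)
    found <- found[keep][order(canon[keep])]
  }
  constructs <- lapply(seq_along(found), function(i)
    ds_fragment(found[[i]]$canonical, topology = "circular",
                id = sprintf("construct_%d", i)))
  diagnostics <- if (length(found)) {
    do.call(rbind, lapply(seq_along(found), function(i) {
      d <- found[[i]]$junctions
      cbind(construct = sprintf("construct_%d", i), d)
    }))
  } else {
    data.frame(construct = character(), from_id = character(),
               from_orient = character(), to_id = character(),
               to_orient = character(), overhang = character(),
               stringsAsFactors = FALSE)
  }
  used_idx <- sort(unique(unlist(lapply(found, `[[`, "members"))))
  leftovers <- fragments[setdiff(seq_along(fragments), used_idx)]
  structure(list(constructs = constructs, diagnostics = diagnostics,
                 leftovers = leftovers),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result: %d construct(s), %d leftover fragment(s)\n",
              length(x$constructs), length(x$leftovers)))
  for (con in x$constructs) {
    cat(sprintf("  %s: circular, %d nt\n", con$id, nchar(con$seq)))
  }
  invisible(x)
}

# recognition-site count on a circular (or linear) plus strand, both strands
count_sites <- function(seq, enzyme, circular = FALSE) {
  scan_seq <- if (circular) paste0(seq, seq) else seq
  hits <- find_sites(scan_seq, enzyme$recognition, "both")
  if (circular) hits <- hits[hits$start < nchar(seq), , drop = FALSE]
  nrow(hits)
}

#' One-pot Golden Gate assembly
#'
#' Digests the destination vector and every insert with the enzyme, ligates
#' the pooled fragments, and keeps only circular constructs free of the
#' enzyme's recognition site -- the fixed point of the iterative cut-ligate
#' reaction, since any religation that recreates a site is re-cut. With a
#' correctly designed insert/vector pair exactly one construct survives.
#'
#' @param vector A circular `ds_fragment` containing the dropout cassette
#'   (>= 2 recognition sites).
#' @param inserts A `cloned_fragment` (from [add_cloning_arms()]), a
#'   `ds_fragment`, or a list of either.
#' @param enzyme An `rgr_enzyme`.
#' @param max_states Passed to [ligate()].
#' @return An `assembly_result`; `diagnostics` additionally records
#'   constructs discarded for carrying recognition sites, and when no
#'   construct survives the `ends` attribute lists every fragment end to
#'   explain the dead junctions.
#' @export
golden_gate <- function(vector, inserts, enzyme, max_states = 10000L) {
  stopifnot(inherits(vector, "ds_fragment"),
            vector$topology == "circular",
            inherits(enzyme, "rgr_enzyme"))
  if (inherits(inserts, c("cloned_fragment", "ds_fragment"))) {
    inserts <- list(inserts)
  }
  inserts <- lapply(inserts, function(x) {
    if (inherits(x, "cloned_fragment")) x$ds else x
  })
  if (count_sites(vector$seq, enzyme, circular = TRUE) < 2L) {
    stop(sprintf("vector carries fewer than 2 %s sites (no dropout cassette)",
                 enzyme$name), call. = FALSE)
  }
  if (is.null(vector$id)) vector$id <- "vector"
  pool <- digest(vector, enzyme)
  for (ins in inserts) {
    stopifnot(inherits(ins, "ds_fragment"))
    pool <- c(pool, digest(ins, enzyme))
  }
  res <- ligate(pool, max_states = max_states)

  keep <- vapply(res$constructs, function(con)
    count_sites(con$seq, enzyme, circular = TRUE) == 0L, logical(1))
  dropped <- res$constructs[!keep]
  drop_ids <- vapply(dropped, `[[`, character(1), "id")
  diagnostics <- res$diagnostics
  if (nrow(diagnostics)) {
    diagnostics$status <- ifelse(
      diagnostics$construct %in% drop_ids, "discarded_recuttable", "kept")
    diagnostics$construct[diagnostics$construct %in% drop_ids] <-
      paste0("discarded:", diagnostics$construct[
        diagnostics$construct %in% drop_ids])
  }
  constructs <- res$constructs[keep]
  # renumber surviving constructs deterministically
  for (i in seq_along(constructs)) {
    old <- constructs[[i]]$id
    diagnostics$construct[diagnostics$construct == old] <-
      sprintf("construct_%d", i)
    constructs[[i]]$id <- sprintf("construct_%d", i)
  }
  out <- structure(list(constructs = constructs, diagnostics = diagnostics,
                        leftovers = res$leftovers),
                   class = "assembly_result")
  if (length(constructs) == 0L) {
    ends <- do.call(rbind, lapply(pool, function(f) {
      ov <- fragment_overhangs(f)
      data.frame(id = if (is.null(f$id)) "?" else f$id,
                 left_overhang = ov$left, right_overhang = ov$right,
                 length = nchar(f$seq), stringsAsFactors = FALSE)
    }))
    attr(out, "ends") <- ends
  }
  out
}
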