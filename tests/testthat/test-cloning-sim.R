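test_that("ds_fragment enforces its structural invariants", {
  expect_error(ds_fragment("ACGT", left_len = 3, right_len = 2),
               "out of range")
  expect_error(ds_fragment("ACGTACGT", left_len = 2,
                           topology = "circular"), "cannot carry overhangs")
  f <- ds_fragment("AATGGCCTTGCA", left_len = 3, right_len = 3)
  expect_identical(fragment_overhangs(f), list(left = "AAT", right = "GCA"))
})

test_that("digest matches the positional-arithmetic oracle", {
  reg <- default_registry()
  set.seed(17)
  for (enz_name in c("SapI", "BbsI")) {
    enz <- get_enzyme(reg, enz_name)
    for (i in 1:8) {
      # plant 1-3 sites (either orientation) into clean backbone
      nsites <- sample(1:3, 1)
      pieces <- rgrtools:::random_domesticated(40, reg$enzymes)
      for (k in seq_len(nsites)) {
        site <- if (runif(1) < 0.5) enz$recognition else
          reverse_complement(enz$recognition)
        pieces <- paste0(pieces, site,
                         rgrtools:::random_domesticated(40, reg$enzymes))
      }
      frag <- ds_fragment(pieces)
      got <- digest(frag, enz)
      want <- oracle_digest_linear(pieces, enz$recognition,
                                   enz$cut_offset_top, enz$cut_offset_bottom)
      expect_identical(length(got), length(want))
      for (j in seq_along(got)) {
        expect_identical(got[[j]]$seq, want[[j]]$seq)
        expect_identical(got[[j]]$left_len, as.integer(want[[j]]$left_len))
        expect_identical(got[[j]]$right_len, as.integer(want[[j]]$right_len))
      }
    }
  }
})

test_that("one linear cut yields two fragments with complementary overhangs", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  seq <- paste0(strrep("A", 10), "GCTCTTC", "TGCATG", strrep("C", 10))
  out <- digest(ds_fragment(seq), enz)
  expect_identical(length(out), 2L)
  # 3-nt cut window read directly off the parent at offsets 1/4 past site
  window <- substr(seq, 19, 21)
  expect_identical(fragment_overhangs(out[[1]])$right, window)
  expect_identical(fragment_overhangs(out[[2]])$left, window)
  # duplex conservation: merging on the shared window rebuilds the parent
  merged <- paste0(out[[1]]$seq,
                   substring(out[[2]]$seq, out[[2]]$left_len + 1))
  expect_identical(merged, seq)
})

test_that("digest handles no-site, circular and out-of-range inputs", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  clean <- ds_fragment(rgrtools:::random_domesticated(100, reg$enzymes))
  expect_identical(digest(clean, enz), list(clean))

  # site cutting beyond a linear end is an error
  expect_error(digest(ds_fragment("AAGCTCTTCA"), enz), "outside")

  # circular fixture vector: two cuts -> backbone + dropout
  set.seed(18)
  fx <- generate_fixtures(101, n_spacers = 2)
  frags <- digest(fx$vector_sapi, enz)
  expect_identical(length(frags), 2L)
  lens <- vapply(frags, function(f) nchar(f$seq), integer(1))
  backbone <- frags[[which.max(lens)]]
  expect_identical(fragment_overhangs(backbone)$left, "GCA")
  expect_identical(fragment_overhangs(backbone)$right, "AAT")
  # conservation on the circle: spans overlap by one window at each junction
  total <- sum(lens) - sum(vapply(frags, function(f) f$left_len, integer(1)))
  expect_identical(total, nchar(fx$vector_sapi$seq))
})

test_that("digest splits sites spanning the circular origin", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  base <- paste0("GCTCTTC", "TACGCAT", strrep("A", 30))
  # rotate so the recognition site straddles position 0
  rotated <- paste0(substring(base, 5), substr(base, 1, 4))
  out <- digest(ds_fragment(rotated, topology = "circular"), enz)
  expect_identical(length(out), 1L)
  expect_identical(nchar(out[[1]]$seq),
                   nchar(base) + out[[1]]$left_len)
  expect_identical(out[[1]]$left_len, 3L)
})

test_that("ligate closes compatible circles and reports leftovers", {
  # two fragments with matching windows AAT / GCA
  a <- ds_fragment("AATGGTTCCGCA", left_len = 3, right_len = 3, id = "a")
  b <- ds_fragment("GCATTACCGAAT", left_len = 3, right_len = 3, id = "b")
  res <- ligate(list(a, b))
  expect_identical(length(res$constructs), 1L)
  expect_identical(length(res$leftovers), 0L)
  circ <- res$constructs[[1]]
  expect_identical(circ$topology, "circular")
  # circle length = sum of spans minus the two shared windows
  expect_identical(nchar(circ$seq), 12L + 12L - 6L)
  expect_identical(nrow(res$diagnostics), 2L)

  # non-complementary ends: nothing closes
  lone <- ds_fragment("AATGGTTCCTAG", left_len = 3, right_len = 3)
  res2 <- ligate(list(lone))
  expect_identical(length(res2$constructs), 0L)
  expect_identical(length(res2$leftovers), 1L)

  # identical end windows: self-circularization
  selfc <- ds_fragment("AATGGTTCCAAT", left_len = 3, right_len = 3)
  res3 <- ligate(list(selfc))
  expect_identical(length(res3$constructs), 1L)
  expect_identical(nchar(res3$constructs[[1]]$seq), 9L)
})

test_that("blunt ends never ligate", {
  a <- ds_fragment("AATGGTTCC")
  b <- ds_fragment("GGTTCCAAT")
  res <- ligate(list(a, b))
  expect_identical(length(res$constructs), 0L)
  expect_identical(length(res$leftovers), 2L)
})

test_that("ligate is invariant to fragment order and finds flipped joins", {
  a <- ds_fragment("AATGGTTCCGCA", left_len = 3, right_len = 3, id = "a")
  b <- ds_fragment("GCATTACCGAAT", left_len = 3, right_len = 3, id = "b")
  # same physical molecule as b, handed over on the other strand
  b_flipped <- rgrtools:::flip_fragment(b)
  key <- function(res) vapply(res$constructs, `[[`, character(1), "seq")
  base <- key(ligate(list(a, b)))
  expect_identical(key(ligate(list(b, a))), base)
  expect_identical(key(ligate(list(a, b_flipped))), base)
})

test_that("junction-graph explosion hits the state cap, not a hang", {
  frs <- lapply(1:8, function(i)
    ds_fragment("AATGGTTCCAAT", left_len = 3, right_len = 3,
                id = sprintf("f%d", i)))
  expect_error(ligate(frs, max_states = 50), "exceeded 50 states")
})

test_that("golden gate assembles the designed insert exactly once", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  arr <- two_guide_array(reg)
  cf <- add_cloning_arms(arr, enz, c("AAT", "GCA"))
  set.seed(19)
  fx <- generate_fixtures(7, n_spacers = 2)
  res <- golden_gate(fx$vector_sapi, cf, enz)
  expect_identical(length(res$constructs), 1L)
  con <- res$constructs[[1]]
  # the array rides along verbatim (search the doubled circle)
  expect_true(grepl(arr$full_sequence, paste0(con$seq, con$seq),
                    fixed = TRUE))
  expect_identical(rgrtools:::count_sites(con$seq, enz, circular = TRUE), 0L)
  expect_true(all(res$diagnostics$status[
    res$diagnostics$construct == con$id] == "kept"))

  # swapped overhangs: no directional closure exists
  swapped <- add_cloning_arms(arr, enz, c("GCA", "AAT"))
  res2 <- golden_gate(fx$vector_sapi, swapped, enz)
  expect_identical(length(res2$constructs), 0L)
  expect_false(is.null(attr(res2, "ends")))
})

test_that("golden gate works with the BbsI vector variant", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "BbsI")
  arr <- two_guide_array(reg)
  cf <- add_cloning_arms(arr, enz, c("AATG", "GCAA"))
  set.seed(20)
  fx <- generate_fixtures(7, n_spacers = 2)
  res <- golden_gate(fx$vector_bbsi, cf, enz)
  expect_identical(length(res$constructs), 1L)
  expect_true(grepl(arr$full_sequence,
                    paste0(res$constructs[[1]]$seq, res$constructs[[1]]$seq),
                    fixed = TRUE))
})

test_that("chained overhangs assemble two inserts in order", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  arr1 <- build_array(list(spacer("GACCTTAAGGCCAATAGGTT", "spcas9", "g1")),
                      reg)
  arr2 <- build_array(list(spacer("TTGACCTTAAGGCCAATAGGTCA", "lbcas12a",
                                  "g2")), reg)
  # vector expects AAT ... GCA; chain through intermediate overhang CCT
  ins1 <- add_cloning_arms(arr1, enz, c("AAT", "CCT"))
  ins2 <- add_cloning_arms(arr2, enz, c("CCT", "GCA"))
  set.seed(21)
  fx <- generate_fixtures(7, n_spacers = 2)
  res <- golden_gate(fx$vector_sapi, list(ins1, ins2), enz)
  expect_identical(length(res$constructs), 1L)
  doubled <- paste0(res$constructs[[1]]$seq, res$constructs[[1]]$seq)
  expect_true(grepl(paste0(arr1$full_sequence, "CCT", arr2$full_sequence),
                    doubled, fixed = TRUE))
})

test_that("golden gate rejects vectors without a dropout cassette", {
  reg <- default_registry()
  enz <- get_enzyme(reg, "SapI")
  bare <- ds_fragment(rgrtools:::random_domesticated(300, reg$enzymes),
                      topology = "circular")
  arr <- two_guide_array(reg)
  cf <- add_cloning_arms(arr, enz, c("AAT", "GCA"))
  expect_error(golden_gate(bare, cf, enz), "fewer than 2")
})
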