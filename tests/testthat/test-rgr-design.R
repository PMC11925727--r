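test_that("design_stem returns the reverse complement of the hexamer", {
  expect_identical(design_stem("GAAACC"), "GGTTTC")
  expect_identical(design_stem("ATGCAT"), "ATGCAT")  # palindromic input
  expect_error(design_stem("GAAAC"), "exactly 6")
  expect_error(design_stem("GAAACCA"), "exactly 6")
  expect_error(design_stem("GANACC"), "invalid DNA")
})

test_that("every stem base is Watson-Crick paired with its partner", {
  pair <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(3)
  for (i in 1:100) {
    hex <- random_dna_str(6)
    stem <- design_stem(hex)
    for (j in 1:6) {
      expect_identical(substr(stem, j, j),
                       unname(pair[substr(hex, 7 - j, 7 - j)]))
    }
  }
})

test_that("spacer construction validates alphabet, length and label", {
  expect_error(spacer("ACGTACGTACGTACGTACGX", "spcas9", "x"), "invalid DNA")
  expect_error(spacer("ACGT", "spcas9", "x"), "outside allowed bounds")
  expect_error(spacer(strrep("A", 30), "spcas9", "x"),
               "outside allowed bounds")
  sp <- spacer("acgtacgtacgtacgtacgt", "spcas9", "lower")
  expect_identical(sp$sequence, "ACGTACGTACGTACGTACGT")
})

test_that("SpCas9 cassettes pair the stem with the spacer start", {
  reg <- default_registry()
  set.seed(4)
  for (i in 1:25) {
    sp <- spacer(random_dna_str(20), "spcas9", sprintf("s%d", i))
    cs <- suppressWarnings(build_rgr(sp, reg))
    expect_identical(substr(cs$full_sequence, 1, 6),
                     reverse_complement(substr(sp$sequence, 1, 6)))
    expect_true(startsWith(cs$guide_body, sp$sequence))
  }
})

test_that("LbCas12a cassettes pair the stem with the direct repeat", {
  reg <- default_registry()
  dr <- get_part(reg, "cas12a_direct_repeat")$sequence
  set.seed(5)
  stems <- replicate(10, {
    sp <- spacer(random_dna_str(23), "lbcas12a", paste0("r", sample(1e6, 1)))
    cs <- suppressWarnings(build_rgr(sp, reg))
    expect_true(startsWith(cs$guide_body, dr))
    substr(cs$full_sequence, 1, 6)
  })
  # repeat-first crRNA: the stem is spacer-independent
  expect_identical(unique(stems), reverse_complement(substr(dr, 1, 6)))
})

test_that("cassette length and boundaries are additive and consistent", {
  reg <- default_registry()
  hh_len <- nchar(get_part(reg, "hh_template")$sequence)
  hdv_len <- nchar(get_part(reg, "hdv")$sequence)
  set.seed(6)
  for (i in 1:50) {
    cas <- sample(c("spcas9", "lbcas12a"), 1)
    len <- sample(18:25, 1)
    sp <- spacer(random_dna_str(len), cas, sprintf("c%d", i))
    cs <- suppressWarnings(build_rgr(sp, reg))
    expect_identical(nchar(cs$full_sequence),
                     hh_len + nchar(cs$guide_body) + hdv_len)
    b <- cs$boundaries
    expect_identical(substr(cs$full_sequence, b$hh[1] + 1, b$hh[2]), cs$hh)
    expect_identical(substr(cs$full_sequence, b$guide_body[1] + 1,
                            b$guide_body[2]), cs$guide_body)
    expect_identical(substr(cs$full_sequence, b$hdv[1] + 1, b$hdv[2]),
                     cs$hdv)
  }
})

test_that("a spacer carrying an enzyme site triggers a domestication warning", {
  reg <- default_registry()
  sp <- spacer("ACGTGAAGACACGTACGTAC", "spcas9", "dirty")
  expect_warning(cs <- build_rgr(sp, reg), "BbsI")
  expect_gt(nrow(cs$domestication), 0L)
})

test_that("build_array preserves order and rejects bad input", {
  reg <- default_registry()
  arr <- two_guide_array(reg)
  expect_identical(length(arr$cassettes), 2L)
  expect_identical(arr$cassettes[[1]]$spacer$cas, "lbcas12a")
  expect_identical(arr$cassettes[[2]]$spacer$cas, "spcas9")
  expect_identical(
    arr$full_sequence,
    paste0(arr$cassettes[[1]]$full_sequence,
           arr$cassettes[[2]]$full_sequence))

  single <- build_array(list(spacer(random_dna_str(20), "spcas9", "solo")),
                        reg)
  expect_identical(single$full_sequence,
                   single$cassettes[[1]]$full_sequence)

  s <- spacer(random_dna_str(20), "spcas9", "dup")
  expect_error(build_array(list(s, s), reg), "duplicate")
  expect_error(build_array(list(), reg), "at least one")
})

test_that("array length is additive with the linker", {
  reg <- default_registry()
  set.seed(9)
  for (linker in c("", "AACCGG")) {
    n <- sample(2:4, 1)
    sps <- lapply(seq_len(n), function(i)
      spacer(random_dna_str(20), "spcas9", sprintf("l%d", i)))
    arr <- suppressWarnings(build_array(sps, reg, linker = linker))
    expect_identical(
      nchar(arr$full_sequence),
      sum(vapply(arr$cassettes, function(c) nchar(c$full_sequence),
                 integer(1))) + (n - 1L) * nchar(linker))
  }
})

test_that("domesticate_check finds planted sites on both strands", {
  seq <- paste0(strrep("A", 10), "GAAGAC", strrep("C", 84), "GTCTTC",
                strrep("A", 20))
  reg <- default_registry()
  v <- domesticate_check(seq, list(get_enzyme(reg, "BbsI")))
  expect_identical(nrow(v), 2L)
  expect_identical(v$start, c(10L, 100L))
  expect_identical(v$strand, c("+", "-"))
})

test_that("domesticate_check agrees with find_sites over all enzymes", {
  reg <- default_registry()
  set.seed(10)
  for (i in 1:10) {
    s <- random_dna_str(400)
    v <- domesticate_check(s, reg$enzymes)
    manual <- rbind(find_sites(s, "GCTCTTC", "both"),
                    find_sites(s, "GAAGAC", "both"))
    expect_identical(nrow(v), nrow(manual))
  }
  # rejection-sampled clean sequences are reported clean
  set.seed(3)
  clean <- rgrtools:::random_domesticated(500, reg$enzymes)
  expect_identical(nrow(domesticate_check(clean, reg$enzymes)), 0L)
})

test_that("add_cloning_arms yields an insert with the designed overhangs", {
  reg <- default_registry()
  arr <- two_guide_array(reg)
  for (case in list(list("SapI", c("AAT", "GCA")),
                    list("BbsI", c("AATG", "GCAA")))) {
    enz <- get_enzyme(reg, case[[1]])
    cf <- add_cloning_arms(arr, enz, case[[2]])
    frags <- digest(cf$ds, enz)
    expect_identical(length(frags), 3L)
    insert <- frags[[2]]
    ov <- fragment_overhangs(insert)
    expect_identical(ov$left, case[[2]][1])
    expect_identical(ov$right, case[[2]][2])
    expect_identical(insert$left_len, enz$overhang_len)
    # duplex interior of the insert is exactly the array
    interior <- substr(insert$seq, insert$left_len + 1,
                       nchar(insert$seq) - insert$right_len)
    expect_identical(interior, arr$full_sequence)
    # no recognition site survives on the insert
    expect_identical(nrow(find_sites(insert$seq, enz$recognition, "both")),
                     0L)
  }
})

test_that("internal recognition sites are fatal at add_cloning_arms", {
  reg <- default_registry()
  sp <- spacer("ACGTGCTCTTCGTACGTACG", "spcas9", "poison")
  arr <- suppressWarnings(build_array(list(sp), reg))
  err <- tryCatch(
    add_cloning_arms(arr, get_enzyme(reg, "SapI"), c("AAT", "GCA")),
    error = conditionMessage)
  expect_match(err, "internal SapI")
  expect_match(err, "\\[\\d+,\\d+\\)")  # offsets are listed
  expect_error(
    add_cloning_arms(arr, get_enzyme(reg, "BbsI"), c("AAT", "GCA")),
    "two 4-nt")
})

test_that("candidate scan recovers a single planted SpCas9 site", {
  background <- strrep("AC", 200)  # PAM-free on both strands
  tss <- 350L
  a <- tss - 119L                  # protospacer [a, a+20), then AGG PAM
  plant <- paste0(random_dna_str(0), "GTCAGTCAGTCAGTCAGTCA", "AGG")
  promoter <- paste0(substr(background, 1, a),
                     plant,
                     substring(background, a + nchar(plant) + 1))
  cand <- find_candidate_spacers(promoter, tss, "spcas9")
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, a)
  expect_identical(cand$strand, "+")
  expect_identical(cand$pam, "AGG")
  expect_identical(cand$sequence, "GTCAGTCAGTCAGTCAGTCA")
  expect_identical(cand$dist_to_tss, tss - (a + 19L))
  want <- oracle_candidate_scan(promoter, tss, "spcas9")
  expect_identical(cand$start, want$start)
})

test_that("candidate scan has no hits without PAMs and validates inputs", {
  allA <- strrep("A", 400)
  expect_identical(nrow(find_candidate_spacers(allA, 350, "spcas9")), 0L)
  expect_identical(nrow(find_candidate_spacers(allA, 350, "lbcas12a")), 0L)
  expect_error(find_candidate_spacers(allA, 500, "spcas9"), "out of range")
  expect_warning(
    empty <- find_candidate_spacers(strrep("AC", 100), 100, "spcas9"),
    "upstream")
  expect_identical(nrow(empty), 0L)
})

test_that("candidate scan equals exhaustive enumeration on random promoters", {
  set.seed(11)
  for (i in 1:6) {
    promoter <- random_dna_str(sample(c(400, 800, 2000), 1))
    tss <- nchar(promoter) - 40L
    for (cas in c("spcas9", "lbcas12a")) {
      got <- find_candidate_spacers(promoter, tss, cas)
      want <- oracle_candidate_scan(promoter, tss, cas)
      expect_identical(got$start, want$start,
                       info = sprintf("%s iter %d", cas, i))
      expect_identical(got$end, want$end)
      expect_identical(got$strand, want$strand)
    }
  }
})

test_that("spacer files round trip through table and FASTA formats", {
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "spacers.tsv")
  writeLines(c("# comment",
               "g1\tGACCTTAAGGCCAATAGGTT\tspcas9",
               "g2\tTTGACCTTAAGGCCAATAGGTCA\tlbcas12a"), tab)
  sps <- read_spacers(tab)
  expect_identical(length(sps), 2L)
  expect_identical(sps[[1]]$label, "g1")
  expect_identical(sps[[2]]$cas, "lbcas12a")

  fa <- file.path(dir, "spacers.fasta")
  writeLines(c(">g1 cas=spcas9", "GACCTTAAGGCCAATAGGTT",
               ">g2 cas=lbcas12a", "TTGACCTTAAGGCCAATAGGTCA"), fa)
  sps2 <- read_spacers(fa)
  expect_identical(vapply(sps2, `[[`, character(1), "sequence"),
                   vapply(sps, `[[`, character(1), "sequence"))
  writeLines(c(">g3", "GACCTTAAGGCCAATAGGTT"), fa)
  expect_error(read_spacers(fa), "cas=")
})

test_that("candidate spacers export to BED with 0-based half-open intervals", {
  background <- strrep("AC", 200)
  promoter <- paste0(substr(background, 1, 231),
                     "GTCAGTCAGTCAGTCAGTCAAGG",
                     substring(background, 255))
  cand <- find_candidate_spacers(promoter, 350, "spcas9")
  p <- withr::local_tempfile(fileext = ".bed")
  spacers_to_bed(cand, p)
  bed <- read.table(p, sep = "\t")
  expect_identical(bed$V2, cand$start)
  expect_identical(bed$V3, cand$end)
  expect_identical(bed$V6, cand$strand)
})
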