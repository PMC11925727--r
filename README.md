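# rgrtools

Design and in-silico validation of **RGR (ribozyme-gRNA-ribozyme)
cassettes**: CRISPR guide RNAs flanked by a hammerhead (HH) and a
hepatitis delta virus (HDV) self-cleaving ribozyme, so that functional
guides are excised precisely from a single RNA polymerase II transcript.
This architecture lets inducible Pol II promoters (optogenetic,
chemogenetic, tissue-specific) drive guide expression -- releasing one or
several guides, for one or several Cas effectors, from the same mRNA that
encodes a reporter protein.

The package is for researchers building such constructs. It covers the
complete design path from spacer list to cloning-ready, verified
cassette:

* **Stem rule.** The HH ribozyme's first six nucleotides must base-pair
  with the six nucleotides immediately following its 3' end, so the stem
  is `reverse_complement(guide_body[1..6])`. For spacer-first SpCas9
  sgRNAs (spacer + scaffold) the stem tracks the spacer; for repeat-first
  LbCas12a crRNAs (direct repeat + spacer) it is constant.
* **Cleavage simulation.** HH cuts at its own 3' boundary, HDV at its own
  5' boundary; for an `n`-cassette array the transcript falls into
  `2n + 1` labeled fragments, `n` of them guides that must equal their
  guide bodies byte-for-byte in RNA form.
* **Golden Gate simulation.** Type IIS digestion (SapI/LguI `GCTCTTC`
  cut 1/4, BbsI `GAAGAC` cut 2/6, 5' overhangs) and exhaustive sticky-end
  ligation verify that an arm-flanked cassette inserts directionally and
  uniquely into a destination vector, with zero recognition sites left in
  the product.
* **CRISPRa spacer enumeration.** All protospacers on both strands with a
  correctly placed PAM (NGG 3'-adjacent for SpCas9, TTTV 5'-adjacent for
  LbCas12a) lying wholly within a window 75-300 bp upstream of the TSS
  (inclusive bounds, configurable).

All part sequences and enzyme definitions are configuration (a YAML
registry with documented defaults), not code constants. See
`vignette("rgr-design")` for the model and every design decision.

## Worked example

Two guides for different Cas effectors on one transcript, cleaved and
cloned:

```r
library(rgrtools)
reg <- default_registry()

arr <- build_array(list(
  spacer("TTGACCTTAAGGCCAATAGGTCA", "lbcas12a", "pdgfb_guide"),
  spacer("GACCTTAAGGCCAATAGGTT",    "spcas9",   "bmp2_guide")
), reg)
arr
#> multiplex_array: 2 cassette(s), 362 nt total
#>   pdgfb_guide [lbcas12a] 155 nt
#>   bmp2_guide [spcas9] 207 nt
arr$cassettes[[2]]
#> RGR cassette 'bmp2_guide' [spcas9], 207 nt
#>   stem AAGGTC | HH 43 nt | guide body 96 nt | HDV 68 nt
```

The stem `AAGGTC` is the reverse complement of `GACCTT`, the spacer's
first six bases. Simulated self-cleavage of the transcript releases five
fragments -- two of them the guides, with exact ends:

```r
pr <- simulate_cleavage(assemble_transcript(arr), "complete")
pr[, c("role", "source_label", "start", "end")]
#>                   role source_label start end
#> 1   upstream_byproduct            -     0  43
#> 2                guide  pdgfb_guide    43  87
#> 3      inter_byproduct            -    87 198
#> 4                guide   bmp2_guide   198 294
#> 5 downstream_byproduct            -  294 362
substr(released_guides(pr)$rna[2], 1, 30)
#> [1] "GACCUUAAGGCCAAUAGGUUGUUUUAGAGC"   # spacer, then scaffold, in RNA
```

Attach SapI arms with the directional overhang pair `AAT`/`GCA` and
assemble into a synthetic destination vector; exactly one site-free
circular construct results, carrying the array verbatim:

```r
enz <- get_enzyme(reg, "SapI")
cf  <- add_cloning_arms(arr, enz, c("AAT", "GCA"))
fx  <- generate_fixtures(7, n_spacers = 2)
golden_gate(fx$vector_sapi, cf, enz)
#> assembly_result: 1 construct(s), 2 leftover fragment(s)
#>   construct_1: circular, 2786 nt
```

Swapping the overhangs (`GCA`/`AAT`) gives zero constructs -- the
directionality guarantee. Finally, the dose helper converts a pulsed
blue-light regime into duty cycle and fluence:

```r
illumination_dose(illumination_regime(1, 20, 40, 1))  # 1 mW/cm2, 1 h
#> $duty_cycle 0.333  $total_on_s 1200  $fluence_J_cm2 1.2
```

A command-line interface wrapping the same functions ships at
`inst/cli/rgrtools.R` (subcommands `design`, `multiplex`, `arms`,
`cleave`, `assemble`, `spacers`, `dose`, `fixtures`; exit codes 0 /
2 validation error / 3 design infeasible).

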