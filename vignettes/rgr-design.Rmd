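---
title: "Designing and simulating ribozyme-flanked guide RNA cassettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating ribozyme-flanked guide RNA cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgrtools)
```

## The design problem

CRISPR guide RNAs are conventionally expressed from Pol III promoters,
which cannot be coupled to the inducible, protein-coding transcription
machinery that optogenetic and other conditional expression systems
control. The RGR (ribozyme-gRNA-ribozyme) architecture solves this by
embedding the guide in a Pol II transcript between two self-cleaving
ribozymes: a hammerhead (HH) ribozyme upstream and a hepatitis delta virus
(HDV) ribozyme downstream. Co-transcriptional self-cleavage excises the
guide with exact 5' and 3' ends, so one induced mRNA can simultaneously
produce a protein (e.g. a fluorescent reporter) and one or several
functional guides -- including guides for different Cas effectors on the
same transcript.

`rgrtools` automates the sequence design and verifies it in silico:

1. **Cassette construction** (`build_rgr`, `build_array`): compose
   HH + guide body + HDV, applying the stem rule below.
2. **Cleavage simulation** (`assemble_transcript`, `simulate_cleavage`):
   predict every fragment the transcript releases and check the guides
   come out byte-exact.
3. **Cloning simulation** (`add_cloning_arms`, `digest`, `ligate`,
   `golden_gate`): verify the cassette assembles directionally into a
   destination vector by type IIS Golden Gate cloning.
4. **CRISPRa spacer enumeration** (`find_candidate_spacers`): list every
   PAM-compatible protospacer in a window upstream of a transcription
   start site.

## The stem rule

The hammerhead ribozyme folds correctly only if its 5' end base-pairs with
the sequence immediately downstream of its own cleavage site. The design
rule is positional: **the first six nucleotides of the HH ribozyme are the
reverse complement of the six nucleotides immediately following the HH
ribozyme's 3' end**. `design_stem()` implements exactly this, and
`build_rgr()` substitutes the result into the 6-nt placeholder (`NNNNNN`)
at the start of the hammerhead template.

What follows the ribozyme depends on the guide architecture:

* **SpCas9** sgRNAs are *spacer-first* (spacer + constant scaffold), so
  the stem pairs with the first six nucleotides of the spacer and changes
  with every guide.
* **LbCas12a** crRNAs are *repeat-first* (constant direct repeat +
  spacer), so a literal application of the positional rule pairs the stem
  with the direct repeat, making the stem spacer-independent.

The repeat-first reading for Cas12a was a genuinely open choice: one could
instead reorder the crRNA so the spacer abuts the hammerhead. We implement
the literal positional rule because that is how the rule is stated, and
because the constant-stem consequence is testable and self-consistent. A
user who prefers the alternative ordering can supply a registry whose
parts encode it; nothing else in the package changes.

```{r stem}
design_stem("GAAACC")
cs <- build_rgr(spacer("GACCTTAAGGCCAATAGGTT", "spcas9", "demo"))
substr(cs$full_sequence, 1, 6) == reverse_complement(substr(cs$guide_body, 1, 6))
```

## Parts are configuration, not constants

The HH template, HDV ribozyme, SpCas9 scaffold and LbCas12a direct repeat
live in a `part_registry` (YAML; see
`system.file("extdata", "default_registry.yaml", package = "rgrtools")`).
The shipped defaults are the minimal hammerhead and genomic HDV ribozyme
of the RGR literature plus the canonical SpCas9 sgRNA scaffold and
LbCas12a direct repeat. They are deliberately labeled *defaults*: any
specific vector system fixes its own exact part sequences, and users
should override the registry to reproduce a particular construct
bit-exactly. Registry loading validates every structural invariant (stem
placeholder, 5'-overhang enzyme geometry, overhang distinctness and
non-self-complementarity) and `validate_registry()` additionally checks
that no part carries an internal recognition site for any registered
enzyme -- an internal site would shatter the part during assembly.

Enzyme geometry is encoded as (recognition site, top-strand cut offset,
bottom-strand cut offset): SapI `GCTCTTC` 1/4 (3-nt 5' overhangs), BbsI
`GAAGAC` 2/6 (4-nt), with LguI aliased to SapI as an isoschizomer.
Enzymes leaving 3' overhangs (bottom offset less than top) are rejected at
load time; the assembly model only represents 5' extensions because both
supported enzymes produce them.

## Cleavage model

Ribozyme chemistry is reduced to exact junction cuts: the HH ribozyme
cleaves at its own 3' boundary and HDV at its own 5' boundary. The HH
byproduct therefore retains the stem (which is part of the ribozyme), and
the released guide carries neither stem nor ribozyme nucleotides. We do
not model the 2',3'-cyclic phosphate and 5'-OH marks cleavage leaves on
fragment ends, nor folding kinetics or cleavage rates -- the design claim
being checked is *precision of excision*, which is a pure sequence
property. Partial processing is modeled combinatorially through per-site
flags (`simulate_cleavage(t, c(TRUE, FALSE, ...))`), not kinetically,
because no rate parameters are part of the design.

Two invariants anchor the test suite: fragment concatenation always
reconstitutes the transcript exactly, and released guides are invariant
to the upstream ORF, the trailer, and the other cassettes in a multiplex
array.

## Cloning model

Double-stranded fragments use a *span* representation: the plus-strand
sequence of everything either strand covers, plus the lengths of the 5'
single-stranded regions at each end. Both fragments created by one type
IIS cut carry the cut window in their spans (one keeps the top strand of
the window, the other the bottom), which makes conservation checks --
"concatenating fragments, merging shared windows, rebuilds the parent" --
exact string identities.

Ligation joins ends whose overhangs are Watson-Crick complementary,
explores the junction graph exhaustively (each physical fragment used at
most once per construct, both orientations considered), and returns all
distinct circular closures. Mismatch (near-cognate) ligation is not
modeled: overhang fidelity is binary, matching the deterministic-assembly
assumption of Golden Gate design. Blunt ends never ligate. The search is
capped (default 10,000 states) with an explicit error, since a user can
construct pathological overhang sets.

Circular identity is the lexicographically smallest rotation over *both*
strands. Using both strands (rather than the plus strand only) is a
deliberate choice: the exploration finds each physical circle in both
handednesses, and a circular duplex has no intrinsic plus strand, so
strand-insensitive canonicalization is what de-duplicates physical
molecules correctly.

`golden_gate()` models the one-pot reaction as digest-everything,
ligate, then keep only constructs free of the enzyme's recognition site.
This is the fixed point of the iterative cut-ligate process: any
religation that recreates a site (e.g. backbone + original dropout) would
be re-cut, so only site-free closures persist. With a correctly designed
arm pair exactly one construct survives; swapping the two overhangs
yields zero, and the diagnostics list every fragment end to explain the
dead junctions.

## CRISPRa window semantics

Candidate protospacers for transcriptional activation are enumerated in a
window 75-300 bp upstream of the TSS (defaults; configurable via
`target_window()`). Three conventions had to be fixed where reasonable
alternatives exist; all are documented and configurable or at least
localized:

* **Containment**: the *entire protospacer* must lie within the closed
  interval `[tss - 300, tss - 75]` in plus-strand coordinates, both
  boundaries inclusive. The window could alternatively be measured to the
  PAM or the cut site; protospacer containment is the plainest reading of
  "targets N bp upstream" and is what the boundary tests pin down
  (accepted at exactly 75 and 300, rejected at 74 and 301).
* **Strands**: both strands are searched; promoter-proximal CRISPRa
  guides are routinely strand-agnostic.
* **PAM geometry**: NGG 3'-adjacent for SpCas9, TTTV 5'-adjacent for
  LbCas12a, PAM excluded from the spacer -- standard CRISPR geometry.

Default protospacer lengths are 20 nt (SpCas9) and 23 nt (LbCas12a),
configurable per call. Output is deterministic (sorted by plus-strand
start, plus before minus) so downstream tooling can diff it.

## Synthetic data

`generate_fixtures(seed)` produces everything the simulations need with
no external inputs: spacers rejection-sampled to be free of enzyme sites,
circular destination vectors whose dropout cassette is flanked by
outward-facing SapI (or BbsI) sites leaving the registry's directional
overhang pair, and a 1 kb promoter whose background suppresses PAMs (no
GG/CC dinucleotides or TTT/AAA runs) so that one SpCas9 and one LbCas12a
protospacer planted inside the window are recoverable at known
coordinates. The same seed yields a byte-identical bundle.

What the fixtures do *not* emulate: real vectors carry replication
origins, resistance markers and promoters that this generator represents
only as random domesticated backbone; real promoters have PAM-dense,
GC-skewed sequence where a scan returns many candidates rather than the
planted ones alone. Passing tests therefore demonstrate the correctness
of the design arithmetic and assembly logic, not biological activity,
off-target safety, or ribozyme folding in any particular sequence
context -- those remain wet-lab properties.

## Numerical and degenerate-input choices

* Coordinates are 0-based, half-open everywhere internally; GenBank
  output converts to 1-based inclusive.
* `reverse_complement("")` returns `""`; motif scans on sequences shorter
  than the motif return an empty hit table rather than erroring.
* A palindromic motif matching one interval on both strands is reported
  once (strand `+`): one physical site is one site.
* Lowercase input is folded to uppercase; `U` in DNA input is an error,
  never a silent conversion.
* Candidate lists, digestion fragments and assembly constructs are
  sorted deterministically so identical inputs give identical files.
* A spacer carrying an internal recognition site warns at `build_rgr()`
  and errors at `add_cloning_arms()` -- the point where it becomes fatal.
* The test suite sizes its random-instance suites (2 kb oracles, 1000
  fuzzed cassettes, tens of conservation instances) to run in well under
  a minute while still exercising every code path; the acceptance script
  uses the same sizes.

## The illumination-dose helper

Blue-light induction protocols are specified as pulsed regimes;
`illumination_dose()` converts (intensity, ON seconds, OFF seconds,
duration) into duty cycle, cumulative ON time and fluence
(J/cm^2 = mW/cm^2 x s / 1000). The two regimes used throughout this
package's examples -- 20 s ON / 40 s OFF (duty 1/3) and 20 s ON / 60 s OFF
(duty 1/4) at 1 mW/cm^2, 470 nm -- are arithmetic only: no photochemistry
(EL222 dimerization kinetics, reversion half-life) is modeled, because
those are properties of the protein, not of the cassette design.

## Known limitations

* Ribozyme activity is assumed, not predicted: no secondary-structure
  folding or thermodynamic ranking of stems (a stem that base-pairs
  perfectly can still misfold in an unlucky sequence context).
* No on/off-target activity scoring for candidate spacers; use a
  dedicated scoring tool on the enumerated candidates.
* Golden Gate fidelity is binary; ligase kinetics, star activity and
  methylation sensitivity are out of scope.
* The GenBank writer/reader is minimal and round-trips only files this
  package writes.
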