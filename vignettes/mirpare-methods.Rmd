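---
title: "Methods and design of the mirpare pipeline"
author: "mirpare maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mirpare pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirpare)
```

# Scope

`mirpare` implements the computational core of a two-condition plant
small-RNA study without biological replicates: read cleaning and
collapsing into unique tags, perfect-match genome mapping, hairpin
excision and folding, novel miRNA calling against the standard plant
(Meyers-style) criteria with miRNA* (star) evidence, an exact
two-library count test for differential expression, six-rule target
prediction with a position penalty score, and degradome (PARE)
validation of cleavage sites with category I/II/III classification.
A seeded synthetic-data generator produces genomes, libraries and
degradome data with complete ground truth, so every stage is testable
without any external download.

# The synthetic data generator

The generator defines the study conditions used throughout the test
suite and the acceptance script. Its defaults are fixed once and are
not tuned per test:

* **Genome**: 2 scaffolds of 40 kb; 20 planted hairpin precursors.
  Each precursor is a perfect inverted repeat (stem drawn so the
  precursor is 80–280 nt, the length range of published plant
  precursors) around an 8-nt loop. Perfect Watson–Crick stems satisfy
  the ≥80 % pairing that real precursors show, and make the planted
  mature/star duplex an exact structural invariant: the star is the
  segment pairing mature positions 1..L−2, extended 2 nt at its 3' end,
  giving 2-nt 3' overhangs on both ends of the duplex. Coordinates are
  1-based inclusive with explicit strand, serialized
  `scaffold:start:end:strand`, so the precursor length LP always equals
  `end − start + 1`.
* **Libraries**: expected mature counts follow log-uniform relative
  abundances scaled to a 50 000-read library; the star is expressed at
  one tenth of its mature. Counts are negative binomial with
  `variance = mu + dispersion * mu^2`; the default dispersion of 0.01
  reflects the near-Poisson technical variation seen between sequencing
  libraries. Over-dispersion is deliberately configurable because it is
  the realistic stress case for the exact test (below). Drought means
  are the control means times the configured fold changes (defaults:
  two miRNAs up 4-fold, two down 4-fold). Reads are insert + 3' adapter
  (the standard small-RNA adapter `TGGAATTCTCGGGTGCCAAGG`); 8 % of
  reads come from planted rRNA/tRNA loci and 2 % are junk (<18-nt
  inserts or uniformly low quality) to exercise cleaning.
* **Transcriptome and degradome**: each planted miRNA gets one exact
  reverse-complement site in its own transcript (one site per
  transcript, so the true site is the only signal peak there). The true
  cleavage position is the transcript base paired to miRNA position 10.
  Half of the degradome reads (default signal fraction 0.5) start
  exactly at true cleavage positions; the rest start uniformly at
  random, the simplest null for adapter-ligated decay fragments. Reads
  are 20–21 nt of sense-strand sequence.

What the generator does **not** emulate: sequencing errors, quality
profiles, isomiR end-heterogeneity, multi-mapping repeat families
beyond the contaminant tracks, or a realistic transcriptome (UTR/CDS
structure). Passing tests therefore demonstrate the correctness of the
computational contracts, not performance on noisy biological data.

# Folding model

Secondary structure is predicted with a deliberately simplified,
exhaustively checkable stacking model: admissible pairs G:C, A:U, G:U;
minimum hairpin loop 3; energy carried entirely by stacks of adjacent
pairs (G:C-on-G:C −3.0, A:U-on-A:U −2.0, G:U-on-G:U −1.0 kcal/mol,
mixed stacks the mean of their two pairs); isolated pairs contribute 0,
so the energy is always ≤ 0. Dynamic programming minimises the energy
over all nested structures; ties resolve toward the pairing whose 5'
index is smallest. The suite verifies optimality against brute-force
enumeration of every nested structure at short lengths.

This is not a full nearest-neighbour (Turner) model, and the package
never claims to reproduce thermodynamic energies from MFOLD-class
programs — the published hairpin energies shipped with the reference
table are treated as fixture annotation. The −30 kcal/mol acceptance
threshold applies to whichever backend is configured; a replacement
backend honouring the same contract can be passed to `foldRNA()` and
flows through excision and discovery.

# Discovery: excision, star finding, acceptance

Candidate precursor windows are tried with the tag on either arm,
window lengths 60–280 nt stepped by 20 (covering the published LP range
80–272); per arm the lowest-energy window is kept, ties to the shorter
window. A window counts as a hairpin only when the tag lies on one arm
of a single major stem. Operationally that means: ≥16 of the tag's
nucleotides paired, all opening (or all closing) brackets, partners in
one compact block (range ≤ tag length + 4), near-constant helix
register (position + partner drifting ≤ 2, i.e. bulges of at most the
size the duplex criteria tolerate), and ≥80 % Watson–Crick pairs among
the tag's pairs — the same WC dominance that defines the planted stems.
The qualitative "single major stem" phrase needs these operational
teeth because a 280-nt random window offers hundreds of pairing
registers to a GU-permissive folder; even so, chance windows pass
occasionally (roughly one locus in ten yields some candidate window).
Specificity comes from the star requirement in the acceptance step, and
the recovery tests assert zero falsely *accepted* loci.

`findStar()` reads the star from the structure: the partner region of
mature positions 1..L−2, shifted so both strands' 3' ends overhang by
2 nt. A candidate is accepted iff the star sequence is observed among
the tags (count ≥ 1), the mature::star duplex has ≤4 unpaired mature
positions and no bulge >2 nt, the overhang geometry holds, and the
precursor energy is at or below the −30 threshold. Overlapping accepted
hairpins (the mature/star mirror of one duplex, or the antisense
hairpin of an inverted repeat) collapse to one record keeping the most
abundant mature, which is how the mature arm is conventionally chosen.
Families are sets of identical mature sequences; distinct loci of one
family get letter suffixes. Applied to the packaged 65-entry reference
table this sequence-identity rule reproduces its 54 families exactly.

# The exact count test

For a tag with counts x, y in libraries of sizes N1, N2 the conditional
distribution of y given x is negative binomial in form:
`p(y|x) = (N2/N1)^y * (x+y)!/(x!y!) * (1+N2/N1)^-(x+y+1)`; the
two-tail p-value is the smaller of the lower (`k ≤ y`) and upper
(`k ≥ y`) tail sums. Numerical policy: all terms in log space; the
upper tail uses the complement `1 − Σ_{k<y}` with compensated (Kahan)
summation while the complement is ≥0.01, and direct max-shifted
summation of the tail below that, where cancellation against 1 and the
lgamma-limited accuracy of individual terms would otherwise dominate.
This keeps relative error against direct summation below 1e-10
throughout the representable range.

Two properties of the printed formula worth knowing: it conditions on
x, so it is **not** symmetric under exchanging (x, N1) with (y, N2)
(hand summation gives p(3,7)=11/64 but p(7,3)=29/256 at equal totals);
and it assumes Poisson sampling, so its type-I error is controlled
under mild over-dispersion only for low-abundance tags — the regime of
the vast majority of unique tags — and inflates for highly expressed
ones. The DE caller therefore combines the p-value (α = 0.01) with a
two-fold change requirement on RPM-normalised values, keeps records
with RPM ≥ 1 in at least one library (preserving on/off miRNAs), and
reports a Benjamini–Hochberg column for reference without using it for
calls, matching the original single-library design. `2^-ΔΔCt` relative
expression is provided for RT-qPCR comparison.

# Target prediction and the penalty score

Duplexes are anti-parallel alignments of the miRNA (5'→3') against a
transcript window, with at most one single-nucleotide gap on either
strand (window length within one base of the miRNA). The penalty score
weighs mismatches 1.0, G:U wobbles 0.5 and gaps 2.0, doubling every
column at miRNA positions 2–13; the gap is placed to minimise the
score, ties toward the largest miRNA position. A target bulge between
miRNA positions g and g+1 is charged at position g+1. The weights are
config-exposed: the literature states the cutoff (<2.5 for de novo
prediction; degradome-supported confirmation conventionally relaxes to
4) but not the exact weights, so the standard plant target-prediction
convention is used.

The six rules: (i) ≤4 mismatch equivalents overall (G:U = 0.5, gap
counted like a mismatch); (ii) no run of >2 adjacent mismatches; (iii)
no two adjacent mismatches in positions 2–12; (iv) positions 10–11 not
mismatched (G:U tolerated, gaps not); (v) ≤2.5 mismatch equivalents in
positions 1–12; (vi) duplex energy ≥74 % of the miRNA bound to its
perfect complement, both scored with the same stacking model. The
transcriptome sweep computes per-start minimum penalties for the three
window lengths in one pass (prefix/suffix decompositions in compiled
code) and re-evaluates candidate windows with the reference aligner;
the suite checks the sweep against brute-force evaluation of every
window and every gap placement. Overlapping sites of one miRNA merge
keeping the lowest score.

# Degradome analysis

Read 5' ends are mapped by exact matching of the first 20 nt against
transcript sense strands; multi-mapped reads count once per matching
transcript. The cleavage site of a duplex is the transcript base paired
to miRNA position 10; an event requires at least one read 5' end at
exactly that position (a window option exists for noisy data, but
nucleotide resolution is PARE's premise and the default). Events are
classified relative to their transcript's profile: category I at the
maximum (ties as I), II at or above the median without being the
maximum, III below the median. Max and median are computed over
positions with ≥1 read by default; including the zero positions of a
sparse profile would push nearly every event into category II, which is
why the detected-position reference is the default (switchable via
`medianOver = "all"`).

Significance uses composition-preserving miRNA shuffles: p = (1 + s) /
(1 + n) where s counts shuffles achieving any event with penalty ≤ and
read support ≥ the observed one, with the +1 pseudocount avoiding p = 0
at finite n (default n = 100). When the observed score is 0 a shuffle
can only succeed through a perfect Watson–Crick match, so the check
reduces to exact string matching of each shuffle's reverse complement —
an algebraic shortcut, not an approximation; nonzero observed scores
rescan the transcriptome per shuffle.

# Pipeline

`runPipeline()` executes preprocess → discovery → differential
expression → target prediction → degradome over a single YAML
configuration with per-stage parameter blocks; unknown parameters are
rejected before any stage runs, a failing stage halts with its name,
and all randomness derives from one root seed expanded per stage, so a
rerun with the same configuration reproduces every output byte. Stage
outputs are TSVs mirroring the published table layouts, plus a JSON
manifest with input digests and parameters. A thin command-line wrapper
(`inst/scripts/mirpipe.R`) exposes simulate/run/report subcommands.

# Problem sizes

The default study conditions (2 × 40 kb genome, 20 hairpins, 50 000
reads per library, 10 000 degradome reads, 100 shuffles) were chosen so
a complete discovery–DE–degradome cycle is a desk-scale computation; DE
operating characteristics are exercised at count level with library
totals of 10^6, where read-level simulation would add nothing but I/O.
Published headline numbers that depend on the original ~27–30M-read
libraries (total tag counts, 207 conserved miRNAs, 274 candidates and
the like) are not reproducible at this scale and are not targets; the
worked-example quantities from the packaged 65-entry table are.

# Known limitations

* The stacking folding model underestimates structure relative to
  full thermodynamic folders; its −30 threshold is calibrated to the
  model, not to published MFOLD energies.
* Window selection prefers the lowest energy, so reported precursor
  lengths tend toward the largest admissible window rather than the
  minimal hairpin.
* The exact test inflates type-I error for highly expressed tags under
  over-dispersion; with no replicates in the design this is a property
  of the method, mitigated (not removed) by the fold-change filter.
* Excision specificity relies on downstream star evidence; roughly one
  random locus in ten can produce a structurally plausible candidate
  window under the internal model.
* Genome mapping is exact-match only (no mismatch tolerance,
  no color space, no paired ends), per the original analysis design.
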