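---
title: "Models and methods behind beadphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beadphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadphase)
```

## The experiment being modelled

beadphase analyses (and simulates) a two-stage emulsion experiment that
phases short amplicons to single DNA molecules. In a first emulsion,
primer-coated beads are mixed with degenerate barcode oligonucleotides
(a stretch of 15–20 random bases flanked by fixed handle sequences) at a
deliberately low loading of about 0.1 copies per bead (c.p.b.), so that
a bead that receives any barcode almost always receives exactly one.
Occupied beads are enriched, then paired in a second emulsion with
genomic fragments, again at ~0.1 c.p.b. Target regions (here two
variable 16S rRNA regions, "16S.1" and "16S.2") are amplified from the
fragment and coupled to the bead barcode, so that after sequencing,
reads sharing a barcode derive — ideally — from one founding molecule.
Grouping reads by barcode ("barcode clusters"), calling a consensus per
target, and classifying each consensus taxonomically then lets one ask
whether the two targets of a cluster agree, i.e. whether phasing
succeeded.

## The Poisson loading model

Molecule-to-compartment loading is Poisson with rate $\lambda$ (the
c.p.b.). The package exposes the four closed forms used throughout:

* occupancy $P(K \ge 1) = 1 - e^{-\lambda}$ — the expected enriched
  fraction (9.52% at $\lambda = 0.1$, the "~10%" rule of thumb);
* monoclonality among occupied compartments
  $P(K = 1 \mid K \ge 1) = \lambda e^{-\lambda} / (1 - e^{-\lambda})$
  (95.08% at $\lambda = 0.1$);
* expected molecule count $N\lambda$ and expected enriched beads
  $N(1 - e^{-\lambda})$.

These are both predictions for real runs and the oracle the simulator
is validated against. Numerically, `expm1` is used so the forms stay
accurate for $\lambda \to 0$. "Monoclonal" here is defined at the
loading level ($K = 1$); the read-based classifications downstream are
separate observables that are *compared* to this prediction.

## What the simulator emulates — and what it does not

`simulate_phasing_run()` draws, per bead, $K \sim
\mathrm{Poisson}(\texttt{barcode\_cpb})$ uniform random barcodes; each
droplet holds one enriched bead and $M \sim
\mathrm{Poisson}(\texttt{fragment\_cpb})$ fragments from the configured
species mixture; every (fragment, target) amplicon emits a
Poisson-distributed number of read pairs; and every base of both mates
is substituted independently with probability
`substitution_error_rate`. Polyclonal beads emit each read with one of
their barcodes chosen uniformly, modelling a clonal mixture on one bead
without extra parameters. A complete ground truth (bead → barcodes,
droplet → fragments, read → origin) is returned alongside the reads, so
every pipeline stage can be scored against truth.

Defaults are the study conditions: 15 nt barcodes, 0.1 c.p.b. at both
stages, four species at the skewed mixture 0.4/0.3/0.2/0.1, two targets,
and a 0.5% substitution error rate. Two values the protocol does not
pin down numerically were fixed once as field-realistic choices: a mean
of 20 read pairs per amplicon (deep enough that the default filters are
rarely the binding constraint, as in the study's sequencing depth) and
5,000 droplets per simulated run, a desk-scale problem size that still
yields ~475 occupied droplets for stable rates. The tests and examples
state the sizes they use.

Deliberately out of scope: indels and quality-score error profiles
(all comparisons are Hamming-style, as mismatch tolerances are
specified in mismatches), PCR chimeras and recombination, droplet-size
heterogeneity, and the enrichment chemistry itself. Consequently,
passing tests show the *computational* pipeline recovers truth under
substitution noise and Poisson loading; they cannot certify behaviour
under structural artefacts real libraries may contain.

The synthetic reference (`make_reference()`) derives each species from
one random ancestor per target at a configurable per-base divergence
(default 5%, species-level divergence in 16S variable regions), while
holding the first 20 nt fixed across species as the conserved
amplification primer. The conserved prefix is a deliberate design
choice of the generator: read-to-target assignment works by primer
prefix matching, exactly as conserved priming sites flank variable
regions in real 16S amplicons. Two independently mutated copies of an
ancestor differ at an expected $2d(1-d)$ of variable sites, which the
tests verify.

## Barcode clustering

`cluster_barcodes()` implements iterative abundance-seeded grouping:
rank distinct barcodes by read count, let each barcode in rank order
seed a cluster and absorb every lower-ranked unassigned barcode within
`max_mismatch` (default 2), aggregate counts onto the seeds, and repeat
on the seeds until the number of clusters stops changing. Ties in
abundance are broken lexicographically, and a barcode within range of
two seeds joins the higher-ranked one — both rules exist purely to make
the procedure deterministic. Absorption is restricted to the seed's
radius within a pass; the iteration over seeds can still chain merges,
which is intended (it is what "repeat until no decrease" does). The
test-suite checks the implementation against an independently written
naive transcription of the same procedure on random instances, plus
partition/conservation and fixed-point properties.

At the defaults (15 nt barcodes, tolerance 2, errors ≤ 1%), true
barcodes at mutual distance ≥ 5 essentially never merge, and ≥ 99% of
reads land in the cluster seeded by their true barcode; barcodes drawn
uniformly at random from $4^{15}$ are almost surely that far apart.

## Consensus, clonality, classification

Reads of a retained cluster are split by target (primer prefix within 2
mismatches; the primer set is validated to be unambiguous at that
tolerance), filtered (≥ 3 reads per target group, ≥ 5 per cluster —
configurable stand-ins for depth filters whose published values are not
available in the main text), and sub-clustered into variant groups with
the same greedy algorithm at a per-base threshold of 2% of the compared
length. 2% sits between the sequencing error rate (0.5%, which must
collapse into one group) and the inter-species divergence (5%, which
must separate); both sides are tested. The consensus is a positional
majority (ties to the lexicographically smallest base, length = modal
read length) — no multiple alignment, which is consistent only because
the error model is substitution-only. A cluster is monoclonal when
every present target's largest variant group holds ≥ 90% of that
target's reads (again a configurable surrogate for an unpublished
criterion).

Classification replaces a BLAST search against a public database with a
deterministic k-mer containment score against the run's own reference:
score = fraction of the query's distinct 8-mers present in the
reference species' target sequence. The hit list keeps species within
0.05 of the top score; the best call must beat the runner-up by more
than that margin, else the call is "ambiguous". This surrogate is
validated on simulations (100% correct on error-free monoclonal
consensuses, monotone degradation with noise), not against real-data
hit counts, which depend on an external database.

## Phasing statistics

With two targets per cluster, the headline statistics are:

* presence fractions (target 1 only / target 2 only / both);
* observed phasing rate $P_\mathrm{obs}$: among eligible clusters
  (both targets called, neither ambiguous), the fraction whose calls
  agree;
* random match rate $P_\mathrm{rand}$: the mean match fraction after
  uniformly permuting the second target's calls across eligible
  clusters (100 shuffles by default, Monte-Carlo SE reported), which
  converges to the collision probability $\sum_i p_i^2$ of the call
  frequencies — 25% for four even species;
* corrected rate $P_\mathrm{corr} = (P_\mathrm{obs} -
  P_\mathrm{rand})/(1 - P_\mathrm{rand})$, clamped below at zero: the
  estimated fraction of matches not explained by chance. The published
  arithmetic (91.5% observed, 11.9% random → 90.3%) reproduces to
  within 0.1 percentage point from these rounded inputs.

Eligibility decisions that were genuinely open were resolved as
follows. Ambiguous calls are excluded, since a match cannot be
adjudicated. By default the pipeline computes the phasing statistics on
amplification-*monoclonal* clusters (`phasing_on_monoclonal = TRUE`):
a polyclonal cluster's per-target consensus is an arbitrary winner
among founding molecules, so including it mixes a coin-flip into
$P_\mathrm{obs}$; restricting to monoclonal clusters makes
$P_\mathrm{corr}$ a clean estimate of the single-fragment fraction,
which the end-to-end test verifies against ground truth to within 3
percentage points. Setting the flag to `FALSE` reproduces the
unrestricted definition.

`remove_dominant_species()` re-runs the statistics after discarding
every cluster that involves the most abundant species — the correction
used when one species dominates a sample and inflates
$P_\mathrm{rand}$. The hit-list overlap reduction uses $1 - |A \cap B|
/ \mathrm{mean}(|A|, |B|)$ per cluster; since no canonical denominator
exists, `min` and `max` are offered as labelled alternatives.
`depth_subsample()` reruns the pipeline on read subsamples to show how
the both-targets fraction grows with sequencing depth.

Zero-eligible situations (no cluster with both targets, everything
removed with the dominant species, a random match rate of 1) raise a
typed `beadphase_undefined` condition rather than returning a silent
zero; the pipeline catches it and reports `NA`.

## Determinism

Every randomised stage forks its RNG stream from the run seed and a
stage name (`stage_seed()`), so identical configurations give
byte-identical FASTQ, tables and summaries regardless of stage order,
and subsampling or shuffling cannot perturb unrelated stages. The
command-line front end (`inst/cli/beadphase`) exposes `--seed`
everywhere and is covered by byte-identity tests.

## Known limitations

* No indel or chimera handling; real libraries containing either would
  need alignment-based extraction and consensus.
* The k-mer classifier is a small-reference surrogate; it is not a
  replacement for database search when the species set is open.
* Filtering thresholds, the 90% dominance criterion and the 10%
  well-clonality criterion are configurable surrogates for unpublished
  values, and results should be read as conditional on them.
* The shuffle null permutes one target's calls only; joint permutation
  schemes would be needed for more than two targets.
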