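# beadphase

Simulation and analysis of two-stage emulsion bead-barcoding
experiments that phase short amplicons to single DNA molecules.

## The problem

Short-read sequencing loses phase: it cannot tell whether two sequence
variants sat on the same physical DNA molecule. One way to recover
phase at scale is massively parallel bead barcoding: beads are loaded
with degenerate barcode oligonucleotides at ~0.1 copies per bead
(c.p.b.) in a first emulsion, so occupied beads are almost always
uniquely barcoded; in a second emulsion each barcoded bead is paired
with a single genomic fragment and the target regions amplified from it
are coupled to the bead barcode. After sequencing, reads sharing a
barcode ("barcode clusters") should derive from one founding molecule,
so two target regions that classify to the same origin within a cluster
are phased.

beadphase is for people building or evaluating such protocols. It
provides, as testable R functions with a thin command-line front end:

* **Poisson loading expectations** — with loading rate λ (c.p.b.),
  occupancy `1 − e^−λ`, monoclonality among occupied compartments
  `λe^−λ / (1 − e^−λ)`, and the expected molecule/enriched-bead counts.
* **A seeded simulator** of bead libraries, phasing runs and
  well-sorting runs, emitting paired FASTQ plus a complete ground
  truth.
* **Mismatch-tolerant iterative barcode clustering** (rank by
  abundance, absorb within 2 mismatches, iterate on seeds to a fixed
  point), well demultiplexing and handle-based barcode extraction.
* **Amplicon consensus calling** — per-target variant sub-clustering,
  positional majority consensus, monoclonal/polyclonal classification.
* **k-mer containment classification** of consensuses against a small
  reference panel, with explicit ambiguity.
* **Phasing statistics** — observed phasing rate `P_obs`, shuffle-based
  random match rate `P_rand` (chance baseline, → Σp²), corrected rate
  `P_corr = (P_obs − P_rand)/(1 − P_rand)`, dominant-species removal,
  hit-list overlap reduction, and sequencing-depth subsampling.

## Worked example

```r
library(beadphase)

print(loading_model(cpb = 0.1, n_beads = 2.4e6))
#> Poisson loading model: 0.1 c.p.b., 2,400,000 beads
#>   occupancy (enriched fraction): 0.0952
#>   monoclonal fraction of occupied: 0.9508
#>   expected molecules: 240,000
#>   expected enriched beads: 228,390

ref <- make_reference(4, divergence = 0.05, seed = 1)  # 4-species panel
cfg <- sim_config(seed = 7)   # 5,000 droplets, 0.1 c.p.b., 0.5% errors
run <- simulate_phasing_run(cfg, ref)
res <- run_phasing_pipeline(run)
print(res)
#> Phasing pipeline result: 478 clusters passed filtering
#>   target presence: 16S.1 only 0.0%, 16S.2 only 0.0%, both 100.0%
#>   monoclonal amplification: 94.1%
#>   observed phasing rate:  100.0% (450 eligible clusters)
#>   random match rate:      29.2% (+/- 0.20% SE)
#>   corrected phasing rate: 100.0%

truth_single_fragment_fraction(run, res)
#> [1] 0.9888889 ...
```

Reading the numbers: ~9.5% of the 5,000 droplets received a fragment,
giving 478 clusters deep enough to pass filtering. 94.1% of clusters
amplified monoclonally, close to the Poisson prediction of 95.1% at
0.1 c.p.b. (two same-species fragments in one droplet look monoclonal,
two different-species fragments polyclonal). Because the simulation is
deep, every cluster carries both targets. The observed phasing rate of
100% must be discounted by the 29.2% chance-match baseline (the skewed
0.4/0.3/0.2/0.1 mixture collides more often than the 25% of an even
four-species mix); the corrected rate, 100%, agrees with the
ground-truth single-fragment fraction of 98.9% within sampling error.

The same stages run from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "beadphase", package = "beadphase"))')
$CLI model --cpb 0.1 --n-beads 2400000 --json
$CLI simulate --out sim --seed 7
$CLI phase --fastq1 sim/reads_1.fastq --fastq2 sim/reads_2.fastq \
           --reference sim/reference.fasta --out phased --seed 7
```

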