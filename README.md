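# structmotif

Structure-based prediction of transcription-factor (TF) DNA-binding motifs.

Most TFs have no experimentally determined binding motif, but many have a
co-crystal structure with DNA — or can be modeled onto one. structmotif turns
such a structure into a motif with no binding-assay data: it threads every
possible DNA k-mer onto the fixed sugar-phosphate backbone of the complex,
scores each threaded interface with a knowledge-based potential, converts the
scores into relative binding affinities, and summarises the high-affinity
sequences as a position weight matrix (PWM). Downstream modules compare and
cluster motifs with decoy-calibrated similarity Z-scores and scan promoter
sequences for putative target genes. It is aimed at structural and regulatory
bioinformaticians who have complex structures (PDB format) and want motifs,
motif clusters, or ranked target-gene lists.

## The method in brief

Given a curated complex with `k` protein-contacting base pairs
(trimmed at a 4.5 Å heavy-atom contact cutoff, `k <= 9`):

1. **Threading.** Each of the 4^k duplex sequences is built by replacing the
   bases on both strands; the anchor triad (glycosidic nitrogen plus its two
   bonded ring carbons) is retained to preserve base direction and plane, and
   an idealized base is superposed onto it by a Kabsch fit. Backbone and
   protein stay untouched.
2. **Scoring.** A distance-dependent, residue-specific contact potential
   (10 Å cutoff; one 3 Å bin plus seven 1 Å bins) assigns each model a raw
   interface score `S_RV = sum of e(type_p, type_d, bin)`, with energies
   trained as log-odds `-ln((N + sigma)/(N_exp + sigma))` over a curated
   structure set.
3. **Affinities.** Scores are min-max normalized (`S_norm`, 0 = strongest
   binder) and mapped to relative affinities
   `K_a = exp(-A/(k_B T) * S_norm)` with `A = 4.74` kcal/mol, `T = 298` K.
4. **Motif.** Sequences with `K_a >= 0.25` (at most 300) are weighted by
   `K_a` to give the PWM columns.
5. **Comparison.** Motif pairs get a best sliding Fisher–Irwin exact
   p-value (consensus matches vs. the 1-in-4 random expectation, both
   strands), calibrated to a Z-score against a non-redundant decoy motif
   set; `Z >= 2` marks similarity at 95% confidence. Distances
   `D = |Z - 10| / 11.1` feed UPGMA clustering.
6. **Scanning.** Promoters (−1500/+500 around each TSS) are scanned with
   frequency-sum match scores and exact p-values from a convolution null;
   hits at `p <= 1e-4` rank target genes by best score.

A fixture module generates synthetic TF–DNA complexes with controlled
contacts, planted potentials with a known optimal k-mer, random PWM sets and
toy genomes with planted sites, so the full pipeline is testable offline.

## Worked example

```r
library(structmotif)

# a synthetic complex whose pseudo-protein touches base pairs 4-6,
# and a potential that favors the k-mer GCT at those positions
cplx <- make_toy_complex(n_bp = 9, contacts = 4:6, seed = 11)
cc   <- curate_complex(cplx)
cc
#> <curated_complex> toy_CCTATAATC_seed11: k=3 (ATA), 15 protein / 123 DNA / 1 water atoms

pot    <- make_planted_potential("GCT")
scores <- score_all_kmers(cc, pot)        # threads and scores all 64 k-mers
affin  <- normalize_scores(scores)
sites  <- select_sites(affin)
sites
#>   kmer s_rv s_norm k_a
#> 1  GCT  -24      0   1

motif <- build_pwm(sites, name = "toy_TF")
motif
#> <pwm> toy_TF (3 columns), consensus GCT
#>   [,1] [,2] [,3]
#> A    0    0    0
#> C    0    1    0
#> G    1    0    0
#> T    0    0    1
```

The planted sequence GCT gets the lowest raw score (−24), hence normalized
score 0 and relative affinity 1; it is the only sequence above the 0.25
affinity cutoff, so the PWM is its point-mass motif. Comparing the
prediction against the planted truth calibrates to a significant Z:

```r
decoys <- build_decoy_set(make_random_pwms(30, 3, seed = 2))
truth  <- pwm(matrix(c(0,0,1,0, 0,1,0,0, 0,0,0,1), 4, 3,
                     dimnames = list(c("A","C","G","T"))), name = "planted")
cmp <- fisher_slide_compare(motif, truth)
similarity_zscore(cmp, motif, decoys)
#> [1] 3.03939     # Z >= 2: similar at 95% confidence
```

A thin command-line front end covering curation, threading, training,
motif building, comparison, clustering and scanning is installed at
`system.file("scripts", "structmotif", package = "structmotif")`.

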