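---
title: "Structure-based motif prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based motif prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmotif)
```

# The problem

A transcription factor (TF) selects its genomic binding sites through the
physical chemistry of its protein-DNA interface. When a co-crystal structure
of the TF bound to DNA exists (or a reliable model of one), the binding
preference can be predicted without any binding-assay data: replace the bases
of the bound DNA with every possible sequence, score each hypothetical complex
with an energy function, and summarise the best-scoring sequences as a
position weight matrix (PWM). structmotif implements that pipeline: curation
of the complex, exhaustive base threading, a knowledge-based scoring
potential, affinity-weighted PWM construction, decoy-calibrated motif
comparison and clustering, and promoter scanning for putative target genes.

# Curation of TF-DNA complexes

`curate_complex()` applies the structural filters before any modeling:

* **Resolution**: structures worse than 2.5 Å are rejected; at lower
  resolution the atomic detail the potential depends on is unreliable.
* **DNA trimming**: only the part of the DNA in contact with the protein is
  kept, using a 4.5 Å heavy-atom distance cutoff (boundary inclusive, so a
  pair at exactly 4.5 Å counts). A contact with either strand marks the base
  *pair*; the retained stretch is made contiguous, because a duplex with
  interior gaps cannot be threaded. The stretch length is the motif length
  *k*.
* **k ≤ 9**: exhaustive threading enumerates $4^k$ sequences; $4^9 =
  262{,}144$ is the practical ceiling.
* **Base sanity**: any retained base that is non-canonical (including uracil)
  or missing base heavy atoms rejects the complex.
* **Interface waters**: crystal waters within the contact cutoff of both
  protein and DNA frequently mediate protein-DNA hydrogen bonds; they are
  carried through threading untouched (they are never scored).

One open point in the trimming definition is whether "contact" should count
only base atoms or any DNA atom. We use *all* DNA heavy atoms (base and
backbone), matching the any-atomic-pair phrasing of the contact rule; for
real structures this choice can change *k*, which is why it is centralised in
`contacting_positions()`.

All protein chains in the file are treated as one TF unit. Obligate
homodimers therefore work out of the box; splitting chains is left to file
preparation rather than automated biological-unit reconstruction.

# Base threading

`swap_bases()` rebuilds the bound DNA for an arbitrary k-mer while leaving
the sugar-phosphate backbone, the protein and the waters bit-identical. At
each position, the **anchor triad** — the glycosidic nitrogen and its two
bonded ring carbons (N9-C8-C4 for purines, N1-C6-C2 for pyrimidines) — is
retained at its crystallographic coordinates; it fixes the direction and
plane of the base. The idealized replacement base (planar heavy-atom
geometry frozen into the package from standard chemical-component tables) is
superposed onto the retained triad by a proper-rotation Kabsch fit and
supplies every base atom beyond the triad. Purine/pyrimidine swaps map the
triads element-wise (N9↔N1, C8↔C6, C4↔C2), preserving the glycosidic
direction. Whether the C1' sugar atom should join the fit is not settled;
we fit base-frame atoms only, since including a backbone atom would let
backbone strain tilt the new base.

The optional relaxation step, `relax_clashes()`, is a deliberately simple
soft-sphere minimizer: steepest descent with backtracking on
$\sum \max(0, r_i + r_j - d_{ij})^2$ over clashing pairs, moving only the
rebuilt base atoms, for at most 100 iterations (energy is monotone
non-increasing; a clash-free model is returned unchanged). It is a stand-in
for a force-field minimization, not an approximation of one — full
vacuum minimization contributes only a few percent to prediction quality
in this setting, so the default pipeline does not relax at all, and a hook
(`relax = TRUE` in `score_all_kmers()`) turns the stand-in on.

# The knowledge-based potential

`train_potential()` builds a distance-dependent, residue-specific contact
potential from a set of curated complexes. Protein-DNA heavy-atom pairs
within 10 Å are typed as *(residue type, protein atom name) ×
(base, base atom name)* and binned by distance: one 3 Å first bin, then
seven 1 Å bins — 8 bins in total. The wide first bin pools the sparse
short-range contacts; beyond 10 Å pairs carry no signal. Energies are
log-odds against a factorized reference state,

$$ e(t_p, t_d, b) \;=\; -\ln \frac{N(t_p, t_d, b) + \sigma}
   {N_{\exp}(t_p, t_d, b) + \sigma}, \qquad
   N_{\exp} = N(t_p, t_d, \cdot)\,\frac{N(\cdot, \cdot, b)}{N(\cdot,\cdot,\cdot)}, $$

with pseudocount $\sigma = 1$: a pair type seen more often at a distance
than its marginals predict scores favorably (negative). Pair types never
observed keep energy 0 (the pseudocount limit), so scoring degrades
gracefully on unseen chemistry. The published potential this models derives
from a different reference-state construction whose details live outside
the pipeline description; the factorized reference is isolated behind the
`pair_potential` object so an alternative can be swapped in without touching
scoring. Per-(residue, atom-name) typing is our reading of
"residue-specific"; pooling atom types across residues is the main
alternative and would only change the table layout.

The interface score of a threaded model is the plain sum
$S_{RV} = \sum e(t_p, t_d, b(d))$ over in-range pairs
(`score_interface()`). Waters are excluded from the sum. Neighbor search is
a vectorized all-pairs distance computation rather than a spatial grid: the
interfaces in scope are hundreds of atoms per side, where the grid's
complexity buys nothing; the scoring contract is bit-identity with a
double-loop oracle, which the tests enforce.

A `self_swapped = TRUE` training flag rethreads each training complex with
its own native sequence first, so that training sees exactly the idealized
base geometry that scoring of threaded models sees.

# From scores to a motif

Raw scores are min-max normalized over the full enumeration,
$S_{norm} = (S_{RV} - S^{lowest}_{RV})/(S^{highest}_{RV} - S^{lowest}_{RV})$,
so 0 marks the strongest predicted binder and 1 the weakest
(`normalize_scores()`; a table with all scores equal carries no specificity
signal and is rejected rather than silently emitting a flat motif).
Normalized scores become relative affinities through

$$ K_a = e^{-\frac{A}{k_B T} S_{norm}}, $$

with $A = 4.74$ kcal/mol at $T = 298$ K and
$k_B = 1.9872041 \times 10^{-3}$ kcal/(mol·K) fixed so the slope
$A/(k_B T) \approx 8.004$ is reproducible. Sites with $K_a \ge \gamma =
0.25$ are selected — the cutoff is taken inclusive; the source phrasing
("above") does not settle the boundary, and inclusivity makes the selected
set a closed, deterministic object — capped at the 300 best, with boundary
ties broken lexicographically (`select_sites()`). The PWM weighs each
selected k-mer by its $K_a$:
$f(pos, b) = \sum_{sites, b} K_a / \sum_{sites} K_a$ (`build_pwm()`).
Threading enumerates k-mers at fixed positions, so all sites are already in
register and no alignment step is needed. PWMs read and write JASPAR PFM
and MEME minimal dialects (`read_jaspar()`, `write_meme()`, ...); counts
inputs are normalized to frequencies.

# Motif comparison and clustering

`fisher_slide_compare()` slides one motif over the other (both strands of
the slider), and at each alignment with at least `min_overlap = 3` columns
compares the per-column consensus strings: with $m$ matches out of $L$
columns, the one-sided Fisher-Irwin exact p-value of the table
$[m, L-m; \mathrm{round}(L/4), L-\mathrm{round}(L/4)]$ measures surprise
against the 1-in-4 random match expectation. The minimum over alignments
wins. How to turn two frequency matrices into one 2×2 table is genuinely
underdetermined; the consensus-match construction is exact, parameter-free
and monotone in similarity, and it sits behind the function boundary so a
column-count contingency variant can replace it. `min_overlap = 3` keeps
3 bp motifs comparable — some real TF motifs are that short.

Best p-values depend on motif length and on the best-alignment selection, so
they are calibrated to Z-scores against a non-redundant decoy motif set
(`build_decoy_set()`: greedy in input order, rejecting any candidate whose
best p against a retained decoy falls below 0.05). For a query-target pair,
$x = -\log_{10} p$ is standardized by the mean and standard deviation of the
query's best-p values against each decoy, computed with *exactly the same
sliding search*, and capped at 10. An alternative that restricts decoy
alignments to the query-target overlap length is available
(`overlap =` argument) but is not the default: the query-target statistic is
a best-over-all-alignments maximum, and referencing it against a null built
from only the equal-overlap alignments leaves the selection effect
uncancelled — measured on random-PWM pairs it yields a ~18% false-positive
rate at $Z \ge 2$, versus ~2% for the matched-search default, against a
calibration target of at most 8%. $-\log_{10} p$ is used because the decoy
distribution is roughly normal on that scale.

Z-scores map to tree distances by $D = |Z - 10|/11.1$ (10 = the cap,
11.1 = the working Z range, so $Z \in [-1.1, 10]$ maps onto $[0, 1]$);
`upgma_tree()` clusters the distance matrix by unweighted arithmetic-mean
linkage with node heights at half the merge distance, and `cut_clusters()`
cuts at the height corresponding to $Z = 2$ — with these conventions "merged
below the cut" coincides exactly with "pairwise distance at most $D(Z=2)$".
`benchmark_success()` reports the fraction of (predicted, experimental)
motif pairs reaching $Z \ge 2$, the 95%-confidence similarity criterion.

# Promoter scanning

Promoters are the window from 1500 bp upstream to 500 bp downstream of a
TSS, strand-aware and reverse-complemented for minus-strand genes so the
sequence reads 5'→3' relative to the gene (`extract_promoters()`; windows
clipped at contig edges are flagged). Coordinates are 0-based half-open
internally; BED is read natively and GFF converted at the parser boundary.

The scanner scores a window by the sum of the PWM frequencies of its
letters — the frequency-sum match score; a log-odds variant is the usual
alternative but the frequency-sum form is the one this pipeline is defined
with. P-values come from the exact null distribution of that score under an
iid background (default: the scanned promoter set's own base composition),
computed by per-column convolution on a discrete score grid of $10^{-4}$
(`score_distribution()`); scanned scores are rounded to the same grid, so
the p-value lookup is exact on the grid rather than approximate off it.
Windows containing ambiguous bases are skipped. Hits at $p \le 10^{-4}$ are
reported with no multiple-testing correction — the fixed per-window
threshold is part of the method definition. Genes collapse over their
promoters and strands by best hit score (`rank_targets()`), with ties broken
by p-value and then gene id.

# The fixture generator

Real TF-DNA structures cannot ship with the package, so `make_toy_complex()`
builds synthetic complexes with *controlled* ground truth: full heavy-atom
planar bases on a regular helix (36° twist, glycosidic nitrogens at 9 Å
radius), a compact synthetic sugar-phosphate layout shared by all four
nucleotides, and a deliberately stretched 7 Å rise. The stretch is the point:
with the true ~3.4 Å stacking rise, any probe close enough to one base's
first distance bin is inside the 4.5 Å contact shell of its neighbors, and
contact bookkeeping — the only thing the potential sees — becomes
uncontrollable. The complementary strand is a radially displaced copy, which
keeps strand pairing unambiguous without modeling base-pairing geometry.
One five-atom pseudo-protein residue sits above each requested contact
position (its CB 2.6 Å over the swap-invariant glycosidic nitrogen, i.e.
inside the first potential bin for every base identity), with a distinct
amino-acid type per contact in contact order. `make_planted_potential()`
keys first-bin rewards on those residue types and the planted base's atoms,
which provably makes the planted k-mer the unique raw-score optimum on a
contiguous-contact toy complex.

What the toy complexes do *not* emulate: base-pairing and stacking
geometry, grooves, DNA shape readout, backbone covalent structure, water
networks, side-chain packing. Tests passing on these fixtures certify the
pipeline's bookkeeping, scoring algebra and calibration — not predictive
accuracy on crystallographic structures, which depends on training-set
coverage and model quality.

`make_random_pwms()` draws Dirichlet-style columns (gamma shape
$1/\mathrm{sharpness}$; underflowed all-zero columns take the correct
$\alpha \to 0$ limit of a random point mass). `make_toy_genome()` plants
motif words at recorded promoter offsets and strands on a random-background
chromosome and returns the truth table alongside FASTA/BED outputs. Every
fixture is byte-reproducible from its seed.

# Numerical choices and degenerate inputs

* Distance bins are half-open, $[0,3), [3,4), \dots, [9,10)$; a pair at
  exactly the 10 Å cutoff is not scored; a contact at exactly 4.5 Å is.
* Kabsch fits reject collinear triads and never return reflections.
* All-equal score tables, empty binding-site sets, zero-variance decoy
  calibrations and asymmetric distance matrices raise informative errors
  rather than producing silent garbage.
* Consensus ties resolve to the lexicographically first base; site-selection
  boundary ties resolve lexicographically by k-mer; UPGMA ties follow
  the agglomeration order of average-linkage `hclust`.
* The score grid ($10^{-4}$) bounds the p-value discretization error; both
  the null distribution and the scanned scores round to the same grid.

# Problem sizes used in the test suite

The suite exercises the pipeline at sizes a laptop handles in about three
minutes total: planted-motif recovery over 20 seeds at $k=3$ (64 threaded
models each), score-oracle agreement on 50 random fixtures, exhaustive
Fisher-table checks for all alignments up to $L = 12$, UPGMA cross-checks on
random 8×8 matrices, Monte-Carlo validation of exact scan p-values at
$10^5$ draws, and Z-score false-positive calibration on 1000 random motif
pairs against a 106-motif decoy set.

# Known limitations

* The shipped potential machinery reproduces the *construction*, not the
  published table values: the original training corpus of 171 curated
  complexes is not redistributable, so numeric energies depend on whatever
  training set the user supplies.
* Homology modeling of the TF-DNA complex is out of scope by design: the
  pipeline consumes an existing complex structure. `swap_bases()` is the
  documented hook where an external modeling adapter would attach.
* Threading keeps the backbone rigid; sequence-dependent DNA deformation
  (shape readout) is invisible to the score.
* The greedy sequence-identity clustering used for redundancy removal is a
  stand-in for cd-hit's word-filter algorithm; on the small curated sets in
  scope the difference is immaterial.
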