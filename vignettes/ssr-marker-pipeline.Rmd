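---
title: "Genome-wide SSR marker development and diversity analysis with ssrkit"
author: "ssrkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide SSR marker development and diversity analysis with ssrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
library(GenomicRanges)
```

# Scope

`ssrkit` implements a complete marker-development pipeline for simple
sequence repeats (SSRs, microsatellites): mining perfect repeats from a
scaffold-level genome assembly, classifying their genomic context against
GFF3 gene models, designing locus-specific PCR primer pairs, anchoring
scaffolds to a genetic map, naming markers, and analysing codominant SSR
genotypes — per-locus diversity statistics, similarity-based UPGMA
clustering, and model-based population clustering with Evanno delta-K
model selection. Every stage runs on synthetic data built by the package
itself, so the whole pipeline is testable without downloading a genome.

# Repeat detection

A perfect SSR is an uninterrupted tandem repetition of a 1–6 bp motif. The
scanner reports every **maximal** perfect tract: one that cannot be
extended by even a partial repeat unit on either side. Detection is gated
by per-class minimum repeat numbers — 12, 8, 5, 5, 5 and 5 full units for
mono- through hexanucleotide motifs — the conventional thresholds for
genomic SSR mining. Only full units are counted: a trailing partial unit
terminates the tract, so a run `(AGC)5AG` is reported as five repeats.

Three normalisations make tracts comparable:

* **Minimal period.** A poly-A run is a mononucleotide repeat, never
  `(AA)n`; a motif must be primitive (not a tandem power of a shorter
  unit). Since every reported tract spans at least two units, the
  Fine–Wilf periodicity argument guarantees that primitivity of the
  leading motif is equivalent to the tract having that minimal period.
* **Canonical motif classes.** Motifs are equivalent under cyclic
  rotation and reverse complement (`AG` = `GA` = `CT` = `TC`); the class
  representative is the lexicographically smallest member. There are 2
  mono, 4 di and 10 tri classes; the enumeration is verified exhaustively
  in the tests.
* **N handling.** Assembly gaps and ambiguous bases never belong to a
  tract; no IUPAC expansion is attempted.

Overlapping maximal tracts of different periods (possible at tract
borders) are all reported and then flagged **compound**: any two tracts
whose gap is at most `compoundGap` bases (default 0, i.e. abutting or
overlapping) are flagged, transitively along chains. Compound loci are
excluded from primer design. The gap default is deliberately
conservative; it is a configuration knob because different mining tools
treat interrupted repeats differently.

The scanner core is compiled (Rcpp) and linear-time per period; the test
suite checks it against an independent regex-backreference brute-force
oracle on random sequences with planted, deliberately messy tandem
arrays.

# Genomic context

Each locus receives exactly one context label against the gene models:
coding exon > 5' UTR > 3' UTR > intron > flanking categories >
intergenic. A single base of overlap suffices; the priority order
resolves loci that touch several features (the category counts published
for such surveys are disjoint but the precedence is rarely stated, so it
is fixed here explicitly). Flanks are strand-aware windows of `flank`
bases (default 1000): upstream of the transcription start and downstream
of the transcription **termination** site — reading "downstream" as
downstream of the start site would duplicate the gene body, so the
termination-site reading is used. A locus upstream of one gene and
downstream of another within both windows is `between_genes_1kb`.
`geneIds` lists every associated gene (sorted, comma-separated) and is
empty exactly for intergenic loci.

# Primer design

The design stage replaces an external primer-design program with a
deterministic exhaustive search, because published constraint boxes
rarely include the program's internal penalty weights. The constraint box
(all defaults changeable via `designConstraints()`):

| parameter | default | units |
|---|---|---|
| primer length | 18–28, optimum 20 | bases |
| product size | 100–300 | bases |
| melting temperature | 55–65, optimum 60 | °C |
| pair Tm difference | ≤ 1 | °C |
| homopolymer run | < 5 | bases |
| self reverse-complement stretch | < 8 | bases |

Melting temperatures come from the unified nearest-neighbor
thermodynamic parameter set (duplex initiation terms, 50 mM monovalent
salt entropy correction, 50 nM total oligo concentration, symmetry
correction for self-complementary oligos). Among all candidate pairs
whose product contains the full repeat tract, the search minimises

```
|lenF − 20| + |lenR − 20| + |TmF − 60| + |TmR − 60| + |TmF − TmR|
```

with deterministic tie-breaking (leftmost then shortest forward primer,
then leftmost then shortest reverse). The last two sequence-quality
filters are not part of classical constraint boxes; they are added for
realism and can be disabled.

The annealing temperature is reported as `round(min(TmF, TmR)) − 3`
clipped to [50, 65] °C — a standard bench rule; published Ta values for
legacy marker panels cannot generally be reverse-engineered, so this rule
is a documented stand-in.

**Cross-pair uniqueness.** After design, any primer sequence occurring in
more than one pair marks *all* involved pairs non-unique, and those pairs
are dropped from the retained marker set. This is the strictest reading
of "delete primers with more than one copy so each pair amplifies a
single locus": deleting whole pairs, not single primers. Retention
bookkeeping (`retentionSummary()`) partitions the input loci into
designed / compound-skipped / no-valid-pair / dedup-removed / retained.

# Map anchoring and marker names

A scaffold's genetic position is the arithmetic mean cM of its mapped
SNPs. Scaffolds whose SNPs lie on one linkage group anchor there
(`single`); scaffolds spanning 2–3 groups are reported `ambiguous` with
the candidate set (mirroring the convention of reporting "2–3 linkage
groups"); more than 3 groups, or no mapped SNP, is `unknown`.

Marker names follow `Pb<motif length>L<linkage group|U>N<serial>`, e.g.
`Pb3L11N5758` (trinucleotide, LG 11) or `Pb2LUN25693` (unplaced
dinucleotide). Published tables show varying zero-padding and do not
state the numbering order, so the package fixes its own deterministic
scheme: serials run within each motif-length series ordered by linkage
group, genetic position, then physical position, unplaced markers last;
padding is the series' natural width (minimum 4). Names round-trip
through `parseMarkerName()`.

# Diversity statistics

For a codominant locus with allele frequencies $p_i$ estimated from all
non-missing calls (two gene copies per individual):

* Na, Ng — numbers of distinct alleles and genotypes;
* major allele frequency $\max_i p_i$;
* observed heterozygosity $H_o$ — fraction of heterozygous individuals;
* expected heterozygosity (Nei's gene diversity)
  $H_e = 1 - \sum_i p_i^2$, with the small-sample factor $2n/(2n-1)$ as
  an option (`unbiased = TRUE`) since reports rarely state which form
  was used;
* polymorphism information content, codominant form
  $PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2$.

$PIC \le H_e \le 1 - 1/Na$ always, with equality at equifrequent
alleles; the tests verify the statistics against brute-force enumeration
on small matrices and against these closed forms.

Similarity between individuals treats genotypes as binary allele-presence
bands (a heterozygote shows two bands, a homozygote one) and applies the
Dice coefficient $2a/(2a+b+c)$, the conventional codominant treatment
when the original coefficient is unstated; simple matching is available
as an option. Loci missing in either member of a pair are excluded
pairwise; per-locus statistics instead drop missing individuals per
locus.

`upgmaTree()` agglomerates $d = 1 - s$ with size-weighted averaging
(UPGMA proper). Tie-breaking is explicit — the smallest pair of cluster
indices in formation order — so results are deterministic and label
permutations give isomorphic trees. The output is ultrametric: every
leaf is equidistant from the root and the cophenetic matrix of the tree
reproduces an ultrametric input exactly (both properties are tested;
`stats::hclust(method = "average")` serves as an independent
cross-check, never as the implementation).

# Population structure

Full Bayesian MCMC clustering is out of scope; the package substitutes a
documented EM mixture with the same no-admixture likelihood: each
individual belongs to one of $K$ populations and its two allele copies
per locus are independent draws from that population's allele
frequencies. EM alternates soft assignment (responsibilities) with
frequency/mixing updates; the reported log-likelihood is the allele-copy
likelihood (the constant heterozygote pairing factor is omitted) and is
non-decreasing over iterations. Missing calls contribute nothing.

The Evanno statistics are computed exactly from replicate run
log-likelihoods: $L'(K)$ the first difference of the per-K means,
$|L''(K)|$ the absolute second difference, and
$\Delta K = |L''(K)| / sd(K)$, defined for interior K with positive
replicate spread (a zero spread yields NA at that K, not an error). The
peak of $\Delta K$ suggests the number of populations.

Two numerical choices matter and were settled deliberately:

* **Restarts.** Each fit takes the best of `nStarts = 3` random
  initialisations. Mixture likelihoods are multimodal; without restarts,
  replicate fits at the true K frequently land in different local optima,
  inflating $sd(K)$ and flattening the $\Delta K$ peak. With a small
  number of restarts, replicates concentrate on the dominant optimum
  while the finite convergence tolerance (`tol = 1e-6` on the
  log-likelihood) leaves genuine run-to-run spread, keeping $\Delta K$
  well defined — the EM analog of the run-to-run noise that MCMC
  estimates carry naturally.
* **Reproducibility.** All replicate and restart seeds derive
  deterministically from one master seed by counter hashing, so a whole
  `inferStructure()` sweep is reproducible from a single integer.

`inferStructure()` fits K = 1..Kmax with `replicates = 10` runs per K
(the customary replicate count), reports the Evanno table, and refits the
best-likelihood model at the $\Delta K$ peak. When no interior K has a
defined $\Delta K$, or the maximum is below 10, the result is flagged
`lowSignal`: on panmictic data the second differences are noise-scale, so
$\Delta K$ stays small, whereas genuine two-population structure produces
peaks orders of magnitude larger; the threshold of 10 separates these
regimes comfortably and is exposed as a parameter. Nested substructure is
probed the standard way: re-running the inference inside one cluster's
individuals.

# The synthetic data generators

`simulateGenome()` builds a uniform-composition background guaranteed by
rejection sampling to contain no SSR at the scan thresholds, plants the
requested tracts verbatim, and fixes the junction bases so a planted
tract cannot extend by even a partial unit. The returned truth table is
therefore exactly recoverable by the scanner — a clean positive and
negative control in one object.

`simulateGenotypes()` emulates a diversity panel of 44 individuals typed
at 18 codominant loci with 5–15 alleles per locus: two diverged
populations of 14 and 29 individuals plus one outlier accession
(44 in total; at K = 2 the outlier sides with the first population,
giving a 15/29 split). Its defaults are the package's study conditions:

* per locus, population frequencies are Dirichlet draws around a shared
  base vector with total concentration $A/\mathrm{divergence}$;
  `divergence = 1.5` gives $F_{ST} \approx 0.13$, a realistic value for
  the split between occidental and oriental cultivar groups of a
  self-incompatible fruit tree;
* the outlier draws each allele copy from a private allele (probability
  0.7) or from frequencies diverged from population 1 by three times the
  population divergence — a distinct, semi-wild-like germplasm accession
  that is nearer the first population than the second yet basal to both
  in a cluster analysis;
* allele states are emitted as plausible fragment sizes on a 2 bp ladder
  within 100–300 bp, matching the data shapes of capillary genotyping;
* 2% of cells are missing at random (both alleles together, never
  half-called); a locus is redrawn if fewer than 5 alleles segregate.

What the generator does **not** emulate: stepwise mutation along
pedigrees, linkage between loci, null alleles, allele-calling error,
admixed individuals, and within-population substructure. Passing tests
therefore demonstrate correctness of the algorithms under
Hardy–Weinberg-style sampling with known truth — not robustness to the
full messiness of real genotyping data.

# Problem sizes and tolerances

The test suite and the acceptance script use sizes chosen to exercise
every code path while staying quick: scanner–oracle equivalence on one
hundred 50 kb sequences with planted arrays; primer design on a handful
of planted loci per run; diversity brute-force checks on matrices of at
most 6 individuals; and fifty independently seeded 44 × 18 panels for the
stochastic recovery properties (UPGMA outlier placement and the
$\Delta K$ peak at K = 2, each required in at least 90% of trials).
Exact quantities (scanner output, bookkeeping identities, closed-form
statistics) are compared exactly or at numerical tolerance (1e-9 for Tm
against the independent oracle; 1e-10 for cophenetic round-trips); EM
monotonicity allows 1e-8 of floating-point slack.

# Known limitations

* Imperfect (interrupted) repeats and minisatellites (period > 6) are
  out of scope; compound loci are detected but never get primers.
* The Tm model is a single published nearest-neighbor parameterisation
  at fixed salt and oligo concentration; no divalent-cation or dNTP
  corrections.
* Primer search considers each locus independently — no multiplex
  compatibility or cross-pair dimer thermodynamics beyond exact-sequence
  deduplication.
* The mixture model has no admixture component and assumes
  Hardy–Weinberg within populations; the Evanno construction cannot, by
  design, evaluate K = 1 (it needs an interior K), which is why the
  low-signal flag exists.
* Anchoring transfers a scaffold-level mean position to every locus on
  the scaffold; within-scaffold recombination is invisible.
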