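---
title: "Methods: somatic evolution from multi-sample tumour/normal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic evolution from multi-sample tumour/normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somafoot)
```

somafoot reconstructs the somatic evolution of neoplasms and their
surrounding normal tissue from per-site read counts of many samples of one
individual - typically blood, histologically normal kidney and one or more
tumours, each whole-genome sequenced to moderate depth (50-80x). This
vignette describes each statistical component, the assumptions behind it,
the tunable parameters, and the design choices made where the design was
genuinely open. Because the patient data such analyses run on are
controlled-access, the package includes a synthetic-cohort generator with
full truth labels; the closing sections explain exactly what that generator
does and does not emulate, and therefore what the passing test suite does
and does not demonstrate about real data.

## Germline versus somatic classification

For each variant, read counts are pooled across the normal (blood and
kidney) samples of the individual, restricted to samples whose local copy
number at the site equals the expected normal ploidy (two on autosomes, one
on male sex chromosomes). A one-sided exact binomial test compares the
pooled alt count against the germline heterozygous null: success
probability 0.5, or 0.95 on male sex chromosomes, where a hemizygous
germline variant should be supported by essentially every read and 0.95
absorbs residual error. The p-value is the lower tail
\(P(X \le \text{alt} \mid \text{depth}, p_0)\); the null is rejected - the
variant is somatic - when \(p < \alpha\) with \(\alpha = 10^{-5}\), the
same stringency constant that defines the somatic alternative. Sites with
no copy-number-eligible normal sample are reported `unresolved` rather than
forced through an incorrect null.

Read-level filters accompany the test for burden analyses: proximity to an
indel (within 10 bp), at least 3 supporting reads in blood, consistently
low depth (below 10 in every sample), and a high-quality read fraction
(`hq_alt/alt`) of at most 0.75 in any sample with supporting reads. The
filters commute; each failure is recorded as a reason code so downstream
stages can choose which reasons disqualify (the blood-read filter, for
instance, belongs to somatic burden counting, not to presence calling).

## The beta-binomial artifact model

Sequencing artifacts recur at the same loci across unrelated individuals.
A reference panel of normal samples provides, per locus, a beta-binomial
error null parameterised by the mean error rate \(\mu\) and overdispersion
\(\rho\) (with \(\rho \to 0\) recovering the binomial). \(\mu\) is a
pseudocount-stabilised pooled estimate,
\((\sum \text{alt} + 0.1)/(\sum \text{depth} + 0.2)\); \(\rho\) is fitted
by maximum likelihood on a log-spaced grid over \([10^{-6}, 0.89]\) with
\(\mu\) held fixed. One numerical subtlety: at a clean site with no alt
reads the profile likelihood is weakly *increasing* in \(\rho\)
(overdispersion concentrates mass at zero), so raw maximisation would
assign maximal overdispersion to sites that show none and deflate
sensitivity there. The estimator therefore keeps the minimal-overdispersion
model unless some grid value beats it by at least 0.5 log-likelihood units;
genuinely noisy sites have sharply peaked profiles and take the true
maximiser.

Per-sample presence is then a one-sided upper-tail test
\(P(X \ge \text{alt})\) under the site's null, computed by direct summation
of the probability mass. P-values are corrected with Benjamini-Hochberg
jointly across all variant-by-sample tests of one patient - one coherent
error budget per individual (a per-sample family is available via
`family = "sample"`) - and presence is called at \(q < 0.005\). Sites
absent from the panel fall back to a configurable global model
(\(\mu = 10^{-3}\), \(\rho = 10^{-2}\)) with a warning.

## Clonal expansions in normal kidney

Clonal expansions in histologically normal kidney are read out as two
disjoint variant sets: *precursor* mutations, present in at least one
tumour and in kidney but absent from blood (fewer than two supporting reads
in every blood sample), and *kidney-private* mutations, present in kidney,
absent from blood, and not called in any tumour. "Present in kidney" uses
the beta-binomial call by default - the statistical replacement for manual
read inspection - with a minimum-read override available. Each clone is
summarised by its mutation count, its largest kidney VAF, and a cell
fraction estimated as twice the median kidney VAF at diploid sites. A
per-variant review table with all counts is emitted for optional human
curation.

## The mosaic LOH screen

Within a tumour-defined LOH region (the widest tumour segment with minor
copy number zero, by default), informative sites are candidate germline
heterozygous positions at which the tumour is effectively homozygous:
pooled tumour VAF at or above 0.9, or at or below 0.1, at pooled depth of
at least 10. The allele retained by the tumour defines the orientation.
Heterozygosity is judged from pooled blood VAF in \([0.3, 0.7]\) when blood
is unaffected; for suspected germline LOH a `known_het` list must be
supplied instead (array or caller genotypes in a real study). Each normal
sample's counts are converted to retained-allele VAFs and averaged; a mean
strictly above 0.5 flags the sample, and the LOH cell fraction is solved
from the mean under each mode:

* copy-neutral: mean \(= 0.5 + f/2\), so \(\hat f = 2(\text{mean} - 0.5)\);
* deletion: mean \(= 1/(2 - f)\), so \(\hat f = 2 - 1/\text{mean}\);

both clipped to \([0, 1]\). At \(f = 0\) the mean VAF is 0.5 in
expectation, so the flag fires on noise about half the time by design - it
is advisory, mirroring a manual-inspection step - and the report always
carries both inversions, the number of informative sites, and a one-sided
exact binomial test of the pooled retained counts against 0.5. The
homozygosity cutoff of 0.9 implies the screen needs a reasonably pure
tumour to define retained alleles (deletion mode requires purity above
about 0.89, copy-neutral above 0.8); the cutoff is configurable.

## Phylogeny reconstruction

Somatic variants called per sample enter a presence matrix. Presence
additionally requires the VAF to clear a floor: 0.03 in normals and
\(0.2 \times \text{purity}\) in tumours. The tumour floor is deliberately
higher than a bare detection threshold: a tumour biopsy contains
\(1 - p\) contaminating normal kidney cells, and a kidney clonal expansion
at cell fraction \(f\) contributes VAF \((1-p)f/2\) (about 0.045 at default
parameters) to a tumour sample without the tumour lineage carrying the
mutation at all. The floor must sit above this contamination level while
staying far below the clonal expectation \(p/2\); \(0.2p\) does both.
Variants in regions where every tumour sample is non-diploid are excluded,
with reasons listed - their VAFs are not comparable across samples.

Variants are grouped by identical presence pattern and assembled into a
rooted perfect phylogeny: patterns are accepted greedily in order of
decreasing variant support (ties resolved towards the lexicographically
earlier pattern), discarding any pattern incompatible - not nested or
disjoint - with an already accepted one; every discard is logged with the
pattern it clashed with. Internal edges supported by fewer than 3 variants
are pruned as noise: at depths near 80x and error rates near \(10^{-3}\),
chance co-patterns of one or two misread variants recur often enough across
thousands of sites to insert spurious (and individually compatible!) edges.
Leaf and root edges are exempt - they exist structurally. The tree is
serialised as canonical Newick (children ordered by smallest leaf label)
with branch lengths equal to mutation counts and the root edge carrying
mutations shared by every sample; trees are unscaled for display unless the
caller uses the lengths.

Timing labels add a developmental constraint. A somatic variant present in
blood and kidney is `early_mosaic` (it predates the divergence of blood and
kidney lineages within the mesoderm); present in kidney but not blood,
`late_mosaic`; tumour-only, `tumour_only`. Presence for timing is
deliberately more sensitive than presence for the tree: a statistical call
*or* at least two supporting reads in the tissue, the same two-read
evidence convention used for blood absence in the clone definitions. A
variant present in blood and tumours but missed in sampled kidney is still
labelled early (tumours are kidney-lineage descendants, so blood plus any
tumour implies a pre-split origin) and flagged `blood_restricted` for
review. During reconstruction, early-mosaic variants that are *called* in
at least one normal sample have their presence expanded to all blood and
kidney samples, pinning them above the blood/kidney split and healing
sporadic dropout in the shallower normal; early-labelled variants with no
normal call are left as observed, surfacing as logged conflicts rather than
being silently rewritten.

Relatedness of two neoplasms counts mutations present in at least one
sample of each, excluding all normal-tissue-evidenced timing classes
(`germline`, `early_mosaic`, `late_mosaic`): the shared embryonic
background of independent tumours is not tumour-lineage evidence, and
neither are kidney-clone mutations, which contaminate every biopsy taken
through that kidney. Any remaining shared mutation implies a shared trunk
(threshold 0 by default); parallel evolution of the same driver hotspot
with zero shared passengers reads as independent.

## Driver annotation and cancer cell fractions

The rule engine is deterministic and order-independent. Small variants:
missense or in-frame changes at curated hotspots of oncogenes, and
truncating changes in recessive cancer genes, are drivers; an `always_keep`
site list generalises manual rescues of recurrent events that upstream
callers systematically reject (promoter hotspots in low-complexity
sequence). Copy number: focal (< 1 Mb) homozygous deletions over recessive
genes and amplifications strictly above copy number 4 (diploid) or 8
(tetraploid) over oncogenes; sub-threshold oncogene amplifications are
rescued by expression z-scores of at least 3. Rearrangements: whitelisted
fusions, breakpoints in recessive footprints, or regulatory hits of
oncogenes with expression rescue. Promoter hypermethylation: cohort
z-scores of promoter beta values and expression, calling a sample when the
beta z-score is at least 3 and the expression z-score at most -3 (the
threshold is read on the low side of the expression distribution: a z of +3
is *high* expression; both cutoffs are configurable). A germline variant in
a recessive gene is biallelic when any somatic event class - substitution,
indel, rearrangement, deletion/LOH, promoter hypermethylation - hits the
same gene.

Cancer cell fraction follows
\[
\mathrm{CCF} = \mathrm{VAF} \cdot
  \frac{p\,c + 2(1-p)}{p\,m},
\]
with purity \(p\), local total copy number \(c\) and multiplicity \(m\)
(estimated by rounding \(\mathrm{VAF}(pc + 2(1-p))/p\) into \([1, c]\) when
unknown). Raw values are capped at 1.25 - larger values indicate an
inconsistent copy-number or multiplicity assignment and are worth
inspecting - before the reported fraction clamps to 1. Mutations with CCF
at or above 0.8 are labelled clonal; the cutoff is configurable, and
copy-number-event clonality is taken from the upstream caller rather than
recomputed.

## Signature deconvolution

A 96-channel trinucleotide spectrum is deconvolved into a non-negative
mixture of reference signatures by multinomial EM: responsibilities
\(r_{ij} \propto w_j S_{ij}\), weight updates
\(w_j = \sum_i x_i r_{ij} / \sum_i x_i\), uniform initialisation,
convergence when the log-likelihood improves by less than \(10^{-8}\)
(cap 10,000 iterations). The likelihood is concave in the weights for fixed
references, so a single start suffices; optional random restarts guard
numerical ties. The log-likelihood is non-decreasing by construction and
asserted in tests. A deconvolution is accepted only when the fitted mixture
reproduces the input spectrum with cosine similarity strictly greater than
0.8; otherwise the spectrum is reported unresolved and kept as is. The
packaged reference set is six synthetic signatures (distinct sparse
96-channel profiles; pairwise cosines below about 0.3) so that tests need
no external download; genuine COSMIC matrices in the same TSV layout are
drop-in replacements. Extraction of de-novo signatures (hierarchical
Dirichlet processes and the like) is out of scope; this module consumes any
spectrum, whether per-sample counts or externally extracted components.

## The synthetic cohort generator

Each simulated patient has a blood sample, a normal kidney sample and one
or more tumours with configurable biopsies. Variants fall into six truth
classes: germline heterozygous (expected VAF 0.5; hemizygous on male X),
embryonic mosaic (shared unevenly by blood and kidney, clonal in tumours -
reproducing the VAF inflation of embryonic mutations in tumours),
kidney-clone (a precursor expansion at cell fraction `clone_fraction`
ancestral to tumour 1, plus an unrelated private clone), tumour trunk
(Poisson burden with mean `burden_intercept + burden_slope * age_months`,
reflecting the age-proportionality of substitution burdens), tumour private
(per biopsy), and artifact (beta-binomial overdispersed noise in every
sample, with a high-quality-read retention below 0.75 so the quality filter
has something to catch). Per-sample alt counts are binomial around the
expected VAF implied by tissue cell fraction, purity, local copy number and
multiplicity, with the base error rate folded in; depths are per-site
Poisson. Copy number is emitted as integer segments: diploid genomes, a
shared gain region in tumour 1 (exercising the non-diploid exclusion), and
an optional chr11p LOH segment (deletion or copy-neutral) whose mosaic
counterpart in kidney distorts germline SNP VAFs and read depth exactly as
the screen's algebra expects. A matched reference panel is simulated at the
patient's sites: clean sites at the sequencing error rate, artifact sites
with the same overdispersion - which is what makes a panel informative.

Embryonic tissue fractions are a shared lineage fraction
\(F = f_{\min} + (1 - f_{\min})\,\mathrm{Beta}(2, 5)\) perturbed per tissue
by independent asymmetry factors \(\mathrm{Beta}(10, 3)\), so blood and
kidney fractions are correlated but unequal. The floor
\(f_{\min} = 0.25\) is a deliberate modelling choice: the generator
emulates the mosaic mutations a study of this design can actually detect
and reason about - those arising in roughly the first two cell generations
of the embryo proper, with tissue fractions in the 0.1-0.5 range. Mutations
with vanishing tissue fractions exist in real embryos but are invisible to
normal-tissue sequencing at these depths while remaining clonal in tumours
descended from their lineage; no detection rule can distinguish them from
tumour-trunk sharing, and they belong to the regime the method explicitly
does not claim.

What the generator does **not** emulate - and what passing tests therefore
do not show about real data: polyclonal embryonic structure (real blood and
kidney are mixtures of many lineages whose tissue-level presence patterns
can violate a sample-level perfect phylogeny; the generator emits one
consistent truth tree), subclonal tumour architecture (tumour-cell
fractions are 0 or 1 per sample; no mixture modelling within a biopsy),
read-level artifacts (no alignment, mapping or strand structure - the
high-quality recount is a simple binomial thinning), realistic genome
coordinates (three toy contigs), indel mechanics, and panel germline
polymorphism (panel individuals carry only error reads at patient sites,
which is adequate because error models are only consulted at
somatic-candidate sites).

## Problem sizes and numerical choices

The default cohort is three patients at depth 80 with roughly 2,000
variants each (1,500 germline including 200 chr11p SNPs and 20 on chrX, 50
embryonic, 30 + 15 clone, age-model trunk of ~260 at 36 months, 50 private
per biopsy, 50 artifact sites), tumour purity 0.7, error rate \(10^{-3}\),
and a 50-sample panel. Verification scenarios scale deliberately: the
false-discovery check uses 2,000 null sites by 5 samples (10,000 tests)
with a 50-sample panel; topology and bilateral-independence checks run 100
seeded bilateral cohorts of ~250 variants each; LOH inversion uses depth
1,000 at 200 informative sites with purity 0.95, the regime where the
tumour itself can define retained alleles cleanly; EM recovery uses
\(10^5\) mutations. The overdispersion grid has 41 log-spaced points; BH is
`p.adjust`; binomial tails are `pbinom`; the beta-binomial mass is computed
from `lchoose` and `lbeta` in log space and summed directly. All
randomness derives from a single integer seed per configuration, with
per-patient child seeds below \(2^{31}\); identical seeds reproduce every
output byte-for-byte, including TSV serialisations.

## Known limitations

The exact binomial classifier pools all normals, including kidney that may
carry the tumour-precursor clone; a large clone pushes pooled VAF upward
and, in principle, can drag a low-fraction mosaic variant across the
germline boundary (clone leakage). The LOH screen's advisory flag has a
~50% false-flag rate at \(f = 0\) by construction and must be read with
its binomial p-value and site count. The perfect-phylogeny model cannot
represent genuinely reticulate or polyclonal sample compositions; conflicts
are logged, not resolved biologically. Driver annotation consumes
consequence classes and gene assignments as inputs and performs no variant
effect prediction or pathogenicity database curation.
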