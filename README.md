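# somafoot

Somatic footprints of predisposition: an R toolkit for reconstructing the
somatic evolution of tumours and their surrounding normal tissue from
multi-sample whole-genome read counts of one individual.

Childhood kidney tumours (Wilms tumours) frequently arise on a background
of germline or post-zygotic (mosaic) predisposition. Working out how such a
tumour developed requires looking jointly at blood, histologically normal
kidney and one or more tumour biopsies from the same child: which variants
are germline, which arose early in embryogenesis and pervade both blood and
kidney, which define clonal expansions in normal kidney that precede the
tumour, whether normal tissue carries mosaic loss of heterozygosity, how
multiple neoplasms of the same child are phylogenetically related, and
which events are drivers. somafoot implements that analysis chain as
composable, tested R functions, plus a synthetic-cohort generator with full
truth labels that stands in for controlled-access patient genomes.

## The statistical core

* **Germline vs somatic**: pooled normal read counts per variant are tested
  against the heterozygous germline null with a one-sided exact binomial
  test — `P(X ≤ alt | depth, p₀)` with `p₀ = 0.5` (0.95 on male sex
  chromosomes) — rejecting at `p < 1e-5`. Pooling is restricted to normals
  that are copy-number normal at the site.
* **Artifact control**: a per-locus beta-binomial error null `(μ, ρ)` is
  fitted from a reference panel of unrelated normals (pooled-rate `μ` with
  pseudocounts, grid maximum likelihood for the overdispersion `ρ`);
  per-sample presence is the upper tail `P(X ≥ alt)` under that null,
  Benjamini–Hochberg-corrected across all variant×sample tests of the
  patient, called at `q < 0.005`.
* **Clonal expansions**: precursor mutations (tumour ∩ kidney, < 2 blood
  reads) and kidney-private mutations, with clone cell fraction estimated
  as 2 × median kidney VAF in diploid regions.
* **Mosaic LOH screen**: retained-allele VAFs at sites where the tumour is
  homozygous; mean VAF > 0.5 flags a normal sample, and the cell fraction
  inverts as `f = 2(mean − 0.5)` (copy-neutral) or `f = 2 − 1/mean`
  (deletion).
* **Phylogeny**: maximum-compatibility perfect phylogeny over presence
  patterns (purity-scaled VAF floors, non-diploid exclusion, majority
  conflict resolution, canonical Newick out); relatedness of two neoplasms
  counts shared mutations net of embryonic and normal-tissue timing.
* **Drivers and CCF**: hotspot/truncating/focal-CN/fusion/hypermethylation
  rules and `CCF = VAF·(p·c + 2(1−p))/(p·m)` with clonality at CCF ≥ 0.8.
* **Signatures**: multinomial EM deconvolution of 96-channel spectra into
  reference signatures, accepted at cosine similarity > 0.8.

## Worked example

Simulate one patient (blood, kidney, two tumour biopsies; ~2,000 variants
at depth 80), a 50-sample reference panel, and run the full per-patient
analysis:

```r
library(somafoot)

cfg     <- sim_config(n_patients = 1, seed = 1)
patient <- simulate_patient(cfg, 1)
panel   <- simulate_panel(patient, cfg)
res     <- analyse_patient(patient$counts, patient$segments,
                           patient$samples, panel)

table(res$classification$class)
#> germline  somatic
#>     1503      544
```

The truth table holds 1,500 germline variants; 544 somatic calls cover the
embryonic, clone, trunk, private and (pre-filter) artifact classes. The
kidney clone report recovers the simulated precursor expansion (30
mutations at cell fraction 0.3, entering the tumour trunk):

```r
res$clones$summary
#>         set n_mutations   max_vaf est_cell_fraction patient_id
#> 1 precursor          36 0.2888889         0.2408791       P001
#> 2   private           4 0.1125000         0.1256329       P001
```

(The precursor set picks up a handful of embryonic mutations whose blood
reads happen to fall below the two-read threshold — the operational
definition shared by real analyses of this kind.) The reconstructed
phylogeny carries mutation counts on its edges, root edge first:

```r
cat(res$tree$newick)
#> (P001_blood:0,(P001_kidney:10,(P001_tumour1a:50,P001_tumour1b:50):297):29):47;
```

47 embryonic mutations sit above the blood/kidney split, 29 precursor-clone
mutations on the kidney-lineage edge shared with the tumour, a 297-mutation
tumour trunk and 50 private mutations per biopsy. The somatic spectrum
deconvolves into the packaged reference signatures (cosine 0.96, accepted),
and the two annotated trunk events are called as drivers with their cancer
cell fractions:

```r
res$drivers[, c("gene", "consequence", "driver", "rule", "ccf", "clonal")]
#>        gene consequence driver       rule       ccf clonal
#> 1596 CTNNB1    missense   TRUE    hotspot 0.8761905   TRUE
#> 1597    WT1  truncating   TRUE truncating 1.0000000   TRUE
```

`simulate_cohort()` writes a cohort directory (counts, segments, metadata,
panel, truth, manifest with checksums) and `run_pipeline()` processes it
end to end into per-patient reports — classification, calls, clones, LOH
screen, Newick tree, relatedness, drivers, signature weights — plus a
cohort summary; identical inputs produce byte-identical outputs.

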