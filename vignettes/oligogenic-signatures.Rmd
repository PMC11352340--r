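---
title: "Private oligogenic germline signatures from discordant sib pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private oligogenic germline signatures from discordant sib pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosig)
```

## The model

Familial clustering is rare in never-smoker lung cancer, yet the disease
shows clear signs of inherited susceptibility. One explanation is an
*oligogenic* model: each patient carries a small, individually unique
combination of rare deleterious germline variants in cancer-predisposition
genes — a "private predisposing signature" — rather than a single highly
penetrant allele. A signature that is a combination of several rare alleles
is broken up by meiosis, which is exactly why it would not produce visible
familial aggregation.

The study design this package implements compares each patient with an
unaffected full sibling. Sibs share on average 50% of their germline
variants, so an affected/unaffected ("discordant") pair is a naturally
matched case–control unit: variants found in the patient but not the healthy
sib are candidate susceptibility alleles, while shared variants are largely
uninformative. Three data layers are combined per patient:

1. **Germline exomes** (patient blood + sib blood): a prioritization cascade
   reduces the raw variant table to rare, deleterious, affected-exclusive
   variants in a cancer-gene panel.
2. **Tumor exome**: blood-vs-tumor subtraction yields somatic mutations, and
   a zygosity comparison at the candidate loci detects loss of
   heterozygosity (LOH) — a candidate heterozygous in blood but effectively
   homozygous for the alternate allele in the tumor has plausibly lost its
   functional copy (a classical second hit).
3. **Tumor/normal transcriptomes** plus a control group of normal tissues:
   each candidate gene's FPKM pattern across tumor (T), matched normal (N)
   and control normals (C) assigns one of three functional classes, or no
   change.

## The prioritization cascade

`run_cascade()` applies six stages in order; every stage is also exported on
its own, and a `FilterTrace` records, per stage, the input and output counts
and the removed variant keys.

| stage | rule | default |
|---|---|---|
| coverage | total depth ≥ `min_depth` | 10 |
| exonic/rare | exonic consequence and MAF ≤ `max_maf` *or unreported* | 0.01, keep unreported |
| benign/in-house | drop clinically (likely) benign and in-house database keys | — |
| deleterious | truncating always; otherwise CADD ≥ `cadd_min` and MetaSVM "D" | 20, required |
| discordance | key absent (or hom-ref with adequate depth) in the unaffected sib | — |
| cancer panel | gene symbol in the panel, case-insensitive | user panel |

Design notes, in the order the questions arose:

* **"Low coverage" is a qualitative notion** in most exome pipelines; we fix
  the default at 10 reads, the common germline heuristic, and keep it
  configurable. The packaged worked example is constructed to be insensitive
  to this choice.
* **Unreported MAF is kept by default.** A variant absent from population
  databases is more likely ultra-rare than common; treating "not reported"
  as 0 would make the two indistinguishable, so absence is an explicit state
  (`NA`) end to end, never coerced to a number.
* **The deleteriousness rule retains truncating variants unconditionally**
  (`truncating_or_scores`). Missense deleteriousness classifiers such as
  MetaSVM are undefined for frameshift indels and nonsense variants, so a
  conjunction of scores would silently drop the variant class with the most
  direct functional interpretation. Nonsynonymous variants must pass both
  CADD ≥ 20 (the conventional top-1% scaled-score cutoff) and a MetaSVM
  damaging call. `cadd_and_svm` and `cadd_or_svm` are selectable for
  sensitivity analyses. Synonymous variants are never retained.
* **Discordance treats an unobserved site as homozygous reference.** Exome
  variant tables rarely carry reference blocks, so absence of the key from
  the sib's table is accepted as evidence of absence. This is a documented
  limitation: a site that simply failed to be called in the sib looks
  discordant. When the sib does carry an explicit hom-ref call, its depth
  must reach `min_depth` for the discordance to count.
* **Pooling**: cohort candidates are distinct (variant key, case)
  assignments; a variant is *shared* when the same key is a candidate in two
  or more cases. The symmetric direction (`unaffected_only`) implements the
  protective screen — variants private to the healthy sib.

## Somatic extraction and LOH

Somatic calling here is table subtraction (`call_somatic()`): a tumor
variant is somatic when its key is absent from blood or explicitly hom-ref
there. This is deliberately not a probabilistic caller; the package consumes
already-called variant tables.

`detect_loh()` flags a candidate when blood is heterozygous and the tumor is
homozygous-alt, where tumor homozygosity is satisfied by the recorded
genotype state or by an alternate-allele fraction ≥ `min_hom_af` (default
0.8). The allele-fraction route exists because tumor samples are rarely
pure: at tumor purity $p$ the expected allele fraction of a het→hom
conversion is $p + (1-p)/2$, so 0.8 tolerates roughly 60% purity. Purity is
not estimated from data; the simulator exposes a purity parameter only to
scale the planted allele fractions.

## Expression integration

Significance is computed on $\log_2(\mathrm{FPKM} + c)$ with pseudocount
$c = 0.1$ (avoiding infinite ratios at zero expression; configurable). Two
methods are offered:

* `log_t` (default): each single observation $x$ (tumor or normal) is tested
  against the control group $c_1,\dots,c_k$ with the prediction-interval
  form of the one-sample $t$ test,
  $t = (x - \bar c) / (s\sqrt{1 + 1/k})$, $\mathrm{df} = k - 1$; the
  tumor-vs-normal comparison treats both as single draws with the
  control-calibrated variance, $t = (x_T - x_N)/(s\sqrt{2})$. The original
  transcript-assembly tool chain is not reimplemented — the analysis needs a
  defensible p-value on FPKM, not that tool's exact model. Whether the
  published tumor-vs-normal p-values derived from that tool's model or from
  the control-group variance is not stated; the `method` argument records
  the choice made here.
* `permutation`: rank-based exchangeability p-values (the observation pooled
  with the controls; for T-vs-N, the observed difference compared against
  all control pair differences with an add-one correction). These are
  discrete and super-uniform under the null; with $k$ controls the smallest
  attainable p is $1/(k+1)$, so small control groups cannot reach 0.05.

With a degenerate control spread ($s = 0$, possible in noise-free
simulations) the log-t p-value is defined as 0 for any non-zero difference
and 1 otherwise, which makes noise-free recovery tests exact. Ties in the
permutation statistics are compared with a $10^{-12}$ slack so that exact
equality counts as "at least as extreme".

`classify_expression()` assigns exactly one class per gene, with thresholds
`min_fold = 2` and `alpha = 0.05` (the same thresholds applied genome-wide
by `de_summary()`), checked in this order:

1. **BOTH_DOWN** — T and N each ≤ C/`min_fold`, both significant vs C:
   transcript instability in the carrier. This is checked *first* because a
   depressed normal tissue makes the tumor-vs-normal comparison
   uninformative; a gene down 4-fold in both tissues would otherwise be
   called "no change".
2. **TUMOR_DOWN** — T ≤ N/`min_fold`, significant T-vs-N: a putative second
   hit in a tumor suppressor.
3. **TUMOR_UP** — T ≥ N·`min_fold`, significant T-vs-N: a likely oncogene.
4. **NO_CHANGE** otherwise.

The numeric rule separating the three patterns is this package's own
formalization; the source study presents the patterns graphically without
stating thresholds, so we fixed the rule to the thresholds it states for the
genome-wide differential-expression scan. "Functional" means class ≠
NO_CHANGE. A truncated putative tumor suppressor with unchanged mRNA can be
kept on the RNA-effect panel via the explicit `retain_genes` list (the
packaged example retains `URI1` this way); retention by judgment is opt-in,
never automatic.

## Enrichment and networks

`enrich()` is a one-sided hypergeometric (Fisher) upper-tail test per gene
set within a finite universe, with BH correction across sets; the `ease`
variant decrements the overlap by one (so a single-gene overlap carries no
evidence). Exact annotation-service statistics are database-version
dependent and are not reproduced; the module works on user-supplied GMT
collections. `build_candidate_network()` induces the subgraph of a
user-supplied edge list on the candidate genes and reports connected
components of size ≥ 2, labeled with the owning cases; edge provenance
labels are carried as opaque strings (no evidence-score thresholding — the
source gives no cutoffs). `expand_network()` adds up to `k` non-candidate
interactors ranked by connections to the current nodes, ties broken by total
degree then symbol order, making the expansion deterministic.

## The synthetic-data generator

`simulate_cohort()` produces cohorts with planted ground truth
(`SimulationTruth`), against which every other module is tested. Defaults
are the study conditions:

* 4 sib pairs; background variants shared per-variant with probability 0.5
  (a Bernoulli model, not recombination-aware haplotype blocks — the
  analysis uses no linkage information, so block structure would add realism
  without changing any tested property).
* Planted signature: 10 private deleterious variants per case (fixed, or
  Poisson with mean 10), annotated with margins well clear of every default
  threshold (MAF < 0.005 or unreported, CADD 25–40, MetaSVM D, depth ≥ 30).
* Background variants are constructed to violate at least one filter, with a
  sampled violation mode (common, benign, low scores, synonymous,
  noncoding, low depth) and a fifth of the violators placed in panel genes
  so failures happen before the panel stage. Separability is therefore by
  construction: recovery tests are exact, which is their purpose — they
  validate the plumbing, not the discriminative power of the thresholds on
  real data.
* Tumors: every germline variant plus 2568 somatic draws, 41% noncoding,
  coding classes in proportions 1092 : 374 : 43
  (missense : frameshift : nonsense); 9 planted LOH conversions per cohort,
  with allele fraction scaled by purity and the recorded genotype mimicking
  a caller that labels hom-alt at fraction ≥ 0.9.
* Expression: log-normal FPKM with σ = 0.25 on the log2 scale, 5 controls,
  planted fold 4; signature genes draw their class with weights 8 : 3 : 5 :
  24, plus 50 / 40 / 910 genome-wide up / down / null genes.

What the simulator does **not** emulate: linkage and haplotype sharing,
realistic mutational spectra or trinucleotide context, clonal evolution,
FFPE artifacts, mapping or calling error, and annotation error (CADD and
MetaSVM values are planted, never computed). Passing recovery tests
therefore demonstrates correctness of the filtering, subtraction, zygosity
and classification logic under the assumed data model — not performance on
real exomes.

All randomness flows from one seed (`withr::with_seed`); no global RNG state
leaks, and two runs with the same configuration are byte-identical on disk.

## The packaged worked example

`load_paper_fixture()` returns a four-pair cohort transcribed from a
published discordant-sib study of never-smoker early-onset lung
adenocarcinoma: 40 candidate variants with their per-case assignments and
RNA-effect flags. Everything the publication does not print is synthetic and
labeled as such in `inst/extdata/fixture_meta.json`: genomic coordinates
(the source prints HGVS strings only), depths, background variants, FPKM
values (constructed to realize the published expression classes under the
default thresholds), interaction edges, and the identities of the 9 LOH
genes (planted among the downregulated RNA-effect variants, as the source's
summary indicates but never itemizes). The metadata also records two
internal conflicts of the source — the running text and the table disagree
on which cases share the ANGPTL4/ESRRA/CARS variants, and the extracted
table carries one case-4 row more than its printed total supports; the
transcription follows the table's checkmarks and drops the surplus row.

```{r fixture}
res <- run_pipeline(fixture = TRUE)
res
res$summary$per_case
```

## Numerical and representational choices

* Coordinates are 1-based VCF convention; indel alleles are left-normalized
  on read (shared suffix trimmed, then shared prefix beyond the anchor base,
  shifting the position) so that equivalent representations compare equal.
* Variant identity is the `(chrom, pos, ref, alt)` key; per-subject tables
  must be key-unique, and multi-allelic VCF sites are decomposed into one
  record per alternate allele.
* Candidate output order is deterministic (`chrom`, `pos`, `alt`), and gene
  symbol matching is case-insensitive throughout.
* VCF annotation INFO keys are configurable (`default_vcf_keys()`); the
  source names annotation tools, not INFO dialects.
* The TSV dialect writes doubles with 17 significant digits and is read back
  with a correctly rounded parser, so round-trips are bit-exact.

## Problem sizes in the test suite

The suite validates the cascade against a brute-force predicate conjunction
on random tables of up to 1,000 variants, permutation-p super-uniformity on
2,000 null genes, somatic class proportions on 10,000 draws, hypergeometric
p-values against tail enumeration on universes of up to 30 genes, and exact
recovery on noise-free cohorts of 2–4 pairs with a few hundred background
variants per pair — sizes at which every check is exact or has negligible
Monte-Carlo error while the whole suite stays fast.

## Known limitations

* Discordance cannot distinguish "absent in sib" from "not called in sib".
* Somatic subtraction inherits any germline false negatives as somatic false
  positives; there is no joint genotyping.
* The LOH rule does not model copy-neutral LOH versus deletion, and purity
  is a user assumption, not an estimate.
* The expression classes are thresholded point comparisons per gene; with
  one tumor and one matched normal per case there is no shrinkage across
  genes, and the control group carries all of the variance information.
* Counts that depend on raw sequencing data (genome-wide variant totals,
  absolute DE gene counts) are outside what the packaged example can
  reproduce; they parameterize the simulator instead.
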