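---
title: "Methods: recessive filtering and founder-panel screening for renal hypouricemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive filtering and founder-panel screening for renal hypouricemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhucscreen)
```

## The problem and the model

Renal hypouricemia (RHUC) is a recessive disorder of proximal-tubule
urate reabsorption: type 1 is caused by bi-allelic *SLC22A12* (URAT1)
variants, type 2 by *SLC2A9*. Serum uric acid in affected subjects sits
far below the population distribution (around 0.8 mg/dL versus ~5 mg/dL),
but a low measurement alone cannot distinguish constitutive disease from
transient states such as malnutrition. The package implements the
diagnostic analysis as a pipeline over three objects — a phenotype table,
a carrier-call genotype table, and an annotated single-ALT variant table —
assembled into an `rhuc_cohort`.

**Case definition.** A case is a subject with serum urate strictly below
1.3 mg/dL and no secondary-cause flag. The strict inequality is fixed, not
an option: subjects at exactly the threshold flip category under `<=`,
and the case definition in the source cohorts is `< 1.3`. `select_cases()`
returns both the hypouricemic total (for prevalence) and the flag-free
case subset (for genetic testing), because screening frames contain many
hypouricemic subjects that are never tested.

**Recessive filter.** Four steps, in fixed order (the variant-level steps
commute; the order is kept for log comparability):

1. *Frequency*: drop a variant if any populated `af_<source>` exceeds
   `maf_threshold` (default 0.01). A source with no entry contributes no
   evidence — a variant absent from every database **survives**. This
   distinction (missing ≠ 0) is enforced at the type level and decided at
   the filter level, so rare novel alleles are never lost to an absent
   lookup.
2. *In-house*: drop exactly the variants seen homozygous or hemizygous in
   the in-house control panel (`inhouse_hom`); heterozygous presence in
   controls does not remove.
3. *Consequence*: keep missense, stop-gain, frameshift, in-frame indel
   and splice-site classes; synonymous and unclassifiable consequences go.
4. *Bi-allelic collection*: per individual, per gene — homozygous
   dominates, else two or more distinct heterozygous alleles in one gene
   form a putative compound heterozygote, else a male with a qualifying
   allele on an X-labelled chromosome is hemizygous; females need
   bi-allelic X genotypes like autosomes. Single heterozygotes are never
   diagnosed.

Compound-het calls from unphased data carry `phase_resolved = FALSE`
throughout: two hets in one gene may be *cis* and therefore benign-like.
The simulator can plant such pairs (`cis_pair_rate`) and the test suite
demonstrates that the pipeline — like any unphased analysis — calls them
compound het.

When several genes qualify in one individual, all are reported; the
single `gene` field is ranked by majority prior-pathogenicity report and
then lexicographically, mirroring how a curator would pick the reportable
gene while keeping the full list machine-readable.

**Founder panel.** The two-variant panel (p.Trp258\*, p.Arg90His)
emulates a single-base-extension assay as direct genotype lookup.
Categories are a pure function of (panel-A count, panel-B count, other
qualifying alleles in the panel gene): homA, homB, compound_AB,
hetA/B_plus_other, hetA/B_only, others_only (two or more other alleles),
none. In genotyping-only mode (two sites typed, as in a replication
assay) other-allele counts are structurally unknown: they are reported 0
with `others_known = FALSE` and `others_only` cannot occur.

Two yields are deliberately kept apart. `screening_yield()` counts any
subject with ≥ 1 panel allele — the permissive definition used when a
two-site assay is evaluated as a screen, which counts single
heterozygotes even though the trait is recessive; the single-het margin
is reported explicitly (`n_single_het`). `biallelic_yield()` counts true
recessive diagnoses from the cascade. Reported percent strings are
rounded to one decimal; `compare_percent_strings()` recomputes and flags
published strings that disagree with their own counts (the bundled
replication distribution contains one such cell: 3/50 printed as 6.6%
where it computes to 6.0%).

**Conservation and predictions.** Ortholog residues (default panel:
rhesus macaque, mouse, dog, African elephant — mammals sharing the urea
cycle) are compared to the human reference residue after normalizing
one-/three-letter codes; the Asn/Asp distinction must and does survive
normalization. External predictor verdicts are opaque inputs mapped by a
fixed dictionary onto deleterious/benign/ambiguous; consensus is the
majority of non-ambiguous calls, ties are ambiguous. The tools themselves
are never run: web predictors are version-unstable and irreproducible,
whereas their printed verdicts are fixtures.

## The synthetic generator: what it emulates, what it does not

`simulate_cohort()` draws, per individual, two haplotypes each carrying
at most one pathogenic *SLC22A12* allele (founders plus four rarer
catalogue alleles) — this yields exact Hardy–Weinberg genotype
proportions at every site, forbids three-allele genotypes, and puts
compound-het pairs in *trans* by construction. *SLC2A9* haplotypes are
drawn analogously, with the summed frequency set so that a configurable
fraction of genetic cases (`other_gene_fraction`) is type 2. Serum urate
is class-conditional Gaussian truncated at zero; transient mimics are
non-carriers that draw urate from the carrier distribution.

Defaults are fixed once as a plausible East-Asian adult screening frame:

| parameter | default | rationale |
|---|---|---|
| q(p.Trp258\*) | 0.010 | founder allele, ~1% in Korean/Japanese reports; source figures are not machine-quotable, value documented as illustrative |
| q(p.Arg90His) | 0.003 | second founder allele, several-fold rarer |
| other pathogenic ΣAF | 0.001 | rare non-founder alleles |
| other_gene_fraction | 0.05 | *SLC2A9* minority among genetic cases |
| urate, bi-allelic | 0.77 ± 0.25 mg/dL | the published case-cohort mean ± SD |
| urate, single het | 4.0 ± 1.0 mg/dL | mildly lowered, far above threshold |
| urate, non-carrier | 5.2 ± 1.0 mg/dL | population mean |
| transient_rate | 3 × 10⁻⁴ | transient extreme hypouricemia is rarer than the genetic form in an adult screening frame |
| exclusion_flag_rate | 0.08 | each of six flags independently; ~40% of subjects carry some flag |

Under these defaults the simulated extreme-hypouricemia prevalence is
≈ 0.05%, the same order as the 0.083% observed in the source frame.
Recovery and property tests use an explicitly *enriched* scenario
(founder frequencies 0.05/0.02, urate SDs 0.5) fixed a priori, so that
n = 10,000 cohorts contain enough bi-allelic carriers to make exact-set
comparisons meaningful; this is a test harness choice, not a claim about
population frequencies.

The generator does **not** emulate: linkage disequilibrium or haplotype
structure beyond the one-pathogenic-allele-per-haplotype rule,
relatedness or pedigrees, sequencing or genotyping error, call-rate
missingness, or age/sex effects on urate. A green recovery test
therefore establishes that the cascade is a faithful inverse of the
generative genotype model — not that real exomes are this clean.
Decoy content (common benign variants, a rare synonymous change, a rare
in-house-homozygous change, X-linked common decoys with hemizygous male
calls) exists precisely so that every filter step has work to do.

## Worked-example cohorts

`make_paper_cohort()` deterministically reconstructs the two published
Korean cohorts from their reported allele configurations (31 discovery /
50 replication subjects). Individual ids are synthetic (D01…, R01…);
serum urate values are deterministic sequences below 1.3 mg/dL with the
published case-mean scale; the three discovery subjects with two
non-founder alleles carry the compound pairs the publication describes,
which makes the prose-level counts (24/31 previously-reported, 3/31
novel-missense carriers, four novel variants overall) emerge from the
reconstruction rather than being asserted. The four subjects without
*SLC22A12* genotypes carry one *SLC2A9* compound het and three bi-allelic
genotypes in placeholder genes named `CAND1–3`, documented as synthetic.

## Numerical and interface choices

- **Rounding**: percents print at 1 decimal (distribution tables, yields)
  and 3 decimals (prevalence), via one shared `sprintf` path; tests check
  that printed strings reconstruct their ratios within 0.05.
- **VCF dialect**: VCF 4.2, one ALT per record, GT-only FORMAT, `Number=A`
  INFO (`GENE, CSQ, PCH, CDC, AF_<source>, IHH, KP`); "." encodes a
  missing opaque label. Reading is delegated to Bioconductor
  `VariantAnnotation` (multi-allelic inputs are split per ALT, conserving
  per-site allele totals); writing emits the dialect directly and is
  validated by byte-identical round-trips and external `bcftools`
  parsing. Male genotypes on X-labelled chromosomes are written haploid,
  and the container enforces that hemizygosity flags agree with
  (sex, chromosome).
- **Determinism**: all randomness flows from the config seed; equal seeds
  give byte-identical files, and `provenance.json` records version, seed
  and an analytic config hash (output paths excluded from the hash).
- **Degenerate inputs**: empty cohorts write header-only VCFs and flow
  through every stage; zero-case yield calls are hard errors rather than
  NaN; unknown consequence strings degrade to `other` with a warning
  (and are then filtered), unknown sex and sample-set mismatches are hard
  errors.
- **Config format** is JSON rather than YAML, matching the guaranteed
  dependency set of the build environment.

## Known limitations

- Compound-het diagnoses are phase-blind; `phase_resolved = FALSE` is a
  caveat, not a solution. Parental genotypes would be needed to resolve
  *cis*/*trans*.
- The in-house exclusion models only homozygous/hemizygous control hits,
  taking the published filter text literally; a high het count in a small
  control panel is not used as evidence.
- The MAF policy treats any single populated source above threshold as
  disqualifying; with per-source scalar frequencies this coincides with
  the max-across-sources policy, and both are exposed.
- `panel_category()` is defined for two-variant panels only; larger
  panels would need a different category scheme.
- The conservation profile is identity-at-aligned-residue over a
  four-species panel; it is an evidence annotation, not a substitution
  model.
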