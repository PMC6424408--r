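---
title: "Trio-based recessive variant discovery with TrioSeg"
author: "TrioSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based recessive variant discovery with TrioSeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioSeg)
```

# The problem

A recessive retinal degeneration segregating in a dog family can be mapped
by whole-genome sequencing of a small pedigree: two unaffected parents and
two affected offspring. If the disease is fully penetrant and autosomal
recessive, the causal variant must be homozygous for the alternate allele
in every affected offspring while both (unaffected) parents are obligate
heterozygous carriers. TrioSeg implements this discovery cascade as
reusable, tested components: VCF genotype handling with indel
normalization, per-trio recessive filtering, intersection across trios
sharing the same parents, private-variant exclusion against a panel of
additional genomes, transcript-level consequence prediction for the
surviving candidates, effect-score banding, disease-gene list
intersection, and a cohort concordance test. A seeded simulator generates
every input the pipeline consumes, so the whole analysis is exercisable
end to end at desk scale.

The motivating application is a single-cytosine insertion in a
seven-cytosine mononucleotide run of the canine *ABCA4* gene
(`c.4176insC`), which shifts the reading frame at codon 1,393
(Phe&nbsp;→&nbsp;Leu) and creates a premature stop at absolute codon
1,395, truncating the 2,268-residue transporter to a 1,394-residue
product and removing the last 874 wild-type residues — including the
second nucleotide-binding domain essential for flippase activity.

# The segregation model

For a trio (sire, dam, affected offspring) the recessive filter retains a
variant exactly when

$$ g_\text{offspring} = 2 \quad\wedge\quad g_\text{sire} = 1
   \quad\wedge\quad g_\text{dam} = 1, $$

with $g$ the alternate-allele dose. A homozygous-reference parent is
excluded deliberately: for a fully penetrant recessive disease an
affected, hom-alt offspring *requires* both parents to carry the allele,
and an unaffected parent cannot be hom-alt, so the het/het/hom-alt
configuration is the only Mendelian one. This is conservative with
respect to genotyping error. Missing genotypes likewise exclude a variant
by default (a discovery filter should not promote uncalled sites); a
`keepMissing` flag provides the permissive alternative. Sex chromosomes
are excluded by contig name, configurably.

With two affected siblings of the same parents, the cascade runs one
filter per trio and intersects the results. The panel stage then removes
any candidate that is homozygous-alternate in at least one of the
comparison genomes (23 by default). Heterozygous panel carriers do *not*
exclude a candidate: a recessive allele can legitimately segregate in the
wider population, and the causal allele itself is expected in carriers.
Exonic and nonsynonymous status are consumed as input annotation flags —
annotation engines are mature external tools and re-implementing one here
would add nothing.

The genome-scale counts that such a cascade produces on real sequencing
data (millions of variants funnelled down to a handful of private
nonsynonymous candidates) depend on the input data volume and are not
reproducible at desk scale; the package instead verifies the cascade
*structurally*: monotone non-increasing counts, exhaustive truth-table
agreement for the trio rule, a linear-scan oracle for the panel rule, and
exact recovery of a planted causal variant over seeded replicates.

# Consequence prediction and naming

`callConsequence()` applies a coding variant to the CDS, translates
wild-type and mutant with the standard nuclear genetic code, finds the
first changed residue and the first new stop, and classifies the edit
(synonymous, missense, stop gained/lost, in-frame indel, frameshift,
start lost). Stop codons are never counted in protein lengths.

Two dialect decisions deserve explanation:

* **Indel anchoring.** Indels inside repeat runs are ambiguous; VCF
  convention left-aligns them, but clinical reporting of this class of
  insertion anchors on the *last* base of the run (the 3'-most
  placement), naming the cytosine insertion `c.4176insC` rather than
  `c.4170insC` or `c.4176_4177insC`. TrioSeg therefore right-aligns by
  default, in transcript coordinates, and exposes `align = "left"`
  (normalization) and `dialect = "hgvs"` (naming) for interoperability.
  Canonicality is tested by enumerating every equivalent spelling in
  runs up to length 10.
* **Frameshift stop index.** The default protein name uses the
  *absolute* codon index of the new stop (`p.F1393Lfs*1395`); standard
  HGVS counts from the first changed residue (`p.F1393Lfs*3`). Both are
  emitted, absolute first, because the absolute index is what truncation
  metrics are computed from.

`residuesLost` is defined as `wtLength - mutLength` (2,268 − 1,394 =
874). Note the subtlety: residues 1,393–1,394 of the mutant are
*substituted*, not merely absent, so the "lost" count intentionally
measures C-terminal shortening only; the first changed residue is
reported separately.

# Prioritization

PolyPhen-2 and PROVEAN scores are pipeline inputs. The banding uses the
tools' published cutoffs — PROVEAN damaging at ≤ −2.5, PolyPhen-2
(HumDiv) benign below 0.446 and probably-damaging at ≥ 0.908 — because
the upstream analysis labels variants without stating thresholds; all
three edges are arguments. With both scores present, `damaging` requires
both predictors to agree and `neutral` requires both to be benign;
disagreement is `indeterminate` rather than silently resolved.
Frameshift and stop-gain variants are damaging by rule (the predictors do
not score them). The classification is monotone in both scores, and that
property is tested.

The concordance test encodes full penetrance without phenocopies:
affected ⇔ hom-alt, unaffected ⇔ het or hom-ref. Discordant animals are
*listed*, not auto-excluded — discarding a discordant candidate gene is
an analyst's decision, and the one worked example of that decision (a
second candidate discordant in a validation cohort) is exactly why the
per-animal list is surfaced.

# Phenotype quantification

Three small formula layers support the downstream molecular phenotyping:
relative expression by ΔΔCt (`2^{-\Delta\Delta C_T}`, efficiency fixed at
the ideal 2.0), rod-count inference (ONL nuclei minus PNA-identified
cones, with the explicit convention that a zero cone count is valid),
background-corrected autofluorescence (region mean minus adjacent
background mean, negatives flagged), and percent reduction relative to a
reference group. Group summaries report mean ± SD over technical
replicates; inferential testing (ANOVA, Tukey) is deliberately left to
standard statistics routines.

# What the simulator emulates — and what it does not

`simConfig()` defaults *are* the study conditions: a 2,268-codon CDS
with the C₇ run at c.4170–c.4176, wild-type TTC (Phe) at codon 1,393, an
engineered first +1-frame stop at codon 1,395, 50 exons whose boundaries
never split the run, a quartet segregating the insertion, a 23-genome
panel in which the causal allele occurs only in carriers (frequency
0.1), a validation cohort of 8 affected and 14 unaffected animals, and
one nuisance variant per cascade condition, each violating exactly that
condition. Phenotype fixtures plant a 4-fold homozygote expression
knockdown (Ct noise SD 0.2 cycles), a 46% ONL nuclei reduction (count
noise SD 3 nuclei per 67-µm field, 6 technical replicates per group,
matching the published field width and replicate count) and a 7-fold
autofluorescence contrast (intensity noise SD 1 a.u.). Values without a
published counterpart (noise SDs, panel nuisance allele frequencies
uniform on 0–0.3, toy genome 100 kb) were chosen once as realistic for
the data type and are documented rather than revisited.

The generated sequence reproduces the *published coordinates and
lengths* of the transcript, not the true CanFam3.1 sequence — exact
sequence fidelity is explicitly not claimed, and no real-data properties
(linkage disequilibrium, demography, read-level error, genotype-quality
distributions) are modelled. Passing tests therefore demonstrate
correctness of the filtering and annotation logic under Mendelian
genotypes, not robustness to real-world call-set noise; the
missing-genotype and sex-contig policies are where that robustness would
enter, and they are configurable.

Determinism: one master integer seed drives every generator through
derived substreams, restoring the caller's RNG state afterwards; the
same seed yields byte-identical output bundles.

# Numerical and design notes

* Coordinates are 1-based inclusive throughout, so the length of an
  interval is `end − start + 1` (the seven-cytosine run spans seven
  positions).
* Multiallelic VCF records are split into biallelic rows; in each row,
  alleles of a *different* alternate are recoded as reference. This
  keeps the segregation filter binary; the alternative (dropping such
  genotypes) would discard trio information at mixed sites.
* Phased and unphased genotype separators are treated identically — no
  stage of the cascade uses phase.
* Any missing allele makes the whole diploid call missing.
* Upstream variant-quality filtering (GQ/DP thresholds) is assumed done
  by the caller; the upstream analysis applied its caller's defaults
  without enumerating them, so no threshold is guessed here.
* The orchestration layer is a pair of R functions (`runGenerate()`,
  `runDiscovery()`) over the module operations, configured by a named
  list or JSON file with toggles and threshold overrides; reports echo
  the full configuration for provenance.
* Test problem sizes: the consequence caller is checked against a
  brute-force re-translation oracle on 200+ random CDS/edit pairs
  (15–60 codons), the trio filter against all 64 genotype combinations,
  and causal-variant recovery over 100 seeded replicates of the default
  bundle; these sizes give exhaustive or high-multiplicity coverage in
  seconds.

# Known limitations

Compound heterozygotes, de-novo models, linkage/IBD mapping, splice-site
effects, UTR variants, NMD-escape rules and reduced penetrance are out
of scope. BCF and structural variants are not supported. Single
transcript per gene; no canonical-transcript selection.

# A worked run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 7)
dir <- tempfile()
runGenerate(cfg, dir)
report <- runDiscovery(list(
    vcf = file.path(dir, "quartet.vcf"),
    pedigree = file.path(dir, "pedigree.tsv"),
    reference = file.path(dir, "reference.fa"),
    transcripts = file.path(dir, "transcripts.tsv"),
    panelVcf = file.path(dir, "panel.vcf"),
    scores = file.path(dir, "scores.tsv"),
    geneList = file.path(dir, "genes.txt"),
    cohort = file.path(dir, "cohort.tsv")))
report$filterSummary
report$candidates
```

The cascade funnels the six simulated variants down to the planted
insertion, annotated `c.4176insC` / `p.F1393Lfs*1395`, damaging, in the
disease-gene list, with a fully concordant 22-animal validation cohort.
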