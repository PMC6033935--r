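---
title: "Family-based variant prioritization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelsieve)
```

## The problem

In a rare Mendelian disease study, whole-exome sequencing of a handful of
families yields millions of called variants, of which at most a few are
causal. `mendelsieve` implements the standard triage funnel for this
setting, specialized for nuclear families with known affection statuses:

1. **Rarity** — a severe, fully or highly penetrant disease allele cannot
   be common. Variants whose *pooled maximum* allele frequency across
   reference cohorts (columns emulating 1000 Genomes, NHLBI-EVS and ExAC)
   exceeds `max_af` are removed. The default is 0.2% (`max_af = 0.002`)
   with a strict `>` comparison, so a variant observed at exactly 0.2%
   survives. Pooling by maximum is the conservative reading of "present
   in either cohort"; a per-source threshold would only pass more
   variants.
2. **Impact** — only protein-altering consequences are retained:
   missense, nonsense (stop gained/lost), start loss, frameshift,
   in-frame indels and the two intronic splice-site bases. "Potentially
   protein-altering" is interpreted as the splice region (3–8 nt into the
   intron) and sits behind `include_potentially_altering`, off by
   default, because the class is not precisely defined in common usage.
3. **Segregation** — each family is tested independently against three
   inheritance models (below).
4. **Panel intersection** — candidates are restricted to genes on a
   disease panel (for retinal disease, a RetNet-style list).
5. **Known-gene review** — every variant present in a family within a
   designated known disease gene is added back *unconditionally*,
   regardless of frequency, impact or segregation. This mirrors manual
   review practice and is deliberately placed after the panel stage so a
   review gene outside the panel still surfaces.

The funnel records the surviving-variant count after each stage; counts
are monotone non-increasing through stages 1–4, and stage 5 may add.

## Isoform-aware annotation

Consequences are computed per transcript isoform and all are retained: a
variant can be missense on one isoform and noncoding on another. Gene
membership for segregation is the union over isoforms with a
protein-altering consequence, so a compound-heterozygous pair may combine
variants that are coding on *different* transcripts of the same gene —
the configuration this package exists to detect. The packaged fixture
encodes exactly that situation: a toy two-isoform gene in which one
variant is coding only within the alternate isoform's unique exon.

Coordinates are 1-based inclusive throughout (VCF/GFF convention); there
is no internal 0-based layer. Codon arithmetic is the standard HGVS
relation `codon = ceiling(cds_pos / 3)`. Indel consequences are
simplified to length-mod-3 frameshift/in-frame classification without
repeat left-alignment, which is exact for the SNV-only fixture and
adequate for simulated indels.

## Segregation models

All models operate on per-member zygosities (`hom_ref`, `het`,
`hom_alt`, `missing`) and are autosomal; sex is stored for pedigree
validation only. A model never fits a family with no affected member — a
vacuously satisfied pattern carries no evidence. Missing genotypes raise
`missing_genotype` exceptions and fail a model under the default strict
handling (`strict_missing = TRUE`); the lenient mode treats them as
compatible, which is appropriate only when missingness is rare and
random.

**Recessive homozygous (`AR_hom`).** Every affected member homozygous
for the alternate allele; no unaffected member homozygous; every
genotyped parent of an affected member heterozygous (the obligate
carrier constraint). Unaffected carriers are expected and fine.

**Dominant (`AD`).** In strict mode, every affected member carries the
allele and no unaffected member does; a de novo configuration (affected
child, non-carrier parents) is allowed. In incomplete-penetrance mode,
unaffected carriers are tolerated but each is reported as an
`unaffected_carrier` exception, so the asymptomatic-carrier-parent
configuration fits while remaining visible in the report.

**Compound heterozygous (`comp_het`).** For each unordered pair of
variants in one gene: every affected member heterozygous for both, no
unaffected member heterozygous for both, and the trans configuration
certain for every affected member. Trans certainty is inferred from
parental genotypes without phased calls — input phase is discarded
because pedigree-derived phase is the stronger evidence. For each
variant, the possible donor parents are those that carry the alternate
allele *while the other parent can supply the child's reference allele*;
the second clause matters because a homozygous-alternate parent
transmits the allele to every child, which can both force and resolve
phase. If each variant has exactly one possible donor and the donors
differ, trans is certain; if some variant has no possible donor the pair
is Mendelian-inconsistent and rejected; if both variants are forced to
the same donor, cis is certain and the pair is rejected even under
`allow_phase_unknown`; anything else is `phase_unknown`, rejected by
default and accepted with `allow_phase_unknown = TRUE`.

This closed-form rule is tested for exact equivalence against a
brute-force oracle that enumerates all phased parental haplotype
configurations and transmissions, over every Mendelian-consistent
genotype assignment on trio and quartet pedigrees.

When several models fit the same variant in a family (a recessive
homozygote is also a trivially consistent incomplete-penetrance
dominant), the report keeps one row per family-variant using the fixed
precedence `AR_hom > comp_het > AD_strict > AD_incomplete_penetrance >
known_gene_review` — most-constrained first, since a more constrained
fit is rarer under the null. `report_all` disables nothing here; it
controls whether non-fitting scan verdicts are returned by
`segregation_scan()`.

Both the dominant filter and the review route are provided for the
asymptomatic-carrier configuration: a heterozygous variant in a known
gene whose carrier parent is unaffected is found by the
incomplete-penetrance model when that model is enabled, and by the
known-gene review otherwise, so either analysis route reproduces the
same candidate.

## The synthetic-data generator

No genotype data are packaged; everything is built in code.

`build_fixture()` is deterministic and encodes the four-family study
design: 20 members, 8 affected; two recessive-homozygous families, one
compound-heterozygous family whose pair spans two isoforms, and one
dominant family with an asymptomatic carrier father. The toy gene is
*synthetic*: only the constrained codons (reference amino acids Arg47,
Thr91, Tyr131, Arg150 on the canonical isoform and Val216 on the
alternate), the resulting substitutions, and the two-isoform exon
geometry are fixed; filler codons are an arbitrary stop-free cycle and
genomic coordinates are arbitrary constants. The canonical isoform is
scaled to 250 codons (the real protein has 585) — nothing downstream
depends on its length beyond containing codon 150. One fixture variant
carries a tiny non-zero population frequency (1e-4) because its
real-world counterpart had been previously reported; the others are
novel. Three decoy variants in a second gene make the rarity, impact and
segregation stages each do real work, so the fixture funnel is
8 → 7 → 6 → 5 → 5 → 5.

`simulate_cohort()` performs gene-drop simulation: founder alleles drawn
from Hardy–Weinberg at each variant's frequency, one allele transmitted
per parent per child, uniformly. Causal genotypes are planted
constructively (parents seeded as carriers, proband forced into the
causal configuration — forcing a valid transmission outcome, never an
inconsistent one) and affection is assigned from genotype: carriers of
the causal configuration are affected with probability `penetrance`,
the proband always (families are ascertained through an affected
proband), everyone else unaffected. Phenocopies are not simulated.
Background variants are cohort-level — shared across families like real
population variation in a joint-called VCF — with frequencies from a
point-mass/uniform mixture whose default support is 1%–50%, entirely
above the 0.2% filter. The default benchmarking condition is 50 nuclear
quartets per model, 200 background variants, error rate 0 and penetrance
1; at that size the full recovery experiment runs in well under a minute.

What passing these simulations does **not** show about real data:
genotyping error, phenocopies, locus and allelic heterogeneity,
population stratification, linkage between background variants and
pedigree-relationship errors are all absent. The recovery experiment
validates the *logic* of the funnel, not its sensitivity on noisy
exomes; the `genotyping_error_rate` knob exists precisely to probe how
strict missing/mismatch handling loses families, with no fixed expected
value.

## Junction support

Split-read counting is exact: a read supports a junction only when two
consecutive aligned blocks end at the donor's last exonic base and start
at the acceptor's first exonic base, with at least `min_overhang`
(default 3) aligned bases on each side. No fuzzy window is applied;
junction-calling tolerance belongs in the aligner, not the counter.
Duplicate read ids are counted once. Junctions are represented in
genomic orientation (left exon end, right exon start) regardless of
strand, which is unambiguous for counting. Input is a minimal SAM subset
(QNAME, RNAME, POS, CIGAR); per-base coverage is deliberately not
normalized.

## Numerical and degenerate-input choices

* Ties in report ordering are broken by (family, gene, position, alt,
  model), making reports byte-identical across runs and input orders.
* Empty inputs propagate: an empty VCF yields an empty report with an
  all-zero funnel; a single-exon transcript has no junctions; a gene
  with one variant has no pairs.
* Multiallelic sites are split before any filtering; in a split record,
  alleles belonging to other ALTs become missing half-calls, and
  zygosity counts alternate dosage over the observed alleles (so `1/2`
  is het for each of its two ALTs).
* Frequency-table absence means frequency 0, which is the correct prior
  for a novel variant under a rarity *ceiling*.

## Limitations

X-linked and mitochondrial models are not implemented (the motivating
loci are autosomal), consanguinity loops are not encoded, phasing from
read-backed evidence is out of scope, and the absolute variant counts of
a real exome funnel are not reproducible from synthetic cohorts — the
package reproduces the funnel's shape and endpoints, not its raw-data
magnitudes.
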