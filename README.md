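# mendelsieve

Family-based prioritization of candidate disease variants in
multi-sample exome VCFs, for rare-disease researchers working with
small pedigrees. The package implements the classic triage funnel used
to pin down causal mutations in Mendelian retinal disease — its
motivating use case is bestrophinopathy, where *BEST1* variants may act
recessively (homozygous or compound heterozygous, including pairs that
span different transcript isoforms) or dominantly with incomplete
penetrance.

## The method

Given a joint-called VCF, PED pedigrees, transcript models with coding
sequences, and a population allele-frequency table, the funnel applies,
in fixed order:

1. **Rarity** — drop variants with pooled max AF > 0.2%
   (`max_af = 0.002`, strict `>`, maximum over reference cohorts).
2. **Impact** — keep protein-altering consequences on *any* isoform
   (missense, nonsense, start loss, frameshift, in-frame indel,
   splice site; splice region optionally).
3. **Segregation**, per family:
   * `AR_hom` — every affected hom-alt, no unaffected hom-alt, each
     genotyped parent of an affected an obligate het carrier;
   * `comp_het` — for a variant pair in one gene: every affected het
     for both, no unaffected het for both, and the pair in *trans*,
     inferred from parental genotypes (each variant must have a unique
     possible donor parent and the donors must differ);
   * `AD` — all affected carriers; strict mode forbids unaffected
     carriers, incomplete-penetrance mode reports them as exceptions.
4. **Panel intersection** — keep genes on a disease panel
   (RetNet-style).
5. **Known-gene review** — add back every variant present in a family
   within a designated known disease gene, unconditionally.

Gene membership is collapsed across isoforms, so a compound-het pair
may combine variants coding on different transcripts of one gene. A
gene-drop simulator (Hardy–Weinberg founders, uniform transmission)
generates benchmarking cohorts with planted causal configurations, and
a junction module counts isoform-discriminating split reads from
SAM-style spliced alignments. Codon arithmetic follows
`codon = ceiling(c / 3)`, e.g. c.392 → codon 131.

## Worked example

The packaged fixture encodes four bestrophinopathy-style families
(20 members, 8 affected) genotyped at a synthetic two-isoform toy gene
plus decoys:

```r
library(mendelsieve)

fx <- build_fixture()
cfg <- pipeline_config(panel_genes = fx$panel_genes,
                       review_genes = fx$review_genes)
report <- run_pipeline(fx$vcf, fx$peds, fx$transcripts,
                       fx$coding_seqs, fx$freqs, cfg)
report
#> candidate_report: 5 row(s), 5 distinct variant(s)
#> funnel: input=8 -> rare=7 -> protein_altering=6 -> segregating=5 -> panel=5 -> final=5
```

The funnel starts from 8 sites, loses one common decoy to the rarity
filter, one synonymous decoy to the impact filter, one non-segregating
decoy at the segregation stage, and ends with 5 candidate variants:

```r
report$candidates[, c("family_id", "key", "model")]
#>   family_id key            model
#> 1 A         chr11:1392:A>G AR_hom
#> 2 B         chr11:1449:G>C AR_hom
#> 3 C         chr11:1140:G>A comp_het
#> 4 C         chr11:4106:G>A comp_het
#> 5 D         chr11:1272:C>T AD_incomplete_penetrance
```

Families A and B fit the recessive-homozygous model (het parents,
hom-alt affected children); family C carries a compound-het pair whose
second variant is coding only on the alternate isoform's unique exon;
family D's heterozygous variant fits the dominant model with two
`unaffected_carrier` exceptions (the asymptomatic father and sister),
recorded in the report's `notes` column. `write_report(report, path)`
serializes this as a TSV with the funnel in a commented header.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --fixture --out fixture_dir
Rscript inst/cli/prioritize.R --vcf fixture_dir/fixture.vcf \
  --ped fixture_dir/fixture.ped --transcripts fixture_dir/transcripts.tsv \
  --fasta fixture_dir/coding.fa --freq fixture_dir/freqs.tsv \
  --panel fixture_dir/panel.tsv --review-genes BEST1 --out report.tsv
```

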