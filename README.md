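# perichrom

Downstream annotation and enrichment analysis for differential chromatin
peak sets against pericentromeric heterochromatin.

When a genetic perturbation changes chromatin accessibility (ATAC-seq) or
an activity mark (H3K27ac ChIP-seq), the follow-up questions are spatial:
do the changed regions concentrate in pericentromeric heterochromatin, in
HP1-bound or H3K9me3-marked domains? Which genes do the peaks belong to,
and how far from their TSSs do they sit? How do the affected gene sets
split by expression status and five-colour chromatin state? perichrom
answers those questions reproducibly, starting from peak tables (it does no
peak calling itself), and ships a seed-deterministic synthetic-genome
generator so the entire pipeline is testable without sequencing data.

## The statistics at the core

For a query peak set *Q* and region set *R* on a genome of *N* bp, the
base-pair contingency table (a = bp in *Q*∩*R*, b = *Q*-only, c = *R*-only,
d = remainder, a+b+c+d = N) is tested with the uncorrected Pearson
chi-squared statistic

    X² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)),  df = 1,

and every (query, region) family is BH-corrected. Because bases within one
peak are correlated, the bp-scale test is reported descriptively; the
significance call (`enriched`) comes from the peak-count mode (peaks
overlapping *R* versus the binomial expectation under *R*'s genome
fraction), and a within-chromosome, length-preserving permutation test is
available as the assumption-free confirmation. Peaks are assigned to genes
curated-map-first, then nearest TSS (edge-based distance; proximal ≤ 5 kb;
bins 0–1, 1–5, >5 kb).

## Worked example

```r
library(perichrom)

sim <- simulate_dataset(default_sim_spec(seed = 1))
report <- enrichment_report(
  sim$peaks,
  c(list(pericentromeric = sim$het_map$intervals), sim$tracks),
  sim$sizes, alpha = 0.001)
subset(report, region == "pericentromeric" & mode == "peak",
       select = c(query, observed_fraction, background_fraction, q_value, enriched))
```

```
      query observed_fraction background_fraction   q_value enriched
2   ATAC_UP            0.2085               0.141 4.702e-24     TRUE
8 ATAC_DOWN            0.1472               0.141 3.834e-01    FALSE
```

The default design plants an accessibility-gain set with heterochromatin
placement probability 0.221 against a 14.1% pericentromeric background and
a loss set placed at exactly the background rate: the gain stratum is
flagged (q ≈ 5e-24), the loss stratum is not (q ≈ 0.38). The observed
fractions are the per-seed binomial realizations of the planted 0.221 and
0.141.

The same analysis runs from the shell on files:

```sh
Rscript inst/cli/perichrom.R simulate --config config.yaml --outdir simdata
Rscript inst/cli/perichrom.R run      --config run.yaml    --outdir results
```

`run` writes one TSV per report panel (`distance_bins.tsv`,
`expression_breakdown.tsv`, `state_breakdown.tsv`, `venn_genes.tsv`,
`enrichment.tsv`/`summary.tsv`, per-set `assignments_*.tsv`) plus a
provenance log with the config hash and seed.

### Config schema (YAML)

```yaml
seed: 1
outdir: results
inputs:
  chrom_sizes: chrom_sizes.tsv        # name <TAB> length
  genes: genes.refflat.tsv            # gene_id chrom strand start end (0-based)
  genes_dialect: refflat              # or gff
  states: states.bed                  # BED4, state in {black,blue,green,yellow,red}
  curated: curated.bed                # BED4, genes ';'-joined (optional)
  expression: expression.tsv          # gene_id log2fc p fdr tpm
  peaks:
    - {label: ATAC_UP, path: peaks_ATAC_UP.bed, assay: ATAC, dialect: bed6plus}
  tracks:
    - {label: HP1, path: track_HP1.bed}        # BED3
boundaries:
  arms:
    - {chrom: simA, boundary: 2577000, side: RIGHT_OF_BOUNDARY}
  whole: []                           # fully heterochromatic chromosomes
thresholds:
  alpha: 0.05          # FDR level for the enriched flag
  min_bp: 1            # minimum overlap for a peak to count
  tpm_cutoff: 1        # "expressed" definition
  log2fc: 0.4          # gene-set |log2FC| threshold (strict)
  significance: 0.05   # gene-set significance cutoff (strict)
  significance_kind: FDR   # or P
```

Peak files in `bed6plus` dialect carry direction (`UP`/`DOWN`) and the most
stringent FDR tier (`0.05`/`0.01`/`0.001`) in columns 7–8; the `tsv`
dialect uses named header columns. Unknown config keys are rejected.

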