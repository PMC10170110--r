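# scSmallRNA

Decoding, quantification and quality control for **single-cell small RNA
sequencing** libraries built on a nanowell protocol: reads carry a fixed
adapter architecture — `AAANNAAANNAAANN` + insert + `NNCTGTAGGCAC` — whose
free (`N`) bases form an 8-nt unique molecular index (UMI), plus a 12-nt
cell barcode. The package is for researchers who want to turn such raw
FASTQ runs into per-cell small RNA expression matrices, and to validate
every analytical step against simulated data with known truth.

## What it computes

For each read the decoder recovers (cell barcode, UMI, insert), correcting
barcodes against a whitelist within Hamming distance 2 (ties discarded).
Inserts of 16–39 nt are aligned to the genome with **zero mismatches** on
both strands; all loci are kept. Hits are assigned to same-strand
annotated features by biotype priority (miRNA > tRNA > rRNA > snRNA >
snoRNA > CDS > other). Within each (cell, feature), reads with identical
or 1-mismatch-adjacent UMIs collapse into molecules (connected
components), and a molecule mapping to *n* loci contributes 1/*n* per
locus, so the matrix mass equals the deduplicated molecule count.

Quality and downstream statistics:

- per-cell **saturation** `1 − N_deduped/N_total`;
- **small RNA ratios** (per-cell barcoded and bulk forms);
- pairwise **Jaccard reproducibility** of detected species;
- **downsampling** sensitivity curves (miRNA species vs depth);
- **cell-ontology scoring**: Spearman correlation to a reference atlas,
  term enrichment by the modified t-test
  `t = (m − M)/√(s²/n + S²/n)`, `df = (n−1)(s²+S²)²/(s⁴+S⁴)`;
- **marker calling**: one-vs-rest Wilcoxon rank-sum per cluster, markers
  at corrected p < 0.01, in-cluster fraction > 0.2, logFC > 1.

A fully seeded simulator (`simulate_dataset()`) generates reference,
annotations, whitelist, FASTQ reads and truth tables, including the
power-law expression skew under which a cell's ten most abundant miRNAs
carry more than half of its miRNA molecules.

## Worked example

```r
library(scSmallRNA)

cfg <- sim_config(seed = 1, n_cells = 20, molecules_per_cell = 200,
                  duplication = 5, error_rate = 0.005)
sim <- simulate_dataset(cfg, "simdata")

res <- run_pipeline("simdata/reads.fastq", "simdata/reference.fa",
                    "simdata/annotations.gff3", "simdata/whitelist.txt",
                    barcode_fastq = "simdata/barcodes.fastq")
res$counters
#>                 ok        no_adapter5        no_adapter3         bad_length
#>              18169                887                943                  0
#> barcode_unassigned              total
#>                  1              20000
head(res$qc[, c("cell_barcode", "n_total_reads", "n_deduped_reads",
                "saturation", "n_mirna_species", "mirna_fraction")], 3)
#>   cell_barcode n_total_reads n_deduped_reads saturation n_mirna_species
#> 1 ACCCCACTTTGG           779             198  0.7458280              39
#> 2 AGATCCTAATTT           816             200  0.7549020              32
#> 3 AGCTAAAGGCGT           790             200  0.7468354              42
#>   mirna_fraction
#> 1      0.6818182
#> 2      0.7300000
#> 3      0.7250000
```

Reading the output: 90.8% of reads decode cleanly (the rest lost mostly
to substitution errors in fixed adapter bases); each cell's ~200
simulated molecules are recovered from ~800 mapped reads at a saturation
near `1 − 1/5 = 0.8`; fractional deduplicated counts appear where a
molecule multimaps. `write_matrix_dir()` exports the matrix as a
10x-style MatrixMarket triplet; `normalize_log()`, `find_markers()`,
`spearman_to_reference()` and `ontology_score()` take it from there.

A thin CLI over the same functions ships in
`inst/scripts/scsmallrna.R` (subcommands `simulate`, `demux`, `quant`,
`qc`).

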