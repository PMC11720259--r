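# rohscape

Runs of homozygosity (ROH), genomic inbreeding and ROH islands from
SNP-array genotypes.

When two copies of a chromosome segment descend from the same ancestor, the
individual is homozygous at every SNP along it. `rohscape` detects these
runs with the standard sliding-window scan on PLINK text genotypes, turns
them into the genomic inbreeding coefficient

> F_ROH = Σ L_ROH / L_genome

with its decomposition into recent and ancestral components (ROH of length
≥ 100/(2g) Mb date inbreeding to within g generations: ≥ 16.6 Mb → 3
generations, ≥ 8.3 Mb → 6, ≥ 5.5 Mb → 9; the remainder is ancestral), and
scans the population for **ROH islands** — regions where ROH incidence is
far above the uniform-null expectation p = (M − c + 1)/(M + 1) — annotating
them with overlapping genes from BED/GFF3. The minimum SNPs per run follow
the false-positive control L = ln(α/(n_s·n_i)) / ln(1 − het); at a
64,203-SNP, 506-individual equine panel with het = 0.323 this gives the
default L = 52.

Because datasets of this kind are usually confidential, the package ships a
synthetic-population generator (`simulate_population()`) that plants
homozygous tracts and shared islands with full ground truth, so the entire
pipeline is validated end-to-end against known answers.

Audience: population and conservation geneticists working with SNP-array
genotypes of livestock or other managed populations.

## Worked example

```r
library(rohscape)

cfg <- sim_config(seed = 11, n = 40L,
                  islands = data.frame(chrom = 3L, center_bp = 5e7,
                                       span_bp = 2.5e6, carrier_frac = 0.9))
sim <- simulate_population(cfg)
sim$gm
#> genotype_matrix: 40 individuals x 14000 SNPs on 5 chromosome(s)
#>   missing rate 0.0052

seg <- detect_roh(sim$gm)          # sliding-window scan, defaults w = L = 52
nrow(seg)
#> [1] 636
head(seg, 3)
#>   individual chrom start_bp   end_bp n_snps length_bp
#> 1     ind001     1 25076166 27940944     72   2864778
#> 2     ind001     1 58825735 60796456     57   1970721
#> 3     ind001     2   995122 16886992    480  15891870

rec <- compute_froh(seg, sim$truth$genome, individuals = sim$gm$individuals)
summarize_froh(rec)
#>   coefficient  mean    sd pct_of_froh
#> 1       F_ROH 0.159 0.051          NA
#> 2    F_ROH_3G 0.011 0.018           7
#> 3    F_ROH_6G 0.045 0.039          28
#> 4    F_ROH_9G 0.078 0.042          49
#> 5   F_ROH_ANC 0.081 0.025          51

tr  <- incidence_pvalues(snp_incidence(seg, sim$gm))   # closed-form null
call_islands(tr, p_max = 0.05)
#>   island chrom start_bp   end_bp n_snps     mean_p length_bp
#> 1      1     3 48811356 51243085     72 0.04129129   2431729
```

Reading: the cohort carries a mean genomic inbreeding of 0.159 (SD 0.051),
of which about half traces to events more than nine generations back
(F_ROH_ANC share 51%) and only 7% to the last three generations. The one
called island is exactly the 2.5-Mb region planted at 47.5–52.5 Mb on
chromosome 3 in 90% of individuals (at n = 40 the minimum attainable null
p is 1/(M+1) ≈ 0.026, hence the relaxed `p_max`; at study-scale cohorts
the default 0.01 applies). `run_pipeline()` chains all stages and writes
the report tables (`roh_segments.tsv`, `froh_individual.csv`,
`islands.csv`, ...) plus a JSON manifest of every parameter and seed;
`inst/scripts/roh_pipeline.R` wraps it for shell use.

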