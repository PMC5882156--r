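# tfcensus

Comparative census and domain-architecture analysis of prokaryotic
DNA-binding transcription factor (TF) families.

Most bacterial and archaeal TFs combine a DNA-binding domain (DBD), which
defines the TF's family, with one or more *companion domains* (CDs) that
bind ligands, mediate oligomerization, or carry enzymatic activity.
`tfcensus` takes per-genome structural-domain assignment tables (precomputed
HMM hits — the package never scans sequences) and computes, for the 19
canonical TF families:

* **Abundance** — per-family, per-genome member counts `A_i`, normalized
  profiles `A_n = (A_i − A_avg)/A_sdv`, Pearson correlation of abundance
  with genome size (in ORFs) with the strong / intermediate / low classes
  (R ≥ 0.70 / 0.20–0.70 / < 0.20), percentage shares, and the four
  abundance groups.
* **Lifestyle stratification** — per-genome TF proportions (TFs / ORFs)
  grouped by *free-living*, *pathogen*, *extremophile*, *intracellular*;
  tie-corrected Kruskal–Wallis comparison; family-by-lifestyle occurrence
  rates clustered with Manhattan distance and average linkage (Newick
  export).
* **Promiscuity** — per family and genome, the weighted
  domain-architecture score

      IAF = log2(P_t / P_d)      IV = 1 / f_d      WS = IAF × IV

  where `P_t` is the genome's protein count, `P_d` the proteins carrying
  the family DBD, and `f_d` the number of distinct partner domains adjacent
  to the DBD. WS near 0 marks promiscuous families, high WS monolithic
  ones; families are classified by the coefficient of variation of WS
  across genomes (boundaries 1.55 / 3.0). Genome sizes are binned with
  Sturges's rule `k = round(1 + log2(N))`.
* **Enrichment** — one-tailed Fisher's exact test (upper hypergeometric
  tail) for every DBD–CD pair over the TF-protein universe, with joint
  Benjamini–Hochberg correction and the `p_adj ≤ 1e-10` significance rule;
  unique-CD flags and the directed CD-sharing matrix between families.
* **Synthetic data** — a deterministic generator that emulates the
  reference dataset (761 genomes, 672 bacteria + 89 archaea, ORF range
  500–9696, published family rates and CD pool sizes) with planted,
  recoverable structure: abundance–size slopes, CD-usage concentration,
  lifestyle effects, and DBD–CD enrichments, all recorded in a truth
  ledger.

## A worked example

```r
library(tfcensus)

ds <- generate_dataset(synthetic_config(n_genomes = 60, seed = 7))
dir <- tempfile(); out <- tempfile()
write_dataset(ds, dir)

res <- run_pipeline(pipeline_config(dir, out))
head(res$report[, c("family", "total", "share_pct", "pearson_r",
                    "cv", "promiscuity_class")], 8)
```

```
      family total share_pct pearson_r   cv  promiscuity_class
14      LysR   833     14.85     0.855 1.30 highly_promiscuous
18 TetR/AcrR   797     14.21     0.842 1.34 highly_promiscuous
10      GntR   482      8.59     0.769 1.11 highly_promiscuous
15      MarR   453      8.08     0.736 1.13 highly_promiscuous
17      SinR   427      7.61     0.729 1.19 highly_promiscuous
1  AraC/XylS   412      7.35     0.750 1.08 highly_promiscuous
9       GerE   386      6.88     0.699 1.12 highly_promiscuous
16      PhoB   306      5.46     0.732 1.01 highly_promiscuous
```

LysR and TetR/AcrR dominate the synthetic collection (≈29% of all TFs
together, as planted from the published family totals), and the abundant
families correlate strongly with genome size. Further down the same run:

```r
res$census
#>  monodomain  two-domain multidomain
#>       0.307       0.607       0.087      # planted: 0.32 / 0.59 / 0.09
res$kruskal$p_value
#> 6.35e-06                                 # free-living > ... > intracellular
sum(res$enrichment$enriched)
#> 33                                       # DBD-CD pairs at p_adj <= 1e-10
```

`run_pipeline()` writes every stage table (`abundance_matrix.tsv`,
`family_summary.tsv`, `lifestyle_summary.tsv`, `ws_scores.tsv`,
`promiscuity_classes.tsv`, `enrichment.tsv`, `sharing_matrix.tsv`, a
consolidated `family_report.tsv`, a Newick dendrogram and a run manifest)
into the output directory, each stamped with the run's configuration hash.

A thin command-line wrapper lives at `inst/cli/tfcensus.R`:

```sh
Rscript inst/cli/tfcensus.R generate --out data/ --genomes 100 --seed 1
Rscript inst/cli/tfcensus.R validate --in data/
Rscript inst/cli/tfcensus.R all --in data/ --out results/
```

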