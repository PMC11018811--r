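# tcrtrack

Clonal tracking of T cell receptor (TCR) repertoires across tissue
compartments.

## What this is for

In adoptive-transfer experiments — e.g. donor regulatory T cells (Treg)
infused to prevent graft-versus-host disease after allogeneic bone marrow
transplantation — a cell product with a UMI-sequenced TCR repertoire is
injected, and the donor cells are later re-isolated from host organs
(spleen, liver, colon) and sequenced again. `tcrtrack` answers the clonal
questions of such designs:

* Did in vitro expansion (polyclonal vs allo-antigen-selective) narrow the
  repertoire? — rarefied **inverse Simpson diversity**,
  `iSI = 1 / Σ p_i²`, after hypergeometric downsampling to a common UMI
  depth.
* How much do repertoires overlap between organs, recipients and the
  graft? — **Morisita–Horn** index `2Σpq / (Σp² + Σq²)`, the classical
  Morisita variant, and directional/pooled **UMI-overlap fractions** for
  circos-style sharing plots.
* Are clones organ-spanning or organ-restricted? — **barycentric
  coordinates** `w_X = f_X / Σf` over three compartments with a normalized
  clone size, plus a `restricted / biased / ubiquitous` classification.
* Do organ-detected clones concentrate among the top frequency ranks of
  the graft? — **TSEA** (TCR set enrichment analysis): standardized mean
  rank of the hits (closed-form null moments), permutation p-value with
  the add-one estimator, GSEA-style running sum and fixed-scale "worm"
  densities.
* Is a designated Vβ segment set (default *Trbv12-1*, *Trbv12-2*,
  *Trbv26*) enriched in one organ or cell cluster? — two-sided **Fisher
  exact tests** per group vs rest with **Benjamini–Hochberg** correction.

Inputs are clonotype tables: AIRR Rearrangement TSV, MiXCR-style export
TSV, and 10x `filtered_contig_annotations`-style CSVs (reduced to
paired-αβ single-cell clones). Read-level processing is out of scope.

A first-class synthetic-data module (`sim_config()`,
`simulate_experiment()`) emulates the whole design — heavy-tailed donor
repertoire, poly/allo expansion, three-organ seeding in several recipients
with planted alloreactive, tissue-restricted and bystander clone classes —
so every analysis stage can be validated against ground truth.

## Worked example

```r
library(tcrtrack)

ex <- simulate_experiment(sim_config(seed = 1))

# diversity: allo-selective culture narrows the repertoire
diversity_profile(list(ex$donor$table, ex$products$poly, ex$products$allo),
                  n_reps = 25, seed = 1)
#>   sample_id    depth n_reps   isi isi_sd    seed
#> 1 donor_fresh  11928     25  834.   0    1030526
#> 2 poly_product 11928     25  754.  19.1   203303
#> 3 allo_product 11928     25  294.   6.47   63336
```

The fresh donor repertoire has an effective size of ~834 clones at the
common depth; polyclonal expansion largely preserves it (~754) while
allo-selective expansion narrows it sharply (~294).

```r
pools <- lapply(c("spleen", "liver", "colon"), function(o)
  pool_samples(ex$organs$poly[grepl(o, names(ex$organs$poly))], o))
round(pairwise_overlap(pools), 4)
#>        spleen  liver  colon
#> spleen 1.0000 0.9996 0.9629
#> liver  0.9996 1.0000 0.9619
#> colon  0.9629 0.9619 1.0000
```

Spleen and liver repertoires are the most alike; the colon deviates,
carrying its tissue-restricted component.

```r
table(top_clones(barycentric_points(pools), 500)$class)
#> biased(colon)    ubiquitous
#>             1           499
```

Essentially all of the 500 largest re-isolated clones span all three
organs — the organ-spanning, alloantigen-driven component dominates.

```r
segment_set_enrichment(setNames(pools, c("spleen", "liver", "colon")))
#>    group set_in_group nonset_in_group odds_ratio        p      p_adj
#> 1 spleen           68            1941       0.75 0.0464   0.0696
#> 2  liver           71            1963       0.78 0.0871   0.0871
#> 3  colon          110            1912       1.62 0.00034  0.0010
```

The planted Vβ set is significantly enriched only in the colon
(OR 1.62, BH-adjusted p ≈ 0.001).

```r
tsea_test(clone_keys(pools[[3]]), rank_reference(ex$products$poly),
          n_perm = 999, seed = 1)
#> TSEA: 2022 query keys, 1923 hits (99 absent from reference)
#>   standardized mean rank = 9.575, ES = 0.132
#>   permutation p = 0.001 (999 permutations, toward_top)
```

Clones re-detected in the colon sit far above random among the
frequency-ranked graft clonotypes.

`run_pipeline()` drives the same flow from a YAML/list config with
fail-fast validation and a checksummed output manifest; reruns with the
same seed are byte-identical.

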