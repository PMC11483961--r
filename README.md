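# kinscan

Pedigree reconstruction and gene-flow analysis for diploid biallelic SNP
panels, aimed at germplasm collections of clonally propagated crops
(grapevine and similar perennials), where a few founder cultivars have
generated networks of first-degree relatives that were then fixed by
vegetative propagation.

Given genotypes (VCF or TSV), chromosome lengths and a repeat mask,
kinscan:

* tiles the genome into windows holding a fixed span (default 200 kb) of
  non-repetitive sequence;
* classifies every window as **IBD0/IBD1/IBD2** for every accession pair
  from the IBS counts — opposite homozygotes (`ibs0`) are impossible
  under shared descent except through genotyping error, so a window is
  IBD2 if `ibs2/n ≥ t2`, else IBD1 if `ibs0/n ≤ t0`, else IBD0 — and
  calls **parent–offspring** pairs with the thresholds
  `IBD0 < 15%`, `IBD1 > 60%` of informative genome length and longest
  IBD0 segment `< 3.8 Mb`, and **clones** at `f_IBD2 ≥ 0.90`;
* validates candidate **P1 × P2 → F trios** by counting Mendelian
  inconsistencies over the 27 ordered genotype triples (15 compatible,
  12 incompatible, derived from first principles and symmetric in the
  parents), modelling the ~0.8% background of undercalled
  heterozygotes, and rejecting trios whose unmatching SNPs **cluster
  chromosomally** (runs of ≥ 3 windows whose error counts exceed a
  Bonferroni-corrected binomial tail) — the signature of a wrong parent;
* infers **full siblings** from accepted trios, assembles a typed,
  partially oriented **kinship network** (igraph; GraphML/DOT/TSV
  export) and extracts founder **descent groups**;
* scans for **haplotype sharing** with a reference accession that is
  homozygous across a target region, calls carrier **dosage** (0/1/2)
  without phasing, and estimates per-population **haplotype
  frequencies** — the crop-to-wild introgression analysis;
* groups accessions by externally estimated **ancestry coefficients**
  (strict `> 0.85` majority rule, otherwise "admixed").

A forward **pedigree simulator** generates panels with known
parent-offspring pairs, trios, full-sib quartets, clones, an error model
dominated by heterozygote-to-homozygote undercalls, and a planted
haplotype at exact population frequency, together with a machine-readable
truth set. It drives the entire test suite.

## Worked example

```r
library(kinscan)

sim   <- simulate_pedigree_data(sim_config(seed = 7))  # 20 accessions, ~20k SNPs
ws    <- build_windows(sim$genome)                     # 200 windows x 200 kb non-repetitive
pairs <- ibd_all_pairs(sim$genotypes, ws)
table(pairs$call)
#>            clone            other parent_offspring
#>                1              166               23

res <- search_trios(sim$genotypes, ws, pairs)
res$accepted[, c("p1", "p2", "f", "error_rate", "verdict")]
#>         p1    p2       f error_rate  verdict
#> 20 CloneB1 FndB2    Sib1     0.0045 accepted
#> 23   FndB3 FndB4    ParX     0.0035 accepted
#> 26   FndA1 FndA2  Quart1     0.0045 accepted
#> ...                                          (10 accepted trios in total)
```

The 23 parent-offspring calls are exactly the planted first-degree pairs
(including those through the clone `CloneB1` of founder `FndB1`, which
the trio search collapses to one representative). The accepted trios
carry Mendelian-inconsistency rates of 0.35–0.49% — pure genotyping-error
background, scattered across the genome. The four-offspring quartet
yields its 6 full-sib pairs:

```r
res$full_sibs            # 8 pairs: C(4,2) quartet + Sib1/Sib2 + ParX/ParXSib
g <- build_kinship_graph(pairs, res$accepted, res$full_sibs)
sort(descent_group(g, c("FndA1", "FndA2")))
#> "CloneB1" "Cross1" "FndB1" "FndB2" "Quart1" ... "Sib1" "Sib2"
```

A deliberately false pedigree — replacing a true parent by its full
sibling — is rejected for *clustered* inconsistencies, not merely an
elevated rate:

```r
test_trio(sim$genotypes, ws, "ParXSib", "FndB5", "Off8")$verdict
#> "rejected_clustered"
```

End-to-end runs (simulate → IBD → trios → network → haploshare) are
driven by `run_pipeline(run_config(...))` or a YAML config, write a
manifest with every effective parameter and output checksums, and are
byte-reproducible under a fixed seed. `inst/scripts/kinpipe.R` exposes
each stage on the command line.

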