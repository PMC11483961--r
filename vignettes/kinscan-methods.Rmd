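---
title: "Window-based IBD, trio validation and haplotype-sharing scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based IBD, trio validation and haplotype-sharing scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscan)
```

## Problem and scope

Germplasm collections of clonally propagated crops such as grapevine are
networks of first-degree relatives: a handful of founder cultivars has
generated many descendants within a few sexual generations, after which
genotypes were fixed by vegetative propagation. kinscan reconstructs that
structure from biallelic diploid SNP genotypes — typically a
reduced-representation panel with hundreds of thousands of genic SNPs —
and traces crop-to-wild gene flow through haplotypes shared with a
reference cultivar. It deliberately stops short of model-based ancestry
estimation (it *consumes* an externally estimated Q matrix), phasing,
likelihood-based parentage and probabilistic IBD HMMs.

## The window system

All pairwise statistics are computed in windows that hold a fixed span
(default 200 kb) of *non-repetitive* sequence. Repeat-masked sequence
carries few reliable SNPs and no information, so windows are accumulated
left to right along each chromosome and close at the exact base where
200 kb of non-repetitive sequence has been gathered; a window spanning a
repeat gap is physically wider, and the last window of a chromosome may
be short. Which repeat annotation defines "non-repetitive" is a user
input (a BED file); the package makes no assumption about its origin.
Coordinates follow the two standards exactly: VCF positions are 1-based,
BED intervals and all internal windows 0-based half-open.

## Pairwise IBD classification

For a pair of accessions, each window with at least `min_sites` (10)
doubly genotyped sites is summarised by the IBS counts: `ibs0` (opposite
homozygotes), `ibs2` (identical genotypes), `ibs1` (the remainder) and
the genotypic distance $(ibs_1 + 2\,ibs_0)/(2n)$. Classification rests
on one genetic fact: opposite homozygotes are impossible between
individuals sharing at least one haplotype by descent, except through
genotyping error. The dominant error mode of low-coverage
reduced-representation genotyping is the undercalled heterozygote (a het
read as a matching homozygote), which converts an `ibs1` site into an
apparent `ibs0` site at roughly half the het-to-hom rate. Hence:

* **IBD2** if $ibs_2/n \ge t_2$ (default 0.95),
* else **IBD1** if $ibs_0/n \le t_0$ (default 0.02),
* else **IBD0**.

$t_0 = 0.02$ tolerates an error regime of about 1% undercalled
heterozygotes. $t_2$ was set at 0.95 rather than something tighter
because a *true* IBD2 pair (a clone) already mismatches at
$\approx 2 \times$ the het-to-hom rate times the heterozygosity — around
0.8% of sites at the defaults — so with ~80 sites per window a 0.98
cutoff misclassifies ~14% of genuinely identical windows and drags
clone pairs below the clone cutoff; 0.95 leaves a sixfold margin over
the expected mismatch rate while remaining far above the
identical-genotype fraction of any true IBD1 window (~0.6).

Genome-wide, fractions $f_{IBD0}, f_{IBD1}, f_{IBD2}$ are weighted by
each informative window's non-repetitive span (uninformative windows
leave both numerator and denominator), and the longest IBD0 segment is
the physical bp span of the longest run of consecutive IBD0 windows
within a chromosome (uninformative windows do not interrupt a run). The
relationship call is:

* **clone** if $f_{IBD2} \ge 0.90$;
* **parent-offspring** if $f_{IBD0} < 15\%$, $f_{IBD1} > 60\%$ and the
  longest IBD0 segment is shorter than 3.8 Mb;
* **undetermined** below `min_windows` (50) informative windows;
* **other** otherwise.

The segment rule is what separates parent-offspring pairs from other
close relatives: any non-PO first/second-degree relative has *some*
genuine IBD0 tract, and with realistically few crossovers per
chromosome such tracts are several Mb long.

## Trio validation

A candidate trio P1 × P2 → F is tested at every site genotyped in all
three accessions. The compatibility of each ordered genotype triple is
derived from first principles — one offspring allele must be
attributable to each parent — giving 15 compatible and 12 incompatible
triples out of 27, symmetric in the parents. Incompatible sites in a
genuine trio arise from genotyping error (undercalled heterozygotes in
parent or offspring, plus hemizygous regions in real data) at a
background rate of roughly 0.8%; a wrong parent instead produces
inconsistencies *concentrated* in the genomic intervals where the
offspring's true parental haplotype is absent from the proposed parent.

The validator therefore distinguishes two rejection modes:

* **rejected_rate**: genome-wide inconsistency rate above `max_rate`
  (default 1.3%, above the background of genuine low-coverage trios yet
  below what a wrong close relative produces);
* **rejected_clustered**: a run of `run_min` (3) or more consecutive
  windows whose error counts exceed the one-sided Bonferroni-corrected
  tail of $\mathrm{Binomial}(n_w, \text{null rate})$ at
  $\alpha_w = 0.05$.

The null rate is `max(background_rate, lower-quartile window rate)`
with `background_rate` defaulting to 0.008. Two numerical choices
matter here. First, the null is *not* the trio's own genome-wide rate:
a wrong parent inflates that rate with the very clusters being sought
and masks them. Second, the robust floor uses the lower quartile rather
than the median because a substituted close relative can contaminate
about half of all windows, making a median bimodal. Both rejection
modes are reported separately because a genuine trio with sparse data
can run somewhat above the background rate yet show randomly scattered
inconsistencies.

`search_trios()` tests, for every accession, each unordered pair of its
parent-offspring partners, after collapsing clone pairs to a single
representative — panels are assumed to represent unique genotypes, and
a clone of a true parent would otherwise duplicate every trio it
resolves. Full siblings are offspring of the same unordered accepted
parent pair. An exhaustive mode re-tests arbitrary user-specified
combinations, which is how a popular-but-false pedigree is dissected:
`incompatible_regions()` then merges the flagged runs and reports how
much of the haploid genome is incompatible with the proposed parents.

## Kinship network

Accepted trios orient their two parent→offspring edges;
parent-offspring pairs never resolved in a trio stay unoriented;
full-sib edges are symmetric. A pair carries at most one edge, and trio
evidence upgrades an unoriented edge. Orientation beyond trio evidence
(e.g. historical precedence of one cultivar over another) is a matter
of interpretation, not computation, and is left to the user. Descent
groups are connected components reachable from a founder set through
parent-offspring edges in either direction; full-sib edges are not
followed (sibs of a member connect through their shared parents
whenever those are present).

## Haplotype sharing, dosage and population frequencies

The introgression scan exploits a reference accession that is
*homozygous* for the haplotype of interest across the target region
(verified before scanning, default ≥ 99% homozygous calls): at
reference-homozygous sites, an opposite homozygote in another accession
excludes sharing outright, no phasing needed. The scanned chromosome is
cut into `n_windows` (50) equal-width windows — a coarser grid,
independent of the 200-kb IBD windows. Per window a sharing state is
called: `shares_none` when opposite homozygotes exceed both a fraction
`t_err` (0.02) *and* a count `min_opp` (3) of informative sites;
`shares_two` when at least `t2` (0.98) of sites carry the reference's
exact homozygous genotype; otherwise `shares_one_or_two`. The count
floor exists because the fraction tolerance alone is meaningless at
~50 sites per window, where a single undercalled heterozygote already
exceeds 2% and would veto a truly shared window; a genuinely unshared
window in a diverged population shows opposite homozygotes at ~10% of
sites, so the floor costs no detection power.

Dosage over the target interval follows from the window states (2 if
all informative target windows are `shares_two`, 0 if any is
`shares_none`, else 1; undetermined if all are uninformative), and
population haplotype frequencies are $\sum d_i / (2 n_{called})$ with
undetermined accessions excluded from the denominator and their count
reported. Ancestry grouping from a Q matrix uses a strict majority
rule: an accession joins its top component only if that coefficient
*exceeds* the threshold (default 0.85), otherwise it is `admixed`.

## The synthetic pedigree generator

The generator produces the data structure these methods assume, plus a
machine-readable truth set, and is the substrate of the test suite:

* **Genome**: 5 chromosomes × 10 Mb with a periodic repeat mask leaving
  80% non-repetitive (40 Mb total). This is a desk-scale stand-in for a
  ~500-Mb genome; everything is configurable upward.
* **Sites**: ~20,000 biallelic SNPs clustered around uniformly placed
  gene anchors (Gaussian scatter, sd 2 kb) to mimic the uneven spacing
  of genic targeted sequencing, not a uniform sprinkle.
* **Ancestry components**: per component, site frequencies are drawn
  Balding–Nichols style around a shared ancestral frequency
  (Beta(0.8, 0.8)), with divergence defaults of 0.1 for the two
  cultivated components and 0.3 for the wild component. No quantitative
  divergence between real ancestry components was available to
  calibrate against; these are round values giving clearly separated
  but overlapping frequency spectra.
* **Meiosis**: crossovers are Poisson per chromosome at
  `recomb_rate` (default 0.1/Mb ≈ one crossover per 10-Mb chromosome
  per meiosis). The rate keeps the *per-chromosome* crossover count
  realistic on a shrunken genome, which preserves what matters for the
  methods: multi-Mb IBD segments.
* **Errors**: heterozygotes flip to a random matching homozygote at
  `het_to_hom_rate` (0.01); homozygotes flip to heterozygotes at a
  tenth of that (the secondary mode); calls go missing at 0.02. Truth
  is retained separately.
* **Default pedigree**: two founder pools, a founder pair with a
  four-offspring quartet (6 full-sib pairs), a second pair with two
  offspring, recurrent parents, a second-generation parent whose full
  sibling is also present (the raw material for false-pedigree
  experiments), and one clone.
* **Planted haplotype**: a fixed cultivated-component haplotype copied
  into designated carriers at dosage 1 or 2 across a target interval,
  with exact bookkeeping; `wild_panel_config()` wraps the
  crop-to-wild design (25 wild accessions, one homozygous reference
  carrier, planted frequency realised exactly as `round(2nf)` copies,
  heterozygous carriers first).

What the generator does *not* emulate: linkage disequilibrium within
components (sites are drawn independently given frequencies), coalescent
depth, selection, hemizygous/deleted regions, read-level artefacts
beyond the two symmetric flip modes, and genome-scale physical size.
Passing tests therefore demonstrate the *logic* of the methods under a
realistic error and pedigree structure, not their operating
characteristics on any particular real panel.

## Known limitations

* **Full sibs at desk scale.** With only 50 Mb of genome, the IBD0
  fraction of a full-sib pair is highly variable (few, long segments),
  and an occasional sib pair slips inside the parent-offspring
  thresholds. On a realistic genome (19 chromosomes, ~400 Mb
  informative) the same thresholds separate the classes cleanly. The
  trio validator is the backstop: candidate trios built from a
  mis-called sib pair are rejected by the clustering test, and in the
  test suite trio-level recovery is exact while pairwise precision is
  asserted for founder pairs.
* **The IBS/distance formulas are a reconstruction.** The window
  cutoffs `t0`/`t2` reproduce the qualitative mechanism (opposite
  homozygotes exclude IBD ≥ 1; near-identity implies IBD2); different
  published pipelines weight missing data differently, so all cutoffs
  are configurable.
* **Dosage from unphased genotypes** relies entirely on the reference
  being homozygous; the scan refuses to run otherwise rather than
  attempt statistical phasing.
* **Problem sizes in the tests**: unit fixtures use 2-chromosome,
  6,000-site panels; pedigree-recovery and error-free calling
  experiments use the full default configuration (10 replicate seeds);
  frequency recovery uses 50 seeds per planted frequency. These sizes
  give stable pass/fail behaviour for the properties asserted.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_pedigree_data(sim_config(seed = 7))
ws <- build_windows(sim$genome)          # 200 windows of 200 kb non-repetitive
pairs <- ibd_all_pairs(sim$genotypes, ws)
table(pairs$call)
res <- search_trios(sim$genotypes, ws, pairs)
res$accepted[, c("p1", "p2", "f", "error_rate", "verdict")]
g <- build_kinship_graph(pairs, res$accepted, res$full_sibs,
                         ancestry = sim$truth$ancestry)
descent_group(g, c("FndA1", "FndA2"))
```
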