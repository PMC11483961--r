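# shared fixtures: tiny genomes and genotype panels built in code

# quick genotype_matrix from a sites x accessions matrix of 0/1/2/NA
make_gm <- function(calls, pos = NULL, chrom = "chr1",
                    ids = paste0("acc", seq_len(ncol(calls)))) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 1000L
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C"),
                  ids)
}

# 1-Mb single-chromosome toy genome, fully non-repetitive
toy_genome <- function(len = 1e6, mask = NULL) {
  genome_map(data.frame(chrom = "chr1", length = len), mask)
}

# small, fast pedigree simulation (2 chromosomes, reduced sites)
small_sim <- function(seed, ...) {
  simulate_pedigree_data(sim_config(
    seed = seed, genome = default_sim_genome(n_chrom = 2), n_sites = 6000, ...))
}

# replace clone ids by their truth representative so recovered trios can be
# compared against the planted pedigree (clones are genotypically identical)
canon_clones <- function(x, clones) {
  for (i in seq_len(nrow(clones))) x[x == clones$b[i]] <- clones$a[i]
  x
}

trio_key <- function(p1, p2, f) paste(pmin(p1, p2), pmax(p1, p2), f)

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
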