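#' Default desk-scale genome for simulations
#'
#' Five 10-Mb chromosomes with a periodic repeat mask leaving 80% of
#' each chromosome non-repetitive (each 500-kb block carries 100 kb of
#' repeats at its end), i.e. 40 Mb of non-repetitive sequence in total.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param nonrep_frac fraction of each block that is non-repetitive.
#' @param block block period in bp for the periodic mask.
#' @return a \code{\link{genome_map}}.
#' @export
default_sim_genome <- function(n_chrom = 5, chrom_length = 1e7,
                               nonrep_frac = 0.8, block = 5e5) {
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = chrom_length)
  nb <- ceiling(chrom_length / block)
  starts <- (seq_len(nb) - 1) * block
  iv <- data.frame(start = starts, end = pmin(starts + nonrep_frac * block,
                                              chrom_length))
  mask <- do.call(rbind, lapply(chroms$chrom, function(ch)
    data.frame(chrom = ch, iv)))
  genome_map(chroms, mask)
}

#' Default pedigree script
#'
#' Emulates the structure repeatedly seen in clonally propagated crop
#' germplasm: a founder pair with four full-sib offspring (a quartet), a
#' second founder pair with two offspring, recurrent parents appearing
#' in several crosses, a second-generation parent whose full sibling is
#' also in the panel (the substrate for false-pedigree detection), and
#' one clone.
#'
#' Founders \code{FndA1..FndA4} come from one cultivated ancestry
#' component, \code{FndB1..FndB5} from the other.
#'
#' @return data.frame with columns \code{op} (\code{cross}/\code{self}/
#'   \code{clone}), \code{p1}, \code{p2}, \code{child}.
#' @export
default_pedigree <- function() {
  rbind(
    data.frame(op = "cross", p1 = "FndA1", p2 = "FndA2",
               child = c("Quart1", "Quart2", "Quart3", "Quart4")),
    data.frame(op = "cross", p1 = "FndB1", p2 = "FndB2",
               child = c("Sib1", "Sib2")),
    data.frame(op = "cross", p1 = "FndA1", p2 = "FndB1", child = "Cross1"),
    data.frame(op = "cross", p1 = "FndB3", p2 = "FndB4",
               child = c("ParX", "ParXSib")),
    data.frame(op = "cross", p1 = "ParX", p2 = "FndB5", child = "Off8"),
    data.frame(op = "clone", p1 = "FndB1", p2 = NA, child = "CloneB1")
  )
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; one global stream drives site placement,
#'   founder draws, meioses (in pedigree-script order), haplotype
#'   planting and the error model, in that order.
#' @param genome a \code{\link{genome_map}}; default
#'   \code{\link{default_sim_genome}()}.
#' @param n_sites target number of biallelic sites (default 20000); the
#'   realised count can be slightly lower after removing coincident
#'   positions.
#' @param founders named integer vector: accessions drawn directly from
#'   each ancestry component's allele frequencies. Names become id
#'   prefixes unless the component already names ids via
#'   \code{founder_ids}.
#' @param founder_ids optional named list mapping component name to a
#'   character vector of founder ids (overrides \code{founders} counts).
#' @param divergence named numeric vector, one Fst-like value per
#'   component, controlling how far each component's site frequencies
#'   drift from the shared ancestral frequencies (Balding-Nichols style).
#' @param beta_shape length-2 shape parameters of the ancestral
#'   allele-frequency spectrum.
#' @param pedigree pedigree script, see \code{\link{default_pedigree}}.
#' @param het_to_hom_rate probability that a heterozygous call is
#'   reported as a (random matching) homozygote — the dominant error
#'   mode of low-coverage reduced-representation genotyping.
#' @param hom_to_het_rate secondary error mode; default one tenth of
#'   \code{het_to_hom_rate}.
#' @param genotype_missing_rate probability a call is missing.
#' @param recomb_rate crossovers per Mb per meiosis (default 0.1, i.e.
#'   about one crossover per default 10-Mb chromosome).
#' @param genes_per_mb density of gene anchors around which sites
#'   cluster (SPET-style genic targeting).
#' @param site_cluster_sd sd (bp) of site scatter around gene anchors.
#' @param planted_haplotype optional list with elements \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{dosage} (named
#'   integer vector of 0/1/2 copies per carrier accession), and
#'   optionally \code{component} (component whose frequencies the
#'   planted haplotype is drawn from; default the first).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       genome = default_sim_genome(),
                       n_sites = 20000,
                       founders = c(cultivated1 = 4, cultivated2 = 5),
                       founder_ids = NULL,
                       divergence = NULL,
                       beta_shape = c(0.8, 0.8),
                       pedigree = default_pedigree(),
                       het_to_hom_rate = 0.01,
                       hom_to_het_rate = het_to_hom_rate / 10,
                       genotype_missing_rate = 0.02,
                       recomb_rate = 0.1,
                       genes_per_mb = 25,
                       site_cluster_sd = 2000,
                       planted_haplotype = NULL) {
  if (is.null(founder_ids)) {
    founder_ids <- list()
    for (comp in names(founders)) {
      n <- founders[[comp]]
      pref <- switch(comp, cultivated1 = "FndA", cultivated2 = "FndB",
                     wild = "Wld", comp)
      founder_ids[[comp]] <- paste0(pref, seq_len(n))
    }
  }
  if (is.null(divergence)) {
    divergence <- setNames(ifelse(grepl("wild", names(founder_ids)), 0.3, 0.1),
                           names(founder_ids))
  }
  rates <- c(het_to_hom_rate, hom_to_het_rate, genotype_missing_rate)
  if (any(rates < 0 | rates > 1)) stop("error-model rates must lie in [0, 1]")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  if (n_sites <= 0) stop("n_sites must be positive")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  cfg <- list(seed = seed, genome = genome, n_sites = n_sites,
              founder_ids = founder_ids, divergence = divergence,
              beta_shape = beta_shape, pedigree = pedigree,
              het_to_hom_rate = het_to_hom_rate,
              hom_to_het_rate = hom_to_het_rate,
              genotype_missing_rate = genotype_missing_rate,
              recomb_rate = recomb_rate, genes_per_mb = genes_per_mb,
              site_cluster_sd = site_cluster_sd,
              planted_haplotype = planted_haplotype)
  class(cfg) <- "sim_config"
  validate_pedigree(cfg)
  cfg
}

validate_pedigree <- function(cfg) {
  ped <- cfg$pedigree
  if (is.null(ped) || nrow(ped) == 0) return(invisible(TRUE))
  known <- unlist(cfg$founder_ids, use.names = FALSE)
  for (i in seq_len(nrow(ped))) {
    op <- ped$op[i]
    if (!op %in% c("cross", "self", "clone")) stop("unknown pedigree op: ", op)
    parents <- if (op == "cross") c(ped$p1[i], ped$p2[i]) else ped$p1[i]
    absent <- setdiff(parents, known)
    if (length(absent))
      stop("pedigree row ", i, " names parent(s) before they exist: ",
           paste(absent, collapse = ", "))
    if (ped$child[i] %in% known) stop("duplicate accession id: ", ped$child[i])
    known <- c(known, ped$child[i])
  }
  invisible(TRUE)
}

# sites clustered around gene anchors inside non-repetitive intervals
place_sites <- function(genome, n_sites, genes_per_mb, cluster_sd) {
  nr <- genome$nonrepetitive
  nr_len <- nr$end - nr$start
  chrom_nr <- tapply(nr_len, nr$chrom, sum)
  chrom_nr <- chrom_nr[unique(genome$chromosomes$chrom)]
  chrom_nr <- chrom_nr[!is.na(chrom_nr)]
  n_per <- round(n_sites * chrom_nr / sum(chrom_nr))
  out <- list()
  for (chrom in names(chrom_nr)) {
    iv <- nr[nr$chrom == chrom, , drop = FALSE]
    clen <- genome$chromosomes$length[genome$chromosomes$chrom == chrom]
    n_genes <- max(1, round(genes_per_mb * sum(iv$end - iv$start) / 1e6))
    # anchors uniform over the non-repetitive sequence
    u <- runif(n_genes, 0, sum(iv$end - iv$start))
    cum <- cumsum(iv$end - iv$start)
    j <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    anchors <- iv$start[j] + (u - c(0, cum)[j])
    a <- sample(n_genes, n_per[chrom], replace = TRUE)
    pos0 <- round(anchors[a] + stats::rnorm(n_per[chrom], 0, cluster_sd))
    pos0 <- pmin(pmax(pos0, 0), clen - 1)
    pos <- sort(unique(as.integer(pos0) + 1L)) # 1-based
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                               stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  sites
}

#' Draw founder haplotypes
#'
#' Each ancestry component receives its own site-wise allele frequencies:
#' a shared ancestral frequency is drawn per site from
#' \code{Beta(beta_shape)}, then each component's frequency from
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with \code{F} the component's
#' divergence. Every founder gets two haplotypes sampled
#' site-independently from its component's frequencies.
#'
#' @param cfg a \code{\link{sim_config}}. The caller is responsible for
#'   seeding when using this operation on its own;
#'   \code{\link{simulate_pedigree_data}} seeds the single global stream.
#' @param sites data.frame of site coordinates (default: freshly placed
#'   from the config).
#' @return list with \code{haps} (sites x 2*n_founders 0/1 matrix, two
#'   adjacent columns per founder, named \code{id.1}/\code{id.2}),
#'   \code{sites}, \code{freqs} (sites x components), \code{component}
#'   (named vector mapping founder id to component).
#' @export
simulate_founders <- function(cfg, sites = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sites))
    sites <- place_sites(cfg$genome, cfg$n_sites, cfg$genes_per_mb,
                         cfg$site_cluster_sd)
  m <- nrow(sites)
  p0 <- rbeta(m, cfg$beta_shape[1], cfg$beta_shape[2])
  p0 <- pmin(pmax(p0, 0.01), 0.99)
  comps <- names(cfg$founder_ids)
  freqs <- matrix(NA_real_, m, length(comps), dimnames = list(NULL, comps))
  for (comp in comps) {
    f <- cfg$divergence[[comp]]
    freqs[, comp] <- if (f <= 0) p0 else
      rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  ids <- unlist(cfg$founder_ids, use.names = FALSE)
  component <- setNames(rep(comps, lengths(cfg$founder_ids)), ids)
  haps <- matrix(0L, m, 2 * length(ids))
  colnames(haps) <- paste0(rep(ids, each = 2), ".", 1:2)
  for (i in seq_along(ids)) {
    p <- freqs[, component[[ids[i]]]]
    haps[, 2 * i - 1] <- as.integer(runif(m) < p)
    haps[, 2 * i] <- as.integer(runif(m) < p)
  }
  list(haps = haps, sites = sites, freqs = freqs, component = component)
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean
#' \code{recomb_rate * length/1e6}; breakpoint positions are uniform; the
#' gamete alternates between the two parental haplotypes at breakpoints,
#' starting from a randomly chosen one per chromosome.
#'
#' @param parent_haps sites x 2 matrix of 0/1 parental haplotypes.
#' @param sites data.frame with \code{chrom}, \code{pos} for each row of
#'   \code{parent_haps}.
#' @param genome a \code{\link{genome_map}}.
#' @param recomb_rate crossovers per Mb.
#' @return integer vector: the gamete haplotype.
#' @export
simulate_meiosis <- function(parent_haps, sites, genome, recomb_rate) {
  stopifnot(ncol(parent_haps) == 2, nrow(parent_haps) == nrow(sites),
            recomb_rate >= 0)
  gamete <- integer(nrow(sites))
  for (k in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$chrom[k]
    clen <- genome$chromosomes$length[k]
    sel <- which(sites$chrom == chrom)
    n_x <- rpois(1, recomb_rate * clen / 1e6)
    breaks <- sort(runif(n_x, 0, clen))
    start_hap <- sample.int(2, 1)
    if (!length(sel)) next
    seg <- findInterval(sites$pos[sel] - 1, breaks) # segments between breakpoints
    use <- (start_hap + seg - 1) %% 2 + 1
    gamete[sel] <- parent_haps[cbind(sel, use)]
  }
  gamete
}

#' Plant a fixed haplotype into accession haplotypes
#'
#' Overwrites, for each designated carrier, 1 or 2 of its haplotypes
#' across the target interval with one fixed haplotype (drawn once from
#' the designated component's allele frequencies). This emulates a
#' recessive haplotype of cultivated origin segregating at known dosage
#' in wild-like populations.
#'
#' @param haps sites x 2N 0/1 matrix (columns \code{id.1}, \code{id.2}).
#' @param sites site table matching \code{haps} rows.
#' @param planted list with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{dosage} (named 0/1/2 vector), optional
#'   \code{hap} (explicit 0/1 vector over interval sites, overrides the
#'   random draw) and \code{component}.
#' @param freqs site x component frequency matrix (used when \code{hap}
#'   is not supplied).
#' @param genome a \code{\link{genome_map}} (interval validation).
#' @return list: \code{haps} (modified), \code{dosage} (named vector over
#'   all accessions, non-carriers 0), \code{hap} (the planted haplotype),
#'   \code{interval_sites} (row indices of interval sites).
#' @export
plant_haplotype <- function(haps, sites, planted, freqs = NULL, genome = NULL) {
  if (!is.null(genome)) {
    row <- genome$chromosomes[genome$chromosomes$chrom == planted$chrom, ]
    if (nrow(row) == 0 || planted$start < 0 || planted$end > row$length ||
        planted$start >= planted$end)
      stop("planted interval outside the genome: ", planted$chrom, ":",
           planted$start, "-", planted$end)
  }
  sel <- which(sites$chrom == planted$chrom &
               sites$pos - 1 >= planted$start & sites$pos - 1 < planted$end)
  if (!length(sel)) stop("no sites in the planted interval")
  hap <- planted$hap
  if (is.null(hap)) {
    comp <- planted$component %||% colnames(freqs)[1]
    hap <- as.integer(runif(length(sel)) < freqs[sel, comp])
  }
  ids <- unique(sub("\\.[12]$", "", colnames(haps)))
  dosage <- setNames(integer(length(ids)), ids)
  for (id in names(planted$dosage)) {
    d <- planted$dosage[[id]]
    if (!id %in% ids) stop("planted carrier not in panel: ", id)
    if (!d %in% 0:2) stop("dosage must be 0, 1 or 2")
    dosage[id] <- d
    if (d >= 1) haps[sel, paste0(id, ".1")] <- hap
    if (d == 2) haps[sel, paste0(id, ".2")] <- hap
  }
  list(haps = haps, dosage = dosage, hap = hap, interval_sites = sel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the genotyping-error model
#'
#' Heterozygous calls flip to a random matching homozygote with
#' probability \code{het_to_hom_rate}; homozygotes flip to heterozygotes
#' with probability \code{hom_to_het_rate}; finally every call is set
#' missing with probability \code{genotype_missing_rate}.
#'
#' @param gm true \code{\link{genotype_matrix}}.
#' @param het_to_hom_rate,hom_to_het_rate,genotype_missing_rate rates in
#'   [0, 1].
#' @return an observed \code{genotype_matrix}; the truth is untouched.
#' @export
apply_error_model <- function(gm, het_to_hom_rate = 0.01,
                              hom_to_het_rate = het_to_hom_rate / 10,
                              genotype_missing_rate = 0.02) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  if (het_to_hom_rate > 0) {
    het <- which(!is.na(calls) & calls == GT_HET)
    flip <- het[runif(length(het)) < het_to_hom_rate]
    calls[flip] <- ifelse(runif(length(flip)) < 0.5, GT_HOM_REF, GT_HOM_ALT)
  }
  if (hom_to_het_rate > 0) {
    hom <- which(!is.na(calls) & calls != GT_HET)
    flip <- hom[runif(length(hom)) < hom_to_het_rate]
    calls[flip] <- GT_HET
  }
  if (genotype_missing_rate > 0)
    calls[runif(length(calls)) < genotype_missing_rate] <- NA_integer_
  genotype_matrix(calls, gm$sites, gm$accession_ids)
}

#' Simulate a full pedigree dataset with truth set
#'
#' Runs the whole generator under one seeded RNG stream: site placement,
#' founder haplotypes, pedigree-script meioses (in script order),
#' optional haplotype planting, then the error model.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a list of class \code{kinscan_sim} with elements
#'   \code{genotypes} (observed \code{\link{genotype_matrix}}),
#'   \code{genome}, \code{config} and \code{truth}, the latter holding
#'   \code{genotypes} (error-free), \code{haps}, \code{po_pairs}
#'   (oriented parent/offspring), \code{trios}, \code{full_sibs},
#'   \code{clones}, \code{dosage}, \code{planted_hap} and
#'   \code{ancestry} (accessions x components proportions).
#' @export
simulate_pedigree_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fnd <- simulate_founders(cfg)
  sites <- fnd$sites
  haps <- fnd$haps
  comps <- names(cfg$founder_ids)
  ancestry <- matrix(0, length(fnd$component), length(comps),
                     dimnames = list(names(fnd$component), comps))
  ancestry[cbind(seq_along(fnd$component), match(fnd$component, comps))] <- 1

  ped <- cfg$pedigree
  po <- data.frame(parent = character(0), offspring = character(0))
  trios <- data.frame(p1 = character(0), p2 = character(0), f = character(0))
  clones <- data.frame(a = character(0), b = character(0))
  if (!is.null(ped) && nrow(ped)) for (i in seq_len(nrow(ped))) {
    id <- ped$child[i]
    p1 <- ped$p1[i]
    cols1 <- paste0(p1, ".", 1:2)
    if (ped$op[i] == "clone") {
      child <- haps[, cols1, drop = FALSE]
      clones <- rbind(clones, data.frame(a = p1, b = id))
      anc <- ancestry[p1, ]
    } else {
      p2 <- if (ped$op[i] == "self") p1 else ped$p2[i]
      g1 <- simulate_meiosis(haps[, cols1, drop = FALSE], sites, cfg$genome,
                             cfg$recomb_rate)
      g2 <- simulate_meiosis(haps[, paste0(p2, ".", 1:2), drop = FALSE], sites,
                             cfg$genome, cfg$recomb_rate)
      child <- cbind(g1, g2)
      po <- rbind(po, data.frame(parent = unique(c(p1, p2)), offspring = id))
      trios <- rbind(trios, data.frame(p1 = min(p1, p2), p2 = max(p1, p2), f = id))
      anc <- (ancestry[p1, ] + ancestry[p2, ]) / 2
    }
    colnames(child) <- paste0(id, ".", 1:2)
    haps <- cbind(haps, child)
    ancestry <- rbind(ancestry, anc)
    rownames(ancestry)[nrow(ancestry)] <- id
  }

  dosage <- NULL; planted_hap <- NULL
  if (!is.null(cfg$planted_haplotype)) {
    pl <- plant_haplotype(haps, sites, cfg$planted_haplotype, fnd$freqs,
                          cfg$genome)
    haps <- pl$haps
    dosage <- pl$dosage
    planted_hap <- list(hap = pl$hap, interval_sites = pl$interval_sites,
                        chrom = cfg$planted_haplotype$chrom,
                        start = cfg$planted_haplotype$start,
                        end = cfg$planted_haplotype$end)
  }

  ids <- unique(sub("\\.[12]$", "", colnames(haps)))
  truth_calls <- haps[, paste0(ids, ".1"), drop = FALSE] +
    haps[, paste0(ids, ".2"), drop = FALSE]
  colnames(truth_calls) <- ids
  truth_gm <- genotype_matrix(truth_calls, sites, ids)
  obs_gm <- apply_error_model(truth_gm, cfg$het_to_hom_rate,
                              cfg$hom_to_het_rate, cfg$genotype_missing_rate)

  full_sibs <- truth_full_sibs(trios)
  structure(list(
    genotypes = obs_gm, genome = cfg$genome, config = cfg,
    truth = list(genotypes = truth_gm, haps = haps, po_pairs = po,
                 trios = trios, full_sibs = full_sibs, clones = clones,
                 dosage = dosage, planted_hap = planted_hap,
                 ancestry = ancestry)
  ), class = "kinscan_sim")
}

truth_full_sibs <- function(trios) {
  out <- data.frame(a = character(0), b = character(0))
  if (!nrow(trios)) return(out)
  key <- paste(trios$p1, trios$p2)
  for (k in unique(key)) {
    kids <- sort(trios$f[key == k])
    if (length(kids) >= 2) {
      cmb <- utils::combn(kids, 2)
      out <- rbind(out, data.frame(a = cmb[1, ], b = cmb[2, ]))
    }
  }
  out
}

#' Expected parent-offspring calls after clone expansion
#'
#' Genotype-based relationship calling cannot distinguish an accession
#' from its clone, so the expected set of parent-offspring pairs in the
#' observable genotype data is the truth set expanded through clone
#' equivalence classes (a clone of a parent is a parent, genotypically).
#'
#' @param truth the \code{truth} element of a \code{\link{simulate_pedigree_data}} result.
#' @return data.frame of unordered pairs (\code{a} < \code{b}).
#' @export
expected_po_calls <- function(truth) {
  equiv <- setNames(as.list(unique(c(truth$po_pairs$parent,
                                     truth$po_pairs$offspring,
                                     truth$clones$a, truth$clones$b))),
                    NULL)
  group_of <- function(id) {
    g <- id
    repeat {
      more <- unique(c(g, truth$clones$b[truth$clones$a %in% g],
                       truth$clones$a[truth$clones$b %in% g]))
      if (length(more) == length(g)) return(g)
      g <- more
    }
  }
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(truth$po_pairs)), function(i) {
    p <- group_of(truth$po_pairs$parent[i])
    o <- group_of(truth$po_pairs$offspring[i])
    expand.grid(a = p, b = o, stringsAsFactors = FALSE)
  })))
  data.frame(a = pmin(pairs$a, pairs$b), b = pmax(pairs$a, pairs$b)) |>
    unique()
}

#' Write a simulated dataset to disk
#'
#' Writes \code{genotypes.vcf}, \code{genome.tsv}, \code{mask.bed},
#' \code{truth_pairs.tsv}, \code{truth_trios.tsv}, \code{truth_sibs.tsv},
#' \code{truth_clones.tsv}, and (when a haplotype was planted)
#' \code{truth_dosage.tsv}.
#'
#' @param sim a \code{\link{simulate_pedigree_data}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "kinscan_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_genome_map(sim$genome, file.path(dir, "genome.tsv"),
                   file.path(dir, "mask.bed"))
  tr <- sim$truth
  data.table::fwrite(tr$po_pairs, file.path(dir, "truth_pairs.tsv"), sep = "\t")
  data.table::fwrite(tr$trios, file.path(dir, "truth_trios.tsv"), sep = "\t")
  data.table::fwrite(tr$full_sibs, file.path(dir, "truth_sibs.tsv"), sep = "\t")
  data.table::fwrite(tr$clones, file.path(dir, "truth_clones.tsv"), sep = "\t")
  if (!is.null(tr$dosage))
    data.table::fwrite(data.frame(id = names(tr$dosage), dosage = tr$dosage),
                       file.path(dir, "truth_dosage.tsv"), sep = "\t")
  invisible(dir)
}

#' Configuration for a wild-panel haplotype-introgression experiment
#'
#' A panel of \code{n_wild} wild-like accessions plus one cultivated
#' reference carrier, with a cultivated haplotype planted across the
#' lower arm of the scan chromosome: the reference carries two copies
#' (so it is homozygous throughout the target region) and the planted
#' population frequency is realised exactly as \code{round(2 n f)}
#' haplotype copies spread over the wild accessions, heterozygous
#' carriers first (introgressed haplotypes segregate mostly in
#' heterozygous condition).
#'
#' @param seed RNG seed.
#' @param frequency planted haplotype frequency in the wild panel.
#' @param n_wild wild panel size (default 25).
#' @param n_sites number of sites (default 8000 on a 2-chromosome
#'   genome).
#' @param chrom,start,end planted interval (defaults: lower arm of
#'   chr2, 6-10 Mb).
#' @param ref_id id of the homozygous reference carrier.
#' @param ... further arguments passed to \code{\link{sim_config}}.
#' @return a \code{\link{sim_config}}.
#' @export
wild_panel_config <- function(seed, frequency, n_wild = 25, n_sites = 8000,
                              chrom = "chr2", start = 6e6, end = 1e7,
                              ref_id = "RefCarrier", ...) {
  stopifnot(frequency >= 0, frequency <= 1)
  k <- round(2 * n_wild * frequency)
  wild <- sprintf("Wld%02d", seq_len(n_wild))
  dosage <- setNames(rep(0L, n_wild), wild)
  dosage[seq_len(min(k, n_wild))] <- 1L
  if (k > n_wild) dosage[seq_len(k - n_wild)] <- 2L
  dosage <- c(dosage[dosage > 0], setNames(2L, ref_id))
  sim_config(seed = seed,
             genome = default_sim_genome(n_chrom = 2),
             n_sites = n_sites,
             founders = c(cultivated1 = 1, wild = n_wild),
             founder_ids = list(cultivated1 = ref_id, wild = wild),
             pedigree = data.frame(op = character(0), p1 = character(0),
                                   p2 = character(0), child = character(0)),
             planted_haplotype = list(chrom = chrom, start = start, end = end,
                                      dosage = as.list(dosage),
                                      component = "cultivated1"),
             ...)
}
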