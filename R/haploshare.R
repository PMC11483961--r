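#' Verify that a reference accession is homozygous across a region
#'
#' The sharing scan requires a reference accession homozygous for the
#' target haplotype throughout the scanned region; at such sites every
#' opposite homozygote in another accession excludes sharing without any
#' phasing.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ref_id reference accession id.
#' @param chrom chromosome of the region.
#' @param start,end region interval, 0-based half-open.
#' @param min_hom_frac pass threshold on the homozygous fraction
#'   (default 0.99).
#' @return list with \code{fraction_homozygous}, \code{n_sites},
#'   \code{pass}.
#' @export
verify_reference_homozygosity <- function(gm, ref_id, chrom, start, end,
                                          min_hom_frac = 0.99) {
  if (!ref_id %in% gm$accession_ids) stop("unknown accession: ", ref_id)
  sel <- which(gm$sites$chrom == chrom & gm$sites$pos - 1 >= start &
               gm$sites$pos - 1 < end)
  g <- gm$calls[sel, ref_id]
  g <- g[!is.na(g)]
  if (!length(g))
    return(list(fraction_homozygous = NA_real_, n_sites = 0L, pass = FALSE,
                message = "no genotyped sites in region"))
  frac <- mean(g != GT_HET)
  list(fraction_homozygous = frac, n_sites = length(g),
       pass = frac >= min_hom_frac)
}

#' Scan accessions for haplotype sharing with a homozygous reference
#'
#' The scanned chromosome is cut into \code{n_windows} equal-width
#' windows (a coarser, scan-specific grid, independent of the IBD
#' window system). Only sites where the reference is homozygous and
#' non-missing are used. Per accession and window, the sharing state is:
#' \code{shares_none} when the accession is homozygous for the allele
#' opposite to the reference at more than a fraction \code{t_err} of
#' sites AND at no fewer than \code{min_opp} sites (one or two opposite
#' homozygotes are within the het-to-hom undercall error mode and cannot
#' veto a shared window); \code{shares_two} when the fraction
#' of sites with the reference's exact homozygous genotype is at least
#' \code{t2}; otherwise \code{shares_one_or_two}; \code{uninformative}
#' below \code{min_sites}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param genome a \code{\link{genome_map}} (chromosome length).
#' @param ref_id reference accession, homozygous across the region of
#'   interest (enforced via \code{\link{verify_reference_homozygosity}}
#'   over the whole scanned chromosome span covered by \code{verify});
#' @param chrom chromosome to scan.
#' @param n_windows number of equal-width scan windows (default 50).
#' @param t_err tolerated fraction of opposite-homozygote sites
#'   (default 0.02).
#' @param min_opp minimum count of opposite-homozygote sites required to
#'   call \code{shares_none} (default 3).
#' @param t2 minimum fraction of identical-to-reference genotypes for
#'   \code{shares_two} (default 0.98).
#' @param min_sites minimum informative sites per window (default 10).
#' @param verify interval (\code{c(start, end)}, 0-based half-open) over
#'   which the reference must pass the homozygosity check before
#'   scanning; \code{NULL} skips the check.
#' @param min_hom_frac threshold for that check.
#' @return a list of class \code{sharing_scan}: \code{windows}
#'   (data.frame \code{chrom}, \code{start}, \code{end}), \code{states}
#'   (accessions x windows character matrix), \code{ref_id}.
#' @export
sharing_scan <- function(gm, genome, ref_id, chrom, n_windows = 50,
                         t_err = 0.02, t2 = 0.98, min_sites = 10,
                         min_opp = 3, verify = NULL, min_hom_frac = 0.99) {
  row <- genome$chromosomes[genome$chromosomes$chrom == chrom, ]
  if (nrow(row) == 0) stop("unknown chromosome: ", chrom)
  if (!is.null(verify)) {
    chk <- verify_reference_homozygosity(gm, ref_id, chrom, verify[1],
                                         verify[2], min_hom_frac)
    if (!chk$pass)
      stop("reference ", ref_id, " failed the homozygosity check (",
           ifelse(is.na(chk$fraction_homozygous), "no sites",
                  sprintf("%.3f homozygous", chk$fraction_homozygous)), ")")
  }
  clen <- row$length
  bounds <- seq(0, clen, length.out = n_windows + 1)
  wins <- data.frame(chrom = chrom, start = bounds[-(n_windows + 1)],
                     end = bounds[-1])
  sel <- which(gm$sites$chrom == chrom)
  gref <- gm$calls[sel, ref_id]
  use <- !is.na(gref) & gref != GT_HET # reference-homozygous sites only
  sel <- sel[use]; gref <- gref[use]
  widx <- findInterval(gm$sites$pos[sel] - 1, bounds,
                       rightmost.closed = TRUE)
  states <- matrix("uninformative", length(gm$accession_ids), n_windows,
                   dimnames = list(gm$accession_ids, NULL))
  opp_of <- 2L - gref # the homozygote opposite to the reference's
  for (acc in gm$accession_ids) {
    g <- gm$calls[sel, acc]
    ok <- !is.na(g)
    n <- tabulate(widx[ok], nbins = n_windows)
    n_opp <- tabulate(widx[ok & g == opp_of], nbins = n_windows)
    n_match <- tabulate(widx[ok & g == gref], nbins = n_windows)
    st <- rep("uninformative", n_windows)
    inf <- n >= min_sites
    st[inf & n_opp >= min_opp & n_opp / pmax(n, 1) > t_err] <- "shares_none"
    st[inf & st != "shares_none" & n_match / pmax(n, 1) >= t2] <- "shares_two"
    st[inf & st == "uninformative"] <- "shares_one_or_two"
    states[acc, ] <- st
  }
  structure(list(windows = wins, states = states, ref_id = ref_id,
                 chrom = chrom), class = "sharing_scan")
}

#' Call planted-haplotype dosage from a sharing scan
#'
#' Over the scan windows overlapping the target interval: dosage 2 when
#' every informative window matches the reference's homozygous genotype
#' (\code{shares_two}); 0 when any window excludes sharing
#' (\code{shares_none}); otherwise 1; \code{NA} (undetermined) when all
#' target windows are uninformative.
#'
#' @param scan a \code{\link{sharing_scan}} result.
#' @param target_start,target_end target interval (0-based half-open) on
#'   the scanned chromosome.
#' @return named integer vector of dosages (NA = undetermined).
#' @export
call_dosage <- function(scan, target_start, target_end) {
  w <- which(scan$windows$start < target_end & scan$windows$end > target_start)
  if (!length(w)) stop("target interval overlaps no scan window")
  apply(scan$states[, w, drop = FALSE], 1, function(st) {
    st <- st[st != "uninformative"]
    if (!length(st)) return(NA_integer_)
    if (any(st == "shares_none")) return(0L)
    if (all(st == "shares_two")) return(2L)
    1L
  })
}

#' Haplotype frequency per population
#'
#' @param dosages named dosage vector from \code{\link{call_dosage}}.
#' @param populations data.frame with columns \code{id},
#'   \code{population}; accessions may belong to at most one population.
#' @return data.frame, one row per population: \code{population},
#'   \code{n}, \code{n_called}, \code{n_undetermined}, \code{sum_dosage},
#'   \code{frequency} (= sum_dosage / (2 n_called); \code{NA} for an
#'   empty population).
#' @export
population_frequencies <- function(dosages, populations) {
  if (anyDuplicated(populations$id))
    stop("accession(s) assigned to more than one population: ",
         paste(unique(populations$id[duplicated(populations$id)]),
               collapse = ", "))
  out <- lapply(split(populations$id, populations$population), function(ids) {
    d <- dosages[intersect(ids, names(dosages))]
    called <- d[!is.na(d)]
    data.frame(n = length(ids), n_called = length(called),
               n_undetermined = sum(is.na(d)) + sum(!ids %in% names(dosages)),
               sum_dosage = sum(called),
               frequency = if (length(called)) sum(called) / (2 * length(called))
                           else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- cbind(population = names(out), res)
  rownames(res) <- NULL
  res
}

#' Assign accessions to ancestry groups from a Q matrix
#'
#' An accession is assigned to its majority component when that
#' component's coefficient strictly exceeds \code{threshold}; otherwise
#' it is \code{"admixed"}.
#'
#' @param q_matrix numeric matrix (accessions x components) with rows
#'   summing to 1 (tolerance 1e-6); rownames are accession ids,
#'   colnames the component labels.
#' @param threshold assignment cutoff (default 0.85, strict inequality).
#' @return named character vector of group labels.
#' @export
assign_ancestry_groups <- function(q_matrix, threshold = 0.85) {
  q_matrix <- as.matrix(q_matrix)
  if (is.null(colnames(q_matrix)))
    colnames(q_matrix) <- paste0("K", seq_len(ncol(q_matrix)))
  sums <- rowSums(q_matrix)
  bad <- which(is.na(sums) | abs(sums - 1) > 1e-6)
  if (length(bad))
    stop("Q rows do not sum to 1 for: ",
         paste(rownames(q_matrix)[bad] %||% bad, collapse = ", "))
  labels <- apply(q_matrix, 1, function(q) {
    k <- which.max(q)
    if (q[k] > threshold) colnames(q_matrix)[k] else "admixed"
  })
  setNames(labels, rownames(q_matrix))
}
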