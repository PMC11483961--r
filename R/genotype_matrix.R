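#' Construct a genotype matrix
#'
#' The central container: diploid, unphased, biallelic genotype calls for
#' a panel of accessions. Calls are coded as allele dosage of the
#' alternative allele: 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternative), \code{NA} (missing). Phase, if present in
#' the input, is discarded; none of the downstream methods uses it.
#'
#' @param calls integer matrix, one row per site, one column per
#'   accession, values in \{0, 1, 2, NA\}.
#' @param sites data.frame with columns \code{chrom} (character),
#'   \code{pos} (1-based bp), \code{ref}, \code{alt} (single-letter
#'   alleles). Positions must be sortable strictly increasing within a
#'   chromosome.
#' @param accession_ids character vector of unique accession names, one
#'   per column of \code{calls}.
#' @return An object of class \code{genotype_matrix}: a list with
#'   elements \code{calls}, \code{sites}, \code{accession_ids}.
#' @export
genotype_matrix <- function(calls, sites, accession_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(accession_ids))
    stop("duplicate accession ids: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  if (ncol(calls) != length(accession_ids))
    stop("calls has ", ncol(calls), " columns but ", length(accession_ids),
         " accession ids were given")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites must have columns ", paste(need, collapse = ", "))
  if (nrow(sites) != nrow(calls))
    stop("calls has ", nrow(calls), " rows but sites describes ", nrow(sites))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    warning("sites were not sorted by (chromosome, position); sorting")
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    rownames(sites) <- NULL
  }
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup))
    stop("duplicated site positions: e.g. ", sites$chrom[dup][1], ":",
         sites$pos[dup][1])
  colnames(calls) <- accession_ids
  structure(list(calls = calls, sites = sites, accession_ids = accession_ids),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$accession_ids), " accessions x ",
      nrow(x$sites), " biallelic sites on ",
      length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by accessions and/or sites
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param accessions character vector of accession ids to keep (default all).
#' @param site_idx integer vector of site rows to keep (default all).
#' @return a \code{genotype_matrix}.
#' @export
subset_genotypes <- function(gm, accessions = gm$accession_ids,
                             site_idx = seq_len(nrow(gm$sites))) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- setdiff(accessions, gm$accession_ids)
  if (length(miss)) stop("unknown accession(s): ", paste(miss, collapse = ", "))
  sites <- gm$sites[site_idx, , drop = FALSE]
  rownames(sites) <- NULL
  genotype_matrix(gm$calls[site_idx, accessions, drop = FALSE], sites, accessions)
}

#' Minor-allele frequency per site
#'
#' Computed over non-missing calls only; sites with no non-missing call
#' get \code{NA}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @return numeric vector of MAF, one per site.
#' @export
site_maf <- function(gm) {
  n_called <- rowSums(!is.na(gm$calls))
  alt <- rowSums(gm$calls, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  pmin(p, 1 - p)
}

#' Drop sites with minor-allele frequency at or below a cutoff
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param min_maf sites with MAF \code{<= min_maf} among non-missing
#'   calls are removed. \code{0} keeps everything except all-missing or
#'   strictly monomorphic sites would need \code{min_maf = 0} to go; use
#'   a negative value to keep all sites.
#' @return a filtered \code{genotype_matrix}.
#' @export
filter_maf <- function(gm, min_maf = 0) {
  maf <- site_maf(gm)
  keep <- !is.na(maf) & maf > min_maf
  subset_genotypes(gm, site_idx = which(keep))
}
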