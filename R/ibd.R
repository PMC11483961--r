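#' Parameters for window IBD classification and relationship calling
#'
#' @param min_sites minimum sites with both calls present for a window
#'   to be informative.
#' @param min_windows minimum informative windows for a pair to be
#'   callable; below this the call is \code{"undetermined"}.
#' @param t2 IBD2 cutoff: a window is IBD2 when the fraction of
#'   identical genotypes \code{ibs2/n} is at least \code{t2}.
#' @param t0 IBD1 tolerance: a non-IBD2 window is IBD1 when the fraction
#'   of opposite homozygotes \code{ibs0/n} is at most \code{t0}
#'   (opposite homozygotes are impossible under shared descent except
#'   through the het-to-hom error mode, which this tolerance absorbs).
#' @param po_ibd0,po_ibd1,po_max_seg parent-offspring thresholds:
#'   IBD0 fraction below \code{po_ibd0} (0.15), IBD1 fraction above
#'   \code{po_ibd1} (0.60) of informative genome length, and longest
#'   IBD0 segment shorter than \code{po_max_seg} bp (3.8 Mb).
#' @param clone_f2 clone cutoff on the IBD2 fraction.
#' @return a list of class \code{ibd_params}.
#' @export
ibd_params <- function(min_sites = 10, min_windows = 50, t2 = 0.95, t0 = 0.02,
                       po_ibd0 = 0.15, po_ibd1 = 0.60, po_max_seg = 3.8e6,
                       clone_f2 = 0.90) {
  p <- list(min_sites = min_sites, min_windows = min_windows, t2 = t2, t0 = t0,
            po_ibd0 = po_ibd0, po_ibd1 = po_ibd1, po_max_seg = po_max_seg,
            clone_f2 = clone_f2)
  frac <- c(t2 = t2, t0 = t0, po_ibd0 = po_ibd0, po_ibd1 = po_ibd1,
            clone_f2 = clone_f2)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad)) stop(paste(bad, collapse = ", "), " must lie in [0, 1]")
  if (po_max_seg <= 0) stop("po_max_seg must be positive")
  class(p) <- "ibd_params"
  p
}

#' Per-window IBS statistics for one accession pair
#'
#' For each window: \code{n_informative} sites with both calls present,
#' \code{ibs0} opposite homozygotes, \code{ibs2} identical genotypes,
#' \code{ibs1} the remainder, and the genotypic distance
#' \code{(ibs1 + 2*ibs0) / (2*n_informative)} (0 for identical
#' genotypes, 1 for opposite homozygotes throughout).
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ws a \code{\link{build_windows}} result.
#' @param a,b accession ids.
#' @param params an \code{\link{ibd_params}}.
#' @param widx optional precomputed \code{\link{assign_sites_to_windows}}.
#' @return data.frame, one row per window: \code{chrom}, \code{start},
#'   \code{end}, \code{n_informative}, \code{ibs0}, \code{ibs1},
#'   \code{ibs2}, \code{genotypic_distance}, \code{informative}.
#' @export
pair_window_stats <- function(gm, ws, a, b, params = ibd_params(),
                              widx = NULL) {
  miss <- setdiff(c(a, b), gm$accession_ids)
  if (length(miss)) stop("unknown accession(s): ", paste(miss, collapse = ", "))
  if (is.null(widx)) widx <- assign_sites_to_windows(gm, ws)
  g1 <- gm$calls[, a]
  g2 <- gm$calls[, b]
  ok <- which(!is.na(g1) & !is.na(g2) & !is.na(widx))
  nw <- nrow(ws)
  wsel <- widx[ok]
  d <- g1[ok] - g2[ok]
  n <- tabulate(wsel, nbins = nw)
  ibs0 <- tabulate(wsel[abs(d) == 2L], nbins = nw)
  ibs2 <- tabulate(wsel[d == 0L], nbins = nw)
  ibs1 <- n - ibs0 - ibs2
  dist <- ifelse(n > 0, (ibs1 + 2 * ibs0) / (2 * n), NA_real_)
  data.frame(chrom = ws$chrom, start = ws$start, end = ws$end,
             n_informative = n, ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2,
             genotypic_distance = dist,
             informative = n >= params$min_sites)
}

#' Classify windows as IBD0/IBD1/IBD2
#'
#' A window is IBD2 when almost all genotypes agree
#' (\code{ibs2/n >= t2}); otherwise IBD1 when opposite homozygotes are
#' within the error tolerance (\code{ibs0/n <= t0}); otherwise IBD0.
#' Windows with fewer than \code{min_sites} informative sites are
#' \code{UNINFORMATIVE}.
#'
#' @param stats a \code{\link{pair_window_stats}} result.
#' @param params an \code{\link{ibd_params}}.
#' @return character vector of window states.
#' @export
classify_windows <- function(stats, params = ibd_params()) {
  state <- rep("UNINFORMATIVE", nrow(stats))
  inf <- stats$informative
  n <- stats$n_informative
  ibd2 <- inf & stats$ibs2 / n >= params$t2
  ibd1 <- inf & !ibd2 & stats$ibs0 / n <= params$t0
  ibd0 <- inf & !ibd2 & !ibd1
  state[ibd2] <- "IBD2"; state[ibd1] <- "IBD1"; state[ibd0] <- "IBD0"
  state
}

# longest physical span (bp) of a run of consecutive IBD0 windows within a
# chromosome; uninformative windows do not interrupt a run but IBD1/2 do
longest_state_segment <- function(stats, state, which_state = "IBD0") {
  best <- 0
  for (chrom in unique(stats$chrom)) {
    sel <- which(stats$chrom == chrom & state != "UNINFORMATIVE")
    if (!length(sel)) next
    s <- state[sel]
    r <- rle(s == which_state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i1 <- sel[starts[j]]; i2 <- sel[ends[j]]
      best <- max(best, stats$end[i2] - stats$start[i1])
    }
  }
  best
}

#' Genome-wide IBD profile for one accession pair
#'
#' IBD fractions are weighted by each informative window's span of
#' non-repetitive sequence, so they are fractions of the informative
#' genome length.
#'
#' @inheritParams pair_window_stats
#' @return a list of class \code{pair_ibd_profile}: \code{a}, \code{b},
#'   \code{window_states} (with the per-window statistics), \code{f_ibd0},
#'   \code{f_ibd1}, \code{f_ibd2}, \code{longest_ibd0_bp},
#'   \code{n_informative_windows}, \code{call}.
#' @export
pair_ibd_profile <- function(gm, ws, a, b, params = ibd_params(),
                             widx = NULL) {
  stats <- pair_window_stats(gm, ws, a, b, params, widx)
  state <- classify_windows(stats, params)
  w <- ws$nonrep_span
  inf <- state != "UNINFORMATIVE"
  tot <- sum(w[inf])
  f <- function(s) if (tot > 0) sum(w[inf & state == s]) / tot else NA_real_
  longest <- longest_state_segment(stats, state)
  prof <- list(a = a, b = b,
               window_states = cbind(stats, state = state),
               f_ibd0 = f("IBD0"), f_ibd1 = f("IBD1"), f_ibd2 = f("IBD2"),
               longest_ibd0_bp = longest,
               n_informative_windows = sum(inf))
  prof$call <- call_relationship(prof, params)
  class(prof) <- "pair_ibd_profile"
  prof
}

#' Call the relationship for a pair profile
#'
#' \code{clone} when the IBD2 fraction reaches \code{clone_f2};
#' \code{parent_offspring} when IBD0 < \code{po_ibd0}, IBD1 >
#' \code{po_ibd1} of informative genome length and the longest IBD0
#' segment is shorter than \code{po_max_seg}; otherwise \code{other}.
#' Pairs with fewer than \code{min_windows} informative windows are
#' \code{undetermined}.
#'
#' @param profile a \code{\link{pair_ibd_profile}} (or any list with the
#'   same summary fields).
#' @param params an \code{\link{ibd_params}}.
#' @return character scalar.
#' @export
call_relationship <- function(profile, params = ibd_params()) {
  if (is.na(profile$f_ibd0) ||
      profile$n_informative_windows < params$min_windows)
    return("undetermined")
  if (profile$f_ibd2 >= params$clone_f2) return("clone")
  if (profile$f_ibd0 < params$po_ibd0 && profile$f_ibd1 > params$po_ibd1 &&
      profile$longest_ibd0_bp < params$po_max_seg)
    return("parent_offspring")
  "other"
}

#' @export
#' @method print pair_ibd_profile
print.pair_ibd_profile <- function(x, ...) {
  cat(sprintf("pair %s - %s: IBD0 %.1f%%, IBD1 %.1f%%, IBD2 %.1f%% (%d windows), longest IBD0 %.2f Mb -> %s\n",
              x$a, x$b, 100 * x$f_ibd0, 100 * x$f_ibd1, 100 * x$f_ibd2,
              x$n_informative_windows, x$longest_ibd0_bp / 1e6, x$call))
  invisible(x)
}

#' IBD profiles and relationship calls for all accession pairs
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ws a \code{\link{build_windows}} result.
#' @param params an \code{\link{ibd_params}}.
#' @param accessions accessions to analyse (default all, all unordered
#'   pairs).
#' @param keep_profiles if \code{TRUE}, attach the full per-window
#'   profiles as attribute \code{"profiles"}.
#' @return data.frame, one row per unordered pair: \code{a}, \code{b},
#'   \code{f_ibd0}, \code{f_ibd1}, \code{f_ibd2}, \code{longest_ibd0_bp},
#'   \code{n_informative_windows}, \code{call}.
#' @export
ibd_all_pairs <- function(gm, ws, params = ibd_params(),
                          accessions = gm$accession_ids,
                          keep_profiles = FALSE) {
  if (length(accessions) < 2) stop("need at least two accessions")
  widx <- assign_sites_to_windows(gm, ws)
  pairs <- utils::combn(accessions, 2)
  profs <- vector("list", ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    p <- pair_ibd_profile(gm, ws, pairs[1, i], pairs[2, i], params, widx)
    rows[[i]] <- data.frame(a = p$a, b = p$b, f_ibd0 = p$f_ibd0,
                            f_ibd1 = p$f_ibd1, f_ibd2 = p$f_ibd2,
                            longest_ibd0_bp = p$longest_ibd0_bp,
                            n_informative_windows = p$n_informative_windows,
                            call = p$call, stringsAsFactors = FALSE)
    if (keep_profiles) profs[[i]] <- p
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_profiles) attr(out, "profiles") <- profs
  out
}

#' Write the pair summary table
#' @param pairs an \code{\link{ibd_all_pairs}} result.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(pairs, path, sep = "\t")
  invisible(path)
}
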