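#' Mendelian compatibility table for genotype triples
#'
#' Derived from first principles: a triple (gP1, gP2, gF) is compatible
#' with P1 x P2 -> F when the offspring's two alleles can be split so
#' that one is carried by P1 and the other by P2. Of the 27 ordered
#' triples over \{aa, ab, bb\}, 15 are compatible and 12 incompatible;
#' the table is symmetric in the two parents.
#'
#' @return data.frame with columns \code{p1}, \code{p2}, \code{f}
#'   (genotype codes 0/1/2), \code{label} (\code{"aa"}-style triple) and
#'   \code{compatible} (logical), plus attribute \code{lookup}: a
#'   27-long logical vector indexed by \code{9*p1 + 3*p2 + f + 1}.
#' @export
build_compatibility_table <- function() {
  allele_sets <- list(`0` = "a", `1` = c("a", "b"), `2` = "b") # transmissible
  gametes <- list(`0` = c("a", "a"), `1` = c("a", "b"), `2` = c("b", "b"))
  gl <- c("aa", "ab", "bb")
  grid <- expand.grid(f = 0:2, p2 = 0:2, p1 = 0:2)[, c("p1", "p2", "f")]
  compatible <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f_alleles <- gametes[[as.character(grid$f[i])]]
    s1 <- allele_sets[[as.character(grid$p1[i])]]
    s2 <- allele_sets[[as.character(grid$p2[i])]]
    compatible[i] <- (f_alleles[1] %in% s1 && f_alleles[2] %in% s2) ||
                     (f_alleles[2] %in% s1 && f_alleles[1] %in% s2)
  }
  tab <- data.frame(grid, label = paste0(gl[grid$p1 + 1], "x", gl[grid$p2 + 1],
                                         "->", gl[grid$f + 1]),
                    compatible = compatible)
  lookup <- logical(27)
  lookup[9 * tab$p1 + 3 * tab$p2 + tab$f + 1] <- tab$compatible
  attr(tab, "lookup") <- lookup
  tab
}

#' Parameters for trio validation
#'
#' @param max_rate maximum genome-wide Mendelian-inconsistency rate for
#'   an accepted trio (default 0.013, above the background rate of
#'   genuine low-coverage trios but below rates produced by a wrong
#'   parent).
#' @param alpha_w one-sided significance level for flagging a window's
#'   error count against the Binomial null, Bonferroni corrected over
#'   windows.
#' @param run_min a trio is rejected for clustering when at least this
#'   many consecutive windows are flagged.
#' @param background_rate expected Mendelian-inconsistency rate in a
#'   genuine trio from genotyping error alone (default 0.008, the
#'   background produced by low-coverage het-to-hom undercalls). The
#'   Binomial null rate for window flagging is
#'   \code{max(background_rate, lower-quartile per-window rate)}: a
#'   trio's own genome-wide rate would be inflated by the very clusters
#'   being sought, masking them.
#' @return a list of class \code{trio_params}.
#' @export
trio_params <- function(max_rate = 0.013, alpha_w = 0.05, run_min = 3,
                        background_rate = 0.008) {
  if (max_rate < 0 || max_rate > 1) stop("max_rate must lie in [0, 1]")
  if (alpha_w <= 0 || alpha_w > 1) stop("alpha_w must lie in (0, 1]")
  if (run_min < 1) stop("run_min must be >= 1")
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must lie in [0, 1]")
  structure(list(max_rate = max_rate, alpha_w = alpha_w, run_min = run_min,
                 background_rate = background_rate),
            class = "trio_params")
}

#' Test a candidate parent-parent-offspring trio
#'
#' Counts Mendelian inconsistencies over sites genotyped in all three
#' accessions using the \code{\link{build_compatibility_table}} rules,
#' then tests whether inconsistencies cluster chromosomally: a window is
#' flagged when its error count exceeds the Bonferroni-corrected upper
#' tail of Binomial(n_sites_in_window, background error rate), and a
#' run of \code{run_min} or more consecutive flagged windows rejects the
#' trio as \code{rejected_clustered} (the signature of a wrong parent:
#' contiguous IBD0 intervals). Trios with a genome-wide rate above
#' \code{max_rate} but no clustering are \code{rejected_rate}; the rest
#' are \code{accepted}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ws a \code{\link{build_windows}} result.
#' @param p1,p2,f three distinct accession ids (parents, offspring).
#' @param params a \code{\link{trio_params}}.
#' @param widx optional precomputed site-to-window map.
#' @return a list of class \code{trio_report}: ids, \code{n_informative},
#'   \code{n_mendelian_errors}, \code{error_rate}, \code{windows}
#'   (per-window site/error counts with \code{flagged}), \code{flagged_runs}
#'   (data.frame of window-index runs), \code{verdict}.
#' @export
test_trio <- function(gm, ws, p1, p2, f, params = trio_params(), widx = NULL) {
  ids <- c(p1, p2, f)
  if (anyDuplicated(ids)) stop("trio members must be distinct")
  miss <- setdiff(ids, gm$accession_ids)
  if (length(miss)) stop("unknown accession(s): ", paste(miss, collapse = ", "))
  if (is.null(widx)) widx <- assign_sites_to_windows(gm, ws)
  lookup <- attr(build_compatibility_table(), "lookup")
  g1 <- gm$calls[, p1]; g2 <- gm$calls[, p2]; gf <- gm$calls[, f]
  inf <- which(!is.na(g1) & !is.na(g2) & !is.na(gf) & !is.na(widx))
  n_informative <- length(inf)
  err <- inf[!lookup[9L * g1[inf] + 3L * g2[inf] + gf[inf] + 1L]]
  n_err <- length(err)
  rate <- if (n_informative > 0) n_err / n_informative else NA_real_
  nw <- nrow(ws)
  wins <- data.frame(chrom = ws$chrom, start = ws$start, end = ws$end,
                     n_sites = tabulate(widx[inf], nbins = nw),
                     n_errors = tabulate(widx[err], nbins = nw))
  if (n_informative == 0) {
    rep <- list(p1 = p1, p2 = p2, f = f, n_informative = 0L,
                n_mendelian_errors = 0L, error_rate = NA_real_,
                windows = cbind(wins, flagged = FALSE),
                flagged_runs = data.frame(), verdict = "undetermined")
    class(rep) <- "trio_report"
    return(rep)
  }
  # one-sided binomial tail, Bonferroni over windows with sites; the null is
  # the background error rate of genuine trios (robustly floored by the
  # median window rate so a uniformly noisier panel does not flag everywhere)
  n_tested <- sum(wins$n_sites > 0)
  # lower quartile, not median: a wrong parent can contaminate half the
  # windows, which would drag a median null up to the contaminated rate
  q25_rate <- stats::quantile(wins$n_errors[wins$n_sites > 0] /
                              wins$n_sites[wins$n_sites > 0],
                              0.25, names = FALSE)
  null_rate <- max(params$background_rate, q25_rate)
  crit <- qbinom(1 - params$alpha_w / max(n_tested, 1), wins$n_sites, null_rate)
  wins$flagged <- wins$n_sites > 0 & wins$n_errors > crit
  runs <- flagged_runs(wins, params$run_min)
  verdict <- if (nrow(runs) > 0) "rejected_clustered"
             else if (rate > params$max_rate) "rejected_rate"
             else "accepted"
  rep <- list(p1 = p1, p2 = p2, f = f, n_informative = n_informative,
              n_mendelian_errors = n_err, error_rate = rate,
              windows = wins, flagged_runs = runs, verdict = verdict)
  class(rep) <- "trio_report"
  rep
}

# maximal runs of >= run_min consecutive flagged windows, per chromosome
flagged_runs <- function(wins, run_min) {
  out <- list()
  for (chrom in unique(wins$chrom)) {
    sel <- which(wins$chrom == chrom)
    r <- rle(wins$flagged[sel])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= run_min)
    for (j in keep)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, first_window = sel[starts[j]],
        last_window = sel[ends[j]], n_windows = r$lengths[j])
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      first_window = integer(0),
                                      last_window = integer(0),
                                      n_windows = integer(0)))
  do.call(rbind, out)
}

#' @export
#' @method print trio_report
print.trio_report <- function(x, ...) {
  cat(sprintf("trio %s x %s -> %s: %d/%s informative sites inconsistent (%.2f%%), %d flagged run(s) -> %s\n",
              x$p1, x$p2, x$f, x$n_mendelian_errors,
              format(x$n_informative, big.mark = ","),
              100 * x$error_rate, nrow(x$flagged_runs), x$verdict))
  invisible(x)
}

#' Genomic intervals incompatible with a tested trio
#'
#' Merges each run of flagged windows into one interval and reports the
#' cumulative non-repetitive span as a fraction of the genome-wide
#' non-repetitive total — the portion of the haploid genome that cannot
#' have been inherited from the proposed parents.
#'
#' @param report a \code{\link{test_trio}} result.
#' @param ws the \code{\link{build_windows}} result used for the test.
#' @return list with \code{intervals} (data.frame \code{chrom},
#'   \code{start}, \code{end}, \code{nonrep_bp}, \code{fraction}) and
#'   \code{total_fraction}.
#' @export
incompatible_regions <- function(report, ws) {
  runs <- report$flagged_runs
  tot <- sum(ws$nonrep_span)
  if (!nrow(runs))
    return(list(intervals = data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0), nonrep_bp = numeric(0),
                                       fraction = numeric(0)),
                total_fraction = 0))
  iv <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    w <- runs$first_window[i]:runs$last_window[i]
    data.frame(chrom = runs$chrom[i], start = ws$start[runs$first_window[i]],
               end = ws$end[runs$last_window[i]],
               nonrep_bp = sum(ws$nonrep_span[w]))
  }))
  iv$fraction <- iv$nonrep_bp / tot
  list(intervals = iv, total_fraction = sum(iv$fraction))
}

#' Search for complete trios and infer full siblings
#'
#' For every accession F, each unordered pair of F's parent-offspring
#' partners (from the pairwise IBD calls) is tested as a candidate
#' parent pair; accepted trios are returned. Accessions detected as
#' clones are first collapsed to one representative (panels are assumed
#' to represent unique genotypes; a clone of a parent would otherwise
#' duplicate every trio it resolves). Full siblings are accessions
#' appearing as offspring of the same unordered parent pair among
#' accepted trios. An exhaustive list of extra candidate combinations
#' can be supplied to re-test specific parent pairs irrespective of the
#' pairwise pre-filter.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ws a \code{\link{build_windows}} result.
#' @param pair_calls an \code{\link{ibd_all_pairs}} result.
#' @param params a \code{\link{trio_params}}.
#' @param extra_candidates optional data.frame (\code{p1}, \code{p2},
#'   \code{f}) of combinations to test in addition to the pre-filtered
#'   ones.
#' @return list with \code{trios} (data.frame of all tested trios:
#'   \code{p1}, \code{p2}, \code{f}, \code{n_informative},
#'   \code{n_mendelian_errors}, \code{error_rate}, \code{n_flagged_runs},
#'   \code{verdict}), \code{accepted} (subset), \code{full_sibs}
#'   (data.frame \code{a}, \code{b}), \code{clone_rep} (named vector
#'   mapping dropped clone ids to their representative), and
#'   \code{reports} (list of \code{trio_report}s for accepted trios).
#' @export
search_trios <- function(gm, ws, pair_calls, params = trio_params(),
                         extra_candidates = NULL) {
  widx <- assign_sites_to_windows(gm, ws)
  # collapse clone pairs to a single representative (first id encountered)
  clone_rep <- character(0)
  cl <- pair_calls[pair_calls$call == "clone", , drop = FALSE]
  if (nrow(cl)) {
    g <- igraph::graph_from_data_frame(cl[, c("a", "b")], directed = FALSE)
    comp <- igraph::components(g)$membership
    for (grp in split(names(comp), comp)) {
      rep_id <- sort(grp)[1]
      for (id in setdiff(grp, rep_id)) clone_rep[id] <- rep_id
    }
  }
  dropped <- names(clone_rep)
  po <- pair_calls[pair_calls$call == "parent_offspring" &
                   !(pair_calls$a %in% dropped) & !(pair_calls$b %in% dropped), ,
                   drop = FALSE]
  cand <- list()
  ids <- unique(c(po$a, po$b))
  for (f in ids) {
    partners <- sort(unique(c(po$b[po$a == f], po$a[po$b == f])))
    if (length(partners) < 2) next
    cmb <- utils::combn(partners, 2)
    cand[[f]] <- data.frame(p1 = cmb[1, ], p2 = cmb[2, ], f = f)
  }
  cand <- do.call(rbind, cand)
  if (!is.null(extra_candidates))
    cand <- rbind(cand, extra_candidates[, c("p1", "p2", "f")])
  empty_trios <- data.frame(p1 = character(0), p2 = character(0),
                            f = character(0), n_informative = integer(0),
                            n_mendelian_errors = integer(0),
                            error_rate = numeric(0),
                            n_flagged_runs = integer(0),
                            verdict = character(0))
  if (is.null(cand) || !nrow(cand))
    return(list(trios = empty_trios, accepted = empty_trios,
                full_sibs = data.frame(a = character(0), b = character(0)),
                clone_rep = clone_rep, reports = list()))
  cand <- unique(cand)
  rows <- vector("list", nrow(cand))
  reports <- list()
  for (i in seq_len(nrow(cand))) {
    r <- test_trio(gm, ws, cand$p1[i], cand$p2[i], cand$f[i], params, widx)
    rows[[i]] <- data.frame(p1 = r$p1, p2 = r$p2, f = r$f,
                            n_informative = r$n_informative,
                            n_mendelian_errors = r$n_mendelian_errors,
                            error_rate = r$error_rate,
                            n_flagged_runs = nrow(r$flagged_runs),
                            verdict = r$verdict)
    if (r$verdict == "accepted") reports[[length(reports) + 1]] <- r
  }
  trios <- do.call(rbind, rows)
  rownames(trios) <- NULL
  accepted <- trios[trios$verdict == "accepted", , drop = FALSE]
  fs <- list()
  if (nrow(accepted)) {
    key <- paste(pmin(accepted$p1, accepted$p2), pmax(accepted$p1, accepted$p2))
    for (k in unique(key)) {
      kids <- sort(unique(accepted$f[key == k]))
      if (length(kids) >= 2) {
        cmb <- utils::combn(kids, 2)
        fs[[k]] <- data.frame(a = cmb[1, ], b = cmb[2, ])
      }
    }
  }
  full_sibs <- if (length(fs)) unique(do.call(rbind, fs)) else
    data.frame(a = character(0), b = character(0))
  rownames(full_sibs) <- NULL
  list(trios = trios, accepted = accepted, full_sibs = full_sibs,
       clone_rep = clone_rep, reports = reports)
}

#' Write trio search results
#' @param res a \code{\link{search_trios}} result.
#' @param path output TSV for the tested-trio table.
#' @return \code{path}, invisibly.
#' @export
write_trios <- function(res, path) {
  data.table::fwrite(res$trios, path, sep = "\t")
  invisible(path)
}
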