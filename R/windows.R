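#' Construct a genome map
#'
#' Chromosome lengths plus the intervals of non-repetitive sequence
#' (typically the complement of a repeat annotation). All intervals are
#' 0-based half-open, as in BED; they are clipped to the chromosome,
#' sorted and merged on construction.
#'
#' @param chromosomes data.frame with columns \code{chrom} and
#'   \code{length} (bp).
#' @param nonrepetitive data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open). Defaults to the whole
#'   genome (no repeats).
#' @return An object of class \code{genome_map}.
#' @export
genome_map <- function(chromosomes, nonrepetitive = NULL) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome ids")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (is.null(nonrepetitive)) {
    nonrepetitive <- data.frame(chrom = chromosomes$chrom, start = 0,
                                end = chromosomes$length)
  }
  nonrepetitive <- as.data.frame(nonrepetitive, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(nonrepetitive)))
  nonrepetitive$chrom <- as.character(nonrepetitive$chrom)
  unknown <- setdiff(nonrepetitive$chrom, chromosomes$chrom)
  if (length(unknown))
    stop("mask names unknown chromosome(s): ", paste(unknown, collapse = ", "))
  # clip, drop empty, sort, merge overlapping/adjacent
  len <- chromosomes$length[match(nonrepetitive$chrom, chromosomes$chrom)]
  nonrepetitive$start <- pmax(0, as.numeric(nonrepetitive$start))
  nonrepetitive$end <- pmin(len, as.numeric(nonrepetitive$end))
  nonrepetitive <- nonrepetitive[nonrepetitive$end > nonrepetitive$start, , drop = FALSE]
  nonrepetitive <- nonrepetitive[order(nonrepetitive$chrom, nonrepetitive$start), , drop = FALSE]
  merged <- do.call(rbind, lapply(split(nonrepetitive, nonrepetitive$chrom), function(iv) {
    out_s <- iv$start[1]; out_e <- iv$end[1]
    ss <- numeric(0); ee <- numeric(0)
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e) out_e <- max(out_e, iv$end[i])
      else { ss <- c(ss, out_s); ee <- c(ee, out_e); out_s <- iv$start[i]; out_e <- iv$end[i] }
    }
    data.frame(chrom = iv$chrom[1], start = c(ss, out_s), end = c(ee, out_e),
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  structure(list(chromosomes = chromosomes, nonrepetitive = merged),
            class = "genome_map")
}

#' @export
#' @method print genome_map
print.genome_map <- function(x, ...) {
  cat("genome_map: ", nrow(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp, ",
      format(nonrepetitive_total(x), big.mark = ","),
      " bp non-repetitive\n", sep = "")
  invisible(x)
}

#' Total non-repetitive bp in a genome map
#' @param genome a \code{\link{genome_map}}.
#' @return numeric scalar (bp).
#' @export
nonrepetitive_total <- function(genome) {
  sum(genome$nonrepetitive$end - genome$nonrepetitive$start)
}

#' Tile a genome into windows of fixed non-repetitive span
#'
#' Windows are accumulated left to right along each chromosome: a window
#' closes at the exact base where the non-repetitive sequence gathered
#' since its start reaches \code{target_span}; repetitive gaps contribute
#' nothing, so a window spanning a repeat-masked gap is physically wider
#' than \code{target_span}. The last window of each chromosome may hold
#' less than \code{target_span}. Windows tile each chromosome without
#' overlap: the first starts at 0 and the last ends at the chromosome
#' length. A chromosome with no non-repetitive sequence contributes no
#' windows (with a warning).
#'
#' @param genome a \code{\link{genome_map}}.
#' @param target_span bp of non-repetitive sequence per window
#'   (default 200000, i.e. 200 kb).
#' @return An object of class \code{window_set}: a data.frame with
#'   columns \code{chrom}, \code{start}, \code{end} (0-based half-open)
#'   and \code{nonrep_span}, plus attribute \code{target_span}.
#' @export
build_windows <- function(genome, target_span = 200000) {
  stopifnot(inherits(genome, "genome_map"), target_span > 0)
  res <- list()
  for (k in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$chrom[k]
    clen <- genome$chromosomes$length[k]
    iv <- genome$nonrepetitive[genome$nonrepetitive$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0) {
      warning("chromosome ", chrom, " has no non-repetitive sequence; no windows")
      next
    }
    starts <- numeric(0); ends <- numeric(0); spans <- numeric(0)
    win_start <- 0
    acc <- 0 # non-repetitive bp accumulated in the open window
    for (i in seq_len(nrow(iv))) {
      s <- iv$start[i]; e <- iv$end[i]
      while (acc + (e - s) >= target_span) {
        cut <- s + (target_span - acc) # exact bp where the window closes
        starts <- c(starts, win_start); ends <- c(ends, cut)
        spans <- c(spans, target_span)
        win_start <- cut
        s <- cut
        acc <- 0
      }
      acc <- acc + (e - s)
    }
    if (acc > 0) { # trailing short window, extended to the chromosome end
      starts <- c(starts, win_start); ends <- c(ends, clen); spans <- c(spans, acc)
    } else if (length(ends)) {
      ends[length(ends)] <- clen # absorb trailing repetitive tail
    }
    res[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               nonrep_span = spans, stringsAsFactors = FALSE)
  }
  ws <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               nonrep_span = numeric(0))
  rownames(ws) <- NULL
  attr(ws, "target_span") <- target_span
  class(ws) <- c("window_set", "data.frame")
  ws
}

#' Assign sites to windows
#'
#' Each site is mapped to the unique window whose half-open interval
#' \code{[start, end)} contains its 0-based coordinate (\code{pos - 1}
#' for 1-based VCF positions). Sites on chromosomes without windows map
#' to \code{NA} and are excluded from windowed statistics.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param ws a \code{\link{build_windows}} result.
#' @return integer vector, one window row index (or \code{NA}) per site.
#' @export
assign_sites_to_windows <- function(gm, ws) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(ws, "window_set"))
  idx <- rep(NA_integer_, nrow(gm$sites))
  pos0 <- gm$sites$pos - 1 # VCF positions are 1-based; windows 0-based half-open
  for (chrom in unique(gm$sites$chrom)) {
    w <- which(ws$chrom == chrom)
    if (!length(w)) next
    sel <- which(gm$sites$chrom == chrom)
    j <- findInterval(pos0[sel], ws$start[w])
    ok <- j >= 1 & pos0[sel] < ws$end[w][pmax(j, 1)]
    idx[sel[ok]] <- w[j[ok]]
  }
  idx
}
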