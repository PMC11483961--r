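#' Read genotypes from VCF or genotype TSV
#'
#' VCF (v4.x) files are parsed with \pkg{vcfR}; phase separators are
#' ignored (all calls treated as unphased). Records with more than one
#' alternative allele are skipped with a warning reporting the count.
#' The TSV dialect is detected from the header: a column set
#' \code{chrom, pos, ref, alt} followed by one column per accession with
#' codes \code{0/1/2} and \code{.} for missing.
#'
#' @param path file path (\code{.vcf} or genotype TSV).
#' @param min_maf optional minor-allele-frequency filter: if
#'   \code{> 0}, sites with MAF \code{<= min_maf} among non-missing
#'   calls are dropped.
#' @return a \code{\link{genotype_matrix}} with sites sorted by
#'   (chromosome, position).
#' @export
read_genotypes <- function(path, min_maf = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  gm <- if (startsWith(first, "##fileformat=VCF")) read_genotypes_vcf(path)
        else read_genotypes_tsv(path)
  if (min_maf > 0) gm <- filter_maf(gm, min_maf)
  gm
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi))
    warning(sum(multi), " multi-allelic or ALT-less record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  code <- function(g) {
    g <- sub(":.*", "", g)
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- apply(gt[keep, , drop = FALSE], 2, code)
  if (length(keep) == 1L) calls <- matrix(calls, nrow = 1L,
                                          dimnames = list(NULL, colnames(gt)))
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = alt[keep],
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, colnames(gt))
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = ".", colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt)))
    stop("genotype TSV must start with columns ", paste(need, collapse = ", "))
  acc <- setdiff(names(dt), need)
  if (!length(acc)) stop("genotype TSV has no accession columns")
  calls <- as.matrix(dt[, acc, drop = FALSE])
  storage.mode(calls) <- "integer"
  genotype_matrix(calls, dt[, need], acc)
}

#' Write genotypes
#'
#' Writes either the package's genotype TSV dialect (codes 0/1/2, "."
#' for missing; trivially diffable) or a minimal well-formed VCF v4.2
#' with unphased GT fields.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output file; format chosen by extension (\code{.vcf}
#'   gives VCF, anything else TSV) unless \code{format} is given.
#' @param format \code{"tsv"}, \code{"vcf"} or \code{NULL} (detect).
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gm, path, format = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") {
    m <- gm$calls
    mode(m) <- "character"
    m[is.na(m)] <- "."
    out <- data.frame(gm$sites, m, check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = ".")
  } else if (format == "vcf") {
    gts <- c("0/0", "0/1", "1/1")
    m <- matrix(gts[gm$calls + 1L], nrow = nrow(gm$calls))
    m[is.na(gm$calls)] <- "./."
    lines <- c("##fileformat=VCFv4.2",
               "##source=kinscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$accession_ids), collapse = "\t"))
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                  ".", "PASS", ".", "GT",
                  apply(m, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(lines, body), path)
  } else stop("unknown format: ", format)
  invisible(path)
}

#' Read a genome description
#'
#' @param genome_path 2-column TSV (\code{chrom}, \code{length}), with or
#'   without a header line.
#' @param mask_path optional BED file (0-based half-open) of
#'   non-repetitive intervals; if omitted the whole genome is taken as
#'   non-repetitive.
#' @return a \code{\link{genome_map}}.
#' @export
read_genome_map <- function(genome_path, mask_path = NULL) {
  g <- data.table::fread(genome_path, header = "auto", data.table = FALSE)
  names(g)[1:2] <- c("chrom", "length")
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- data.table::fread(mask_path, header = FALSE, data.table = FALSE)
    if (ncol(mask) < 3) stop("BED mask needs at least 3 columns")
    mask <- mask[, 1:3]
    names(mask) <- c("chrom", "start", "end")
  }
  genome_map(g[, c("chrom", "length")], mask)
}

#' Write a genome map to genome TSV + BED mask
#' @param genome a \code{\link{genome_map}}.
#' @param genome_path output TSV of chromosome lengths.
#' @param mask_path output BED of non-repetitive intervals.
#' @return invisibly, a list of the two paths.
#' @export
write_genome_map <- function(genome, genome_path, mask_path) {
  data.table::fwrite(genome$chromosomes, genome_path, sep = "\t", col.names = TRUE)
  data.table::fwrite(format_bed(genome$nonrepetitive), mask_path, sep = "\t",
                     col.names = FALSE)
  invisible(list(genome = genome_path, mask = mask_path))
}

format_bed <- function(df) {
  data.frame(chrom = df$chrom,
             start = format(df$start, scientific = FALSE, trim = TRUE),
             end = format(df$end, scientific = FALSE, trim = TRUE))
}

#' Write a window table
#' @param ws a \code{\link{build_windows}} result.
#' @param gm optional \code{\link{genotype_matrix}} used to add an
#'   \code{n_sites} column.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_windows <- function(ws, path, gm = NULL) {
  out <- as.data.frame(ws)
  if (!is.null(gm)) {
    widx <- assign_sites_to_windows(gm, ws)
    out$n_sites <- tabulate(widx, nbins = nrow(ws))
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an ancestry-coefficient (Q) matrix
#'
#' @param path TSV with an accession-id column named \code{id} (or the
#'   first column) followed by one numeric column per ancestry component.
#' @return numeric matrix with accession row names.
#' @export
read_q_matrix <- function(path) {
  q <- data.table::fread(path, data.table = FALSE, header = TRUE)
  idcol <- if ("id" %in% names(q)) "id" else names(q)[1]
  ids <- as.character(q[[idcol]])
  m <- as.matrix(q[, setdiff(names(q), idcol), drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a population assignment table
#' @param path TSV with columns \code{id} and \code{population} (header
#'   optional; first two columns used).
#' @return data.frame with columns \code{id}, \code{population}.
#' @export
read_populations <- function(path) {
  p <- data.table::fread(path, data.table = FALSE, header = "auto")
  p <- p[, 1:2]
  names(p) <- c("id", "population")
  p$id <- as.character(p$id)
  p$population <- as.character(p$population)
  p
}
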