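#' Build a pipeline run configuration
#'
#' One flat, auditable namespace holding every threshold of the
#' pipeline, the seed, the input paths (or the simulator switch) and the
#' output directory. Configurations can also be read from a YAML file
#' with \code{\link{read_run_config}}; unknown fields are rejected.
#'
#' @param out_dir output directory.
#' @param seed integer seed (drives the simulator; analysis stages are
#'   deterministic).
#' @param simulate logical: generate the input panel with
#'   \code{\link{simulate_pedigree_data}} (default) instead of reading
#'   files.
#' @param vcf,genome,mask input paths used when \code{simulate = FALSE}
#'   (genotypes, chromosome-length TSV, non-repetitive BED).
#' @param pops,q_matrix optional population table and ancestry Q matrix.
#' @param target_span IBD window span (bp of non-repetitive sequence).
#' @param min_maf MAF input filter.
#' @param ibd an \code{\link{ibd_params}}.
#' @param trio a \code{\link{trio_params}}.
#' @param haploshare optional list(ref_id, chrom, target_start,
#'   target_end, n_windows) enabling the sharing-scan stage.
#' @param sim optional \code{\link{sim_config}} overriding the default
#'   simulator configuration (its seed is replaced by \code{seed}).
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE,
                       vcf = NULL, genome = NULL, mask = NULL,
                       pops = NULL, q_matrix = NULL,
                       target_span = 200000, min_maf = 0,
                       ibd = ibd_params(), trio = trio_params(),
                       haploshare = NULL, sim = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              vcf = vcf, genome = genome, mask = mask, pops = pops,
              q_matrix = q_matrix, target_span = target_span,
              min_maf = min_maf, ibd = ibd, trio = trio,
              haploshare = haploshare, sim = sim)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; top-level keys mirror the arguments of
#'   \code{\link{run_config}}, with \code{ibd} and \code{trio} given as
#'   mappings of threshold name to value.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$ibd)) y$ibd <- do.call(ibd_params, y$ibd)
  if (!is.null(y$trio)) y$trio <- do.call(trio_params, y$trio)
  do.call(run_config, y)
}

#' Validate a run configuration
#'
#' @param cfg a \code{\link{run_config}}.
#' @return character vector of violations (empty when runnable); each
#'   entry names the field and the violated constraint.
#' @export
validate_run_config <- function(cfg) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(!is.na(cfg$seed) && cfg$seed >= 0, "seed: must be a non-negative integer")
  chk(is.numeric(cfg$target_span) && cfg$target_span > 0,
      "target_span: must be > 0")
  chk(cfg$min_maf < 0.5, "min_maf: must be < 0.5")
  for (fld in c("po_ibd0", "po_ibd1", "t0", "t2", "clone_f2")) {
    val <- cfg$ibd[[fld]]
    chk(is.numeric(val) && val >= 0 && val <= 1,
        paste0("ibd$", fld, ": must be in [0,1]"))
  }
  chk(cfg$ibd$po_max_seg > 0, "ibd$po_max_seg: must be > 0")
  chk(cfg$trio$max_rate >= 0 && cfg$trio$max_rate <= 1,
      "trio$max_rate: must be in [0,1]")
  chk(cfg$trio$run_min >= 1, "trio$run_min: must be >= 1")
  if (!isTRUE(cfg$simulate)) {
    for (fld in c("vcf", "genome", "mask")) {
      p <- cfg[[fld]]
      if (is.null(p)) v <- c(v, paste0(fld, ": required when simulate is FALSE"))
      else if (!file.exists(p)) v <- c(v, paste0(fld, ": no such file: ", p))
    }
  }
  for (fld in c("pops", "q_matrix"))
    if (!is.null(cfg[[fld]]) && !file.exists(cfg[[fld]]))
      v <- c(v, paste0(fld, ": no such file: ", cfg[[fld]]))
  if (!is.null(cfg$haploshare))
    for (fld in c("ref_id", "chrom", "target_start", "target_end"))
      if (is.null(cfg$haploshare[[fld]]))
        v <- c(v, paste0("haploshare$", fld, ": required"))
  v
}

stage_msg <- function(name, t0) {
  message(sprintf("[kinscan] stage %-10s done in %.1fs", name,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Stages, in dependency order: \code{simulate} (or load inputs),
#' \code{ibd}, \code{trios}, \code{network}, and optionally
#' \code{haploshare}. Every stage's outputs, the effective parameter
#' values and the md5 checksum of every written file are recorded in
#' \code{manifest.yaml}; analysis stages are deterministic, so a rerun
#' with an identical configuration reproduces identical outputs.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  violations <- validate_run_config(cfg)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stages <- character(0)
  run_stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_msg(name, t0)
    stages <<- c(stages, name)
    res
  }

  sim <- NULL
  inputs <- run_stage("simulate", function() {
    if (isTRUE(cfg$simulate)) {
      scfg <- cfg$sim %||% sim_config()
      scfg$seed <- cfg$seed
      sim <<- simulate_pedigree_data(scfg)
      dir <- file.path(cfg$out_dir, "sim")
      write_sim(sim, dir)
      outputs <<- c(outputs, file.path(dir, c("genotypes.vcf", "genome.tsv",
                                              "mask.bed")))
      list(gm = sim$genotypes, genome = sim$genome)
    } else {
      list(gm = read_genotypes(cfg$vcf, cfg$min_maf),
           genome = read_genome_map(cfg$genome, cfg$mask))
    }
  })
  gm <- inputs$gm; genome <- inputs$genome
  ws <- build_windows(genome, cfg$target_span)

  pairs <- run_stage("ibd", function() {
    p <- ibd_all_pairs(gm, ws, cfg$ibd)
    f <- file.path(cfg$out_dir, "pairs.tsv")
    write_pairs(p, f)
    outputs <<- c(outputs, f)
    p
  })

  trio_res <- run_stage("trios", function() {
    r <- search_trios(gm, ws, pairs, cfg$trio)
    f <- file.path(cfg$out_dir, "trios.tsv")
    write_trios(r, f)
    outputs <<- c(outputs, f)
    r
  })

  graph <- run_stage("network", function() {
    anc <- if (!is.null(cfg$q_matrix)) read_q_matrix(cfg$q_matrix) else NULL
    g <- build_kinship_graph(pairs, trio_res$accepted, trio_res$full_sibs, anc)
    f1 <- file.path(cfg$out_dir, "network.tsv")
    f2 <- file.path(cfg$out_dir, "network.graphml")
    export_graph(g, f1, "tsv"); export_graph(g, f2, "graphml")
    outputs <<- c(outputs, f1, f2)
    g
  })

  share <- NULL
  if (!is.null(cfg$haploshare)) {
    share <- run_stage("haploshare", function() {
      hs <- cfg$haploshare
      scan <- sharing_scan(gm, genome, hs$ref_id, hs$chrom,
                           n_windows = hs$n_windows %||% 50,
                           verify = c(hs$target_start, hs$target_end))
      dos <- call_dosage(scan, hs$target_start, hs$target_end)
      f <- file.path(cfg$out_dir, "dosage.tsv")
      data.table::fwrite(data.frame(id = names(dos), dosage = dos), f,
                         sep = "\t")
      outputs <<- c(outputs, f)
      freq <- NULL
      if (!is.null(cfg$pops)) {
        freq <- population_frequencies(dos, read_populations(cfg$pops))
        f2 <- file.path(cfg$out_dir, "haplotype_frequencies.tsv")
        data.table::fwrite(freq, f2, sep = "\t")
        outputs <<- c(outputs, f2)
      }
      list(scan = scan, dosage = dos, frequencies = freq)
    })
  }

  manifest <- list(
    seed = cfg$seed,
    stages = stages,
    parameters = list(target_span = cfg$target_span, min_maf = cfg$min_maf,
                      ibd = unclass(cfg$ibd), trio = unclass(cfg$trio),
                      haploshare = cfg$haploshare),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, pairs = pairs, trios = trio_res,
                 graph = graph, haploshare = share, sim = sim))
}
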