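#' Load a capture panel from a pipeline configuration
#'
#' A panel configuration names the genotypes and the per-genotype input
#' files (bedGraph depth track, VCF), plus the shared genome index and
#' target BED, the analysis thresholds and a seed. See [runPipeline()] for
#' the YAML layout.
#'
#' @param config configuration list (already parsed YAML).
#' @param base directory against which relative paths are resolved.
#' @return list with \code{panel} (a [CapturePanel-class]) and
#'   \code{variants} (named list of variant data.frames).
#' @export
loadPanelConfig <- function(config, base = ".") {
  gts <- config$genotypes
  if (is.null(gts) || length(gts) < 2)
    stop("panel configuration needs at least 2 genotypes")
  rp <- function(p) if (file.exists(p)) p else file.path(base, p)
  need <- function(g, field) {
    p <- gts[[g]][[field]]
    if (is.null(p)) stop("genotype '", g, "' is missing its ", field, " path")
    p <- rp(p)
    if (!file.exists(p))
      stop("genotype '", g, "': ", field, " file not found: ", p)
    p
  }
  gi <- readGenomeIndex(rp(config$genome_index))
  tgt <- readTargetBed(rp(config$targets))
  min_depth <- config$min_depth %||% 10
  trks <- list(); vars <- list(); stats <- NULL
  for (g in names(gts)) {
    trks[[g]] <- readBedGraph(need(g, "bedgraph"))
    vars[[g]] <- readVcfGenotypes(need(g, "vcf"), min_depth = min_depth)
  }
  stats_path <- config$alignment_stats
  stats <- if (!is.null(stats_path))
    utils::read.table(rp(stats_path), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  inbred <- config$inbred %||% TRUE
  pan <- CapturePanel(trks, stats = stats, targets = tgt, genomeIndex = gi,
                      inbred = unlist(inbred),
                      read_length = config$read_length %||% 100)
  list(panel = pan, variants = vars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full capture-analysis pipeline
#'
#' Orchestrates simulate (optional) -> capture QC -> CNV/PAV calling ->
#' SNP classification and summary -> copy accounting (optional) ->
#' promoter NJ tree (optional) as one reproducible run. Every stage writes
#' its TSV outputs into the run directory and a \code{manifest.json}
#' records the package version, seed, thresholds, per-stage timings and
#' md5 checksums of all outputs, so a rerun with the same configuration
#' and seed reproduces byte-identical files for the deterministic stages.
#'
#' @param config a YAML file path or a configuration list. Either a
#'   \code{simulate:} block (arguments for [simulationConfig()]) or a
#'   \code{genotypes:} block mapping each genotype to its \code{bedgraph}
#'   and \code{vcf} paths together with \code{genome_index} and
#'   \code{targets} paths. Optional: \code{min_depth} (default 10),
#'   \code{thresholds} (gain/loss/absent), \code{loo}, \code{inventory}
#'   (TSV path) with \code{n_genes}, \code{promoter_alignment} (aligned
#'   FASTA) with \code{bootstrap} replicates, \code{seed}.
#' @param out_dir run directory, created if needed.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  manifest <- list(package = "polycap",
                   version = as.character(utils::packageVersion("polycap")),
                   seed = seed, stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds =
      round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    inputs <- stage("simulate", function() {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      cfg <- do.call(simulationConfig, args)
      sim <<- simulateExperiment(cfg)
      writeSimulation(sim, file.path(out_dir, "inputs"))
      list(panel = panel(sim), variants = sim@variants)
    })
  } else {
    inputs <- stage("load", function()
      loadPanelConfig(config, base = dirname(out_dir)))
  }
  pan <- inputs$panel
  vars <- inputs$variants

  qc <- stage("qc", function() {
    metrics <- panelCaptureMetrics(pan)
    tab <- captureMetricsTable(metrics)
    utils::write.table(tab, file.path(out_dir, "capture_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics
  })

  cnv <- stage("cnv", function() {
    thr <- config$thresholds %||% list()
    thresholds <- cnvThresholds(gain = thr$gain %||% 1.5,
                                loss = thr$loss %||% 0.5,
                                absent = thr$absent %||% 0.05)
    mat <- locusNormalizedMatrix(pan)
    calls <- callCnv(mat, thresholds = thresholds,
                     het_snp_loci = hetSnpLoci(vars, targets(pan)),
                     loo = config$loo)
    utils::write.table(as.data.frame(calls),
                       file.path(out_dir, "cnv_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  snps <- stage("snps", function() {
    ann <- lapply(names(vars), function(g) {
      v <- vars[[g]]
      v$zygosity <- classifyZygosity(v$call, inbred = isInbred(pan)[[g]])
      if (!is.null(sim))
        v <- snpEffects(v, targets(pan), sim@cdsRanges, sim@cds)
      cbind(genotype = g, v)
    })
    ann <- do.call(rbind, ann)
    utils::write.table(ann, file.path(out_dir, "snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sm <- summarizeSnps(vars, targets(pan))
    utils::write.table(sm$per_genotype,
                       file.path(out_dir, "snp_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sm$panel, file.path(out_dir, "snp_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sm
  })

  copies <- NULL
  if (!is.null(config$inventory)) {
    copies <- stage("copies", function() {
      inv <- readCopyInventory(config$inventory)
      out <- summarizeInventory(inv, n_genes = config$n_genes %||%
                                  length(unique(inv$gene_id)))
      utils::write.table(out, file.path(out_dir, "inventory_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
  }

  tree <- NULL
  if (!is.null(config$promoter_alignment) || !is.null(sim)) {
    tree <- stage("tree", function() {
      aln <- if (!is.null(config$promoter_alignment))
        Biostrings::readDNAStringSet(config$promoter_alignment)
      else sim@promoters  # simulated promoters are unaligned but equal-length
      tr <- bootstrapTree(aln, n_reps = config$bootstrap %||% 100,
                          seed = seed)
      ape::write.tree(tr, file.path(out_dir, "promoter_tree.nwk"))
      tr
    })
  }

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(outs))
  names(manifest$checksums) <- substring(names(manifest$checksums),
                                         nchar(out_dir) + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(panel = pan, metrics = qc, cnv = cnv, snps = snps,
                 copies = copies, tree = tree, manifest = manifest))
}
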