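#' Construct a CapturePanel
#'
#' Validating constructor. Coverage tracks are canonicalized (sorted,
#' zero-depth segments dropped) and their sequence levels harmonized with
#' the genome index so interval arithmetic across tracks and targets is
#' well defined.
#'
#' @param tracks named list of coverage \code{GRanges} (a \code{depth}
#'   integer metadata column; as returned by [readBedGraph()]), one per
#'   genotype.
#' @param stats \code{data.frame} with columns \code{genotype},
#'   \code{aligned_reads}, \code{read_length}. If \code{NULL}, aligned reads
#'   are inferred from each track as total aligned bases / read length.
#' @param targets target-region \code{GRanges} as from [readTargetBed()].
#' @param genomeIndex a \code{Seqinfo} as from [readGenomeIndex()].
#' @param inbred logical (scalar or named per genotype): are the samples
#'   fully inbred lines? Governs hemi-SNP interpretation downstream.
#' @param read_length used when \code{stats} is \code{NULL} (default 100).
#' @return a [CapturePanel-class] object.
#' @examples
#' gi <- GenomeInfoDb::Seqinfo("chr1", 10000)
#' trk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), depth = 5L)
#' tgt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
#'   gene_id = "g1", copy_id = "g1.A01_1", subgenome = "A", functional = TRUE)
#' CapturePanel(list(a = trk, b = trk), targets = tgt, genomeIndex = gi)
#' @export
CapturePanel <- function(tracks, stats = NULL, targets, genomeIndex,
                         inbred = TRUE, read_length = 100) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("'tracks' must be a named list (one coverage track per genotype)")
  gt <- names(tracks)
  tracks <- lapply(tracks, function(x) {
    x <- canonicalizeTrack(x)
    GenomeInfoDb::seqlevels(x) <- GenomeInfoDb::seqlevels(genomeIndex)
    x
  })
  checkRegionsWithin(do.call(c, unname(tracks)), genomeIndex, what = "coverage track")
  targets <- harmonizeSeqlevels(targets, genomeIndex)
  checkRegionsWithin(targets, genomeIndex, what = "target region")
  if (is.null(stats)) {
    stats <- data.frame(
      genotype = gt,
      aligned_reads = vapply(tracks, function(x)
        round(trackBaseCount(x) / read_length), numeric(1)),
      read_length = read_length,
      row.names = NULL
    )
  }
  if (length(inbred) == 1L) inbred <- stats::setNames(rep(inbred, length(gt)), gt)
  new("CapturePanel", genotypes = gt, tracks = tracks, stats = stats,
      targets = targets, genomeIndex = genomeIndex, inbred = inbred)
}

#' @rdname CapturePanel-class
#' @export
setMethod("genotypes", "CapturePanel", function(x) x@genotypes)

#' @rdname CapturePanel-class
#' @export
setMethod("tracks", "CapturePanel", function(x) x@tracks)

#' @rdname CapturePanel-class
#' @export
setMethod("targets", "CapturePanel", function(x) x@targets)

#' @rdname CapturePanel-class
#' @export
setMethod("genomeIndex", "CapturePanel", function(x) x@genomeIndex)

#' @rdname CapturePanel-class
#' @export
setMethod("alignmentStats", "CapturePanel", function(x) x@stats)

#' Is each genotype a fully inbred line?
#' @param x a \code{CapturePanel}.
#' @return named logical vector.
#' @export
isInbred <- function(x) {
  stopifnot(is(x, "CapturePanel"))
  x@inbred
}

setMethod("show", "CapturePanel", function(object) {
  cat("CapturePanel with", length(object@genotypes), "genotypes:",
      paste(object@genotypes, collapse = ", "), "\n")
  cat("  targets:", length(object@targets), "regions,",
      length(unique(object@targets$copy_id)), "gene copies,",
      length(unique(object@targets$gene_id)), "genes\n")
  cat("  genome:", length(GenomeInfoDb::seqnames(object@genomeIndex)),
      "sequences,", format(totalGenomeLength(object@genomeIndex),
                           big.mark = ","), "bp\n")
})

#' @rdname CaptureMetrics-class
#' @export
setMethod("metricValues", "CaptureMetrics", function(x) x@values)

setMethod("show", "CaptureMetrics", function(object) {
  cat("CaptureMetrics for", object@genotype, "(k =", object@k, ")\n")
  v <- object@values
  lab <- c(mean_genome_coverage = "Mean genome-wide coverage",
           mean_target_coverage = "Mean target coverage",
           enrichment_factor = "Enrichment factor",
           normalized_mean_target_coverage = "Normalized mean target coverage",
           fraction_target_covered = "Fraction of target covered (%)",
           fraction_target_ge_k = "Target fraction covered at >= k reads (%)",
           specificity = "Bases covering target (%)",
           genome_fraction_ge_k = "Genome fraction covered at >= k reads (%)")
  for (n in names(lab))
    cat(sprintf("  %-42s %10.2f\n", lab[[n]], v[[n]]))
})

#' @rdname CnvCallSet-class
#' @export
setMethod("cnvCalls", "CnvCallSet", function(x) x@calls)

#' Coerce a CnvCallSet to a plain data.frame of calls
#' @param x a \code{CnvCallSet}.
#' @param row.names,optional,... passed on (see \code{as.data.frame}).
#' @method as.data.frame CnvCallSet
#' @export
as.data.frame.CnvCallSet <- function(x, row.names = NULL, optional = FALSE, ...)
  as.data.frame(x@calls, row.names = row.names, optional = optional, ...)

setMethod("show", "CnvCallSet", function(object) {
  st <- object@calls$state
  cat("CnvCallSet:", nrow(object@calls), "calls (",
      sum(object@calls$excluded), "excluded ),",
      "reference =", object@reference, "\n")
  cat("  thresholds: gain >", object@thresholds$gain,
      ", loss <", object@thresholds$loss,
      ", absent <", object@thresholds$absent, "\n")
  tb <- table(factor(st[!object@calls$excluded],
                     levels = c("normal", "gain", "loss", "absent")))
  cat("  states:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

#' @rdname CaptureSimulation-class
#' @export
setMethod("panel", "CaptureSimulation", function(x) x@panel)

#' @rdname CaptureSimulation-class
#' @export
setMethod("truthTable", "CaptureSimulation", function(x) x@truth)

#' @rdname CaptureSimulation-class
#' @export
setMethod("genotypes", "CaptureSimulation", function(x) x@panel@genotypes)

setMethod("show", "CaptureSimulation", function(object) {
  cat("CaptureSimulation:", length(object@panel@genotypes), "genotypes,",
      length(unique(object@panel@targets$copy_id)), "target copies\n")
  cat("  seed:", object@config$seed,
      " enrichment:", object@config$enrichment,
      " background mean:", object@config$background_mean, "\n")
  ev <- object@truth$multipliers
  cat("  events (multiplier != 1):", sum(ev != 1), "\n")
})
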