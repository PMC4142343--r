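#' Mean read depth over a scope
#'
#' Length-weighted mean depth: the sum of depth times segment length over
#' the scope, divided by the scope length in bp. Uncovered bases count as
#' depth 0. With \code{regions = NULL} the scope is the whole genome (so
#' chromosomes without coverage still dilute the mean).
#'
#' @param track coverage \code{GRanges} with a \code{depth} column.
#' @param genomeIndex \code{Seqinfo} giving sequence lengths.
#' @param regions optional \code{GRanges}; the scope is the union of the
#'   regions (overlaps are counted once).
#' @return mean coverage (a dimensionful "x" value).
#' @export
meanDepth <- function(track, genomeIndex, regions = NULL) {
  if (is.null(regions)) {
    scope_len <- totalGenomeLength(genomeIndex)
    bases <- trackBaseCount(track)
  } else {
    regions <- harmonizeSeqlevels(regions, genomeIndex)
    checkRegionsWithin(regions, genomeIndex, what = "scope region")
    red <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
    scope_len <- sum(as.numeric(GenomicRanges::width(red)))
    if (scope_len == 0) stop("empty scope")
    bases <- basesOnRegions(track, red)
  }
  bases / scope_len
}

#' Normalize a read depth by the expected genome-wide mean
#'
#' Converts a raw depth d into the dimensionless quantity
#' \code{d * G / (N * rl)}: depth divided by the expected genome-wide mean
#' coverage given N aligned reads of length rl on a genome of G bp. Each
#' constant-depth segment of a coverage track is an "equally covered
#' region" and is normalized with this factor; per-region values are
#' length-weighted means of the normalized segment depths, which is why
#' the same factor applies to a region's mean depth directly. The value is
#' invariant under rescaling library size (doubling all depths and N
#' together changes nothing).
#'
#' @param depth raw depth (scalar or vector).
#' @param aligned_reads number of aligned reads N (> 0).
#' @param read_length read length rl in bp.
#' @param genomeIndex \code{Seqinfo} (or a single numeric total length G).
#' @return normalized (dimensionless) coverage.
#' @examples
#' normalizedCoverage(50, aligned_reads = 1e4, read_length = 100,
#'                    genomeIndex = 1e6)  # 50
#' @export
normalizedCoverage <- function(depth, aligned_reads, read_length, genomeIndex) {
  G <- if (is.numeric(genomeIndex)) genomeIndex else totalGenomeLength(genomeIndex)
  if (!is.finite(aligned_reads) || aligned_reads <= 0)
    stop("normalization undefined: aligned_reads must be > 0")
  if (read_length <= 0) stop("read_length must be > 0")
  depth * G / (aligned_reads * read_length)
}

#' Capture-performance metrics for one genotype
#'
#' Computes the standard QC panel of a targeted capture experiment from a
#' depth track, the target regions and the alignment totals:
#' mean genome-wide coverage, mean target coverage, their ratio (the
#' enrichment factor), normalized mean target coverage
#' (\code{meanTarget * G / (N * rl)}), the fraction of target bases covered
#' at depth >= 1 (capture sensitivity), the fraction covered at depth >= k,
#' the percentage of all sequenced bases falling in the target
#' (specificity; computed over bases, since read assignment is not
#' recoverable from a depth track) and the genome fraction at depth >= k.
#'
#' @param track coverage \code{GRanges}.
#' @param targets target \code{GRanges} (non-empty).
#' @param aligned_reads,read_length alignment totals for the genotype.
#' @param genomeIndex \code{Seqinfo}.
#' @param k depth threshold for the ">= k" fractions (default 10).
#' @param strict_gt if \code{TRUE}, the k-fractions use depth > k instead
#'   of >= k.
#' @param genotype label carried into the result.
#' @return a [CaptureMetrics-class] object.
#' @export
captureMetrics <- function(track, targets, aligned_reads, read_length,
                           genomeIndex, k = 10, strict_gt = FALSE,
                           genotype = "sample") {
  if (length(targets) == 0) stop("empty target set")
  targets <- harmonizeSeqlevels(targets, genomeIndex)
  checkRegionsWithin(targets, genomeIndex, what = "target region")
  track <- canonicalizeTrack(harmonizeSeqlevels(track, genomeIndex))
  G <- totalGenomeLength(genomeIndex)
  red <- GenomicRanges::reduce(targets, ignore.strand = TRUE)
  target_len <- sum(as.numeric(GenomicRanges::width(red)))

  total_bases <- trackBaseCount(track)
  target_bases <- basesOnRegions(track, red)
  mean_genome <- total_bases / G
  mean_target <- target_bases / target_len
  deep <- if (strict_gt) track[track$depth > k] else track[track$depth >= k]

  vals <- c(
    mean_genome_coverage = mean_genome,
    mean_target_coverage = mean_target,
    enrichment_factor = if (mean_genome > 0) mean_target / mean_genome else NA_real_,
    normalized_mean_target_coverage =
      normalizedCoverage(mean_target, aligned_reads, read_length, G),
    fraction_target_covered = 100 * coveredWidthOnRegions(track, red) / target_len,
    fraction_target_ge_k = 100 * coveredWidthOnRegions(deep, red) / target_len,
    specificity = if (total_bases > 0) 100 * target_bases / total_bases else 0,
    genome_fraction_ge_k =
      100 * sum(as.numeric(GenomicRanges::width(deep))) / G
  )
  new("CaptureMetrics", genotype = genotype, values = vals, k = k,
      metadata = list(
        specificity_unit = "bases (read assignment unavailable from a depth track)",
        k_comparison = if (strict_gt) ">" else ">="))
}

#' Capture metrics for every genotype of a panel
#'
#' @param x a [CapturePanel-class].
#' @param k,strict_gt see [captureMetrics()].
#' @return named list of [CaptureMetrics-class], one per genotype.
#' @export
panelCaptureMetrics <- function(x, k = 10, strict_gt = FALSE) {
  stopifnot(is(x, "CapturePanel"))
  st <- alignmentStats(x)
  out <- lapply(genotypes(x), function(g) {
    row <- st[st$genotype == g, ]
    captureMetrics(tracks(x)[[g]], targets(x), row$aligned_reads,
                   row$read_length, genomeIndex(x), k = k,
                   strict_gt = strict_gt, genotype = g)
  })
  stats::setNames(out, genotypes(x))
}

#' Tabulate capture metrics across genotypes
#'
#' @param metrics list of [CaptureMetrics-class] (as from
#'   [panelCaptureMetrics()]).
#' @return data.frame with one metric per row, one genotype per column.
#' @export
captureMetricsTable <- function(metrics) {
  vals <- vapply(metrics, metricValues, numeric(8))
  data.frame(metric = rownames(vals), vals, row.names = NULL,
             check.names = FALSE)
}
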