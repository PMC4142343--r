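#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges findOverlaps pintersect reduce seqnames start end width strand
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels seqlevels<- seqinfo
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' CapturePanel: a multi-genotype targeted-capture experiment
#'
#' Container for everything the depth-based stages of the pipeline need:
#' one coverage track per genotype (a \code{GRanges} with a \code{depth}
#' metadata column, sorted and disjoint, uncovered bases implicitly 0),
#' per-genotype alignment statistics (aligned read count and read length,
#' the denominator of the coverage normalization), the captured target
#' regions (one range per gene-copy interval, carrying \code{gene_id},
#' \code{copy_id}, \code{subgenome} and \code{functional} metadata) and the
#' genome index (\code{Seqinfo}) that supplies the total genome length.
#'
#' @slot genotypes character vector of genotype (sample) names.
#' @slot tracks named list of coverage \code{GRanges}, one per genotype.
#' @slot stats \code{data.frame} with columns \code{genotype},
#'   \code{aligned_reads}, \code{read_length}.
#' @slot targets \code{GRanges} of target regions.
#' @slot genomeIndex \code{Seqinfo} with the sequence lengths; the sum of
#'   lengths is the total genome length used for normalization.
#' @slot inbred named logical; \code{TRUE} for fully inbred genotypes, which
#'   licenses the hemi-SNP interpretation of heterozygous calls.
#'
#' @seealso [CapturePanel()] for the validating constructor,
#'   [captureMetrics()], [locusNormalizedMatrix()].
#' @export
setClass("CapturePanel",
  representation(
    genotypes = "character",
    tracks = "list",
    stats = "data.frame",
    targets = "GRanges",
    genomeIndex = "Seqinfo",
    inbred = "logical"
  )
)

setValidity("CapturePanel", function(object) {
  msg <- character()
  gt <- object@genotypes
  if (!length(gt) || anyDuplicated(gt))
    msg <- c(msg, "genotype names must be non-empty and unique")
  if (!identical(sort(names(object@tracks)), sort(gt)))
    msg <- c(msg, "tracks must be a list named by the genotypes")
  if (!all(vapply(object@tracks, is, logical(1), "GRanges")))
    msg <- c(msg, "every track must be a GRanges")
  need <- c("genotype", "aligned_reads", "read_length")
  if (!all(need %in% names(object@stats)))
    msg <- c(msg, "stats needs columns genotype, aligned_reads, read_length")
  else {
    if (!setequal(object@stats$genotype, gt))
      msg <- c(msg, "stats must have one row per genotype")
    if (any(object@stats$aligned_reads < 0) || any(object@stats$read_length <= 0))
      msg <- c(msg, "aligned_reads must be >= 0 and read_length > 0")
  }
  if (!all(c("gene_id", "copy_id") %in% names(mcols(object@targets))))
    msg <- c(msg, "targets must carry gene_id and copy_id metadata")
  if (!identical(sort(names(object@inbred)), sort(gt)))
    msg <- c(msg, "inbred must be a logical named by the genotypes")
  if (length(msg)) msg else TRUE
})

#' CaptureMetrics: capture-performance metrics for one genotype
#'
#' Holds the standard capture QC quantities: mean genome-wide and mean
#' on-target coverage, enrichment factor (their ratio), normalized mean
#' target coverage, fraction of target covered (depth >= 1), fraction
#' covered at depth >= k, on-target specificity (percent of sequenced bases
#' falling in the target) and the genome fraction at depth >= k.
#'
#' @slot genotype genotype name.
#' @slot values named numeric vector of the metrics.
#' @slot k depth threshold used for the ">= k" fractions.
#' @slot metadata list of notes (e.g. that specificity is computed over
#'   bases, not reads).
#' @export
setClass("CaptureMetrics",
  representation(genotype = "character", values = "numeric",
                 k = "numeric", metadata = "list")
)

setValidity("CaptureMetrics", function(object) {
  need <- c("mean_genome_coverage", "mean_target_coverage", "enrichment_factor",
            "normalized_mean_target_coverage", "fraction_target_covered",
            "fraction_target_ge_k", "specificity", "genome_fraction_ge_k")
  if (!all(need %in% names(object@values)))
    return(paste("values must contain:", paste(need, collapse = ", ")))
  v <- object@values[need]
  if (any(is.finite(v) & v < 0)) return("metrics must be nonnegative")
  pc <- v[c("fraction_target_covered", "fraction_target_ge_k",
            "specificity", "genome_fraction_ge_k")]
  if (any(is.finite(pc) & pc > 100 + 1e-9)) return("percentages must be <= 100")
  TRUE
})

#' CnvCallSet: CNV/PAV calls for a locus-by-genotype panel
#'
#' One row per target copy and genotype with the normalized coverage, the
#' panel reference, their ratio, and the called state (\code{normal},
#' \code{gain}, \code{loss}, \code{absent}); rows can instead be excluded
#' (with a reason) when the locus carries heterozygous SNPs in that genotype
#' or the panel reference is zero.
#'
#' @slot calls \code{DataFrame} with columns \code{copy_id}, \code{genotype},
#'   \code{coverage}, \code{reference}, \code{ratio}, \code{state},
#'   \code{excluded}, \code{reason}.
#' @slot thresholds list with elements \code{gain}, \code{loss}, \code{absent}.
#' @slot reference \code{"panel-mean"} or \code{"leave-one-out"}.
#' @export
setClass("CnvCallSet",
  representation(calls = "DataFrame", thresholds = "list",
                 reference = "character")
)

setValidity("CnvCallSet", function(object) {
  need <- c("copy_id", "genotype", "coverage", "reference", "ratio",
            "state", "excluded", "reason")
  if (!all(need %in% names(object@calls)))
    return(paste("calls must contain columns:", paste(need, collapse = ", ")))
  st <- object@calls$state
  ok <- st %in% c("normal", "gain", "loss", "absent") | is.na(st)
  if (!all(ok)) return("invalid state labels")
  if (any(!is.na(st) & object@calls$excluded))
    return("excluded calls must carry no state")
  TRUE
})

#' CaptureSimulation: a simulated allopolyploid capture experiment
#'
#' The complete output of [simulateExperiment()]: the simulated
#' [CapturePanel], per-genotype variant tables, the generative truth
#' (per-locus copy multipliers and the placed SNPs with their zygosity
#' class), CDS models and sequences, promoter sequences and the full locus
#' sequences, plus the configuration that produced them.
#'
#' @slot panel the simulated [CapturePanel].
#' @slot variants named list (per genotype) of variant \code{data.frame}s
#'   with columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{call}, \code{depth}.
#' @slot truth list with \code{multipliers} (copy-by-genotype matrix) and
#'   \code{snps} (data.frame of placed variants with zygosity truth).
#' @slot cds \code{DNAStringSet} of CDS sequences named by copy_id.
#' @slot cdsRanges \code{GRanges} of CDS features (GFF3-style).
#' @slot promoters \code{DNAStringSet} of promoter sequences.
#' @slot loci \code{DNAStringSet} of full locus sequences.
#' @slot config the simulation configuration list.
#' @export
setClass("CaptureSimulation",
  representation(
    panel = "CapturePanel",
    variants = "list",
    truth = "list",
    cds = "DNAStringSet",
    cdsRanges = "GRanges",
    promoters = "DNAStringSet",
    loci = "DNAStringSet",
    config = "list"
  )
)
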