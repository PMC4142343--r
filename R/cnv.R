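#' CNV/PAV ratio thresholds
#'
#' The ratio of a genotype's normalized locus coverage to the panel
#' reference is compared against fixed thresholds: copy-number variation is
#' called when the ratio is smaller than \code{loss} (0.5) or higher than
#' \code{gain} (1.5), and presence-absence variation (complete loss of the
#' locus) when it is smaller than \code{absent} (0.05). All comparisons are
#' strict, so a ratio exactly at a threshold stays \code{normal}.
#'
#' @param gain,loss,absent ratio thresholds; must satisfy
#'   \code{0 < absent < loss < 1 < gain}.
#' @return a validated list of thresholds.
#' @export
cnvThresholds <- function(gain = 1.5, loss = 0.5, absent = 0.05) {
  if (!(0 < absent && absent < loss && loss < 1 && 1 < gain))
    stop("thresholds must satisfy 0 < absent < loss < 1 < gain")
  list(gain = gain, loss = loss, absent = absent)
}

#' Normalized locus coverage matrix for a genotype panel
#'
#' For every target copy and genotype, the length-weighted mean normalized
#' coverage over the copy's full span: total aligned bases falling in the
#' copy's region(s), divided by the span length (uncovered bases count as
#' depth 0), scaled by \code{G / (N * rl)}. Library-size differences
#' between genotypes cancel, so two genotypes with the same biology but
#' 3x different sequencing depth get identical entries.
#'
#' @param x a [CapturePanel-class] with at least 2 genotypes, or a named
#'   list of coverage \code{GRanges} (then \code{targets}, \code{stats}
#'   and \code{genomeIndex} must be supplied).
#' @param targets,stats,genomeIndex see [CapturePanel()]; ignored when
#'   \code{x} is a panel.
#' @return numeric matrix, rows = copy_ids, columns = genotypes.
#' @export
locusNormalizedMatrix <- function(x, targets = NULL, stats = NULL,
                                  genomeIndex = NULL) {
  if (is(x, "CapturePanel")) {
    trks <- tracks(x); targets <- targets(x)
    stats <- alignmentStats(x); genomeIndex <- genomeIndex(x)
  } else {
    trks <- x
    if (is.null(targets) || is.null(stats) || is.null(genomeIndex))
      stop("targets, stats and genomeIndex are required")
  }
  gt <- stats$genotype
  if (length(gt) < 2) stop("a panel needs at least 2 genotypes")
  miss <- setdiff(gt, names(trks))
  if (length(miss))
    stop("genotype missing a coverage track: ", paste(miss, collapse = ", "))
  G <- totalGenomeLength(genomeIndex)
  ids <- unique(targets$copy_id)
  span_len <- vapply(split(as.numeric(GenomicRanges::width(targets)),
                           targets$copy_id)[ids], sum, numeric(1))
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(gt),
                dimnames = list(ids, gt))
  for (g in gt) {
    trk <- harmonizeSeqlevels(canonicalizeTrack(trks[[g]]), genomeIndex)
    row <- stats[stats$genotype == g, ]
    hits <- GenomicRanges::findOverlaps(trk, targets, ignore.strand = TRUE)
    bases <- numeric(length(ids)); names(bases) <- ids
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(trk[S4Vectors::queryHits(hits)],
                                      targets[S4Vectors::subjectHits(hits)],
                                      ignore.strand = TRUE)
      contrib <- as.numeric(GenomicRanges::width(ov)) *
        as.numeric(trk$depth[S4Vectors::queryHits(hits)])
      agg <- tapply(contrib, targets$copy_id[S4Vectors::subjectHits(hits)], sum)
      bases[names(agg)] <- agg
    }
    mat[, g] <- normalizedCoverage(bases / span_len, row$aligned_reads,
                                   row$read_length, G)
  }
  mat
}

#' Call CNV and PAV states across a genotype panel
#'
#' For every locus (row) and genotype (column) of a normalized coverage
#' matrix, the ratio of the genotype's coverage to the panel reference is
#' classified: \code{absent} when ratio < absent-threshold (PAV, the
#' extreme of loss and checked first), \code{loss} when < loss-threshold,
#' \code{gain} when > gain-threshold, otherwise \code{normal}. The panel
#' reference is the arithmetic mean of normalized coverages, either over
#' all genotypes (focal included) or leave-one-out (\code{loo}); with a
#' small panel the focal genotype otherwise dominates its own reference,
#' so \code{loo} defaults to \code{TRUE} for panels of up to 6 genotypes.
#' Loci with heterozygous SNPs in a genotype are excluded for that
#' genotype (homoeologous cross-mapping confounds the coverage there), and
#' all calls at a locus are excluded when the panel reference is zero.
#'
#' @param mat matrix from [locusNormalizedMatrix()] (finite, nonnegative;
#'   >= 2 columns).
#' @param thresholds a [cnvThresholds()] list.
#' @param het_snp_loci optional named list (per genotype) of copy_ids at
#'   which heterozygous SNPs were observed; those locus-genotype calls are
#'   excluded.
#' @param loo leave-one-out reference? Default: \code{TRUE} when the panel
#'   has at most 6 genotypes.
#' @return a [CnvCallSet-class].
#' @examples
#' m <- rbind(L1 = c(0.4, 1, 1, 1) * 100)
#' colnames(m) <- paste0("g", 1:4)
#' callCnv(m, loo = FALSE)
#' @export
callCnv <- function(mat, thresholds = cnvThresholds(), het_snp_loci = NULL,
                    loo = NULL) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop("ratios are undefined for a single-genotype panel")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("coverage matrix must be finite and nonnegative")
  if (is.null(loo)) loo <- ncol(mat) <= 6
  gt <- colnames(mat); ids <- rownames(mat)
  n <- ncol(mat)
  rs <- rowSums(mat)
  ref <- if (loo) (rs - mat) / (n - 1) else matrix(rs / n, nrow = nrow(mat),
                                                  ncol = n, dimnames = dimnames(mat))
  ratio <- ifelse(ref > 0, mat / ref, NA_real_)
  state <- matrix(NA_character_, nrow(mat), n, dimnames = dimnames(mat))
  ok <- ref > 0
  state[ok & ratio < thresholds$absent] <- "absent"
  state[ok & is.na(state) & ratio < thresholds$loss] <- "loss"
  state[ok & is.na(state) & ratio > thresholds$gain] <- "gain"
  state[ok & is.na(state)] <- "normal"

  excluded <- !ok
  reason <- matrix("", nrow(mat), n, dimnames = dimnames(mat))
  reason[!ok] <- "no panel coverage"
  if (!is.null(het_snp_loci)) {
    for (g in intersect(names(het_snp_loci), gt)) {
      hit <- ids %in% het_snp_loci[[g]]
      excluded[hit, g] <- TRUE
      reason[hit, g] <- "heterozygous SNPs at locus"
    }
  }
  state[excluded] <- NA_character_

  calls <- S4Vectors::DataFrame(
    copy_id = rep(ids, times = n),
    genotype = rep(gt, each = length(ids)),
    coverage = as.vector(mat),
    reference = as.vector(ref),
    ratio = as.vector(ratio),
    state = as.vector(state),
    excluded = as.vector(excluded),
    reason = as.vector(reason)
  )
  new("CnvCallSet", calls = calls, thresholds = thresholds,
      reference = if (loo) "leave-one-out" else "panel-mean")
}

#' Copy_ids with heterozygous calls, per genotype
#'
#' Convenience extractor feeding the heterozygous-locus exclusion of
#' [callCnv()]: for each genotype, the target copies harboring at least
#' one heterozygous variant call.
#'
#' @param variants named list (per genotype) of variant data.frames (as
#'   from [readVcfGenotypes()]).
#' @param targets target \code{GRanges}.
#' @return named list of character vectors of copy_ids.
#' @export
hetSnpLoci <- function(variants, targets) {
  lapply(variants, function(v) {
    v <- v[v$call == "het", , drop = FALSE]
    if (!nrow(v)) return(character())
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    hits <- GenomicRanges::findOverlaps(gr, targets, ignore.strand = TRUE)
    unique(targets$copy_id[S4Vectors::subjectHits(hits)])
  })
}
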