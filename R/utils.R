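#' @importFrom stats setNames rnbinom runif
#' @importFrom utils read.table write.table packageVersion
NULL

# total aligned base count of a track: sum over segments of depth * width
trackBaseCount <- function(track) {
  if (!length(track)) return(0)
  sum(as.numeric(GenomicRanges::width(track)) * as.numeric(track$depth))
}

#' Total genome length from a genome index
#'
#' @param genomeIndex a \code{Seqinfo}.
#' @return numeric, the sum of all sequence lengths in bp.
#' @export
totalGenomeLength <- function(genomeIndex) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genomeIndex)))
}

# sort a track, drop zero-depth segments, merge adjacent equal-depth runs
canonicalizeTrack <- function(track) {
  stopifnot(is(track, "GRanges"), !is.null(track$depth))
  track <- track[track$depth > 0]
  if (!length(track)) return(track)
  track <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(track))
  chr <- as.character(GenomicRanges::seqnames(track))
  s <- GenomicRanges::start(track); e <- GenomicRanges::end(track)
  d <- track$depth
  n <- length(track)
  same <- c(FALSE, chr[-1] == chr[-n] & s[-1] == e[-n] + 1L & d[-1] == d[-n])
  if (!any(same)) return(track)
  first <- which(!same)
  last <- c(first[-1] - 1L, n)
  GenomicRanges::GRanges(
    chr[first],
    IRanges::IRanges(s[first], e[last]),
    depth = d[first],
    seqinfo = GenomeInfoDb::seqinfo(track)
  )
}

harmonizeSeqlevels <- function(gr, genomeIndex) {
  lv <- GenomeInfoDb::seqlevels(genomeIndex)
  miss <- setdiff(GenomeInfoDb::seqlevels(gr), lv)
  if (length(miss))
    stop("sequences not in genome index: ", paste(miss, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- lv
  gr
}

checkRegionsWithin <- function(gr, genomeIndex, what = "region") {
  if (!length(gr)) return(invisible(TRUE))
  sl <- GenomeInfoDb::seqlengths(genomeIndex)
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad <- !(chr %in% names(sl)) | GenomicRanges::end(gr) > sl[chr] |
    GenomicRanges::start(gr) < 1L
  if (any(bad))
    stop(what, " outside genome index: ",
         paste(utils::head(paste0(chr[bad], ":",
           GenomicRanges::start(gr)[bad], "-", GenomicRanges::end(gr)[bad]), 3),
           collapse = ", "))
  invisible(TRUE)
}

# base count of a track restricted to a set of (already reduced) regions
basesOnRegions <- function(track, regions) {
  if (!length(track) || !length(regions)) return(0)
  hits <- GenomicRanges::findOverlaps(track, regions)
  if (!length(hits)) return(0)
  ov <- GenomicRanges::pintersect(track[S4Vectors::queryHits(hits)],
                                  regions[S4Vectors::subjectHits(hits)])
  sum(as.numeric(GenomicRanges::width(ov)) *
        as.numeric(track$depth[S4Vectors::queryHits(hits)]))
}

# width of track segments (depth filtered upstream) intersected with regions
coveredWidthOnRegions <- function(track, regions) {
  if (!length(track) || !length(regions)) return(0)
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(track),
                                 GenomicRanges::reduce(regions),
                                 ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov)))
}

# complement of single-base alleles (cheap path; full sequences go
# through Biostrings::reverseComplement)
compBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# deterministic sub-seed derivation, kept below 2^31
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}
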