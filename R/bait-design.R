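#' Bait tiling parameters
#'
#' Design parameters for 120-mer hybridization-capture baits: bait length,
#' tiling frequency (only 1x, end-to-end placement, is supported), the
#' overlap-avoidance margin used when deciding whether to rescue an
#' uncovered tail with a terminal bait, and whether repeat-masked sequence
#' (lowercase or N) is avoided.
#'
#' @param bait_length bait length in bp (default 120).
#' @param tiling tiling frequency (only 1 supported).
#' @param avoid_overlap maximum overlap, in bp, that a terminal
#'   tail-rescue bait may have with the previously placed bait (default
#'   20); a tail whose rescue would overlap by more is left uncovered.
#' @param mask_avoid avoid masked (lowercase/N) regions (default TRUE).
#' @return validated parameter list.
#' @export
baitParams <- function(bait_length = 120, tiling = 1, avoid_overlap = 20,
                       mask_avoid = TRUE) {
  if (bait_length <= 0) stop("bait_length must be > 0")
  if (tiling != 1) stop("only 1x tiling is supported")
  if (avoid_overlap < 0) stop("avoid_overlap must be >= 0")
  list(bait_length = bait_length, tiling = tiling,
       avoid_overlap = avoid_overlap, mask_avoid = mask_avoid)
}

#' Tile capture baits over a target sequence
#'
#' Places fixed-length baits end-to-end (1x tiling) within each unmasked
#' run of the sequence. Runs shorter than the bait length yield no bait.
#' When a run leaves an uncovered tail, a terminal bait anchored at the
#' run end is added only if its overlap with the previous bait does not
#' exceed \code{avoid_overlap}; otherwise the tail stays uncovered. The
#' synthesized bait strand follows the strand rule of capture design: for
#' plus-strand genes baits are made antisense (reverse complement of the
#' genomic window), for minus-strand genes in sense (the genomic window as
#' given) -- either way the bait is antisense to the gene's mRNA.
#'
#' @param sequence target sequence (character or \code{DNAString});
#'   lowercase letters or \code{N} mark repeat-masked bases.
#' @param params a [baitParams()] list.
#' @param gene_strand \code{"+"} or \code{"-"}: the strand of the gene on
#'   this sequence.
#' @param copy_id label carried into the output.
#' @return data.frame with \code{copy_id}, \code{start} (0-based offset on
#'   the input sequence), \code{sequence} (the synthesized bait) and
#'   \code{strand} (of synthesis, relative to the input).
#' @examples
#' b <- tileBaits(paste(rep("ACGT", 90), collapse = ""))  # 360 bp
#' b$start  # 0 120 240
#' @export
tileBaits <- function(sequence, params = baitParams(), gene_strand = "+",
                      copy_id = "seq") {
  seq_chr <- as.character(sequence)
  L <- params$bait_length
  n <- nchar(seq_chr)
  empty <- data.frame(copy_id = character(), start = integer(),
                      sequence = character(), strand = character())
  if (n == 0) return(empty)
  masked <- if (params$mask_avoid)
    strsplit(seq_chr, "")[[1]] %in% c("a", "c", "g", "t", "n", "N")
  else rep(FALSE, n)
  runs <- rle(!masked)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  starts <- integer()
  for (r in which(runs$values)) {
    rs <- run_start[r]; rl <- runs$lengths[r]
    nb <- rl %/% L
    if (nb == 0) next
    off <- rs + (seq_len(nb) - 1) * L
    tail_len <- rl %% L
    if (tail_len > 0 && (L - tail_len) <= params$avoid_overlap)
      off <- c(off, rs + rl - L)
    starts <- c(starts, off)
  }
  if (!length(starts)) return(empty)
  wins <- toupper(substring(seq_chr, starts, starts + L - 1))
  if (gene_strand == "+") {
    baits <- revComp(wins)
    strand <- "-"
  } else {
    baits <- wins
    strand <- "+"
  }
  data.frame(copy_id = copy_id, start = starts - 1L, sequence = baits,
             strand = strand)
}

#' Tile baits over a set of target sequences
#'
#' @param sequences \code{DNAStringSet} (or named character vector) of
#'   target sequences; names are copy_ids. \code{DNAString} objects cannot
#'   carry soft-masking, so pass characters when lowercase masking
#'   matters.
#' @param strands named character vector of gene strands per copy_id
#'   (default all \code{"+"}).
#' @param params a [baitParams()] list.
#' @return combined data.frame of baits (see [tileBaits()]).
#' @export
tileBaitSet <- function(sequences, strands = NULL, params = baitParams()) {
  seqs <- if (is(sequences, "XStringSet"))
    stats::setNames(as.character(sequences), names(sequences))
  else sequences
  if (is.null(strands))
    strands <- stats::setNames(rep("+", length(seqs)), names(seqs))
  out <- lapply(names(seqs), function(id)
    tileBaits(seqs[[id]], params, gene_strand = strands[[id]], copy_id = id))
  do.call(rbind, out)
}
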