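# Shared fixtures and independent brute-force oracles.
# Everything here is deliberately naive (per-base vectors, O(n^2) scans)
# so it cannot share bugs with the interval arithmetic it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# a small random genome index (per-base expandable)
randomGenomeIndex <- function(n_chr = 2, chr_len = 5000) {
  GenomeInfoDb::Seqinfo(paste0("chr", seq_len(n_chr)),
                        rep(chr_len, n_chr))
}

# random canonical coverage track: disjoint segments, integer depths,
# gaps between segments (implicit zero coverage)
randomTrack <- function(genomeIndex, n_seg = 50, max_depth = 20) {
  rows <- list()
  for (chr in GenomeInfoDb::seqnames(genomeIndex)) {
    len <- GenomeInfoDb::seqlengths(genomeIndex)[[chr]]
    pos <- 1
    while (pos < len - 10 && length(rows) < n_seg) {
      gap <- sample(0:20, 1)
      w <- sample(1:50, 1)
      if (pos + gap + w > len) break
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = pos + gap, end = pos + gap + w - 1,
        depth = sample(1:max_depth, 1))
      pos <- pos + gap + w
    }
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                depth = as.integer(df$depth), seqinfo = genomeIndex)
  polycap:::canonicalizeTrack(gr)
}

# random target regions aligned to nothing in particular
randomTargets <- function(genomeIndex, n = 5, width = 120) {
  chrs <- sample(GenomeInfoDb::seqnames(genomeIndex), n, replace = TRUE)
  starts <- vapply(chrs, function(ch)
    sample(seq_len(GenomeInfoDb::seqlengths(genomeIndex)[[ch]] - width), 1),
    numeric(1))
  GRanges(chrs, IRanges::IRanges(starts, starts + width - 1),
          copy_id = paste0("copy", seq_len(n)),
          gene_id = paste0("gene", seq_len(n)),
          subgenome = "A", functional = TRUE, seqinfo = genomeIndex)
}

# expand a track into one integer depth vector per chromosome
expandTrack <- function(track, genomeIndex) {
  out <- lapply(GenomeInfoDb::seqlengths(genomeIndex), function(len)
    integer(len))
  for (i in seq_along(track)) {
    ch <- as.character(seqnames(track)[i])
    out[[ch]][start(track)[i]:end(track)[i]] <- track$depth[i]
  }
  out
}

# per-base logical mask of a region set
expandRegions <- function(regions, genomeIndex) {
  out <- lapply(GenomeInfoDb::seqlengths(genomeIndex), function(len)
    logical(len))
  for (i in seq_along(regions)) {
    ch <- as.character(seqnames(regions)[i])
    out[[ch]][start(regions)[i]:end(regions)[i]] <- TRUE
  }
  out
}

# brute-force per-base capture metrics
bruteMetrics <- function(track, targets, N, rl, genomeIndex, k = 10) {
  depth <- expandTrack(track, genomeIndex)
  mask <- expandRegions(targets, genomeIndex)
  d <- unlist(depth, use.names = FALSE)
  m <- unlist(mask, use.names = FALSE)
  G <- length(d)
  c(mean_genome_coverage = mean(d),
    mean_target_coverage = mean(d[m]),
    enrichment_factor = mean(d[m]) / mean(d),
    normalized_mean_target_coverage = mean(d[m]) * G / (N * rl),
    fraction_target_covered = 100 * mean(d[m] >= 1),
    fraction_target_ge_k = 100 * mean(d[m] >= k),
    specificity = if (sum(d) > 0) 100 * sum(d[m]) / sum(d) else 0,
    genome_fraction_ge_k = 100 * mean(d >= k))
}

# small simulation configs used across tests (cheap, but same model)
smallSimConfig <- function(seed = 1, ...) {
  args <- list(n_genes = 4, copies_per_subgenome = c(A = 1, C = 1),
               locus_length = 1000, promoter_length = 300, cds_length = 600,
               genome_length = 4e8,
               n_loss = 1, n_gain = 1, n_absent = 1, n_replacement = 0,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}
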