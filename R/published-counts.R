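#' Expand a per-genotype SNP count table into variant records
#'
#' Reconstructs a minimal set of variant records realizing a published
#' class-count table: per genotype, the requested numbers of homozygous
#' and heterozygous SNPs on and off target, laid out over exactly
#' \code{panel_target_sites} distinct on-target positions and
#' \code{panel_total_sites - panel_target_sites} off-target positions
#' (sites are assigned cyclically, so every distinct site is used by at
#' least one genotype). Feeding the result to [summarizeSnps()] recomputes
#' the panel's class percentages and SNP density from first principles
#' rather than transcribing them.
#'
#' @param counts data.frame with columns \code{genotype},
#'   \code{target_hom}, \code{target_het}, \code{total_hom},
#'   \code{total_het} (totals include the target classes).
#' @param panel_total_sites distinct variant sites across the panel.
#' @param panel_target_sites distinct on-target variant sites.
#' @param target_length total target length in bp.
#' @return list with \code{variants} (named list of per-genotype variant
#'   data.frames), \code{targets} (single-interval target \code{GRanges})
#'   and \code{target_length}.
#' @export
expandSnpCounts <- function(counts, panel_total_sites, panel_target_sites,
                            target_length) {
  off_sites <- panel_total_sites - panel_target_sites
  counts$off_hom <- counts$total_hom - counts$target_hom
  counts$off_het <- counts$total_het - counts$target_het
  if (any(counts$off_hom < 0 | counts$off_het < 0))
    stop("totals must include the target classes")
  if (any(counts$target_hom + counts$target_het > panel_target_sites) ||
      any(counts$off_hom + counts$off_het > off_sites))
    stop("a genotype cannot carry more SNPs than there are distinct sites")
  if (sum(counts$target_hom + counts$target_het) < panel_target_sites ||
      sum(counts$off_hom + counts$off_het) < off_sites)
    stop("counts too small to populate every distinct site")
  take <- function(cursor, k, n) {
    if (k == 0) return(list(pos = integer(), cursor = cursor))
    pos <- ((cursor + seq_len(k) - 2) %% n) + 1
    list(pos = pos, cursor = ((cursor + k - 1) %% n) + 1)
  }
  # on-target sites spread over the target interval; off-target on their own
  # contig so the density denominator is untouched
  tpos_all <- if (panel_target_sites > 1)
    round(seq(1, target_length, length.out = panel_target_sites))
  else 1
  cur_t <- 1; cur_o <- 1
  variants <- list()
  for (i in seq_len(nrow(counts))) {
    g <- counts$genotype[i]
    th <- take(cur_t, counts$target_hom[i], panel_target_sites)
    tt <- take(th$cursor, counts$target_het[i], panel_target_sites)
    cur_t <- tt$cursor
    oh <- take(cur_o, counts$off_hom[i], off_sites)
    ot <- take(oh$cursor, counts$off_het[i], off_sites)
    cur_o <- ot$cursor
    variants[[g]] <- data.frame(
      chrom = rep(c("target", "offtarget"),
                  c(length(th$pos) + length(tt$pos),
                    length(oh$pos) + length(ot$pos))),
      pos = c(tpos_all[th$pos], tpos_all[tt$pos], oh$pos, ot$pos),
      ref = "A", alt = "G",
      call = rep(c("hom_alt", "het", "hom_alt", "het"),
                 c(length(th$pos), length(tt$pos),
                   length(oh$pos), length(ot$pos))),
      depth = 30L)
  }
  targets <- GenomicRanges::GRanges("target",
                                    IRanges::IRanges(1, target_length),
                                    copy_id = "target", gene_id = "target",
                                    subgenome = "unk", functional = TRUE)
  list(variants = variants, targets = targets, target_length = target_length)
}

#' Reference SNP count table of the B. napus flowering-time capture panel
#'
#' Loads the packaged per-genotype SNP class counts of the four-morphotype
#' diversity panel (winter oilseed rape, winter fodder rape, spring canola
#' and swede) together with the panel-wide distinct site totals and target
#' size.
#'
#' @return list with \code{counts} (data.frame), \code{panel_total_sites},
#'   \code{panel_target_sites}, \code{target_length}.
#' @export
referenceSnpCounts <- function() {
  path <- system.file("extdata", "bnapus_flowering_snp_counts.tsv",
                      package = "polycap")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  list(counts = tab[, c("genotype", "total_hom", "total_het",
                        "target_hom", "target_het")],
       panel_total_sites = tab$panel_total_sites[1],
       panel_target_sites = tab$panel_target_sites[1],
       target_length = tab$target_length_bp[1])
}

#' Reference copy inventory of the B. napus flowering-time capture panel
#'
#' Loads the packaged per-copy inventory of the 30 analysed flowering-time
#' gene families (the 29-gene panel plus the co-captured CO-like 2). The
#' per-copy rows were constructed to be consistent with the published
#' aggregate counts (124 full-length + 17 partial functional copies, 23
#' non-functional copies, 9 progenitor-expected copies lost, 28 detected
#' copies that are post-polyploidization duplications); gene and
#' chromosome assignments of individual rows are illustrative.
#'
#' @return inventory data.frame (see [readCopyInventory()]).
#' @export
referenceCopyInventory <- function() {
  readCopyInventory(system.file("extdata", "bnapus_flowering_inventory.tsv",
                                package = "polycap"))
}
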