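#' Classify variant zygosity in inbred allopolyploid lines
#'
#' In a fully inbred line (S5 or later), residual true heterozygosity is
#' negligible, so an apparently heterozygous call is interpreted as a
#' hemi-SNP: reads from two divergent homoeologous or paralogous loci
#' collapsing onto one mapping position. Homozygous-alternate calls are
#' locus-specific homozygous SNPs; homozygous-reference and missing calls
#' are not SNPs for the sample.
#'
#' @param call character vector of genotype calls (\code{hom_ref},
#'   \code{het}, \code{hom_alt}, \code{missing}).
#' @param inbred is the sample a fully inbred line? If \code{FALSE}, the
#'   hemi interpretation is withheld and heterozygous calls are labelled
#'   \code{heterozygous_unresolved}.
#' @return character vector with values \code{homozygous}, \code{hemi},
#'   \code{heterozygous_unresolved} or \code{none}.
#' @export
classifyZygosity <- function(call, inbred = TRUE) {
  stopifnot(is.logical(inbred), length(inbred) == 1)
  out <- rep("none", length(call))
  out[call == "hom_alt"] <- "homozygous"
  out[call == "het"] <- if (inbred) "hemi" else "heterozygous_unresolved"
  out
}

#' Classify a coding substitution as synonymous or non-synonymous
#'
#' Translates the affected codon before and after the substitution with
#' the standard nuclear genetic code. The CDS must already be on the
#' coding strand (minus-strand genes reverse-complemented; see
#' [snpEffects()] for the genomic wrapper) and its length divisible by 3;
#' otherwise the consequence is \code{not_applicable} with a reason.
#'
#' @param cds coding sequence (character or \code{DNAString}), coding
#'   strand, length divisible by 3, no ambiguity codes.
#' @param cds_pos 1-based position of the substitution within the CDS.
#' @param ref,alt reference and alternate base on the coding strand.
#' @return one-row data.frame with \code{consequence} (\code{synonymous},
#'   \code{non_synonymous} or \code{not_applicable}), \code{ref_aa},
#'   \code{alt_aa}, \code{codon_index}, \code{codon_position} and
#'   \code{reason}.
#' @examples
#' classifyEffect("GGACCC", 3, "A", "G")  # GGA -> GGG, Gly/Gly: synonymous
#' @export
classifyEffect <- function(cds, cds_pos, ref, alt) {
  cds <- toupper(as.character(cds))
  na_row <- function(reason) data.frame(
    consequence = "not_applicable", ref_aa = NA_character_,
    alt_aa = NA_character_, codon_index = NA_integer_,
    codon_position = NA_integer_, reason = reason)
  if (grepl("[^ACGT]", cds)) stop("CDS contains ambiguity codes")
  if (nchar(cds) %% 3 != 0)
    return(na_row("CDS length not divisible by 3"))
  if (cds_pos < 1 || cds_pos > nchar(cds))
    return(na_row("position outside CDS"))
  if (substr(cds, cds_pos, cds_pos) != toupper(ref))
    return(na_row("reference allele does not match CDS"))
  codon_idx <- (cds_pos - 1) %/% 3 + 1
  codon_pos <- (cds_pos - 1) %% 3 + 1
  from <- (codon_idx - 1) * 3 + 1
  codon <- substr(cds, from, from + 2)
  alt_codon <- codon
  substr(alt_codon, codon_pos, codon_pos) <- toupper(alt)
  code <- Biostrings::GENETIC_CODE
  data.frame(
    consequence = if (code[[codon]] == code[[alt_codon]]) "synonymous"
                  else "non_synonymous",
    ref_aa = code[[codon]], alt_aa = code[[alt_codon]],
    codon_index = codon_idx, codon_position = codon_pos,
    reason = "")
}

#' Annotate variants with location and coding consequence
#'
#' Assigns each variant a location (\code{exon} when it falls in a CDS
#' feature, \code{promoter}, \code{intron} when inside a target span but
#' outside the CDS, \code{intergenic} otherwise) and, for exonic variants,
#' maps the genomic position onto the CDS coordinate (concatenating CDS
#' parts in transcription order, reverse-complementing minus-strand
#' genes), then classifies the substitution with [classifyEffect()].
#'
#' @param variants data.frame as from [readVcfGenotypes()].
#' @param targets target \code{GRanges} (gene spans, with \code{copy_id}).
#' @param cdsRanges \code{GRanges} of CDS features; metadata column
#'   \code{copy_id} links them to CDS sequences, strand gives orientation.
#' @param cdsSeqs \code{DNAStringSet} of coding-strand CDS sequences named
#'   by copy_id.
#' @param promoters optional \code{GRanges} of promoter regions (with
#'   \code{copy_id}).
#' @return the variants data.frame with columns \code{copy_id},
#'   \code{location}, \code{cds_pos}, \code{consequence}, \code{ref_aa},
#'   \code{alt_aa}, \code{codon_position}, \code{reason} appended.
#' @export
snpEffects <- function(variants, targets, cdsRanges, cdsSeqs,
                       promoters = NULL) {
  n <- nrow(variants)
  out <- cbind(variants,
               data.frame(copy_id = NA_character_, location = "intergenic",
                          cds_pos = NA_integer_,
                          consequence = "not_applicable",
                          ref_aa = NA_character_, alt_aa = NA_character_,
                          codon_position = NA_integer_, reason = "",
                          stringsAsFactors = FALSE))
  if (!n) return(out)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  hit_t <- suppressWarnings(
    GenomicRanges::findOverlaps(vgr, targets, ignore.strand = TRUE, select = "first"))
  in_target <- !is.na(hit_t)
  out$copy_id[in_target] <- targets$copy_id[hit_t[in_target]]
  out$location[in_target] <- "intron"
  if (!is.null(promoters)) {
    hit_p <- suppressWarnings(
      GenomicRanges::findOverlaps(vgr, promoters, ignore.strand = TRUE,
                                  select = "first"))
    out$location[!is.na(hit_p)] <- "promoter"
    idx <- !is.na(hit_p) & is.na(out$copy_id)
    out$copy_id[idx] <- promoters$copy_id[hit_p[idx]]
  }
  hit_c <- suppressWarnings(
    GenomicRanges::findOverlaps(vgr, cdsRanges, ignore.strand = TRUE,
                                select = "first"))
  for (i in which(!is.na(hit_c))) {
    feat <- cdsRanges[hit_c[i]]
    cid <- feat$copy_id
    out$location[i] <- "exon"
    out$copy_id[i] <- cid
    parts <- cdsRanges[cdsRanges$copy_id == cid]
    minus <- as.character(GenomicRanges::strand(feat)) == "-"
    parts <- parts[order(GenomicRanges::start(parts), decreasing = minus)]
    w <- GenomicRanges::width(parts)
    j <- which(GenomicRanges::start(parts) <= variants$pos[i] &
                 GenomicRanges::end(parts) >= variants$pos[i])[1]
    before <- if (j > 1) sum(w[seq_len(j - 1)]) else 0
    offset <- if (minus) GenomicRanges::end(parts)[j] - variants$pos[i]
              else variants$pos[i] - GenomicRanges::start(parts)[j]
    cds_pos <- before + offset + 1
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (minus) {
      ref <- compBase(ref); alt <- compBase(alt)
    }
    if (is.null(cdsSeqs[[cid]])) next
    eff <- classifyEffect(cdsSeqs[[cid]], cds_pos, ref, alt)
    out$cds_pos[i] <- cds_pos
    out$consequence[i] <- eff$consequence
    out$ref_aa[i] <- eff$ref_aa
    out$alt_aa[i] <- eff$alt_aa
    out$codon_position[i] <- eff$codon_position
    out$reason[i] <- eff$reason
  }
  out
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Summarize SNP counts per genotype, with panel-wide percentages
#'
#' Tabulates, per genotype, total and on-target SNPs split into homozygous
#' and heterozygous (hemi) classes. A record counts as a SNP for a
#' genotype when its call is \code{hom_alt} or \code{het}. Percentages use
#' the panel-wide denominators: the number of distinct variant sites
#' across all genotypes (total) and the number of distinct on-target sites
#' (target), the convention under which per-genotype class percentages of
#' a diversity panel are reported. SNP density is target length divided by
#' the panel-wide target site count, rounded to the nearest bp.
#'
#' @param variants named list (per genotype) of variant data.frames,
#'   pre-filtered at the depth threshold.
#' @param targets target \code{GRanges}.
#' @param target_length total target length in bp; defaults to the reduced
#'   width of \code{targets}.
#' @param per_genotype_pct if \code{TRUE}, percentages use each genotype's
#'   own site counts as denominators instead of the panel-wide totals.
#' @return list with \code{per_genotype} (data.frame of counts and
#'   percentages), \code{panel} (distinct site totals and
#'   \code{density_bp_per_snp}).
#' @export
summarizeSnps <- function(variants, targets, target_length = NULL,
                          per_genotype_pct = FALSE) {
  if (is.null(target_length))
    target_length <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::reduce(targets, ignore.strand = TRUE))))
  is_snp <- function(v) v$call %in% c("hom_alt", "het")
  on_target <- function(v) {
    if (!nrow(v)) return(logical(0))
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    suppressWarnings(IRanges::overlapsAny(gr, targets, ignore.strand = TRUE))
  }
  sites_all <- character(); sites_target <- character()
  rows <- lapply(names(variants), function(g) {
    v <- variants[[g]]
    keep <- is_snp(v)
    v <- v[keep, , drop = FALSE]
    tg <- on_target(v)
    key <- paste(v$chrom, v$pos)
    sites_all <<- union(sites_all, key)
    sites_target <<- union(sites_target, key[tg])
    data.frame(genotype = g,
               total = nrow(v),
               total_hom = sum(v$call == "hom_alt"),
               total_het = sum(v$call == "het"),
               target = sum(tg),
               target_hom = sum(tg & v$call == "hom_alt"),
               target_het = sum(tg & v$call == "het"))
  })
  per <- do.call(rbind, rows)
  n_total <- length(sites_all)
  n_target <- length(sites_target)
  den_total <- if (per_genotype_pct) per$total else n_total
  den_target <- if (per_genotype_pct) per$target else n_target
  pct <- function(x, d) {
    d <- rep(d, length.out = length(x))
    out <- round(100 * x / d, 2)
    out[d <= 0] <- NA_real_
    out
  }
  per$total_hom_pct <- pct(per$total_hom, den_total)
  per$total_het_pct <- pct(per$total_het, den_total)
  per$target_hom_pct <- pct(per$target_hom, den_target)
  per$target_het_pct <- pct(per$target_het, den_target)
  list(per_genotype = per,
       panel = data.frame(
         total_sites = n_total,
         target_sites = n_target,
         target_length = target_length,
         density_bp_per_snp = if (n_target > 0)
           round(target_length / n_target) else NA_real_))
}
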