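#' Read a genome index (name, length) TSV
#'
#' The genome index supplies the total genome length G used as the
#' numerator of the coverage normalization, so chromosomes without any
#' aligned read still count. Two whitespace-delimited columns: sequence
#' name and length in bp (the layout of a \code{samtools faidx} index
#' restricted to its first two columns).
#'
#' @param path path to the index file.
#' @return a \code{Seqinfo}.
#' @export
readGenomeIndex <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$name)) stop("duplicated sequence names in genome index")
  if (any(!is.finite(tab$length)) || any(tab$length <= 0))
    stop("sequence lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = tab$name, seqlengths = as.integer(tab$length))
}

#' @rdname readGenomeIndex
#' @param genomeIndex a \code{Seqinfo}.
#' @export
writeGenomeIndex <- function(genomeIndex, path) {
  tab <- data.frame(name = GenomeInfoDb::seqnames(genomeIndex),
                    length = GenomeInfoDb::seqlengths(genomeIndex))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Parses a per-base depth track as written by a genome-coverage tool with
#' per-segment (\code{-bg}) output: whitespace-delimited
#' \code{chrom start end depth}, 0-based half-open. The result is
#' canonicalized: converted to the 1-based closed convention of
#' \code{GRanges} (all coordinate conversion happens inside this module),
#' sorted, zero-depth segments dropped (uncovered bases are implicitly
#' depth 0) and adjacent or overlapping segments of equal depth merged.
#' Overlapping segments with differing depth are contradictory and
#' rejected.
#'
#' @param path path to the bedGraph file.
#' @return a coverage \code{GRanges} with an integer \code{depth} column.
#' @seealso [writeBedGraph()] for the inverse; the two round-trip
#'   byte-identically on canonical files.
#' @export
readBedGraph <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("chrom", "start", "end", "depth"),
                      colClasses = c("character", "numeric", "numeric", "numeric"),
                      comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), depth = numeric()))
      stop("malformed bedGraph '", path, "': ", conditionMessage(e))
    })
  if (!nrow(tab))
    return(GenomicRanges::GRanges(depth = integer()))
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) | !is.finite(tab$depth) |
                 tab$start < 0 | tab$end <= tab$start |
                 tab$depth < 0 | tab$depth != round(tab$depth))
  if (length(bad))
    stop("malformed bedGraph line ", bad[1], " in '", path,
         "': need 0 <= start < end and integer depth >= 0")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1, tab$end),
                               depth = as.integer(tab$depth))
  # normalize: merge overlapping/adjacent segments of equal depth, then
  # reject any remaining (contradictory) overlap between unequal depths
  merged <- unlist(GenomicRanges::GRangesList(lapply(
    split(gr, gr$depth), function(g) {
      red <- GenomicRanges::reduce(g)
      red$depth <- g$depth[1]
      red
    })), use.names = FALSE)
  if (!GenomicRanges::isDisjoint(merged)) {
    hits <- GenomicRanges::findOverlaps(merged, drop.self = TRUE,
                                        drop.redundant = TRUE)
    i <- S4Vectors::queryHits(hits)[1]; j <- S4Vectors::subjectHits(hits)[1]
    stop("overlapping segments with differing depth in '", path, "' near ",
         GenomicRanges::seqnames(merged)[i], ":",
         GenomicRanges::start(merged)[i] - 1, "-",
         GenomicRanges::end(merged)[j])
  }
  canonicalizeTrack(merged)
}

#' Write a coverage track as bedGraph
#'
#' Canonical form: tab-delimited \code{chrom start end depth}, 0-based
#' half-open, sorted, zero-depth segments omitted, no header.
#'
#' @param track a coverage \code{GRanges} with a \code{depth} column.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  track <- canonicalizeTrack(track)
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                    start = GenomicRanges::start(track) - 1,
                    end = GenomicRanges::end(track),
                    depth = track$depth)
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read target regions from a BED6+3 file
#'
#' Columns: chrom, start (0-based), end, copy_id (BED name), score
#' (ignored), strand, gene_id, subgenome (A/C/unk), functional (0/1).
#' One captured gene-copy interval per line; a copy_id may span several
#' non-overlapping lines.
#'
#' @param path path to the BED file.
#' @return a \code{GRanges} with \code{gene_id}, \code{copy_id},
#'   \code{subgenome} and \code{functional} metadata columns.
#' @export
readTargetBed <- function(path) {
  cols <- c("chrom", "start", "end", "copy_id", "score", "strand",
            "gene_id", "subgenome", "functional")
  tab <- utils::read.table(path, header = FALSE, col.names = cols,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "character",
                                          "character", "character", "numeric"))
  if (any(tab$end <= tab$start))
    stop("malformed BED line ", which(tab$end <= tab$start)[1],
         ": start must be < end")
  if (!all(tab$subgenome %in% c("A", "C", "unk")))
    stop("subgenome must be one of A, C, unk")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1, tab$end),
                               strand = tab$strand,
                               copy_id = tab$copy_id,
                               gene_id = tab$gene_id,
                               subgenome = tab$subgenome,
                               functional = tab$functional != 0)
  # regions may not overlap within one copy_id
  for (cid in unique(gr$copy_id)) {
    sub <- gr[gr$copy_id == cid]
    if (length(sub) > 1 && !GenomicRanges::isDisjoint(sub, ignore.strand = TRUE))
      stop("overlapping regions within copy_id '", cid, "'")
  }
  gr
}

#' @rdname readTargetBed
#' @param targets a target \code{GRanges} as returned by [readTargetBed()].
#' @export
writeTargetBed <- function(targets, path) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(targets)),
                    start = GenomicRanges::start(targets) - 1,
                    end = GenomicRanges::end(targets),
                    copy_id = targets$copy_id,
                    score = 0,
                    strand = as.character(GenomicRanges::strand(targets)),
                    gene_id = targets$gene_id,
                    subgenome = targets$subgenome,
                    functional = as.integer(targets$functional))
  tab$strand[tab$strand == "*"] <- "+"
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-genotype variant calls from a VCF
#'
#' Reads a single-sample VCF 4.x (plain or gzip) and returns one row per
#' (position, alternate allele). Multi-allelic records are split, each
#' alternate classified independently, with the record depth retained.
#' Records below the minimum read depth are excluded (the conventional
#' depth filter for capture data is 10). Records without a genotype (GT)
#' field are skipped with a warning giving the count.
#'
#' @param path path to the VCF.
#' @param min_depth minimum DP to retain a record (default 10); records with
#'   \code{DP < min_depth} are dropped. With \code{min_depth > 0} a missing
#'   DP field is a validation error.
#' @return \code{data.frame} with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{call} (one of \code{hom_ref}, \code{het},
#'   \code{hom_alt}, \code{missing}) and \code{depth}.
#' @export
readVcfGenotypes <- function(path, min_depth = 10) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), call = character(), depth = integer()))
  first_col <- function(x, default) {
    if (is.null(x)) return(rep(default, nrow(fix)))
    if (is.null(dim(x))) x else x[, 1]
  }
  gt <- first_col(tryCatch(vcfR::extract.gt(v, element = "GT"),
                           error = function(e) NULL), NA_character_)
  dp <- first_col(tryCatch(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE),
                           error = function(e) NULL), NA_real_)
  if (min_depth > 0 && any(is.na(dp)))
    stop("records without DP cannot be depth-filtered (min_depth = ",
         min_depth, ")")
  no_gt <- is.na(gt)
  if (any(no_gt))
    warning(sum(no_gt), " record(s) without GT skipped")
  keep <- !no_gt & (is.na(dp) | dp >= min_depth)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep]; dp <- dp[keep]
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    al <- strsplit(gt[i], "[/|]")[[1]]
    calls <- vapply(seq_along(alts), function(j) {
      if (any(al == ".")) return("missing")
      hits <- sum(al == as.character(j))
      if (hits == 0) "hom_ref" else if (hits == length(al)) "hom_alt" else "het"
    }, character(1))
    if (any(alts == fix$REF[i]))
      stop("REF equals ALT at ", fix$CHROM[i], ":", fix$POS[i])
    out[[i]] <- data.frame(chrom = fix$CHROM[i],
                           pos = as.integer(fix$POS[i]),
                           ref = fix$REF[i], alt = alts,
                           call = calls, depth = as.integer(dp[i]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a minimal single-sample VCF 4.2
#'
#' Emits the variant table of a simulated genotype (or any data.frame in
#' the [readVcfGenotypes()] layout) as a plain-text VCF with GT:DP fields.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{call}, \code{depth}.
#' @param path output path.
#' @param sample sample name for the header.
#' @param genomeIndex optional \code{Seqinfo}; if given, contig header
#'   lines are written.
#' @export
writeSimpleVcf <- function(variants, path, sample = "sample",
                           genomeIndex = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=polycap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  if (!is.null(genomeIndex)) {
    sl <- GenomeInfoDb::seqlengths(genomeIndex)
    writeLines(sprintf("##contig=<ID=%s,length=%s>", names(sl),
                       format(sl, scientific = FALSE, trim = TRUE)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample), collapse = "\t"), con)
  if (nrow(variants)) {
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    gtcode <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")[v$call]
    writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                     "GT:DP", paste0(gtcode, ":", v$depth), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a copy inventory TSV
#'
#' A copy inventory book-keeps, per gene copy, whether the copy was
#' detected by the capture (\code{full_length}, \code{partial} or
#' \code{not_detected}), whether it is functional, whether it was expected
#' from the progenitor genomes, and how many copies the reference genotype
#' carries at the locus.
#'
#' @param path TSV with header columns \code{copy_id}, \code{gene_id},
#'   \code{subgenome}, \code{detected}, \code{functional},
#'   \code{expected_in_progenitor} and optionally \code{ref_copies}
#'   (default 1).
#' @return a validated \code{data.frame}.
#' @export
readCopyInventory <- function(path) {
  inv <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("copy_id", "gene_id", "subgenome", "detected", "functional",
            "expected_in_progenitor")
  if (!all(need %in% names(inv)))
    stop("inventory needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(inv$copy_id)) stop("copy_id must be unique")
  if (!all(inv$detected %in% c("full_length", "partial", "not_detected")))
    stop("detected must be full_length, partial or not_detected")
  inv$functional <- as.logical(inv$functional)
  inv$expected_in_progenitor <- as.logical(inv$expected_in_progenitor)
  if (any(inv$detected == "not_detected" & !is.na(inv$functional)))
    stop("functional must be unset (NA) for undetected copies")
  if (is.null(inv$ref_copies)) inv$ref_copies <- 1L
  inv
}
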