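test_that("zygosity classification follows the inbred-line interpretation", {
  calls <- c("hom_alt", "het", "hom_ref", "missing")
  expect_equal(classifyZygosity(calls, inbred = TRUE),
               c("homozygous", "hemi", "none", "none"))
  expect_equal(classifyZygosity(calls, inbred = FALSE),
               c("homozygous", "heterozygous_unresolved", "none", "none"))
})

test_that("classifyEffect translates the affected codon on the coding strand", {
  # third-position wobble: GGA -> GGG stays glycine
  eff <- classifyEffect("GGACCC", 3, "A", "G")
  expect_equal(eff$consequence, "synonymous")
  expect_equal(eff$ref_aa, "G")
  expect_equal(eff$codon_position, 3L)
  # first-position change: GGA -> CGA is Gly -> Arg
  eff2 <- classifyEffect("GGACCC", 1, "G", "C")
  expect_equal(eff2$consequence, "non_synonymous")
  expect_equal(c(eff2$ref_aa, eff2$alt_aa), c("G", "R"))
  # degenerate inputs
  expect_equal(classifyEffect("GGAC", 2, "G", "C")$reason,
               "CDS length not divisible by 3")
  expect_equal(classifyEffect("GGACCC", 2, "T", "C")$reason,
               "reference allele does not match CDS")
  expect_error(classifyEffect("GGN", 1, "G", "C"), "ambiguity")
})

test_that("all 576 single-base codon substitutions match an independent translation oracle", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  n_checked <- 0
  for (codon in codons) {
    for (p in 1:3) {
      ref <- substr(codon, p, p)
      for (alt in setdiff(bases, ref)) {
        eff <- classifyEffect(codon, p, ref, alt)
        alt_codon <- codon
        substr(alt_codon, p, p) <- alt
        aa_ref <- seqinr::translate(strsplit(tolower(codon), "")[[1]])
        aa_alt <- seqinr::translate(strsplit(tolower(alt_codon), "")[[1]])
        expect_equal(eff$consequence,
                     if (aa_ref == aa_alt) "synonymous" else "non_synonymous",
                     info = paste(codon, p, alt))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576L)
})

test_that("snpEffects maps genomic positions through multi-exon CDS on both strands", {
  gi <- GenomeInfoDb::Seqinfo("A01", 10000L)
  # plus-strand gene: two CDS exons 101-160 and 301-360 (120 bp CDS)
  # minus-strand gene: two CDS exons 1101-1160 and 1301-1360
  tgt <- GRanges("A01", IRanges::IRanges(c(51, 1051), c(500, 1500)),
                 strand = c("+", "-"), copy_id = c("p", "m"),
                 gene_id = c("p", "m"), subgenome = "A", functional = TRUE,
                 seqinfo = gi)
  cds_r <- GRanges("A01",
                   IRanges::IRanges(c(101, 301, 1101, 1301),
                                    c(160, 360, 1160, 1360)),
                   strand = c("+", "+", "-", "-"),
                   copy_id = c("p", "p", "m", "m"), seqinfo = gi)
  set.seed(99)
  plus_cds <- paste(sample(c("A","C","G","T"), 120, replace = TRUE),
                    collapse = "")
  minus_cds <- paste(sample(c("A","C","G","T"), 120, replace = TRUE),
                     collapse = "")
  cds_seqs <- Biostrings::DNAStringSet(c(p = plus_cds, m = minus_cds))

  # variant in the second plus exon: genomic 310 -> CDS 60 + 10 = 70
  ref_p <- substr(plus_cds, 70, 70)
  alt_p <- setdiff(c("A","C","G","T"), ref_p)[1]
  # variant in the upstream minus exon: genomic 1310.
  # transcription order is 1301-1360 first... reading from the high end:
  # CDS position = 60 (first exon read 1360->1301) gives genomic 1301+?:
  # genomic 1310 lies in exon 1301-1360, offset end-1310 = 50 -> cds 51...
  # wait: for minus strand the first transcribed exon is the rightmost.
  cds_pos_m <- 60 + (1160 - 1110) + 1   # variant at genomic 1110, exon 1101-1160
  ref_m_coding <- substr(minus_cds, cds_pos_m, cds_pos_m)
  ref_m <- polycap:::compBase(ref_m_coding)
  alt_m <- setdiff(c("A","C","G","T"), ref_m)[1]

  vars <- data.frame(chrom = "A01", pos = c(310L, 1110L, 50L, 200L),
                     ref = c(ref_p, ref_m, "A", "A"),
                     alt = c(alt_p, alt_m, "G", "G"),
                     call = "hom_alt", depth = 30L)
  ann <- snpEffects(vars, tgt, cds_r, cds_seqs)
  expect_equal(ann$location, c("exon", "exon", "intergenic", "intron"))
  expect_equal(ann$cds_pos[1], 70)
  expect_equal(ann$cds_pos[2], cds_pos_m)
  # consequences equal direct codon translation on the coding strand
  chk <- classifyEffect(plus_cds, 70, ref_p, alt_p)
  expect_equal(ann$consequence[1], chk$consequence)
  chk_m <- classifyEffect(minus_cds, cds_pos_m, ref_m_coding,
                          polycap:::compBase(alt_m))
  expect_equal(ann$consequence[2], chk_m$consequence)
  expect_equal(ann$consequence[3:4], c("not_applicable", "not_applicable"))
})

test_that("a minus-strand genomic substitution is classified on the coding strand", {
  # CDS "ATGGGA" on the minus strand of genomic 101-106
  # genomic plus sequence is its reverse complement: TCCCAT
  gi <- GenomeInfoDb::Seqinfo("C01", 1000L)
  tgt <- GRanges("C01", IRanges::IRanges(81, 126), strand = "-",
                 copy_id = "m1", gene_id = "m1", subgenome = "C",
                 functional = TRUE, seqinfo = gi)
  cds_r <- GRanges("C01", IRanges::IRanges(101, 106), strand = "-",
                   copy_id = "m1", seqinfo = gi)
  cds_seqs <- Biostrings::DNAStringSet(c(m1 = "ATGGGA"))
  # genomic C -> T at position 102 complements coding G -> A at cds_pos 5:
  # GGA -> GAA, Gly -> Glu (non-synonymous)
  vars <- data.frame(chrom = "C01", pos = 102L, ref = "C", alt = "T",
                     call = "hom_alt", depth = 20L)
  ann <- snpEffects(vars, tgt, cds_r, cds_seqs)
  expect_equal(ann$cds_pos, 5)
  expect_equal(ann$consequence, "non_synonymous")
  expect_equal(c(ann$ref_aa, ann$alt_aa), c("G", "E"))
})

test_that("simulated private and cross-locus SNPs classify as the truth table says", {
  sim <- simulateExperiment(smallSimConfig(seed = 21, n_genes = 6,
                                           cross_locus_rate = 0.004,
                                           events = list(gt3 = c(gene02.C02_1 = 0))))
  snps <- truthTable(sim)$snps
  for (g in genotypes(sim)) {
    v <- sim@variants[[g]]
    z <- classifyZygosity(v$call, inbred = TRUE)
    tg <- snps[snps$genotype == g, ]
    tg <- tg[order(tg$chrom, tg$pos, tg$alt), ]
    v_ord <- order(v$chrom, v$pos, v$alt)
    expect_equal(z[v_ord], tg$zygosity)
  }
  # shared divergent sites are hemi, private sites homozygous
  expect_true(all(snps$zygosity[snps$origin == "private"] == "homozygous"))
  both_present <- snps$origin == "cross_locus" &
    !(snps$genotype == "gt3" & grepl("^gene02", snps$copy_id))
  expect_true(all(snps$zygosity[both_present] == "hemi"))
  lost_partner <- snps$genotype == "gt3" & grepl("^gene02", snps$copy_id)
  if (any(lost_partner))
    expect_true(all(snps$zygosity[lost_partner] == "homozygous"))
})

test_that("simulated exonic SNP consequences match the annotation pipeline", {
  sim <- simulateExperiment(smallSimConfig(seed = 22, cross_locus_rate = 0))
  snps <- truthTable(sim)$snps
  for (g in genotypes(sim)) {
    ann <- snpEffects(sim@variants[[g]], targets(panel(sim)),
                      sim@cdsRanges, sim@cds)
    tg <- snps[snps$genotype == g, ]
    key <- paste(tg$chrom, tg$pos, tg$alt)
    m <- match(paste(ann$chrom, ann$pos, ann$alt), key)
    expect_false(anyNA(m))
    exonic <- ann$location == "exon"
    expect_equal(ann$consequence[exonic], tg$consequence[m][exonic])
    # synonymous + non_synonymous account for every classified exonic SNP
    expect_true(all(ann$consequence[exonic] %in%
                      c("synonymous", "non_synonymous")))
    expect_true(all(ann$consequence[!exonic] == "not_applicable"))
  }
})

test_that("summarizeSnps counts classes and uses panel-wide denominators", {
  gi <- randomGenomeIndex(1, 100000)
  tgt <- GRanges("chr1", IRanges::IRanges(1, 5000), copy_id = "c",
                 gene_id = "g", subgenome = "A", functional = TRUE,
                 seqinfo = gi)
  mk <- function(pos, call) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                       alt = "G", call = call, depth = 30L)
  vars <- list(
    g1 = rbind(mk(c(10, 20), "hom_alt"), mk(30, "het"), mk(8000, "hom_alt"),
               mk(40, "hom_ref")),
    g2 = rbind(mk(c(10, 50), "het"), mk(9000, "hom_alt")))
  sm <- summarizeSnps(vars, tgt)
  per <- sm$per_genotype
  # hom_ref rows are not SNPs
  expect_equal(per$total, c(4, 3))
  expect_equal(per$target, c(3, 2))
  expect_equal(per$target_hom, c(2, 0))
  expect_equal(per$target_het, c(1, 2))
  # distinct sites: target {10,20,30,50} = 4, off {8000,9000} = 2
  expect_equal(sm$panel$target_sites, 4)
  expect_equal(sm$panel$total_sites, 6)
  expect_equal(per$target_hom_pct, round(100 * c(2, 0) / 4, 2))
  expect_equal(per$total_hom_pct, round(100 * c(3, 1) / 6, 2))
  expect_equal(sm$panel$density_bp_per_snp, round(5000 / 4))
  # per-genotype denominators on request
  sm2 <- summarizeSnps(vars, tgt, per_genotype_pct = TRUE)
  expect_equal(sm2$per_genotype$target_hom_pct, round(100 * c(2/3, 0/2), 2))
  # empty record set
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      call = character(0), depth = integer(0))
  sm0 <- summarizeSnps(list(g1 = empty), tgt)
  expect_equal(sm0$per_genotype$total, 0)
  expect_true(is.na(sm0$panel$density_bp_per_snp))
})
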