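#' Configuration for a simulated allopolyploid capture experiment
#'
#' Defines the generative model: a panel of fully inbred genotypes
#' captured over a multi-gene, multi-copy target set with A and C
#' subgenome homoeologs. On-target expected depth at a locus with copy
#' multiplier m is \code{m * enrichment * background_mean}; off-target
#' depth is \code{background_mean}. Depth noise is negative binomial per
#' constant-depth bin (capture depth is substantially overdispersed
#' relative to Poisson). Cross-locus divergent sites between co-captured
#' homoeolog pairs surface as heterozygous hemi-SNP calls in genotypes
#' carrying both partners and as homozygous calls where one partner is
#' missing; locus-specific SNPs are homozygous.
#'
#' @param n_genes number of genes (default 25).
#' @param copies_per_subgenome named integer (default \code{c(A = 2, C = 2)}):
#'   gene copies per subgenome, so the default target set has
#'   \code{25 * 4 = 100} loci.
#' @param locus_length captured span per copy in bp (default 2000; must be
#'   a multiple of \code{target_bin}).
#' @param promoter_length promoter length at the locus 5' end (default 600).
#' @param cds_length CDS length, divisible by 3 (default 900); the CDS
#'   starts right after the promoter.
#' @param inter_homoeolog_identity sequence identity between A/C homoeolog
#'   pairs (default 0.97).
#' @param genome_length total genome length G in bp (default 4e9, spread
#'   over 10 chromosomes). Chosen large so the target is a negligible
#'   genome fraction and the enrichment factor measured against the
#'   genome-wide mean matches the configured on/off depth ratio.
#' @param read_length read length in bp (default 100, single-end).
#' @param aligned_reads aligned reads N per genotype; \code{NULL} (default)
#'   derives N from each simulated track as total aligned bases / rl.
#' @param enrichment on-target/off-target expected depth ratio E
#'   (default 760).
#' @param background_mean,background_dispersion negative-binomial mean and
#'   dispersion of off-target depth per bin (defaults 0.5 and 0.1).
#' @param background_bin,target_bin bin widths (bp) at which depth noise is
#'   drawn off-target (50000) and on-target (50).
#' @param events \code{"random"} (default: \code{n_loss}, \code{n_gain},
#'   \code{n_absent} and \code{n_replacement} events at distinct random
#'   loci and genotypes) or a named list mapping genotype to a named
#'   vector of copy multipliers in \{0, 0.5, 1, 1.5, 2\}.
#' @param n_loss,n_gain,n_absent,n_replacement event counts for random
#'   event assignment (defaults 5, 5, 2, 1). A replacement event
#'   (homoeologous exchange) sets one copy of a pair to 0 and its partner
#'   to 2 in the same genotype.
#' @param snp_rate per-bp rate of locus-specific homozygous SNPs per
#'   genotype (default 0.002).
#' @param cross_locus_rate per-bp rate at which homoeolog divergence
#'   surfaces as hemi-SNPs (default 0.001; must not exceed
#'   \code{1 - inter_homoeolog_identity}).
#' @param depth_bleed fraction of a missing partner's depth that bleeds
#'   into a multiplier-0 locus through ambiguous mapping (default 0).
#' @param genotypes genotype names (default \code{gt1..gt4}).
#' @param inbred logical, are the lines fully inbred (default TRUE).
#' @param seed integer random seed (default 1).
#' @return validated configuration list of class \code{polycap_sim_config}.
#' @export
simulationConfig <- function(n_genes = 25,
                             copies_per_subgenome = c(A = 2, C = 2),
                             locus_length = 2000,
                             promoter_length = 600,
                             cds_length = 900,
                             inter_homoeolog_identity = 0.97,
                             genome_length = 4e9,
                             read_length = 100,
                             aligned_reads = NULL,
                             enrichment = 760,
                             background_mean = 0.5,
                             background_dispersion = 0.1,
                             background_bin = 50000,
                             target_bin = 50,
                             events = "random",
                             n_loss = 5, n_gain = 5, n_absent = 2,
                             n_replacement = 1,
                             snp_rate = 0.002,
                             cross_locus_rate = 0.001,
                             depth_bleed = 0,
                             genotypes = paste0("gt", 1:4),
                             inbred = TRUE,
                             seed = 1) {
  cfg <- as.list(environment())
  # YAML configs hand numbers like "4.0e8" over as strings; coerce them
  num_fields <- c("n_genes", "locus_length", "promoter_length", "cds_length",
                  "inter_homoeolog_identity", "genome_length", "read_length",
                  "aligned_reads", "enrichment", "background_mean",
                  "background_dispersion", "background_bin", "target_bin",
                  "n_loss", "n_gain", "n_absent", "n_replacement", "snp_rate",
                  "cross_locus_rate", "depth_bleed", "seed")
  for (f in num_fields)
    if (is.character(cfg[[f]])) cfg[[f]] <- as.numeric(cfg[[f]])
  if (!(cfg$inter_homoeolog_identity > 0 && cfg$inter_homoeolog_identity <= 1))
    stop("inter_homoeolog_identity must be in (0, 1]")
  if (cfg$cross_locus_rate > 1 - cfg$inter_homoeolog_identity + 1e-12)
    stop("cross_locus_rate cannot exceed homoeolog divergence (1 - identity)")
  if (cfg$snp_rate < 0 || cfg$cross_locus_rate < 0 || cfg$depth_bleed < 0)
    stop("rates must be >= 0")
  if (cfg$cds_length %% 3 != 0) stop("cds_length must be divisible by 3")
  if (cfg$locus_length %% cfg$target_bin != 0)
    stop("locus_length must be a multiple of target_bin")
  if (cfg$promoter_length + cfg$cds_length > cfg$locus_length)
    stop("promoter + CDS exceed the locus length")
  if (is.null(names(cfg$copies_per_subgenome)) ||
      !all(names(cfg$copies_per_subgenome) %in% c("A", "C")))
    stop("copies_per_subgenome must be named with A and/or C")
  n_loci <- cfg$n_genes * sum(cfg$copies_per_subgenome)
  if (cfg$genome_length <= n_loci * cfg$locus_length)
    stop("genome_length must exceed the total target length")
  if (is.list(cfg$events)) {
    mults <- unlist(cfg$events)
    if (length(mults) && !all(mults %in% c(0, 0.5, 1, 1.5, 2)))
      stop("event multipliers must be in {0, 0.5, 1, 1.5, 2}")
  } else if (!identical(cfg$events, "random")) {
    stop("events must be \"random\" or a named list per genotype")
  }
  if (length(cfg$genotypes) < 2) stop("need at least 2 genotypes")
  class(cfg) <- "polycap_sim_config"
  cfg
}

# deterministic layout of chromosomes, loci and homoeolog pairs
simLayout <- function(cfg) {
  n_chr <- 5L
  chroms <- c(sprintf("A%02d", 1:n_chr), sprintf("C%02d", 1:n_chr))
  chr_len <- floor(cfg$genome_length / length(chroms))
  stopifnot(chr_len < 2^31)
  gi <- GenomeInfoDb::Seqinfo(chroms, rep(as.integer(chr_len), length(chroms)))

  rows <- list()
  counter <- stats::setNames(integer(length(chroms)), chroms)
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("gene%02d", g)
    for (sg in names(cfg$copies_per_subgenome)) {
      for (k in seq_len(cfg$copies_per_subgenome[[sg]])) {
        chrom <- sprintf("%s%02d", sg, ((g - 1) %% n_chr) + 1)
        counter[chrom] <- counter[chrom] + 1L
        tile <- counter[chrom]
        start <- (tile - 1) * cfg$background_bin + 1
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, gene_id = gene_id, subgenome = sg, pair = k,
          copy_id = sprintf("%s.%s_%d", gene_id, chrom, k),
          chrom = chrom, start = start,
          end = start + cfg$locus_length - 1,
          strand = if ((g + k) %% 2 == 0) "+" else "-")
      }
    }
  }
  loci <- do.call(rbind, rows)
  stopifnot(max(loci$end) <= chr_len)
  # homoeolog pairs: A copy k of gene g with C copy k of gene g
  pairs <- NULL
  if (all(c("A", "C") %in% names(cfg$copies_per_subgenome))) {
    kmax <- min(cfg$copies_per_subgenome[["A"]], cfg$copies_per_subgenome[["C"]])
    pairs <- expand.grid(gene = seq_len(cfg$n_genes), pair = seq_len(kmax))
    pairs$a <- loci$copy_id[match(paste(pairs$gene, "A", pairs$pair),
                                  paste(loci$gene, loci$subgenome, loci$pair))]
    pairs$c <- loci$copy_id[match(paste(pairs$gene, "C", pairs$pair),
                                  paste(loci$gene, loci$subgenome, loci$pair))]
  }
  list(genomeIndex = gi, loci = loci, pairs = pairs, chr_len = chr_len,
       chroms = chroms)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateBase <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Inject cross-locus divergent sites into a homoeolog pair
#'
#' Samples divergent positions at the given per-bp rate along a pair of
#' aligned homoeologous copies, mutates the second copy there, and emits
#' the variant calls those sites produce in each genotype: heterozygous
#' (hemi-SNP) calls at both loci when the genotype carries both partners,
#' a homozygous call at the surviving locus when one partner is absent,
#' nothing when both are absent. Rates above 0.5 are allowed but flagged
#' as biologically unrealistic.
#'
#' @param seq_a,seq_b equal-length character sequences of the two copies
#'   (seq_b is mutated at the sampled sites).
#' @param rate per-bp divergence rate.
#' @param multipliers named list: genotype -> numeric length-2 vector of
#'   copy multipliers \code{c(a, b)}.
#' @param seed integer seed.
#' @return list with \code{seq_b} (mutated), \code{sites} (1-based
#'   positions) and \code{variants} (data.frame: genotype, locus
#'   (\code{"a"}/\code{"b"}), pos (1-based within the locus), ref, alt,
#'   call).
#' @export
injectHemiSnps <- function(seq_a, seq_b, rate, multipliers, seed = 1) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  if (rate > 0.5)
    warning("divergence rate > 0.5 is unrealistically low identity")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  L <- nchar(seq_a)
  sites <- which(stats::runif(L) < rate)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(sites)) b[sites] <- mutateBase(a[sites])
  vars <- hemiVariantCalls(a, b, sites, multipliers)
  list(seq_b = paste(b, collapse = ""), sites = sites, variants = vars)
}

# calls produced by divergent sites between a pair, per genotype
hemiVariantCalls <- function(a, b, sites, multipliers) {
  out <- list()
  for (g in names(multipliers)) {
    m <- multipliers[[g]]
    if (!length(sites)) next
    if (m[1] > 0 && m[2] > 0) {
      out[[length(out) + 1]] <- data.frame(
        genotype = g, locus = "a", pos = sites, ref = a[sites],
        alt = b[sites], call = "het")
      out[[length(out) + 1]] <- data.frame(
        genotype = g, locus = "b", pos = sites, ref = b[sites],
        alt = a[sites], call = "het")
    } else if (m[1] > 0 && m[2] == 0) {
      out[[length(out) + 1]] <- data.frame(
        genotype = g, locus = "a", pos = sites, ref = a[sites],
        alt = b[sites], call = "hom_alt")
    } else if (m[1] == 0 && m[2] > 0) {
      out[[length(out) + 1]] <- data.frame(
        genotype = g, locus = "b", pos = sites, ref = b[sites],
        alt = a[sites], call = "hom_alt")
    }
  }
  if (!length(out))
    return(data.frame(genotype = character(), locus = character(),
                      pos = integer(), ref = character(), alt = character(),
                      call = character()))
  do.call(rbind, out)
}

#' Simulate a complete allopolyploid capture experiment
#'
#' Generates, under the configured model and seed: the genome index,
#' target regions with gene/subgenome/strand metadata, one coverage track
#' per genotype (negative-binomial depth, on-target mean
#' \code{m * E * background_mean}, off-target \code{background_mean}),
#' per-genotype variant tables (locus-specific homozygous SNPs and
#' cross-locus hemi-SNPs), CDS models and sequences, promoter sequences,
#' and the generative truth (copy multipliers per locus and genotype and
#' the placed SNPs with zygosity class). Identical seeds give identical
#' output.
#'
#' @param config a [simulationConfig()].
#' @return a [CaptureSimulation-class].
#' @export
simulateExperiment <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "polycap_sim_config"))
  cfg <- config
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  lay <- simLayout(cfg)
  loci <- lay$loci
  n_loci <- nrow(loci)
  gt <- cfg$genotypes

  ## locus sequences: ancestral per (gene, pair index); A copy = ancestral,
  ## C copy diverged at rate (1 - identity); extra unpaired copies random
  seqs <- stats::setNames(vector("character", n_loci), loci$copy_id)
  hemi_sites <- list()  # per pair row: divergent positions surfacing as hemi
  div_rate <- 1 - cfg$inter_homoeolog_identity
  pairs <- lay$pairs
  if (!is.null(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      anc <- randomDna(cfg$locus_length)
      a <- strsplit(anc, "")[[1]]
      b <- a
      div <- which(stats::runif(cfg$locus_length) < div_rate)
      if (length(div)) b[div] <- mutateBase(a[div])
      # the subset of divergent sites that surface as hemi-SNP calls
      keep <- if (div_rate > 0)
        div[stats::runif(length(div)) < cfg$cross_locus_rate / div_rate]
      else integer()
      seqs[pairs$a[p]] <- paste(a, collapse = "")
      seqs[pairs$c[p]] <- paste(b, collapse = "")
      hemi_sites[[p]] <- keep
    }
  }
  for (id in loci$copy_id[!nzchar(seqs[loci$copy_id])])
    seqs[id] <- randomDna(cfg$locus_length)

  ## truth multipliers
  mult <- matrix(1, n_loci, length(gt), dimnames = list(loci$copy_id, gt))
  if (is.list(cfg$events)) {
    for (g in names(cfg$events)) {
      ev <- cfg$events[[g]]
      bad <- setdiff(names(ev), loci$copy_id)
      if (length(bad)) stop("unknown copy_id in events: ",
                            paste(bad, collapse = ", "))
      mult[names(ev), g] <- ev
    }
  } else {
    n_ev <- cfg$n_loss + cfg$n_gain + cfg$n_absent
    if (cfg$n_replacement > 0 && is.null(pairs))
      stop("replacement events need homoeolog pairs (both subgenomes)")
    repl_rows <- if (cfg$n_replacement > 0)
      sample(nrow(pairs), cfg$n_replacement) else integer()
    repl_ids <- c(pairs$a[repl_rows], pairs$c[repl_rows])
    free <- setdiff(loci$copy_id, repl_ids)
    if (n_ev > length(free)) stop("more events than available loci")
    ev_loci <- sample(free, n_ev)
    ev_mult <- rep(c(0.5, 2, 0), c(cfg$n_loss, cfg$n_gain, cfg$n_absent))
    ev_gt <- sample(gt, n_ev, replace = TRUE)
    for (i in seq_len(n_ev)) mult[ev_loci[i], ev_gt[i]] <- ev_mult[i]
    for (r in repl_rows) {
      g <- sample(gt, 1)
      mult[pairs$a[r], g] <- 2    # replacement: partner duplicated...
      mult[pairs$c[r], g] <- 0    # ...the replaced copy gone
    }
  }

  ## expected mean on-target depth per locus x genotype
  mean_depth <- mult * cfg$enrichment * cfg$background_mean
  if (cfg$depth_bleed > 0 && !is.null(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      for (g in gt) {
        ma <- mult[pairs$a[p], g]; mc <- mult[pairs$c[p], g]
        if (ma == 0 && mc > 0)
          mean_depth[pairs$a[p], g] <- mean_depth[pairs$a[p], g] +
            cfg$depth_bleed * mc * cfg$enrichment * cfg$background_mean
        if (mc == 0 && ma > 0)
          mean_depth[pairs$c[p], g] <- mean_depth[pairs$c[p], g] +
            cfg$depth_bleed * ma * cfg$enrichment * cfg$background_mean
      }
    }
  }

  ## coverage tracks
  size <- 1 / cfg$background_dispersion
  nb_t <- cfg$locus_length %/% cfg$target_bin
  trks <- stats::setNames(vector("list", length(gt)), gt)
  for (g in gt) {
    chrom_v <- character(); start_v <- numeric(); end_v <- numeric()
    depth_v <- integer()
    for (ch in lay$chroms) {
      n_bins <- lay$chr_len %/% cfg$background_bin
      bg <- stats::rnbinom(n_bins, mu = cfg$background_mean, size = size)
      bs <- (seq_len(n_bins) - 1) * cfg$background_bin + 1
      be <- bs + cfg$background_bin - 1
      lr <- loci[loci$chrom == ch, , drop = FALSE]
      if (nrow(lr)) {
        tile <- (lr$start - 1) %/% cfg$background_bin + 1
        # carve the locus out of its host bin; background keeps the rest
        bs[tile] <- lr$end + 1
        td <- stats::rnbinom(nb_t * nrow(lr),
                             mu = rep(mean_depth[lr$copy_id, g], each = nb_t),
                             size = size)
        ts <- rep(lr$start, each = nb_t) +
          (rep(seq_len(nb_t), nrow(lr)) - 1) * cfg$target_bin
        chrom_v <- c(chrom_v, rep(ch, length(ts)))
        start_v <- c(start_v, ts)
        end_v <- c(end_v, ts + cfg$target_bin - 1)
        depth_v <- c(depth_v, td)
      }
      keep <- bg > 0 & bs <= be
      chrom_v <- c(chrom_v, rep(ch, sum(keep)))
      start_v <- c(start_v, bs[keep]); end_v <- c(end_v, be[keep])
      depth_v <- c(depth_v, bg[keep])
    }
    trk <- GenomicRanges::GRanges(chrom_v,
                                  IRanges::IRanges(start_v, end_v),
                                  depth = as.integer(depth_v),
                                  seqinfo = lay$genomeIndex)
    trks[[g]] <- canonicalizeTrack(trk)
  }

  ## variants
  locus_depth_gt <- function(id, g) max(as.integer(round(mean_depth[id, g])), 0L)
  # divergent sites per copy, so locus-specific SNPs never collide with them
  hemi_by_copy <- stats::setNames(vector("list", n_loci), loci$copy_id)
  if (!is.null(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      hemi_by_copy[[pairs$a[p]]] <- hemi_sites[[p]]
      hemi_by_copy[[pairs$c[p]]] <- hemi_sites[[p]]
    }
  }
  snp_rows <- list()
  for (g in gt) {
    for (i in seq_len(n_loci)) {
      id <- loci$copy_id[i]
      if (mult[id, g] == 0 || cfg$snp_rate == 0) next
      pos <- which(stats::runif(cfg$locus_length) < cfg$snp_rate)
      pos <- setdiff(pos, hemi_by_copy[[id]])
      if (!length(pos)) next
      base <- strsplit(seqs[[id]], "")[[1]][pos]
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        genotype = g, copy_id = id, chrom = loci$chrom[i],
        pos = loci$start[i] + pos - 1, locus_pos = pos,
        ref = base, alt = mutateBase(base), call = "hom_alt",
        zygosity = "homozygous", origin = "private",
        depth = locus_depth_gt(id, g))
    }
  }
  if (!is.null(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      sites <- hemi_sites[[p]]
      if (!length(sites)) next
      ia <- match(pairs$a[p], loci$copy_id)
      ic <- match(pairs$c[p], loci$copy_id)
      a <- strsplit(seqs[[pairs$a[p]]], "")[[1]]
      b <- strsplit(seqs[[pairs$c[p]]], "")[[1]]
      mlist <- lapply(stats::setNames(gt, gt), function(g)
        c(mult[pairs$a[p], g], mult[pairs$c[p], g]))
      vars <- hemiVariantCalls(a, b, sites, mlist)
      if (!nrow(vars)) next
      li <- ifelse(vars$locus == "a", ia, ic)
      vars$copy_id <- loci$copy_id[li]
      vars$chrom <- loci$chrom[li]
      vars$locus_pos <- vars$pos
      vars$pos <- loci$start[li] + vars$locus_pos - 1
      vars$zygosity <- ifelse(vars$call == "het", "hemi", "homozygous")
      vars$origin <- "cross_locus"
      vars$depth <- vapply(seq_len(nrow(vars)), function(r)
        locus_depth_gt(vars$copy_id[r], vars$genotype[r]), integer(1))
      snp_rows[[length(snp_rows) + 1]] <-
        vars[, c("genotype", "copy_id", "chrom", "pos", "locus_pos",
                 "ref", "alt", "call", "zygosity", "origin", "depth")]
    }
  }
  truth_snps <- if (length(snp_rows)) do.call(rbind, snp_rows)
  else data.frame(genotype = character(), copy_id = character(),
                  chrom = character(), pos = integer(), locus_pos = integer(),
                  ref = character(), alt = character(), call = character(),
                  zygosity = character(), origin = character(),
                  depth = integer())
  rownames(truth_snps) <- NULL

  ## CDS models, sequences, promoters, targets
  cds_from <- cfg$promoter_length + 1
  cds_to <- cfg$promoter_length + cfg$cds_length
  tgt <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start, loci$end),
                                strand = loci$strand,
                                copy_id = loci$copy_id,
                                gene_id = loci$gene_id,
                                subgenome = loci$subgenome,
                                functional = TRUE,
                                seqinfo = lay$genomeIndex)
  cds_gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$start + cds_from - 1,
                                                    loci$start + cds_to - 1),
                                   strand = loci$strand,
                                   type = "CDS",
                                   phase = 0L,
                                   copy_id = loci$copy_id,
                                   gene_id = loci$gene_id,
                                   seqinfo = lay$genomeIndex)
  loci_set <- Biostrings::DNAStringSet(seqs[loci$copy_id])
  cds_plus <- Biostrings::subseq(loci_set, cds_from, cds_to)
  minus <- loci$strand == "-"
  cds_set <- cds_plus
  cds_set[minus] <- Biostrings::reverseComplement(cds_plus[minus])
  names(cds_set) <- loci$copy_id
  prom_set <- Biostrings::subseq(loci_set, 1, cfg$promoter_length)
  names(prom_set) <- loci$copy_id

  ## annotate truth SNPs falling inside the CDS with their consequence
  truth_snps$cds_pos <- rep(NA_integer_, nrow(truth_snps))
  truth_snps$consequence <- rep("not_applicable", nrow(truth_snps))
  in_cds <- truth_snps$locus_pos >= cds_from & truth_snps$locus_pos <= cds_to
  code <- Biostrings::GENETIC_CODE
  cds_chars <- as.character(cds_set)
  for (r in which(in_cds)) {
    id <- truth_snps$copy_id[r]
    i <- match(id, loci$copy_id)
    cp <- if (loci$strand[i] == "-") cds_to - truth_snps$locus_pos[r] + 1
          else truth_snps$locus_pos[r] - cds_from + 1
    cds_chr <- cds_chars[[id]]
    ref <- truth_snps$ref[r]; alt <- truth_snps$alt[r]
    if (loci$strand[i] == "-") { ref <- compBase(ref); alt <- compBase(alt) }
    ci <- (cp - 1) %/% 3; cpos <- (cp - 1) %% 3 + 1
    codon <- substr(cds_chr, ci * 3 + 1, ci * 3 + 3)
    alt_codon <- codon
    substr(alt_codon, cpos, cpos) <- alt
    truth_snps$cds_pos[r] <- cp
    truth_snps$consequence[r] <-
      if (code[[codon]] == code[[alt_codon]]) "synonymous" else "non_synonymous"
  }

  variants <- lapply(stats::setNames(gt, gt), function(g) {
    v <- truth_snps[truth_snps$genotype == g,
                    c("chrom", "pos", "ref", "alt", "call", "depth"),
                    drop = FALSE]
    rownames(v) <- NULL
    v[order(v$chrom, v$pos), , drop = FALSE]
  })

  pan <- CapturePanel(trks, stats = NULL, targets = tgt,
                      genomeIndex = lay$genomeIndex, inbred = cfg$inbred,
                      read_length = cfg$read_length)
  if (!is.null(cfg$aligned_reads)) {
    pan@stats$aligned_reads <- rep(cfg$aligned_reads,
                                   length.out = length(gt))
    validObject(pan)
  }
  new("CaptureSimulation",
      panel = pan,
      variants = variants,
      truth = list(multipliers = mult, snps = truth_snps,
                   pairs = pairs),
      cds = cds_set,
      cdsRanges = cds_gr,
      promoters = prom_set,
      loci = loci_set,
      config = unclass(cfg))
}

#' Write a simulated experiment to disk
#'
#' Emits the standard-format files of a capture experiment: one bedGraph
#' and one VCF per genotype, the target BED, the genome index TSV, CDS
#' models (GFF3) and sequences (FASTA), promoter FASTA, locus FASTA, and
#' the truth tables as TSV. Output is deterministic: the same simulation
#' writes byte-identical files.
#'
#' @param sim a [CaptureSimulation-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pan <- panel(sim)
  paths <- list()
  for (g in genotypes(pan)) {
    paths[[paste0("bedgraph_", g)]] <-
      writeBedGraph(tracks(pan)[[g]], file.path(dir, paste0(g, ".bedgraph")))
    paths[[paste0("vcf_", g)]] <-
      writeSimpleVcf(sim@variants[[g]], file.path(dir, paste0(g, ".vcf")),
                     sample = g, genomeIndex = genomeIndex(pan))
  }
  paths$targets <- writeTargetBed(targets(pan), file.path(dir, "targets.bed"))
  paths$genome_index <- writeGenomeIndex(genomeIndex(pan),
                                         file.path(dir, "genome_index.tsv"))
  gff <- sim@cdsRanges
  gff$ID <- gff$copy_id
  gff$source <- "polycap"
  paths$gff <- file.path(dir, "cds.gff3")
  rtracklayer::export(gff, paths$gff, format = "gff3")
  paths$cds <- file.path(dir, "cds.fa")
  Biostrings::writeXStringSet(sim@cds, paths$cds)
  paths$promoters <- file.path(dir, "promoters.fa")
  Biostrings::writeXStringSet(sim@promoters, paths$promoters)
  paths$loci <- file.path(dir, "loci.fa")
  Biostrings::writeXStringSet(sim@loci, paths$loci)
  tm <- data.frame(copy_id = rownames(truthTable(sim)$multipliers),
                   truthTable(sim)$multipliers, check.names = FALSE)
  paths$truth_multipliers <- file.path(dir, "truth_multipliers.tsv")
  utils::write.table(tm, paths$truth_multipliers, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth_snps <- file.path(dir, "truth_snps.tsv")
  utils::write.table(truthTable(sim)$snps, paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$stats <- file.path(dir, "alignment_stats.tsv")
  utils::write.table(alignmentStats(pan), paths$stats, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
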