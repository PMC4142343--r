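test_that("configuration is validated", {
  expect_error(simulationConfig(inter_homoeolog_identity = 0), "identity")
  expect_error(simulationConfig(cross_locus_rate = 0.5),
               "cannot exceed homoeolog divergence")
  expect_error(simulationConfig(cds_length = 901), "divisible by 3")
  expect_error(simulationConfig(locus_length = 1999), "multiple of target_bin")
  expect_error(simulationConfig(genome_length = 1e5), "exceed the total target")
  expect_error(simulationConfig(events = list(gt1 = c(x = 0.7))),
               "multipliers must be in")
  expect_error(simulationConfig(genotypes = "one"), "at least 2 genotypes")
  # replacement events need a homoeolog pair to swap
  cfg <- smallSimConfig(copies_per_subgenome = c(A = 2), n_replacement = 1)
  expect_error(simulateExperiment(cfg), "homoeolog pairs")
})

test_that("null model: unit multipliers and zero SNP rates give no events, empty VCFs", {
  cfg <- smallSimConfig(seed = 5, n_loss = 0, n_gain = 0, n_absent = 0,
                        snp_rate = 0, cross_locus_rate = 0)
  sim <- simulateExperiment(cfg)
  expect_true(all(truthTable(sim)$multipliers == 1))
  expect_equal(nrow(truthTable(sim)$snps), 0L)
  expect_true(all(vapply(sim@variants, nrow, integer(1)) == 0L))
})

test_that("a multiplier-0 locus has zero depth in its genotype's track", {
  cfg <- smallSimConfig(seed = 6, events = list(gt2 = c(gene01.A01_1 = 0)),
                        snp_rate = 0, cross_locus_rate = 0)
  sim <- simulateExperiment(cfg)
  pan <- panel(sim)
  tgt <- targets(pan)
  absent <- tgt[tgt$copy_id == "gene01.A01_1"]
  expect_equal(polycap:::basesOnRegions(tracks(pan)$gt2, absent), 0)
  expect_gt(polycap:::basesOnRegions(tracks(pan)$gt1, absent), 0)
})

test_that("identical seeds reproduce bitwise-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateExperiment(smallSimConfig(seed = 99)), d1)
  writeSimulation(simulateExperiment(smallSimConfig(seed = 99)), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 8)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  # and a different seed changes the depth tracks
  d3 <- withr::local_tempdir()
  writeSimulation(simulateExperiment(smallSimConfig(seed = 100)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "gt1.bedgraph"))),
                         unname(tools::md5sum(file.path(d3, "gt1.bedgraph")))))
})

test_that("written bedGraph and VCF pass the format readers' validation", {
  d <- withr::local_tempdir()
  sim <- simulateExperiment(smallSimConfig(seed = 12))
  writeSimulation(sim, d)
  gi <- readGenomeIndex(file.path(d, "genome_index.tsv"))
  expect_equal(totalGenomeLength(gi), 4e8)
  tgt <- readTargetBed(file.path(d, "targets.bed"))
  expect_equal(sort(tgt$copy_id), sort(targets(panel(sim))$copy_id))
  for (g in genotypes(panel(sim))) {
    trk <- readBedGraph(file.path(d, paste0(g, ".bedgraph")))
    expect_equal(polycap:::trackBaseCount(trk),
                 polycap:::trackBaseCount(tracks(panel(sim))[[g]]))
    v <- readVcfGenotypes(file.path(d, paste0(g, ".vcf")), min_depth = 0)
    expect_equal(nrow(v), nrow(sim@variants[[g]]))
  }
})

test_that("mean on/off-target depth ratio tracks the configured enrichment", {
  # Monte-Carlo check at high background so the off-target mean is stable
  ratios <- vapply(1:10, function(s) {
    sim <- simulateExperiment(smallSimConfig(seed = 1000 + s, n_genes = 2,
                                             enrichment = 50,
                                             background_mean = 5,
                                             n_loss = 0, n_gain = 0,
                                             n_absent = 0,
                                             snp_rate = 0, cross_locus_rate = 0))
    pan <- panel(sim)
    gi <- genomeIndex(pan)
    tgt <- GenomicRanges::reduce(targets(pan), ignore.strand = TRUE)
    on <- mean(vapply(tracks(pan), function(t) meanDepth(t, gi, tgt),
                      numeric(1)))
    gaps <- GenomicRanges::gaps(tgt)
    gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
    off <- mean(vapply(tracks(pan), function(t) meanDepth(t, gi, gaps),
                       numeric(1)))
    on / off
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 50 - 1), 0.05)
})

test_that("per-locus mean depth converges to m * E * background at long loci", {
  # 10x the default 2 kb region length; the mean over loci of the
  # per-locus relative error shrinks with the number of depth bins
  cfg <- smallSimConfig(seed = 42, n_genes = 4, locus_length = 20000,
                        promoter_length = 600, cds_length = 900,
                        n_loss = 0, n_gain = 0, n_absent = 0,
                        snp_rate = 0, cross_locus_rate = 0)
  sim <- simulateExperiment(cfg)
  pan <- panel(sim)
  tgt <- targets(pan)
  expected <- 760 * 0.5
  rel <- c()
  for (g in genotypes(pan)) for (i in seq_along(tgt)) {
    d <- polycap:::basesOnRegions(tracks(pan)[[g]], tgt[i]) / 20000
    rel <- c(rel, d / expected - 1)
  }
  expect_lt(abs(mean(rel)), 0.02)
})

test_that("injectHemiSnps is deterministic and respects copy presence", {
  a <- paste(rep("ACGT", 250), collapse = "")
  mult <- list(g1 = c(1, 1), g2 = c(1, 0), g3 = c(0, 0))
  r0 <- injectHemiSnps(a, a, rate = 0, multipliers = mult, seed = 3)
  expect_equal(length(r0$sites), 0L)
  expect_equal(nrow(r0$variants), 0L)

  r1 <- injectHemiSnps(a, a, rate = 0.01, multipliers = mult, seed = 3)
  r2 <- injectHemiSnps(a, a, rate = 0.01, multipliers = mult, seed = 3)
  expect_identical(r1, r2)
  expect_gt(length(r1$sites), 3)
  expect_lt(length(r1$sites), 25)
  v <- r1$variants
  # both copies present: het at both loci; one copy absent: hom at survivor
  expect_true(all(v$call[v$genotype == "g1"] == "het"))
  expect_equal(sort(unique(v$locus[v$genotype == "g1"])), c("a", "b"))
  expect_true(all(v$call[v$genotype == "g2"] == "hom_alt"))
  expect_true(all(v$locus[v$genotype == "g2"] == "a"))
  expect_false("g3" %in% v$genotype)
  expect_warning(injectHemiSnps(a, a, rate = 0.6, multipliers = mult),
                 "unrealistically")
})

test_that("cross-locus divergent sites surface as hemi het calls at both partners", {
  cfg <- smallSimConfig(seed = 8, n_genes = 6, snp_rate = 0,
                        cross_locus_rate = 0.005,
                        n_loss = 0, n_gain = 0, n_absent = 0)
  sim <- simulateExperiment(cfg)
  snps <- truthTable(sim)$snps
  expect_true(nrow(snps) > 0)
  expect_true(all(snps$origin == "cross_locus"))
  expect_true(all(snps$call == "het"))
  # each divergent site appears at exactly the two partner loci of its
  # homoeolog pair, in every genotype
  pair_key <- paste(sub("\\..*", "", snps$copy_id),      # gene
                    sub(".*_", "", snps$copy_id))        # pair index
  grp <- split(snps$copy_id, paste(snps$genotype, pair_key, snps$locus_pos))
  for (cids in grp) {
    expect_equal(length(cids), 2L)
    expect_setequal(substr(sub("^[^.]+\\.", "", cids), 1, 1), c("A", "C"))
  }
})

test_that("losing one homoeolog turns its hemi sites homozygous at the survivor", {
  cfg <- smallSimConfig(seed = 9, n_genes = 4, snp_rate = 0,
                        cross_locus_rate = 0.01,
                        events = list(gt1 = c(gene01.C01_1 = 0)))
  sim <- simulateExperiment(cfg)
  snps <- truthTable(sim)$snps
  g1 <- snps[snps$genotype == "gt1" & grepl("^gene01", snps$copy_id), ]
  if (nrow(g1)) {
    expect_true(all(g1$copy_id == "gene01.A01_1"))
    expect_true(all(g1$call == "hom_alt"))
    expect_true(all(g1$zygosity == "homozygous"))
  }
  g2 <- snps[snps$genotype == "gt2" & grepl("^gene01", snps$copy_id), ]
  expect_true(all(g2$call == "het"))
  expect_setequal(unique(g2$copy_id), c("gene01.A01_1", "gene01.C01_1"))
})

test_that("truth SNP alleles match the locus sequences and VCF records", {
  sim <- simulateExperiment(smallSimConfig(seed = 13))
  snps <- truthTable(sim)$snps
  seqs <- as.character(sim@loci)
  for (r in sample(seq_len(nrow(snps)), min(25, nrow(snps)))) {
    expect_equal(substr(seqs[[snps$copy_id[r]]], snps$locus_pos[r],
                        snps$locus_pos[r]), snps$ref[r])
    expect_true(snps$alt[r] != snps$ref[r])
  }
  v <- sim@variants$gt1
  t1 <- snps[snps$genotype == "gt1", ]
  expect_equal(nrow(v), nrow(t1))
  expect_setequal(paste(v$chrom, v$pos, v$alt), paste(t1$chrom, t1$pos, t1$alt))
})
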