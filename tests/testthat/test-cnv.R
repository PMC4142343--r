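test_that("locus matrix gives identical columns for identical biology", {
  gi <- randomGenomeIndex(1, 5000)
  set.seed(21)
  trk <- randomTrack(gi, n_seg = 80)
  tgt <- randomTargets(gi, n = 5)
  stats <- data.frame(genotype = c("a", "b"), aligned_reads = 200,
                      read_length = 100)
  mat <- locusNormalizedMatrix(list(a = trk, b = trk), tgt, stats, gi)
  expect_equal(mat[, "a"], mat[, "b"])

  # 3x the library size with 3x the depth: normalization removes it
  trk3 <- trk; trk3$depth <- trk3$depth * 3L
  stats2 <- data.frame(genotype = c("a", "b"),
                       aligned_reads = c(200, 600), read_length = 100)
  mat2 <- locusNormalizedMatrix(list(a = trk, b = trk3), tgt, stats2, gi)
  expect_equal(mat2[, "a"], mat2[, "b"], tolerance = 1e-12)
})

test_that("locus matrix equals the brute-force per-base normalized mean", {
  gi <- randomGenomeIndex(2, 4000)
  for (s in 1:6) {
    set.seed(200 + s)
    trks <- list(a = randomTrack(gi, n_seg = 100),
                 b = randomTrack(gi, n_seg = 100))
    tgt <- randomTargets(gi, n = 6)
    stats <- data.frame(genotype = c("a", "b"),
                        aligned_reads = c(300, 450), read_length = 100)
    mat <- locusNormalizedMatrix(trks, tgt, stats, gi)
    G <- totalGenomeLength(gi)
    for (g in c("a", "b")) {
      depth <- expandTrack(trks[[g]], gi)
      N <- stats$aligned_reads[stats$genotype == g]
      for (i in seq_along(tgt)) {
        ch <- as.character(seqnames(tgt)[i])
        d <- depth[[ch]][start(tgt)[i]:end(tgt)[i]]
        expect_equal(mat[tgt$copy_id[i], g], mean(d) * G / (N * 100),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("locus matrix validates the panel", {
  gi <- randomGenomeIndex(1, 2000)
  set.seed(2)
  trk <- randomTrack(gi, 20)
  tgt <- randomTargets(gi, 2)
  stats1 <- data.frame(genotype = "a", aligned_reads = 10, read_length = 100)
  expect_error(locusNormalizedMatrix(list(a = trk), tgt, stats1, gi),
               "at least 2 genotypes")
  stats2 <- data.frame(genotype = c("a", "b"), aligned_reads = 10,
                       read_length = 100)
  expect_error(locusNormalizedMatrix(list(a = trk), tgt, stats2, gi),
               "missing a coverage track: b")
})

test_that("ratio thresholds map to states with strict boundary handling", {
  # two-genotype rows realize each focal ratio against the panel mean
  mat <- rbind(L_loss = c(0.4, 1.6),
               L_gain = c(1.6, 0.4),
               L_abs = c(0.04, 1.96),
               L_norm = c(1, 1),
               L_edge = c(0.5, 1.5)) * 50
  colnames(mat) <- c("g1", "g2")
  calls <- as.data.frame(callCnv(mat, loo = FALSE))
  g1 <- calls[calls$genotype == "g1", ]
  expect_equal(g1$state[match(c("L_loss", "L_gain", "L_abs", "L_norm"),
                              g1$copy_id)],
               c("loss", "gain", "absent", "normal"))
  # ratios exactly at 0.5 and 1.5: strict inequalities keep them normal
  edge <- calls[calls$copy_id == "L_edge", ]
  expect_equal(edge$ratio, c(0.5, 1.5))
  expect_equal(edge$state, c("normal", "normal"))
})

test_that("threshold validation and state invariants hold", {
  expect_error(cnvThresholds(loss = 0.04, absent = 0.05), "absent < loss")
  expect_error(cnvThresholds(gain = 0.9), "1 < gain")
  set.seed(31)
  mat <- matrix(runif(40, 0, 3), 10, 4,
                dimnames = list(paste0("L", 1:10), paste0("g", 1:4)))
  thr <- cnvThresholds()
  calls <- as.data.frame(callCnv(mat, thr, loo = FALSE))
  ok <- !calls$excluded
  expect_true(all((calls$ratio[ok] < thr$absent) == (calls$state[ok] == "absent")))
  expect_true(all((calls$state[ok] == "loss") ==
                    (calls$ratio[ok] >= thr$absent & calls$ratio[ok] < thr$loss)))
  expect_true(all((calls$state[ok] == "gain") == (calls$ratio[ok] > thr$gain)))
  # with the panel-mean reference the ratios of each locus average to 1
  rmat <- matrix(calls$ratio, nrow = 10,
                 dimnames = list(calls$copy_id[1:10], NULL))
  expect_equal(unname(rowMeans(rmat)), rep(1, 10))
})

test_that("exclusions: heterozygous loci per genotype and zero panel coverage", {
  mat <- rbind(L1 = c(100, 100, 100, 100),
               L2 = c(0, 0, 0, 0),
               L3 = c(40, 100, 100, 100))
  colnames(mat) <- paste0("g", 1:4)
  calls <- as.data.frame(callCnv(mat, het_snp_loci = list(g2 = "L1"),
                                 loo = FALSE))
  r <- function(id, g) calls[calls$copy_id == id & calls$genotype == g, ]
  expect_true(r("L1", "g2")$excluded)
  expect_equal(r("L1", "g2")$reason, "heterozygous SNPs at locus")
  expect_true(is.na(r("L1", "g2")$state))
  expect_false(r("L1", "g1")$excluded)
  expect_true(all(calls$excluded[calls$copy_id == "L2"]))
  expect_true(all(calls$reason[calls$copy_id == "L2"] == "no panel coverage"))
  expect_error(callCnv(mat[, 1, drop = FALSE]), "single-genotype")
  expect_error(callCnv(mat * NA), "finite")
})

test_that("a half-dose event sits exactly on the loss threshold under leave-one-out", {
  # 4 genotypes, one multiplier-0.5 event: the LOO reference is the mean of
  # the three unaffected genotypes, so the expected ratio is exactly 0.5 and
  # the strict inequality leaves a noiseless event uncalled
  mat <- rbind(L1 = c(0.5, 1, 1, 1) * 380)
  colnames(mat) <- paste0("g", 1:4)
  calls <- as.data.frame(callCnv(mat, loo = TRUE))
  focal <- calls[calls$genotype == "g1", ]
  expect_equal(focal$ratio, 0.5)
  expect_equal(focal$state, "normal")
  # against the full panel mean the event is diluted to 0.5/0.875
  calls2 <- as.data.frame(callCnv(mat, loo = FALSE))
  expect_equal(calls2$ratio[calls2$genotype == "g1"], 0.5 / 0.875,
               tolerance = 1e-12)
  # with noise, detection of a half-dose event is a near coin flip; document
  # the knife-edge on simulated data
  hits <- 0; n_ev <- 0
  for (s in 1:12) {
    sim <- simulateExperiment(smallSimConfig(seed = 300 + s, n_genes = 6,
                                             n_loss = 2, n_gain = 0,
                                             n_absent = 0,
                                             snp_rate = 0, cross_locus_rate = 0))
    tr <- truthTable(sim)$multipliers
    calls <- as.data.frame(callCnv(locusNormalizedMatrix(panel(sim)), loo = TRUE))
    ev <- which(tr == 0.5, arr.ind = TRUE)
    for (k in seq_len(nrow(ev))) {
      id <- rownames(tr)[ev[k, 1]]; g <- colnames(tr)[ev[k, 2]]
      st <- calls$state[calls$copy_id == id & calls$genotype == g]
      n_ev <- n_ev + 1
      if (identical(st, "loss")) hits <- hits + 1
    }
  }
  expect_gt(hits / n_ev, 0.2)
  expect_lt(hits / n_ev, 0.8)
})

test_that("gain and absence events are recovered against the simulator truth", {
  false_calls <- 0; n_normal <- 0; edge_states <- character()
  for (s in 1:5) {
    sim <- simulateExperiment(smallSimConfig(seed = 400 + s, n_genes = 8,
                                             n_loss = 0, n_gain = 2,
                                             n_absent = 2))
    tr <- truthTable(sim)$multipliers
    calls <- as.data.frame(callCnv(locusNormalizedMatrix(panel(sim)), loo = TRUE))
    key <- paste(calls$copy_id, calls$genotype)
    st <- setNames(calls$state, key)
    event_locus <- apply(tr != 1, 1, any)
    for (i in seq_len(nrow(tr))) for (g in colnames(tr)) {
      s_ig <- st[[paste(rownames(tr)[i], g)]]
      if (tr[i, g] == 2) expect_equal(s_ig, "gain")
      if (tr[i, g] == 0) expect_equal(s_ig, "absent")
      if (tr[i, g] == 1) {
        if (!event_locus[i]) {
          # clean loci: the false-call rate of the ratio caller itself
          n_normal <- n_normal + 1
          if (!is.na(s_ig) && s_ig != "normal") false_calls <- false_calls + 1
        } else if (!is.na(s_ig) && s_ig != "normal") {
          # partners of an absent genotype sit at the 1.5 LOO knife-edge:
          # any miscall there can only be a gain
          edge_states <- c(edge_states, s_ig)
        }
      }
    }
  }
  expect_lte(false_calls / n_normal, 0.02)
  expect_true(all(edge_states == "gain"))
})

test_that("calls are invariant under rescaling one genotype's library size", {
  sim <- simulateExperiment(smallSimConfig(seed = 77))
  pan <- panel(sim)
  trks <- tracks(pan)
  stats <- alignmentStats(pan)
  mat1 <- locusNormalizedMatrix(trks, targets(pan), stats, genomeIndex(pan))
  g <- genotypes(pan)[2]
  trks[[g]]$depth <- trks[[g]]$depth * 10L
  stats$aligned_reads[stats$genotype == g] <-
    stats$aligned_reads[stats$genotype == g] * 10
  mat2 <- locusNormalizedMatrix(trks, targets(pan), stats, genomeIndex(pan))
  expect_equal(mat1, mat2, tolerance = 1e-12)
  c1 <- as.data.frame(callCnv(mat1))
  c2 <- as.data.frame(callCnv(mat2))
  expect_equal(c1$state, c2$state)
  expect_equal(c1$ratio, c2$ratio, tolerance = 1e-12)
})

test_that("hetSnpLoci maps heterozygous records onto target copies", {
  gi <- randomGenomeIndex(1, 5000)
  tgt <- GRanges("chr1", IRanges::IRanges(c(100, 1000), c(499, 1399)),
                 copy_id = c("c1", "c2"), gene_id = "g",
                 subgenome = c("A", "C"), functional = TRUE, seqinfo = gi)
  vars <- list(
    a = data.frame(chrom = "chr1", pos = c(150L, 2000L), ref = "A", alt = "G",
                   call = c("het", "het"), depth = 30L),
    b = data.frame(chrom = "chr1", pos = 1100L, ref = "A", alt = "G",
                   call = "hom_alt", depth = 30L))
  het <- hetSnpLoci(vars, tgt)
  expect_equal(het$a, "c1")           # off-target het ignored
  expect_equal(het$b, character(0))   # homozygous records never exclude
})
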