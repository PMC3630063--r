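test_that("configs are validated", {
  expect_error(SimulationConfig(stemLength = 10, matureLength = 21),
               "stemLength")
  expect_error(SimulationConfig(adapter = "ACGT"), "adapter")
  expect_error(SimulationConfig(contaminantFraction = 1.4), "fractions")
  expect_error(
    buildGenomeWithHairpins(SimulationConfig(nHairpins = 400,
                                             scaffoldLength = 5000)),
    "too short")
})

test_that("identical config and seed give byte-identical bundles", {
  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  p1 <- writeFixtureBundle(smallConfig(seed = 11), d1)
  p2 <- writeFixtureBundle(smallConfig(seed = 11), d2)
  expect_length(p1, 8L)
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), info = k)
  # different seed changes the genome
  p3 <- writeFixtureBundle(smallConfig(seed = 12), file.path(tempdir(), "bC"))
  expect_false(identical(unname(tools::md5sum(p1[["genome"]])),
                         unname(tools::md5sum(p3[["genome"]]))))
})

test_that("planted precursors obey the 1-based inclusive LP convention", {
  gen <- buildGenomeWithHairpins(smallConfig(seed = 2))
  m <- as.data.frame(truthMirna(gen$truth))
  expect_identical(m$lp, m$end - m$start + 1L)
  expect_true(all(m$lp >= 80L & m$lp <= 280L))
  # contaminant annotation covers rRNA and tRNA loci with valid ranges
  ann <- gen$annotation
  expect_setequal(unique(ann$type), c("rRNA", "tRNA"))
  expect_true(all(GenomicRanges::start(ann) <= GenomicRanges::end(ann)))
})

test_that("every planted mature/star pair is the structure's duplex", {
  gen <- buildGenomeWithHairpins(smallConfig(seed = 8))
  m <- as.data.frame(truthMirna(gen$truth))
  for (k in seq_len(nrow(m))) {
    seg <- as.character(Biostrings::subseq(gen$genome[[m$scaffold[k]]],
                                           m$start[k], m$end[k]))
    if (m$strand[k] == "-")
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    prec <- asRna(seg)
    expect_identical(substr(prec, m$matureStart[k],
                            m$matureStart[k] + m$matureLength[k] - 1L),
                     m$mature[k])
    f <- foldRNA(prec)
    hp <- new("HairpinCandidate", sequence = prec, structure = f$structure,
              mfe = f$mfe, locus = GenomicRanges::GRanges(),
              matureStart = m$matureStart[k],
              matureLength = m$matureLength[k], starStart = NA_integer_,
              starLength = NA_integer_, arm = m$arm[k])
    expect_identical(starSequence(findStar(hp)), m$star[k])
  }
})

test_that("library simulation honours fold changes and the adapter", {
  cfg <- smallConfig(seed = 4, deFoldChanges = c("1" = 4))
  gen <- buildGenomeWithHairpins(cfg)
  m <- as.data.frame(truthMirna(gen$truth))
  expect_equal(m$expMatureDrought[1] / m$expMatureControl[1], 4)
  expect_equal(m$expMatureDrought[2] / m$expMatureControl[2], 1)

  libs <- simulateSmallRnaLibraries(gen$genome, gen$truth, cfg)
  mature1 <- chartr("U", "T", m$mature[1])
  isMir <- startsWith(libs$control$seq, mature1)
  expect_gte(mean(endsWith(libs$control$seq[isMir], cfg@adapter)), 0.99)
})

test_that("null fold changes give log2 RPM ratios centred at zero", {
  for (seed in 1:3) {
    set.seed(700 + seed)
    counts <- simulateMirnaCounts(exp(runif(50, log(50), log(500))),
                                  folds = 1, dispersion = 0.01, seed = seed)
    ok <- counts$x > 0 & counts$y > 0
    lr <- log2((counts$y[ok] / sum(counts$y)) / (counts$x[ok] / sum(counts$x)))
    expect_lt(abs(mean(lr)), 0.2)
  }
})

test_that("simulated counts match the negative-binomial moments", {
  mu <- 80
  disp <- 0.05
  counts <- simulateMirnaCounts(rep(mu, 20000), dispersion = disp,
                                seed = 99)$x
  n <- length(counts)
  v <- mu + disp * mu^2
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(v / n))
  m4 <- mean((counts - mean(counts))^4)
  seVar <- sqrt((m4 - var(counts)^2) / n)
  expect_lt(abs(var(counts) - v), 3 * seVar)
})

test_that("degradome reads concentrate at the planted cleavage sites", {
  cfg <- smallConfig(seed = 6, degradomeSignalFraction = 1)
  gen <- buildGenomeWithHairpins(cfg)
  txb <- buildTranscriptome(gen$truth, cfg)
  tgt <- as.data.frame(truthTargets(txb$truth))

  deg <- simulateDegradomeLibrary(txb$transcripts, txb$truth, cfg)
  prof <- mapDegradome(deg, txb$transcripts)
  for (k in seq_len(nrow(tgt))) {
    p <- prof[[tgt$transcript[k]]]
    expect_identical(which(p > 0L), tgt$cleavage[k])
  }

  # half signal: the modal 5' end per targeted transcript is the true site
  cfg2 <- smallConfig(seed = 6, degradomeSignalFraction = 0.5,
                      degradomeDepth = 10000L)
  deg2 <- simulateDegradomeLibrary(txb$transcripts, txb$truth, cfg2)
  prof2 <- mapDegradome(deg2, txb$transcripts)
  for (k in seq_len(nrow(tgt)))
    expect_identical(which.max(prof2[[tgt$transcript[k]]]),
                     tgt$cleavage[k])

  # no targets: purely uniform background, nothing at fixed positions
  emptyTruth <- gen$truth   # targets not yet planted
  deg3 <- simulateDegradomeLibrary(txb$transcripts, emptyTruth, cfg)
  expect_equal(nrow(deg3), cfg@degradomeDepth)
})

test_that("the ground truth round-trips through JSON", {
  cfg <- smallConfig(seed = 3)
  gen <- buildGenomeWithHairpins(cfg)
  txb <- buildTranscriptome(gen$truth, cfg)
  path <- file.path(tempdir(), "truth-roundtrip.json")
  truthToJson(txb$truth, path)
  back <- truthFromJson(path)
  expect_equal(as.data.frame(truthMirna(back)),
               as.data.frame(truthMirna(txb$truth)))
  expect_equal(as.data.frame(truthTargets(back)),
               as.data.frame(truthTargets(txb$truth)))
  expect_identical(as.character(truthContaminants(back)),
                   as.character(truthContaminants(txb$truth)))
})
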