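# A perfect 21-bp-stem hairpin built by hand: arm A, an 8-nt loop, and
# the reverse complement of arm A. Mature at offset m on the 5' arm; the
# expected star follows from the duplex geometry (2-nt 3' overhangs on
# both ends): it is the reverse complement of the precursor segment
# [m - 2, m + 18].
perfectHairpin <- function(seed = 61, S = 30L, m = 5L) {
  set.seed(seed)
  armA <- paste(sample(c("A", "C", "G", "U"), S, replace = TRUE,
                       prob = c(.3, .2, .2, .3)), collapse = "")
  prec <- paste0(armA, strrep("A", 8L), revCompRna(armA))
  f <- foldRNA(prec)
  hp <- new("HairpinCandidate", sequence = prec, structure = f$structure,
            mfe = f$mfe, locus = GenomicRanges::GRanges(),
            matureStart = m, matureLength = 21L, starStart = NA_integer_,
            starLength = NA_integer_, arm = "5p")
  list(hp = hp, prec = prec,
       expectedStar = revCompRna(substr(prec, m - 2L, m + 18L)))
}

test_that("findStar applies the 2-nt 3' overhang geometry", {
  ph <- perfectHairpin()
  hp <- findStar(ph$hp)
  expect_identical(starSequence(hp), ph$expectedStar)
  expect_identical(hp@starLength, 21L)
  # a mostly unpaired mature (<12 paired nt) defines no star
  unp <- ph$hp
  stv <- strsplit(unp@structure, "", fixed = TRUE)[[1L]]
  partner <- pairingTable(unp@structure)
  pos <- 5:25
  pp <- partner[pos]
  stv[c(pos, pp[!is.na(pp)])] <- "."
  unp@structure <- paste(stv, collapse = "")
  expect_error(findStar(unp), "no star")
})

test_that("exciseAndFold recovers planted hairpins with correct LP", {
  cfg <- smallConfig(seed = 13)
  gen <- buildGenomeWithHairpins(cfg)
  m <- as.data.frame(truthMirna(gen$truth))
  for (k in seq_len(min(3L, nrow(m)))) {
    off <- m$matureStart[k] - 1L
    if (m$strand[k] == "+") {
      ts <- m$start[k] + off
      te <- ts + m$matureLength[k] - 1L
    } else {
      te <- m$end[k] - off
      ts <- te - m$matureLength[k] + 1L
    }
    loc <- GenomicRanges::GRanges(m$scaffold[k], IRanges::IRanges(ts, te),
                                  strand = m$strand[k])
    cands <- exciseAndFold(loc, gen$genome)
    expect_gte(length(cands), 1L)
    found <- FALSE
    for (hp in cands) {
      expect_identical(precursorLength(hp),
                       GenomicRanges::width(hp@locus))
      if (hp@arm == m$arm[k]) found <- TRUE
    }
    expect_true(found)
  }
  # window exceeding scaffold bounds is clipped, not an error
  edge <- GenomicRanges::GRanges(m$scaffold[1], IRanges::IRanges(5, 25),
                                 strand = "+")
  expect_silent(exciseAndFold(edge, gen$genome))
})

test_that("random loci rarely fold into candidates and never into calls", {
  g <- randomDnaString(30000, seed = 71)
  genome <- Biostrings::DNAStringSet(setNames(g, "chr"))
  set.seed(72)
  nCand <- 0L
  for (i in 1:40) {
    s <- sample(300:29000, 1)
    loc <- GenomicRanges::GRanges("chr", IRanges::IRanges(s, s + 20L),
                                  strand = "+")
    nCand <- nCand + length(exciseAndFold(loc, genome))
  }
  # chance complementarity produces sporadic hairpin candidates (~10% of
  # loci under this model) but they carry no star reads, so none survive
  expect_lte(nCand, 10L)

  set.seed(73)
  randomTags <- vapply(1:20, function(i) {
    s <- sample(300:29000, 1)
    asRna(substr(g, s, s + 20L))   # mapped, candidate-annotated tags
  }, character(1))
  tags <- annotateTags(mapTags(makeTags(randomTags), genome),
                       GenomicRanges::GRanges())
  disc <- discoverNovelMirnas(tags, genome)
  expect_identical(nrow(disc$novel), 0L)
})

test_that("evaluateMeyers enforces star evidence, duplex quality and MFE", {
  ph <- perfectHairpin()
  hp <- findStar(ph$hp)
  mature <- substr(ph$prec, 5, 25)

  tagsWithStar <- makeTags(c(mature, ph$expectedStar), control = c(50L, 3L))
  ev <- evaluateMeyers(hp, tagsWithStar)
  expect_true(ev$accepted)
  expect_identical(ev$starCounts[["control"]], 3L)

  tagsNoStar <- makeTags(mature, control = 50L)
  ev2 <- evaluateMeyers(hp, tagsNoStar)
  expect_false(ev2$accepted)
  expect_identical(ev2$reason, "no star evidence")

  # a weakly paired hairpin fails the MFE threshold
  weak <- hp
  weak@mfe <- -12
  ev3 <- evaluateMeyers(weak, tagsWithStar)
  expect_identical(ev3$reason, "MFE above threshold")

  # five mismatched duplex positions exceed the Meyers limit
  mm <- ph$hp
  st <- strsplit(mm@structure, "", fixed = TRUE)[[1L]]
  partner <- pairingTable(mm@structure)
  off <- (5:23)[c(3, 6, 9, 12, 15)]   # 5 positions inside the duplex span
  st[c(off, partner[off])] <- "."
  mm@structure <- paste(st, collapse = "")
  mm <- findStar(mm)
  ev4 <- evaluateMeyers(mm, makeTags(c(mature, starSequence(mm)),
                                     control = 5L))
  expect_false(ev4$accepted)
  expect_identical(ev4$reason, "duplex mismatches")
})

test_that("discovery recovers planted miRNAs end to end on a small genome", {
  cfg <- smallConfig(seed = 17)
  paths <- writeFixtureBundle(cfg, file.path(tempdir(), "disc-bundle"))
  ctrl <- cleanAndCollapse(paths[["control"]], cfg@adapter)
  drt <- cleanAndCollapse(paths[["drought"]], cfg@adapter)
  tags <- annotateTags(mapTags(TagSet(ctrl, drt), paths[["genome"]]),
                       paths[["annotation"]])
  disc <- discoverNovelMirnas(tags, paths[["genome"]])
  truth <- truthFromJson(paths[["truth"]])
  m <- as.data.frame(truthMirna(truth))
  expect_gte(sum(m$mature %in% disc$novel$sequence), nrow(m) - 1L)
  planted <- GenomicRanges::GRanges(m$scaffold, IRanges::IRanges(m$start, m$end))
  called <- parseLocusString(disc$novel$location)
  expect_identical(sum(!IRanges::overlapsAny(called, planted,
                                             ignore.strand = TRUE)), 0L)
  # rejection log names a reason for every rejected candidate window
  if (nrow(disc$rejections))
    expect_true(all(nchar(disc$rejections$reason) > 0))
})

test_that("family grouping is driven by identical mature sequences", {
  novel <- data.frame(
    name = c("miRn1a", "miRn1b", "miRn2"),
    sequence = c(strrep("ACU", 7), strrep("ACU", 7), strrep("GAC", 7)),
    lp = c(100L, 120L, 90L), mfe = c(-50, -60, -40))
  s <- summarizeNovel(novel)
  expect_identical(s$n, 3L)
  expect_identical(s$nFamilies, 2L)
  expect_identical(unname(s$lengthHist[["21"]]), 3L)
  expect_equal(unname(s$firstNt[["A"]]), 2 / 3)
  expect_equal(s$mfeRange, c(-60, -40))
})
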