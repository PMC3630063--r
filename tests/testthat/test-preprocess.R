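adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("cleanAndCollapse trims, filters and collapses", {
  insert <- "ACGTACGTACGTACGTACGTA"      # 21 nt
  fq <- fastqFrom(c(insert, insert,       # duplicates merge
                    "ACGTACGTACGTACGTA",  # 17 nt: dropped
                    "GGGGTTTTCCCCAAAAGGTTCC"), adapter)
  tags <- cleanAndCollapse(fq, adapter)
  expect_setequal(tags$seq, asRna(c(insert, "GGGGTTTTCCCCAAAAGGTTCC")))
  expect_identical(tags$count[tags$seq == asRna(insert)], 2L)
  expect_true(all(grepl("^[ACGU]+$", tags$seq)))

  # low mean quality drops the read; adapter-less 49-mers exceed maxLen
  fq2 <- rbind(fastqFrom(insert, adapter, qual = "#"),
               fastqFrom(strrep("ACGT", 12), ""))
  expect_identical(nrow(cleanAndCollapse(fq2, adapter)), 0L)
})

test_that("malformed FASTQ is rejected with the record index", {
  path <- file.path(tempdir(), "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-no-at", "ACGT", "+", "IIII"),
             path)
  expect_error(readFastq(path), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), path)  # quality length mismatch
  expect_error(readFastq(path), "record 1")
  writeLines(c("@r1", "ACGT", "+"), path)
  expect_error(readFastq(path), "multiple of 4")
})

test_that("mapTags reports exact hits on both strands and applies the cap", {
  g <- randomDnaString(4000, seed = 21)
  tagPlus <- asRna(substr(g, 101, 121))
  tagMinus <- asRna(oracleRevComp(substr(g, 501, 521)))
  tagAbsent <- asRna(strrep("ACGGT", 5))
  g3 <- paste0(g, substr(g, 101, 121), substr(g, 101, 121))  # 3 copies total
  genome <- Biostrings::DNAStringSet(setNames(g3, "chr"))

  tags <- mapTags(makeTags(c(tagPlus, tagMinus, tagAbsent)), genome)
  hp <- tagHits(tags)[[match(tagPlus, tagSequences(tags))]]
  expect_identical(length(hp), 3L)
  expect_identical(GenomicRanges::start(hp)[1], 101L)
  expect_identical(as.character(GenomicRanges::strand(hp)[1]), "+")
  hm <- tagHits(tags)[[match(tagMinus, tagSequences(tags))]]
  expect_identical(GenomicRanges::start(hm), 501L)
  expect_identical(as.character(GenomicRanges::strand(hm)), "-")
  expect_identical(tagAnnotation(tags)[match(tagAbsent, tagSequences(tags))],
                   "unmapped")

  capped <- mapTags(makeTags(tagPlus), genome, maxHits = 2)
  expect_identical(tagAnnotation(capped), "unmapped")
  expect_identical(lengths(tagHits(capped)), setNames(0L, "1"))
})

test_that("mapTags agrees with the regex full-scan oracle", {
  g <- randomDnaString(20000, seed = 31)
  genomeChars <- c(chrA = g, chrB = randomDnaString(8000, seed = 32))
  genome <- Biostrings::DNAStringSet(genomeChars)
  set.seed(33)
  tags <- character(300)
  for (i in seq_along(tags)) {
    if (i %% 2 == 0) {          # planted substring (possibly revcomp)
      sc <- sample(names(genomeChars), 1)
      w <- sample(18:25, 1)
      s <- sample(nchar(genomeChars[[sc]]) - w, 1)
      sub <- substr(genomeChars[[sc]], s, s + w - 1)
      tags[i] <- asRna(if (i %% 4 == 0) oracleRevComp(sub) else sub)
    } else {
      tags[i] <- paste(sample(c("A", "C", "G", "U"), sample(18:25, 1),
                              replace = TRUE), collapse = "")
    }
  }
  tags <- unique(tags)
  mapped <- mapTags(makeTags(tags), genome, maxHits = 10000)
  for (i in seq_along(tags)) {
    got <- tagHits(mapped)[[match(tags[i], tagSequences(mapped))]]
    want <- oracleMatch(tags[i], genomeChars)
    if (is.null(want)) {
      expect_identical(length(got), 0L)
    } else {
      gotKey <- sort(sprintf("%s:%d:%s", GenomicRanges::seqnames(got),
                             GenomicRanges::start(got),
                             GenomicRanges::strand(got)))
      wantKey <- sort(sprintf("%s:%d:%s", want$scaffold, want$start,
                              want$strand))
      expect_identical(gotKey, wantKey, info = tags[i])
    }
  }
})

test_that("annotation precedence is structural > known > candidate", {
  g <- randomDnaString(2000, seed = 41)
  tag <- asRna(substr(g, 301, 321))
  genome <- Biostrings::DNAStringSet(setNames(g, "chr"))
  structural <- GenomicRanges::GRanges("chr", IRanges::IRanges(250, 400))

  tags <- mapTags(makeTags(tag), genome)
  # overlaps an rRNA locus AND matches the catalog: structural wins
  out <- annotateTags(tags, structural, known = tag)
  expect_identical(tagAnnotation(out), "structural")
  # catalog mature with one extra 3' nt on the tag: known (isomiR shift)
  tag2 <- asRna(substr(g, 801, 822))
  cat2 <- asRna(substr(g, 801, 821))
  out2 <- annotateTags(mapTags(makeTags(tag2), genome),
                       GenomicRanges::GRanges("chr", IRanges::IRanges(1, 10)),
                       known = cat2)
  expect_identical(tagAnnotation(out2), "known_mirna")
  # a shift of 3 nt is beyond the isomiR window
  tag3 <- asRna(substr(g, 1201, 1224))
  cat3 <- asRna(substr(g, 1201, 1221))
  out3 <- annotateTags(mapTags(makeTags(tag3), genome),
                       GenomicRanges::GRanges("chr", IRanges::IRanges(1, 10)),
                       known = cat3)
  expect_identical(tagAnnotation(out3), "candidate")
  # every mapped tag gets exactly one label
  expect_error(annotateTags(tags, "not-a-file.gff3"), "invalid GFF3")
})

test_that("lengthStats computes unique, redundant and ratio columns", {
  tags <- TagSet(
    data.frame(seq = c(strrep("A", 21), paste0(strrep("C", 20), "A"),
                       strrep("G", 24)),
               count = c(10L, 2L, 1L)),
    data.frame(seq = character(0), count = integer(0)))
  st <- lengthStats(tags)
  expect_identical(st$unique[st$length == 21], 2L)
  expect_identical(st$redundant[st$length == 21], 12L)
  expect_equal(st$ratio[st$length == 21], 6)
  expect_identical(st$unique[st$length == 24], 1L)
  expect_equal(st$ratio[st$length == 22], 0)
  # conservation: redundant sums to the library totals
  expect_identical(sum(st$redundant), sum(tagCounts(tags)))
  empty <- lengthStats(makeTags(character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("siRNA duplex scan enforces geometry and the 22-24 nt gate", {
  g <- randomDnaString(400, seed = 51)
  genome <- Biostrings::DNAStringSet(setNames(g, "chr"))
  s <- 101L
  w <- 24L
  tagA <- asRna(substr(g, s, s + w - 1L))                       # plus strand
  tagB <- asRna(oracleRevComp(substr(g, s - 2L, s + w - 3L)))   # 2-nt 3' overhangs
  tagBlunt <- asRna(oracleRevComp(substr(g, s, s + w - 1L)))
  tag21 <- asRna(substr(g, 301, 321))
  tag21p <- asRna(oracleRevComp(substr(g, 299, 319)))

  res <- sirnaDuplexScan(mapTags(makeTags(c(tagA, tagB)), genome))
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$pairs$plusTag, tagA)
  expect_identical(res$pairs$minusTag, tagB)
  expect_true(all(tagAnnotation(res$tags) == "sirna_candidate"))

  blunt <- sirnaDuplexScan(mapTags(makeTags(c(tagA, tagBlunt)), genome))
  expect_identical(nrow(blunt$pairs), 0L)

  short <- sirnaDuplexScan(mapTags(makeTags(c(tag21, tag21p)), genome))
  expect_identical(nrow(short$pairs), 0L)
})

test_that("tag FASTA serialization round-trips counts", {
  tags <- TagSet(data.frame(seq = c(strrep("ACGU", 5), strrep("GUCA", 6)),
                            count = c(7L, 3L)),
                 data.frame(seq = strrep("ACGU", 5), count = 11L))
  path <- file.path(tempdir(), "tags-roundtrip.fa")
  writeTagFasta(tags, path)
  expect_match(readLines(path)[1], "^>tag1_x\\d+_y\\d+$")
  back <- readTagFasta(path)
  expect_identical(tagSequences(back), tagSequences(tags))
  expect_identical(tagCounts(back), tagCounts(tags))
})
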