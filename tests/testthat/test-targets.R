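# a 21-nt miRNA designed so specific positions can be mutated into
# mismatches or G:U wobbles in its perfect-complement window
mir <- "ACGUGCAUCAAGCUAAAGCGG"
mirChars <- strsplit(mir, "", fixed = TRUE)[[1L]]
perfectWindow <- revCompRna(mir)

# mutate the window base opposite miRNA position i
mutateAt <- function(window, i, base) {
  L <- nchar(window)
  substr(window, L - i + 1L, L - i + 1L) <- base
  window
}

test_that("alignDuplex classifies pairs and records coordinates", {
  aln <- alignDuplex(mir, perfectWindow, siteStart = 101L)
  expect_true(all(aln@states == "match"))
  expect_equal(aln@penalty, 0)
  expect_identical(aln@siteEnd, 121L)
  # the miRNA 5' end pairs the window's 3'-most base
  expect_identical(aln@targetPos[aln@positions == 1L], 121L)

  w2 <- mutateAt(perfectWindow, 15L, "C")   # A opposite C: mismatch
  aln2 <- alignDuplex(mir, w2)
  expect_identical(aln2@states[aln2@positions == 15L], "mismatch")
  expect_identical(sum(aln2@states == "mismatch"), 1L)
  expect_error(alignDuplex(mir, substr(perfectWindow, 1, 18)), "within 1 nt")
})

test_that("single-gap placement matches exhaustive enumeration", {
  set.seed(301)
  for (t in 1:25) {
    m <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
    full <- revCompRna(m)
    drop <- sample(21, 1)
    w <- paste0(substr(full, 1, drop - 1), substr(full, drop + 1, 21))
    aln <- alignDuplex(m, w)
    # brute force over every gap position, convention written out
    mc <- strsplit(m, "", fixed = TRUE)[[1L]]
    wc <- strsplit(w, "", fixed = TRUE)[[1L]]
    L <- 21L
    pens <- vapply(seq_len(L), function(g) {
      p <- 2 * if (g >= 2 && g <= 13) 2 else 1
      for (i in seq_len(L)) {
        if (i == g) next
        b <- if (i > g) wc[L - i + 1L] else wc[L - i]
        cls <- oraclePairState(mc[i], b)
        wgt <- if (cls == "match") 0 else if (cls == "GU") 0.5 else 1
        p <- p + wgt * if (i >= 2 && i <= 13) 2 else 1
      }
      p
    }, numeric(1))
    expect_equal(aln@penalty, min(pens))
    gapPos <- aln@positions[aln@states == "gap"]
    expect_identical(gapPos, max(which(pens == min(pens))))  # tie-break
  }
})

test_that("penaltyScore applies weights and core doubling", {
  expect_equal(penaltyScore(alignDuplex(mir, perfectWindow)), 0)
  # G:U at position 5 inside the doubled core: 0.5 x 2
  expect_equal(penaltyScore(alignDuplex(mir, mutateAt(perfectWindow, 5L, "U"))),
               1)
  # mismatch at 15 plus G:U at 20, both outside the core
  w <- mutateAt(mutateAt(perfectWindow, 15L, "C"), 20L, "U")
  expect_equal(penaltyScore(alignDuplex(mir, w)), 1.5)
})

test_that("duplexEnergy implements the stacking model on duplexes", {
  allG <- strrep("G", 21)
  en <- duplexEnergy(alignDuplex(allG, revCompRna(allG)))
  expect_equal(en$mfePerfect, -60)
  expect_equal(en$mfeRatio, 1)
  # mismatches at positions 5, 11, 17 leave runs of 4,5,5,4 matches:
  # 14 G:C-on-G:C stacks -> -42, i.e. 70% of the perfect -60
  w <- revCompRna(allG)
  for (i in c(5L, 11L, 17L)) w <- mutateAt(w, i, "A")
  en2 <- duplexEnergy(alignDuplex(allG, w))
  expect_equal(en2$mfeDuplex, -42)
  expect_equal(en2$mfeRatio, 0.7)
})

test_that("checkRules evaluates the six rules positionally", {
  perfect <- alignDuplex(mir, perfectWindow)
  r <- checkRules(perfect)
  expect_true(all(r$pass))
  expect_true(is.na(r$firstFailure))

  # one mismatch at position 10 violates rule iv only among i-v
  r10 <- checkRules(alignDuplex(mir, mutateAt(perfectWindow, 10L, "C")))
  expect_false(r10$pass[["iv"]])
  expect_true(r10$pass[["ii"]])

  # three consecutive mismatches at 15-17: rule ii fails, iii passes
  w <- perfectWindow
  for (i in 15:17) w <- mutateAt(w, i, "C")
  r151617 <- checkRules(alignDuplex(mir, w))
  expect_false(r151617$pass[["ii"]])
  expect_true(r151617$pass[["iii"]])

  # 70% energy ratio fails rule vi
  allG <- strrep("G", 21)
  w2 <- revCompRna(allG)
  for (i in c(5L, 11L, 17L)) w2 <- mutateAt(w2, i, "A")
  expect_false(checkRules(alignDuplex(allG, w2))$pass[["vi"]])

  # five mismatch equivalents fail rule i (all five positions carry
  # non-G miRNA bases, so a C opposite them cannot pair)
  w3 <- perfectWindow
  for (i in c(2L, 6L, 14L, 16L, 19L)) w3 <- mutateAt(w3, i, "C")
  expect_false(checkRules(alignDuplex(mir, w3))$pass[["i"]])
})

test_that("adding a mismatch never decreases the penalty", {
  set.seed(310)
  for (t in 1:10) {
    m <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
    w <- revCompRna(m)
    base <- alignDuplex(m, w)
    i <- sample(21, 1)
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(strsplit(w, "")[[1L]][21 - i + 1L]))
    for (b in bad) {
      p <- penaltyScore(alignDuplex(m, mutateAt(w, i, b)))
      expect_gte(p, base@penalty)
    }
  }
})

test_that("scanTargets finds planted sites and nothing in scrambled text", {
  set.seed(320)
  tx <- randomDnaString(3000, seed = 321)
  site <- chartr("U", "T", revCompRna(mir))
  tx <- paste0(substr(tx, 1, 1000), site, substr(tx, 1022, 3000))
  txs <- Biostrings::DNAStringSet(setNames(tx, "T1"))
  res <- scanTargets(setNames(mir, "m1"), txs)
  expect_identical(nrow(res$sites), 1L)
  expect_identical(res$sites$siteStart, 1001L)
  expect_equal(res$sites$score, 0)

  # scrambled transcriptome: no hits for random 21-mers at cutoff 2.5
  for (t in 1:10) {
    rmir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                  collapse = "")
    scr <- paste(sample(strsplit(tx, "", fixed = TRUE)[[1L]]), collapse = "")
    hits <- scanTargets(setNames(rmir, "r"),
                        Biostrings::DNAStringSet(setNames(scr, "S1")))
    expect_identical(nrow(hits$sites), 0L)
  }
})

test_that("scanTargets equals the brute-force window oracle", {
  set.seed(330)
  tx <- randomDnaString(2500, seed = 331)
  win <- revCompRna(mir)
  plant <- function(tx, at, s) paste0(substr(tx, 1, at - 1), chartr("U", "T", s),
                                      substr(tx, at + nchar(s), nchar(tx)))
  tx <- plant(tx, 200, win)                         # score 0
  tx <- plant(tx, 600, asRna(mutateAt(win, 15L, "C")))  # one uncored mismatch
  gapped <- paste0(substr(win, 1, 4), substr(win, 6, 21))  # miRNA bulge at 17
  tx <- plant(tx, 900, gapped)
  txList <- c(T1 = asRna(tx))
  got <- scanTargets(setNames(mir, "m"),
                     Biostrings::DNAStringSet(setNames(chartr("U", "T", tx),
                                                       "T1")),
                     merge = FALSE)
  rows <- NULL
  pen <- oracleScanPenalties(mir, txList[["T1"]])
  L <- nchar(mir)
  for (v in list(list(p = pen$un, w = L), list(p = pen$del, w = L - 1L),
                 list(p = pen$ins, w = L + 1L))) {
    for (s in which(v$p < 2.5)) {
      aln <- alignDuplex(mir, substr(txList[["T1"]], s, s + v$w - 1L),
                         transcript = "T1", siteStart = s)
      if (aln@penalty < 2.5 && all(checkRules(aln)$pass))
        rows <- rbind(rows, data.frame(s = s, w = v$w, score = aln@penalty))
    }
  }
  expect_gte(nrow(rows), 2L)
  gotKey <- sort(sprintf("%d:%d:%.2f", got$sites$siteStart,
                         got$sites$siteEnd - got$sites$siteStart + 1L,
                         got$sites$score))
  wantKey <- sort(sprintf("%d:%d:%.2f", rows$s, rows$w, rows$score))
  expect_identical(gotKey, wantKey)
})

test_that("overlapping sites merge keeping the lowest score", {
  # a perfect site: the ungapped window plus its L-1 and L+1 variants all
  # pass; merging must retain only the score-0 ungapped alignment
  tx <- paste0(randomDnaString(300, seed = 341),
               chartr("U", "T", revCompRna(mir)),
               randomDnaString(300, seed = 342))
  txs <- Biostrings::DNAStringSet(setNames(tx, "T1"))
  merged <- scanTargets(setNames(mir, "m"), txs, merge = TRUE)
  unmerged <- scanTargets(setNames(mir, "m"), txs, merge = FALSE)
  expect_gte(nrow(unmerged$sites), nrow(merged$sites))
  expect_identical(nrow(merged$sites), 1L)
  expect_equal(merged$sites$score, 0)
})
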