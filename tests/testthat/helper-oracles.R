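# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: structure enumeration is recursive,
# genome scanning is regex-based, and the exact test's reference comes
# from the negative-binomial identity via pnbinom.

## ---- exhaustive nested-structure enumeration (min hairpin loop 3) ----

.structCache <- new.env(parent = emptyenv())

# all pairings of positions 1..w as lists of c(i, j) pairs
enumPairings <- function(w) {
  key <- as.character(w)
  if (!is.null(.structCache[[key]])) return(.structCache[[key]])
  res <- if (w < 5L) list(list()) else {
    out <- enumPairings(w - 1L)                 # position w unpaired
    for (k in seq_len(w - 4L)) {                # w paired with k
      for (a in enumPairings(k - 1L))
        for (b in enumPairings(w - k - 1L))
          out[[length(out) + 1L]] <-
        c(a, lapply(b, function(p) p + k), list(c(k, w)))
    }
    out
  }
  .structCache[[key]] <- res
  res
}

oraclePairValue <- function(a, b) {
  x <- paste0(a, b)
  if (x %in% c("GC", "CG")) 3 else if (x %in% c("AU", "UA")) 2 else
    if (x %in% c("GU", "UG")) 1 else 0
}

# optimal stacking energy by scoring every enumerated structure
oracleFoldMfe <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  best <- 0
  for (ps in enumPairings(length(ch))) {
    if (!length(ps)) next
    vals <- vapply(ps, function(p) oraclePairValue(ch[p[1L]], ch[p[2L]]),
                   numeric(1))
    if (any(vals == 0)) next
    e <- 0
    if (length(ps) > 1L) {
      key <- vapply(ps, function(p) p[1L] * 1000L + p[2L], numeric(1))
      inner <- match(vapply(ps, function(p) (p[1L] + 1L) * 1000L +
                              (p[2L] - 1L), numeric(1)), key)
      st <- which(!is.na(inner))
      if (length(st)) e <- -sum((vals[st] + vals[inner[st]]) / 2)
    }
    if (e < best) best <- e
  }
  best
}

## ---- regex-based exact genome matching ----

oracleRevComp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")

# all (scaffold, start, strand) perfect matches of an RNA tag, both
# strands, overlapping occurrences included
oracleMatch <- function(tagRna, genomeChars) {
  dna <- chartr("U", "T", tagRna)
  out <- NULL
  for (sc in names(genomeChars)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") dna else oracleRevComp(dna)
      hits <- gregexpr(paste0("(?=", pat, ")"), genomeChars[[sc]],
                       perl = TRUE)[[1L]]
      hits <- hits[hits > 0L]
      if (length(hits))
        out <- rbind(out, data.frame(scaffold = sc, start = as.integer(hits),
                                     strand = str))
    }
  }
  out
}

## ---- exact two-library test via the negative-binomial identity ----

oracleAcPvalue <- function(x, y, N1, N2) {
  q <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = q)
  upper <- pnbinom(y - 1, size = x + 1, prob = q, lower.tail = FALSE)
  min(lower, upper, 1)
}

## ---- duplex state classification written out longhand ----

oraclePairState <- function(a, b) {
  if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) "match"
  else if ((a == "G" && b == "U") || (a == "U" && b == "G")) "GU"
  else "mismatch"
}

# per-start minimum penalty for every window length and every explicit
# gap placement: direct summation per placement, no prefix-sum reuse
oracleScanPenalties <- function(mirnaRna, txRna) {
  m <- strsplit(mirnaRna, "", fixed = TRUE)[[1L]]
  tc <- strsplit(txRna, "", fixed = TRUE)[[1L]]
  L <- length(m)
  n <- length(tc)
  wt <- function(i, tIdx) {
    ok <- tIdx >= 1L & tIdx <= n
    w <- rep(Inf, length(tIdx))
    if (any(ok)) {
      cls <- vapply(tc[tIdx[ok]], function(b) oraclePairState(m[i], b), "")
      w[ok] <- ifelse(cls == "match", 0, ifelse(cls == "GU", 0.5, 1))
    }
    w * if (i >= 2L && i <= 13L) 2 else 1
  }
  gapw <- function(g) 2 * if (g >= 2L && g <= 13L) 2 else 1
  nUn <- max(0L, n - L + 1L)
  nDel <- max(0L, n - L + 2L)
  nIns <- max(0L, n - L)
  un <- rep(0, nUn)
  sAll <- seq_len(nDel)
  if (nUn) {
    for (i in seq_len(L)) un <- un + wt(i, seq_len(nUn) + L - i)
  }
  del <- rep(Inf, nDel)
  for (g in seq_len(L)) {
    p <- rep(gapw(g), nDel)
    for (i in seq_len(L)) {
      if (i == g) next
      p <- p + if (i > g) wt(i, sAll + L - i) else wt(i, sAll + L - i - 1L)
    }
    del <- pmin(del, p)
  }
  ins <- rep(Inf, nIns)
  if (nIns) {
    sIns <- seq_len(nIns)
    for (g in seq_len(L - 1L)) {
      p <- rep(gapw(g + 1L), nIns)
      for (i in seq_len(L))
        p <- p + if (i >= g + 1L) wt(i, sIns + L - i) else
          wt(i, sIns + L - i + 1L)
      ins <- pmin(ins, p)
    }
  }
  list(un = un, del = del, ins = ins)
}
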