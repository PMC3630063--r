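## Six-rule plant miRNA target prediction: anti-parallel duplex
## alignment with at most one single-nucleotide gap, a position penalty
## (alignment) score with double-weighted core, and the duplex/perfect
## energy-ratio filter.

## penalty weights per state and the core doubling (miRNA positions 2-13)
.stateWeight <- function(states, positions) {
  w <- ifelse(states == "match", 0,
              ifelse(states == "GU", 0.5, ifelse(states == "gap", 2, 1)))
  w * ifelse(positions >= 2L & positions <= 13L, 2, 1)
}

## mismatch equivalents: mismatch 1, G:U 0.5, gap 1 (no core doubling)
.mmEquiv <- function(states) {
  ifelse(states == "match", 0, ifelse(states == "GU", 0.5, 1))
}

## duplex stacking energies for an aligned column set
.duplexEnergies <- function(mirnaChars, states) {
  val <- .pairValue(states, mirnaChars)
  paired <- states %in% c("match", "GU")
  stacks <- paired[-length(paired)] & paired[-1L]
  mfeDuplex <- -sum((val[-length(val)][stacks] + val[-1L][stacks]) / 2)
  perfectVal <- ifelse(mirnaChars %in% c("G", "C"), 3, 2)
  perfectVal <- perfectVal[!is.na(mirnaChars)]
  mfePerfect <- -sum((perfectVal[-length(perfectVal)] +
                        perfectVal[-1L]) / 2)
  ratio <- if (mfePerfect < 0) mfeDuplex / mfePerfect else NaN
  list(mfeDuplex = mfeDuplex, mfePerfect = mfePerfect, mfeRatio = ratio)
}

## build one gap placement of mirna (chars) against window (chars);
## returns list(states, positions, windowIdx) or NULL if invalid
.placement <- function(m, w, gapAt = NA_integer_, bulgeAfter = NA_integer_) {
  L <- length(m)
  W <- length(w)
  if (!is.na(gapAt)) {            # W == L - 1: miRNA position gapAt unpaired
    states <- character(L)
    positions <- seq_len(L)
    widx <- rep(NA_integer_, L)
    for (i in seq_len(L)) {
      if (i == gapAt) { states[i] <- "gap"; next }
      j <- if (i > gapAt) L - i + 1L else L - i
      widx[i] <- j
      states[i] <- .pairClass(m[i], w[j])
    }
    list(states = states, positions = positions, windowIdx = widx,
         mirnaChar = m)
  } else if (!is.na(bulgeAfter)) { # W == L + 1: target bulge after position g
    g <- bulgeAfter
    states <- character(L + 1L)
    positions <- integer(L + 1L)
    widx <- rep(NA_integer_, L + 1L)
    mc <- rep(NA_character_, L + 1L)
    col <- 0L
    for (i in seq_len(L)) {
      col <- col + 1L
      if (i == g + 1L) {           # insert the bulge column first
        states[col] <- "gap"
        positions[col] <- g + 1L
        widx[col] <- L + 1L - g
        col <- col + 1L
      }
      j <- if (i >= g + 1L) L + 1L - i else L + 2L - i
      states[col] <- .pairClass(m[i], w[j])
      positions[col] <- i
      widx[col] <- j
      mc[col] <- m[i]
    }
    list(states = states, positions = positions, windowIdx = widx,
         mirnaChar = mc)
  } else {                         # W == L: ungapped
    j <- L - seq_len(L) + 1L
    list(states = .pairClass(m, w[j]), positions = seq_len(L),
         windowIdx = j, mirnaChar = m)
  }
}

#' Align a miRNA against a transcript window
#'
#' Anti-parallel alignment of the miRNA (5'->3') against the window
#' (transcript sense strand, 5'->3'): miRNA position 1 pairs the
#' window's 3'-most base. Watson-Crick pairs score as matches, G:U as
#' wobbles, everything else as mismatches. The window may be one base
#' shorter (one miRNA base bulged out, a "gap" column at that miRNA
#' position) or one base longer (one target base bulged, a gap column
#' charged at the following miRNA position) than the miRNA; the single
#' gap is placed to minimise the penalty score, ties resolved toward the
#' largest miRNA position index.
#'
#' @param mirna miRNA sequence (5'->3', RNA or DNA).
#' @param window transcript window (sense strand), length within one
#'   base of the miRNA length.
#' @param mirnaName,transcript,siteStart identifiers recorded in the
#'   result; \code{siteStart} is the window's transcript coordinate.
#' @return a \code{\link[=DuplexAlignment-class]{DuplexAlignment}}.
#' @export
alignDuplex <- function(mirna, window, mirnaName = "miRNA",
                        transcript = "transcript", siteStart = 1L) {
  m <- strsplit(asRna(mirna), "", fixed = TRUE)[[1L]]
  w <- strsplit(asRna(window), "", fixed = TRUE)[[1L]]
  L <- length(m)
  W <- length(w)
  if (abs(W - L) > 1L)
    stop("window length must be within 1 nt of the miRNA length",
         call. = FALSE)
  placements <- if (W == L) list(.placement(m, w)) else if (W == L - 1L)
    lapply(seq_len(L), function(g) .placement(m, w, gapAt = g)) else
      lapply(seq_len(L - 1L), function(g) .placement(m, w, bulgeAfter = g))
  pens <- vapply(placements, function(p)
    sum(.stateWeight(p$states, p$positions)), numeric(1))
  best <- placements[[max(which(pens == min(pens)))]]
  en <- .duplexEnergies(best$mirnaChar, best$states)
  new("DuplexAlignment", mirnaName = mirnaName, mirna = paste(m, collapse = ""),
      transcript = transcript, siteStart = as.integer(siteStart),
      siteEnd = as.integer(siteStart + W - 1L), states = best$states,
      positions = as.integer(best$positions),
      targetPos = as.integer(siteStart - 1L + best$windowIdx),
      penalty = min(pens), mfeDuplex = en$mfeDuplex,
      mfePerfect = en$mfePerfect, mfeRatio = en$mfeRatio)
}

#' Position penalty (alignment) score of a duplex
#'
#' Sum of per-column weights: mismatch 1.0, G:U 0.5, gap 2.0, with every
#' column at miRNA positions 2-13 (the seed/core region) contributing
#' double. Lower is better; 0 iff every column is a Watson-Crick match.
#'
#' @param aln a DuplexAlignment.
#' @return the penalty score (>= 0).
#' @export
penaltyScore <- function(aln) sum(.stateWeight(aln@states, aln@positions))

#' Duplex and perfect-complement energies under the stacking model
#'
#' Applies the stacking energy model of \code{\link{foldRNA}} to the
#' inter-strand stacks of the aligned duplex, and to the miRNA bound to
#' its exact complement; their ratio feeds rule vi. An all-G/C 21-mer
#' against its perfect complement scores 20 stacks x -3.0 = -60.
#'
#' @param aln a DuplexAlignment.
#' @return list: \code{mfeDuplex}, \code{mfePerfect}, \code{mfeRatio}
#'   (NaN when the perfect-complement energy is zero; rule vi then
#'   fails).
#' @export
duplexEnergy <- function(aln) {
  mc <- strsplit(aln@mirna, "", fixed = TRUE)[[1L]]
  ## per-column miRNA characters: gap columns opposite a target bulge
  ## carry no miRNA base
  isBulge <- aln@states == "gap" & !is.na(aln@targetPos)
  full <- rep(NA_character_, length(aln@states))
  full[!isBulge] <- mc[aln@positions[!isBulge]]
  en <- .duplexEnergies(full, aln@states)
  ## perfect complement energy over the full miRNA
  perfectVal <- ifelse(mc %in% c("G", "C"), 3, 2)
  en$mfePerfect <- -sum((perfectVal[-length(perfectVal)] + perfectVal[-1L]) / 2)
  en$mfeRatio <- if (en$mfePerfect < 0) en$mfeDuplex / en$mfePerfect else NaN
  en
}

#' Check the six plant target-prediction rules
#'
#' Rules, with positions counted from the miRNA 5' end and gaps counted
#' like mismatches for adjacency: (i) at most 4 mismatch equivalents
#' overall (mismatch 1, G:U 0.5, gap 1); (ii) no run of more than two
#' adjacent mismatches; (iii) no two adjacent mismatches within
#' positions 2-12; (iv) no mismatch (or gap) at positions 10-11, G:U
#' tolerated; (v) at most 2.5 mismatch equivalents within positions
#' 1-12; (vi) duplex MFE at least \code{mfeRatioMin} (74 percent) of the
#' perfect-complement MFE.
#'
#' @param aln a DuplexAlignment.
#' @param mfeRatioMin rule vi threshold.
#' @return list: \code{pass} (named logical, rules i-vi),
#'   \code{firstFailure} (rule id or NA).
#' @export
checkRules <- function(aln, mfeRatioMin = 0.74) {
  st <- aln@states
  pos <- aln@positions
  mm <- .mmEquiv(st)
  bad <- st %in% c("mismatch", "gap")
  runs <- rle(bad)
  core <- pos >= 2L & pos <= 12L
  adjacentInCore <- any(bad[-length(bad)] & bad[-1L] &
                          core[-length(core)] & core[-1L])
  en <- duplexEnergy(aln)
  pass <- c(
    i = sum(mm) <= 4,
    ii = !any(runs$lengths[runs$values] > 2L),
    iii = !adjacentInCore,
    iv = !any(bad[pos %in% c(10L, 11L)]),
    v = sum(mm[pos >= 1L & pos <= 12L]) <= 2.5,
    vi = is.finite(en$mfeRatio) && en$mfeRatio >= mfeRatioMin)
  list(pass = pass,
       firstFailure = if (all(pass)) NA_character_ else
         names(pass)[which(!pass)[1L]])
}

## minimal penalty per start for each window length (L-1, L, L+1) on
## one transcript; thin wrapper over the C++ sweep
.scanPenalties <- function(mInt, tInt) .scan_penalties_cpp(mInt, tInt)

#' Scan a transcriptome for miRNA target sites
#'
#' Slides every window of the miRNA length and one base either side
#' across each transcript, aligns it (\code{\link{alignDuplex}}), and
#' keeps sites that pass rules i-vi with penalty score below
#' \code{scoreCutoff}. Overlapping sites of one miRNA on one transcript
#' are merged keeping the lowest score; output is sorted by (score,
#' transcript, position).
#'
#' @param mirnas named character vector of miRNA sequences (or path to a
#'   FASTA file).
#' @param transcripts DNAStringSet or path to a transcriptome FASTA.
#' @param scoreCutoff penalty score cutoff (sites with score <
#'   \code{scoreCutoff} are kept). 2.5 is the de novo prediction
#'   default; degradome-supported confirmation conventionally relaxes
#'   this to 4.
#' @param mfeRatioMin rule vi threshold.
#' @param merge merge overlapping sites (the documented behaviour);
#'   disable to obtain every passing window.
#' @return list with \code{sites} (data.frame: mirna, transcript,
#'   siteStart, siteEnd, score, mfeRatio, and logical rule columns) and
#'   \code{alignments} (list of DuplexAlignment, parallel to rows).
#' @export
scanTargets <- function(mirnas, transcripts, scoreCutoff = 2.5,
                        mfeRatioMin = 0.74, merge = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  if (is.character(mirnas) && length(mirnas) == 1L && file.exists(mirnas))
    mirnas <- as.character(Biostrings::readDNAStringSet(mirnas))
  mirnas <- setNames(asRna(mirnas),
                     if (is.null(names(mirnas)))
                       paste0("miRNA_", seq_along(mirnas)) else names(mirnas))
  txChar <- lapply(as.character(transcripts), function(s)
    strsplit(asRna(s), "", fixed = TRUE)[[1L]])
  txInt <- lapply(txChar, function(v) match(v, .RNA_ALPHABET) - 1L)
  rows <- list()
  alns <- list()
  for (mn in names(mirnas)) {
    mInt <- .encodeRna(mirnas[[mn]])
    L <- length(mInt)
    for (tn in names(txChar)) {
      tc <- txChar[[tn]]
      pen <- .scanPenalties(mInt, txInt[[tn]])
      hitDf <- function(p, w) {
        s <- which(p < scoreCutoff)
        if (length(s)) data.frame(s = s, w = w) else NULL
      }
      cand <- rbind(hitDf(pen$un, L), hitDf(pen$del, L - 1L),
                    hitDf(pen$ins, L + 1L))
      if (is.null(cand) || !nrow(cand)) next
      for (r in seq_len(nrow(cand))) {
        s <- cand$s[r]
        w <- cand$w[r]
        window <- paste(tc[s:(s + w - 1L)], collapse = "")
        aln <- alignDuplex(mirnas[[mn]], window, mirnaName = mn,
                           transcript = tn, siteStart = s)
        if (aln@penalty >= scoreCutoff) next
        rules <- checkRules(aln, mfeRatioMin = mfeRatioMin)
        if (!all(rules$pass)) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mn, transcript = tn, siteStart = s,
          siteEnd = s + w - 1L, score = aln@penalty,
          mfeRatio = aln@mfeRatio, t(rules$pass))
        alns[[length(alns) + 1L]] <- aln
      }
    }
  }
  if (!length(rows))
    return(list(sites = data.frame(
      mirna = character(0), transcript = character(0),
      siteStart = integer(0), siteEnd = integer(0), score = numeric(0),
      mfeRatio = numeric(0)), alignments = list()))
  sites <- do.call(rbind, rows)
  o <- order(sites$score, sites$mirna, sites$transcript, sites$siteStart)
  sites <- sites[o, , drop = FALSE]
  alns <- alns[o]
  if (merge) {
    keep <- logical(nrow(sites))
    for (r in seq_len(nrow(sites))) {
      prior <- which(keep & sites$mirna == sites$mirna[r] &
                       sites$transcript == sites$transcript[r])
      overlaps <- any(sites$siteStart[prior] <= sites$siteEnd[r] &
                        sites$siteEnd[prior] >= sites$siteStart[r])
      keep[r] <- !overlaps
    }
    sites <- sites[keep, , drop = FALSE]
    alns <- alns[keep]
  }
  o <- order(sites$score, sites$transcript, sites$siteStart, sites$mirna)
  rownames(sites) <- NULL
  list(sites = sites[o, , drop = FALSE], alignments = alns[o])
}
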