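## Degradome (PARE) analysis: map read 5' ends onto transcripts, detect
## miRNA-guided cleavage at the base paired to miRNA position 10,
## classify events into categories I/II/III, and assess significance
## against composition-preserving miRNA shuffles.

#' Map degradome reads onto transcripts
#'
#' Each read contributes one count at position p of every transcript
#' whose sense strand contains the read's first \code{anchor} nt
#' starting at p (multi-mapped reads are counted once per matching
#' transcript). Reads shorter than \code{anchor} after optional adapter
#' removal are dropped.
#'
#' @param fastq path to the degradome FASTQ, or a data.frame from
#'   \code{\link{readFastq}}.
#' @param transcripts DNAStringSet or path to a transcriptome FASTA.
#' @param anchor number of 5' bases used for exact matching.
#' @param adapter optional 3' adapter to trim first (as in
#'   \code{\link{cleanAndCollapse}}).
#' @return named list of integer vectors, one per transcript, of
#'   per-position 5'-end counts (the degradome profiles).
#' @export
mapDegradome <- function(fastq, transcripts, anchor = 20L, adapter = NULL) {
  if (is.character(fastq)) fastq <- readFastq(fastq)
  if (is.character(transcripts) && length(transcripts) == 1L)
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  names(transcripts) <- sub("\\s.*", "", names(transcripts))
  seqs <- asDna(fastq$seq)
  if (!is.null(adapter)) {
    key <- substr(asDna(adapter), 1L, 8L)
    pos <- regexpr(key, seqs, fixed = TRUE)
    seqs <- substr(seqs, 1L, ifelse(pos > 0L, pos - 1L, nchar(seqs)))
  }
  seqs <- seqs[nchar(seqs) >= anchor]
  profiles <- lapply(Biostrings::width(transcripts), integer)
  names(profiles) <- names(transcripts)
  if (!length(seqs)) return(profiles)
  anchors <- substr(seqs, 1L, anchor)
  tab <- table(anchors)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(names(tab)))
  counts <- as.integer(tab)
  for (tn in names(transcripts)) {
    m <- Biostrings::matchPDict(pd, transcripts[[tn]])
    hit <- which(lengths(m) > 0L)
    for (k in hit) {
      starts <- BiocGenerics::start(m[[k]])
      profiles[[tn]][starts] <- profiles[[tn]][starts] + counts[k]
    }
  }
  profiles
}

#' Detect a miRNA-guided cleavage event
#'
#' The expected cleavage site is the transcript base paired to miRNA
#' position 10 counted from the miRNA 5' end (for a contiguous site this
#' is \code{siteEnd - 9}). An event is emitted iff the degradome profile
#' has at least one read 5' end exactly at that position; if the
#' alignment leaves position 10 unpaired (gap), no site is defined and
#' NULL is returned.
#'
#' @param aln a \code{DuplexAlignment} that passed the degradome-mode
#'   score cutoff.
#' @param profile integer vector of 5'-end counts for
#'   \code{aln@transcript}.
#' @return list (mirna, transcript, cleavage, reads, penalty) or NULL.
#' @export
detectCleavage <- function(aln, profile) {
  col <- which(aln@positions == 10L & aln@states != "gap")
  col <- col[!is.na(aln@targetPos[col])]
  if (!length(col)) return(NULL)
  site <- aln@targetPos[col[1L]]
  if (site < 1L || site > length(profile)) return(NULL)
  reads <- profile[site]
  if (reads < 1L) return(NULL)
  list(mirna = aln@mirnaName, transcript = aln@transcript,
       cleavage = site, reads = reads, penalty = aln@penalty)
}

#' Classify a cleavage event into category I, II or III
#'
#' Relative to the transcript's degradome profile: category I when the
#' read abundance at the cleavage site is the transcript maximum (ties
#' with the maximum count as I); category II when it is not the maximum
#' but at least the transcript median; category III when it is below
#' the median. By default the maximum and median are computed over
#' positions with at least one read; \code{medianOver = "all"} includes
#' zero positions (which drives nearly every event to category II on
#' sparse profiles, hence the detected-position default).
#'
#' @param event list from \code{\link{detectCleavage}} (or any list with
#'   \code{cleavage} and \code{reads}).
#' @param profile the transcript's degradome profile.
#' @param medianOver positions used for the max/median reference.
#' @return "I", "II" or "III".
#' @export
categorizeCleavage <- function(event, profile,
                               medianOver = c("detected", "all")) {
  medianOver <- match.arg(medianOver)
  if (!any(profile >= 1L))
    stop("empty degradome profile: no event can exist", call. = FALSE)
  ref <- if (medianOver == "detected") profile[profile >= 1L] else profile
  mx <- max(ref)
  md <- median(ref)
  if (event$reads >= mx) "I" else if (event$reads >= md) "II" else "III"
}

## composition-preserving shuffle success check for one shuffled miRNA
.shuffleHits <- function(shuffled, transcripts, profiles, maxScore,
                         minReads, mfeRatioMin, ctx = NULL) {
  if (maxScore <= 0 && !is.null(ctx)) {
    ## a score of 0 forces a perfect Watson-Crick duplex: exact match of
    ## the reverse complement, so plain string matching suffices; the
    ## transcripts are concatenated with N spacers so one matchPattern
    ## call covers the whole transcriptome
    pat <- Biostrings::DNAString(asDna(revCompRna(shuffled)))
    m <- Biostrings::matchPattern(pat, ctx$subject)
    if (!length(m)) return(FALSE)
    ends <- BiocGenerics::end(m)
    ti <- findInterval(ends, ctx$starts)
    local <- ends - ctx$starts[ti] + 1L
    site <- local - 9L
    for (k in seq_along(ti)) {
      prof <- profiles[[ctx$names[ti[k]]]]
      if (site[k] >= 1L && site[k] <= length(prof) &&
          prof[site[k]] >= minReads) return(TRUE)
    }
    return(FALSE)
  }
  hits <- scanTargets(setNames(shuffled, "shuffle"), transcripts,
                      scoreCutoff = maxScore + 1e-9,
                      mfeRatioMin = mfeRatioMin, merge = FALSE)
  for (k in seq_along(hits$alignments)) {
    aln <- hits$alignments[[k]]
    if (aln@penalty > maxScore) next
    ev <- detectCleavage(aln, profiles[[aln@transcript]])
    if (!is.null(ev) && ev$reads >= minReads) return(TRUE)
  }
  FALSE
}

#' Shuffled-miRNA empirical p-value for a cleavage event
#'
#' Shuffles the miRNA sequence (composition-preserving permutations,
#' seeded) \code{nShuffles} times and asks how often a shuffle achieves
#' any cleavage event at least as good as the observed one (penalty
#' score <= observed and reads at site >= observed). With a +1
#' pseudocount, p = (1 + successes) / (1 + nShuffles), avoiding p = 0 at
#' finite shuffle counts.
#'
#' @param mirna observed miRNA sequence.
#' @param transcripts DNAStringSet (or FASTA path).
#' @param profiles degradome profiles from \code{\link{mapDegradome}}.
#' @param observedScore,observedReads the observed event's penalty score
#'   and read support.
#' @param nShuffles number of shuffles.
#' @param seed integer seed.
#' @param mfeRatioMin rule vi threshold used when rescanning shuffles.
#' @return the empirical p-value in (0, 1].
#' @export
shufflePvalue <- function(mirna, transcripts, profiles, observedScore,
                          observedReads, nShuffles = 100L, seed = 1L,
                          mfeRatioMin = 0.74) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  names(transcripts) <- sub("\\s.*", "", names(transcripts))
  chars <- strsplit(asRna(mirna), "", fixed = TRUE)[[1L]]
  ctx <- NULL
  if (observedScore <= 0) {
    seqs <- as.character(transcripts)
    spacer <- strrep("N", length(chars) + 4L)
    ctx <- list(
      subject = Biostrings::DNAString(paste(seqs, collapse = spacer)),
      starts = cumsum(c(1L, utils::head(nchar(seqs) + nchar(spacer), -1L))),
      names = names(seqs))
  }
  set.seed(as.integer(seed))
  successes <- 0L
  for (k in seq_len(nShuffles)) {
    shuffled <- paste(sample(chars), collapse = "")
    if (.shuffleHits(shuffled, transcripts, profiles, observedScore,
                     observedReads, mfeRatioMin, ctx = ctx))
      successes <- successes + 1L
  }
  (1 + successes) / (1 + nShuffles)
}

#' Per-position table for a target plot (T-plot)
#'
#' @param profile a transcript degradome profile.
#' @param event optional event whose cleavage position is flagged.
#' @return data.frame: position, count, site (logical); positions with
#'   zero counts are kept so the plot shows the full transcript.
#' @export
tplotTable <- function(profile, event = NULL) {
  out <- data.frame(position = seq_along(profile), count = profile,
                    site = logical(length(profile)))
  if (!is.null(event)) out$site[event$cleavage] <- TRUE
  out
}

#' Degradome-supported target confirmation for a set of miRNAs
#'
#' Scans the transcriptome in degradome mode (relaxed score cutoff),
#' detects cleavage events supported by the profiles, classifies them
#' and attaches shuffled-miRNA p-values.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts DNAStringSet or FASTA path.
#' @param profiles degradome profiles from \code{\link{mapDegradome}}.
#' @param scoreCutoff degradome-mode penalty cutoff (sites with score <
#'   cutoff are considered).
#' @param nShuffles,seed see \code{\link{shufflePvalue}}.
#' @param medianOver see \code{\link{categorizeCleavage}}.
#' @return data.frame: mirna, transcript, category, cleavage, reads,
#'   score, shuffleP (one row per event).
#' @export
runDegradome <- function(mirnas, transcripts, profiles, scoreCutoff = 4,
                         nShuffles = 100L, seed = 1L,
                         medianOver = "detected") {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  names(transcripts) <- sub("\\s.*", "", names(transcripts))
  scan <- scanTargets(mirnas, transcripts, scoreCutoff = scoreCutoff,
                      merge = TRUE)
  rows <- list()
  for (k in seq_along(scan$alignments)) {
    aln <- scan$alignments[[k]]
    ev <- detectCleavage(aln, profiles[[aln@transcript]])
    if (is.null(ev)) next
    cat3 <- categorizeCleavage(ev, profiles[[aln@transcript]],
                               medianOver = medianOver)
    sp <- shufflePvalue(mirnas[[ev$mirna]], transcripts, profiles,
                        observedScore = ev$penalty,
                        observedReads = ev$reads,
                        nShuffles = nShuffles,
                        seed = .deriveSeed(seed, k))
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = ev$mirna, transcript = ev$transcript, category = cat3,
      cleavage = ev$cleavage, reads = ev$reads, score = ev$penalty,
      shuffleP = sp)
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), transcript = character(0),
                      category = character(0), cleavage = integer(0),
                      reads = integer(0), score = numeric(0),
                      shuffleP = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$score, out$transcript, out$cleavage), , drop = FALSE]
}
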