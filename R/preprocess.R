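## Small-RNA preprocessing: adapter cleaning, collapsing to unique tags,
## perfect-match genome mapping, annotation by precedence, length
## statistics and siRNA-like duplex detection.

#' Clean reads and collapse them into unique tags
#'
#' Removes the 3' adapter at the leftmost exact occurrence of its first
#' 8 nt (shorter suffix overlaps are left untrimmed, which keeps trimming
#' deterministic), drops inserts outside \code{[minLen, maxLen]} or with
#' mean Phred quality below \code{minQual}, maps T to U, and merges
#' identical sequences with summed counts.
#'
#' @param fastq path to a FASTQ file, or a data.frame as returned by
#'   \code{\link{readFastq}}.
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param minLen,maxLen retained insert length range (nt).
#' @param minQual minimum mean Phred score over the insert.
#' @return data.frame with columns \code{seq} (RNA) and \code{count},
#'   sorted by sequence.
#' @export
cleanAndCollapse <- function(fastq, adapter, minLen = 18L, maxLen = 30L,
                             minQual = 20) {
  stopifnot(nchar(adapter) >= 8L)
  if (is.character(fastq)) fastq <- readFastq(fastq)
  if (nrow(fastq) == 0L)
    return(data.frame(seq = character(0), count = integer(0)))
  key <- substr(asDna(adapter), 1L, 8L)
  pos <- regexpr(key, fastq$seq, fixed = TRUE)
  insLen <- ifelse(pos > 0L, pos - 1L, nchar(fastq$seq))
  seqs <- substr(fastq$seq, 1L, insLen)
  quals <- substr(fastq$qual, 1L, insLen)
  keep <- insLen >= minLen & insLen <= maxLen
  keep[keep] <- .meanPhred(quals[keep]) >= minQual
  if (!any(keep))
    return(data.frame(seq = character(0), count = integer(0)))
  tab <- table(asRna(seqs[keep]))
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out[order(out$seq, method = "radix"), , drop = FALSE]
}

## exact matching of tags against both genome strands; returns a
## GRangesList parallel to `tags`
.matchGenome <- function(tags, genome) {
  dna <- asDna(tags)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(dna)))
  tagIdx <- integer(0)
  scaff <- character(0)
  st <- integer(0)
  strandVec <- character(0)
  widthVec <- integer(0)
  for (strandChar in c("+", "-")) {
    qry <- if (strandChar == "+") dna else rc
    for (w in unique(nchar(qry))) {
      idx <- which(nchar(qry) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(qry[idx]))
      for (sc in seq_along(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[sc]])
        starts <- Biostrings::startIndex(m)
        nm <- lengths(starts)
        if (!sum(nm)) next
        tagIdx <- c(tagIdx, rep(idx, nm))
        scaff <- c(scaff, rep(names(genome)[sc], sum(nm)))
        st <- c(st, unlist(starts, use.names = FALSE))
        strandVec <- c(strandVec, rep(strandChar, sum(nm)))
        widthVec <- c(widthVec, rep(w, sum(nm)))
      }
    }
  }
  gr <- GRanges(scaff, IRanges(st, width = widthVec), strand = strandVec)
  S4Vectors::split(gr, factor(tagIdx, levels = seq_along(tags)))
}

#' Map tags to the genome by perfect match
#'
#' Reports every exact-match locus of each tag on either strand
#' (reverse-strand hits are loci whose reverse complement equals the
#' tag). Tags with no hit, and tags exceeding \code{maxHits} loci
#' (repeat-derived), are marked \code{unmapped} and excluded from
#' downstream discovery; multi-hit tags additionally have their hit list
#' emptied.
#'
#' @param tags a \code{\link[=TagSet-class]{TagSet}}.
#' @param genome DNAStringSet or path to a genome FASTA.
#' @param maxHits maximum tolerated number of loci per tag.
#' @return the TagSet with \code{hits} filled and \code{annotation} set
#'   to \code{unmapped} where appropriate.
#' @export
mapTags <- function(tags, genome, maxHits = 20L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  hits <- .matchGenome(tags@sequence, genome)
  n <- lengths(hits)
  ann <- tags@annotation
  ann[n == 0L] <- "unmapped"
  over <- n > maxHits
  ann[over] <- "unmapped"
  hits[over] <- GRangesList(GRanges())
  new("TagSet", sequence = tags@sequence, countControl = tags@countControl,
      countDrought = tags@countDrought, annotation = ann, hits = hits)
}

## does tag t match catalog mature m with <= 2 nt shift at either end?
.knownShiftMatch <- function(tags, mature) {
  out <- logical(length(tags))
  lt <- nchar(tags)
  lm <- nchar(mature)
  for (o in -2:2) {
    i1 <- pmax(1L, 1L - o)
    i2 <- pmin(lt, lm - o)
    leftDiff <- abs(o)
    rightDiff <- abs(lm - o - lt)
    ok <- i2 - i1 >= 14L & leftDiff <= 2L & rightDiff <= 2L
    cand <- which(ok & !out)
    if (length(cand)) {
      same <- substr(tags[cand], i1[cand], i2[cand]) ==
        substr(rep(mature, length(cand)), i1[cand] + o, i2[cand] + o)
      out[cand[same]] <- TRUE
    }
  }
  out
}

#' Annotate mapped tags by precedence
#'
#' Assigns exactly one label per tag: \code{structural} when any genome
#' hit overlaps an annotated structural-RNA locus (rRNA, tRNA, snRNA,
#' snoRNA...), else \code{known_mirna} when the tag sequence matches a
#' catalog mature exactly or shifted by at most 2 nt at either end
#' (isomiR-style end variation), else \code{candidate}. Unmapped tags
#' keep their \code{unmapped} label.
#'
#' @param tags a mapped TagSet (see \code{\link{mapTags}}).
#' @param annotation GRanges of structural loci, or path to a GFF3 file.
#' @param known character vector of catalog mature sequences (or path to
#'   a FASTA file). May be empty.
#' @return the TagSet with \code{annotation} filled.
#' @export
annotateTags <- function(tags, annotation, known = character(0)) {
  if (is.character(annotation)) {
    annotation <- tryCatch(suppressWarnings(rtracklayer::import(annotation)),
                           error = function(e)
                             stop("invalid GFF3 annotation (", conditionMessage(e),
                                  ")", call. = FALSE))
  }
  if (is.character(known) && length(known) == 1L && file.exists(known))
    known <- as.character(Biostrings::readDNAStringSet(known))
  known <- asRna(unname(known))
  ann <- tags@annotation
  mapped <- which(ann != "unmapped")
  if (length(mapped)) {
    flat <- unlist(tags@hits[mapped])
    ov <- IRanges::overlapsAny(flat, annotation, ignore.strand = TRUE)
    grp <- rep(mapped, lengths(tags@hits[mapped]))
    structural <- unique(grp[ov])
    ann[mapped] <- "candidate"
    if (length(known)) {
      isKnown <- Reduce(`|`, lapply(known, function(m)
        .knownShiftMatch(tags@sequence, m)), logical(length(tags)))
      ann[mapped][isKnown[mapped]] <- "known_mirna"
    }
    ann[structural] <- "structural"
  }
  new("TagSet", sequence = tags@sequence, countControl = tags@countControl,
      countDrought = tags@countDrought, annotation = ann, hits = tags@hits)
}

#' Per-length unique/redundant statistics
#'
#' For each insert length, the number of distinct tags (unique), the
#' summed read count (redundant), and their ratio (0 where no tag of that
#' length exists). The ratio profile highlights length classes whose
#' members are individually highly expressed, the signature of mature
#' miRNA sizes.
#'
#' @param tags a TagSet.
#' @param library count column to use: both libraries summed, or one.
#' @return data.frame with columns \code{length}, \code{unique},
#'   \code{redundant}, \code{ratio}.
#' @export
lengthStats <- function(tags, library = c("both", "control", "drought")) {
  library <- match.arg(library)
  counts <- switch(library, both = tags@countControl + tags@countDrought,
                   control = tags@countControl, drought = tags@countDrought)
  lens <- nchar(tags@sequence)
  rng <- if (length(lens)) seq(min(lens), max(lens)) else integer(0)
  uniq <- vapply(rng, function(l) sum(lens == l), integer(1))
  red <- vapply(rng, function(l) sum(counts[lens == l]), integer(1))
  data.frame(length = rng, unique = uniq, redundant = red,
             ratio = ifelse(uniq > 0, red / uniq, 0))
}

#' Detect siRNA-like duplexes among mapped tags
#'
#' Reports pairs of 22-24 nt tags mapped to the same locus on opposite
#' strands such that each tag's 3' end extends exactly 2 nt beyond the
#' complementary region of the other (for a plus-strand hit
#' \code{[s, e]}, the partner minus-strand hit is \code{[s - 2, e - 2]}).
#' Both members are annotated \code{sirna_candidate} unless already
#' structural or known.
#'
#' @param tags a mapped TagSet.
#' @return list with \code{pairs} (data.frame: plusTag, minusTag,
#'   scaffold, plusStart, plusEnd) and \code{tags} (the re-annotated
#'   TagSet).
#' @export
sirnaDuplexScan <- function(tags) {
  lens <- nchar(tags@sequence)
  eligible <- which(lens >= 22L & lens <= 24L & lengths(tags@hits) > 0L)
  pairs <- list()
  if (length(eligible)) {
    flat <- unlist(tags@hits[eligible])
    tagIdx <- rep(eligible, lengths(tags@hits[eligible]))
    plus <- as.character(strand(flat)) == "+"
    keyPlus <- sprintf("%s:%d:%d", as.character(seqnames(flat))[plus],
                       start(flat)[plus], end(flat)[plus])
    keyMinus <- sprintf("%s:%d:%d", as.character(seqnames(flat))[!plus],
                        start(flat)[!plus] + 2L, end(flat)[!plus] + 2L)
    m <- match(keyPlus, keyMinus)
    hitP <- which(!is.na(m))
    if (length(hitP)) {
      pi <- tagIdx[plus][hitP]
      mi <- tagIdx[!plus][m[hitP]]
      pairs <- data.frame(
        plusTag = tags@sequence[pi], minusTag = tags@sequence[mi],
        scaffold = as.character(seqnames(flat))[plus][hitP],
        plusStart = start(flat)[plus][hitP],
        plusEnd = end(flat)[plus][hitP])
      ann <- tags@annotation
      member <- unique(c(pi, mi))
      upd <- member[!ann[member] %in% c("structural", "known_mirna")]
      ann[upd] <- "sirna_candidate"
      tags <- new("TagSet", sequence = tags@sequence,
                  countControl = tags@countControl,
                  countDrought = tags@countDrought, annotation = ann,
                  hits = tags@hits)
    }
  }
  if (!length(pairs))
    pairs <- data.frame(plusTag = character(0), minusTag = character(0),
                        scaffold = character(0), plusStart = integer(0),
                        plusEnd = integer(0))
  list(pairs = pairs, tags = tags)
}

#' Serialize collapsed tags as FASTA
#'
#' Headers follow the \code{tag{i}_x{control}_y{drought}} convention.
#'
#' @param tags a TagSet.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeTagFasta <- function(tags, path) {
  hdr <- sprintf("tag%d_x%d_y%d", seq_along(tags@sequence),
                 tags@countControl, tags@countDrought)
  writeLines(paste0(">", hdr, "\n", tags@sequence), path)
  invisible(path)
}

#' @rdname writeTagFasta
#' @export
readTagFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- regmatches(names(x),
                      regexec("^tag\\d+_x(\\d+)_y(\\d+)$", names(x)))
  cc <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  cd <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
  seqs <- unname(asRna(as.character(x)))
  o <- order(seqs, method = "radix")
  new("TagSet", sequence = seqs[o], countControl = cc[o],
      countDrought = cd[o],
      annotation = rep("candidate", length(seqs)),
      hits = GRangesList(rep(list(GRanges()), length(seqs))))
}
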