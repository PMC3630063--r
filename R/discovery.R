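## Novel miRNA discovery: excise candidate precursors around mapped tags,
## fold them, locate the star strand from the duplex geometry, and apply
## the Meyers-style plant miRNA criteria.

## extract the stranded genomic sequence of [s, e] as RNA (5'->3')
.genomicRna <- function(genome, scaffold, s, e, strandChar) {
  seg <- as.character(Biostrings::subseq(genome[[scaffold]], s, e))
  if (strandChar == "-")
    seg <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seg)))
  asRna(seg)
}

#' Excise and fold candidate precursor windows around a tag locus
#'
#' Tries windows that put the tag on the 5' arm (extending 3') and on the
#' 3' arm (extending 5'), with window lengths stepped 60 to
#' \code{flankMax} by 20. Each window is folded; a window is kept when
#' the tag lies on one arm of a single major stem, i.e. at least 16 of
#' its nucleotides are paired and all of them open (or all close) pairs.
#' Per arm, the best window is retained: lowest MFE, ties to the shorter
#' window.
#'
#' @param locus a length-1 GRanges of the tag's genomic hit (stranded).
#' @param genome DNAStringSet.
#' @param flankMax largest window length tried (nt).
#' @param backend optional folding backend, see \code{\link{foldRNA}}.
#' @return list of \code{\link[=HairpinCandidate-class]{HairpinCandidate}}
#'   (possibly empty).
#' @export
exciseAndFold <- function(locus, genome, flankMax = 280L, backend = NULL) {
  stopifnot(is(locus, "GRanges"), length(locus) == 1L)
  sc <- as.character(seqnames(locus))
  strandChar <- as.character(strand(locus))
  if (strandChar == "*") strandChar <- "+"
  tagLen <- width(locus)
  scLen <- length(genome[[sc]])
  best <- list("5p" = NULL, "3p" = NULL)
  for (w in seq(60L, flankMax, by = 20L)) {
    for (arm in c("5p", "3p")) {
      extend3 <- (arm == "5p")
      if (extend3 == (strandChar == "+")) {
        s <- start(locus); e <- min(scLen, start(locus) + w - 1L)
      } else {
        e <- end(locus); s <- max(1L, end(locus) - w + 1L)
      }
      if (e - s + 1L < 60L) next
      seq <- .genomicRna(genome, sc, s, e, strandChar)
      fold <- foldRNA(seq, backend = backend)
      tagOffset <- if (extend3) 1L else nchar(seq) - tagLen + 1L
      tagChars <- strsplit(substr(fold$structure, tagOffset,
                                  tagOffset + tagLen - 1L), "",
                           fixed = TRUE)[[1L]]
      nPaired <- sum(tagChars != ".")
      oneArm <- all(tagChars %in% c(".", "(")) || all(tagChars %in% c(".", ")"))
      if (nPaired < 16L || !oneArm) next
      ## single major stem: the tag's partners must form one compact
      ## block on the opposite arm (random-sequence pairings scatter
      ## across many short helices and fail this)
      partner <- pairingTable(fold$structure)
      tagPos <- tagOffset:(tagOffset + tagLen - 1L)
      paired <- !is.na(partner[tagPos])
      partners <- partner[tagPos][paired]
      if (diff(range(partners)) > tagLen + 4L) next
      ## near-constant helix register: position + partner is constant on
      ## a perfect stem and drifts only by small bulges on a real duplex
      register <- tagPos[paired] + partners
      if (diff(range(register)) > 2L) next
      ## stems are Watson-Crick dominated (>= 80 percent), as in real
      ## miRNA precursors; G:U-heavy chance helices are not stems
      sChars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      wc <- paste0(sChars[tagPos[paired]], sChars[partners]) %in%
        c("AU", "UA", "GC", "CG")
      if (mean(wc) < 0.8) next
      armObs <- if (any(tagChars == "(")) "5p" else "3p"
      cand <- new("HairpinCandidate", sequence = seq,
                  structure = fold$structure, mfe = fold$mfe,
                  locus = GRanges(sc, IRanges(s, e), strand = strandChar),
                  matureStart = tagOffset, matureLength = tagLen,
                  starStart = NA_integer_, starLength = NA_integer_,
                  arm = armObs)
      cur <- best[[armObs]]
      if (is.null(cur) || fold$mfe < cur@mfe ||
          (fold$mfe == cur@mfe &&
           nchar(seq) < nchar(cur@sequence)))
        best[[armObs]] <- cand
    }
  }
  Filter(Negate(is.null), unname(best))
}

#' Locate the star strand of a hairpin candidate
#'
#' Given the mature position on one arm, the star is the segment pairing
#' the mature in the predicted structure, shifted so that each strand's
#' 3' end extends 2 nt beyond the other's paired region (2-nt 3'
#' overhangs on both ends, the duplex geometry Dicer processing leaves).
#' At least 12 mature nucleotides must be paired, otherwise no star is
#' definable and an error is raised.
#'
#' @param hairpin a \code{HairpinCandidate}.
#' @param matureStart,matureLength mature offset within the precursor
#'   (defaults to the candidate's recorded placement).
#' @return the HairpinCandidate with \code{starStart}/\code{starLength}
#'   filled; the star sequence is
#'   \code{substr(sequence, starStart, starStart + starLength - 1)}.
#' @export
findStar <- function(hairpin, matureStart = hairpin@matureStart,
                     matureLength = hairpin@matureLength) {
  partner <- pairingTable(hairpin@structure)
  L <- matureLength
  pos <- matureStart:(matureStart + L - 1L)
  paired <- which(!is.na(partner[pos]))
  if (length(paired) < 12L)
    stop("mature is mostly unpaired (<12 paired nt): no star definable",
         call. = FALSE)
  pairedDuplex <- paired[paired <= L - 2L]
  if (!length(pairedDuplex))
    stop("mature 5' region unpaired: no star definable", call. = FALSE)
  iMin <- min(pairedDuplex)
  iMax <- max(pairedDuplex)
  n <- nchar(hairpin@sequence)
  starEnd <- partner[pos[iMin]] + (iMin - 1L) + 2L
  starStart <- partner[pos[iMax]] - ((L - 2L) - iMax)
  starStart <- max(1L, starStart)
  starEnd <- min(n, starEnd)
  if (starEnd <= starStart)
    stop("degenerate star placement", call. = FALSE)
  hairpin@starStart <- as.integer(starStart)
  hairpin@starLength <- as.integer(starEnd - starStart + 1L)
  hairpin
}

#' @describeIn findStar the star sequence of a candidate with star
#'   placement filled.
#' @export
starSequence <- function(hairpin) {
  stopifnot(!is.na(hairpin@starStart))
  substr(hairpin@sequence, hairpin@starStart,
         hairpin@starStart + hairpin@starLength - 1L)
}

#' Evaluate a hairpin candidate against the plant miRNA criteria
#'
#' A candidate is accepted as a novel miRNA iff (a) its star sequence is
#' observed among the tags with count >= 1, (b) the mature::star duplex
#' has at most 4 mismatched positions and no bulge longer than 2 nt
#' (measured on the mature nucleotides engaged in the duplex), (c) the
#' 2-nt 3' overhang geometry holds (guaranteed by
#' \code{\link{findStar}}'s placement when it succeeds), and (d) the
#' precursor MFE under the configured folding backend is at most
#' \code{mfeThreshold}. Rejections name the first failed criterion.
#'
#' @param hairpin a HairpinCandidate with star placement filled.
#' @param tags a TagSet (star evidence is looked up here).
#' @param mfeThreshold MFE acceptance threshold (kcal/mol, model units).
#' @return a list: \code{accepted} (logical), \code{reason} (NA when
#'   accepted), \code{mature}, \code{star}, \code{starCounts} (control,
#'   drought), \code{hairpin}.
#' @export
evaluateMeyers <- function(hairpin, tags, mfeThreshold = -30) {
  mature <- substr(hairpin@sequence, hairpin@matureStart,
                   hairpin@matureStart + hairpin@matureLength - 1L)
  star <- starSequence(hairpin)
  reject <- function(reason)
    list(accepted = FALSE, reason = reason, mature = mature, star = star,
         starCounts = c(control = 0L, drought = 0L), hairpin = hairpin)

  i <- match(star, tags@sequence)
  starCounts <- if (is.na(i)) c(control = 0L, drought = 0L) else
    c(control = tags@countControl[i], drought = tags@countDrought[i])
  if (sum(starCounts) < 1L) return(reject("no star evidence"))

  partner <- pairingTable(hairpin@structure)
  pos <- hairpin@matureStart:(hairpin@matureStart + hairpin@matureLength - 1L)
  duplexPos <- pos[seq_len(hairpin@matureLength - 2L)]
  unpaired <- is.na(partner[duplexPos])
  if (sum(unpaired) > 4L) return(reject("duplex mismatches"))
  runs <- rle(unpaired)
  if (any(runs$lengths[runs$values] > 2L)) return(reject("duplex bulge"))
  if (hairpin@starStart < 1L ||
      hairpin@starStart + hairpin@starLength - 1L > nchar(hairpin@sequence))
    return(reject("overhang geometry"))
  if (hairpin@mfe > mfeThreshold) return(reject("MFE above threshold"))
  list(accepted = TRUE, reason = NA_character_, mature = mature,
       star = star, starCounts = starCounts, hairpin = hairpin)
}

#' Discover novel miRNAs from a mapped, annotated TagSet
#'
#' Runs \code{\link{exciseAndFold}}, \code{\link{findStar}} and
#' \code{\link{evaluateMeyers}} over every candidate-annotated tag of
#' mature length (19-24 nt) and collects accepted novel miRNAs and a
#' rejection log. Multiple hits of one tag are evaluated independently;
#' duplicate accepted loci are collapsed.
#'
#' @param tags a mapped and annotated TagSet.
#' @param genome DNAStringSet or path to the genome FASTA.
#' @param mfeThreshold see \code{\link{evaluateMeyers}}.
#' @param flankMax see \code{\link{exciseAndFold}}.
#' @param backend optional folding backend.
#' @return list with \code{novel} (data.frame: name, sequence,
#'   countControl, countDrought, starCountControl, starCountDrought,
#'   location, arm, lp, mfe) and \code{rejections} (data.frame: sequence,
#'   location, reason).
#' @export
discoverNovelMirnas <- function(tags, genome, mfeThreshold = -30,
                                flankMax = 280L, backend = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  candIdx <- which(tags@annotation == "candidate" &
                     nchar(tags@sequence) >= 19L &
                     nchar(tags@sequence) <= 24L)
  novel <- list()
  rejections <- list()
  for (i in candIdx) {
    for (h in seq_along(tags@hits[[i]])) {
      locus <- tags@hits[[i]][h]
      cands <- exciseAndFold(locus, genome, flankMax = flankMax,
                             backend = backend)
      if (!length(cands)) {
        rejections[[length(rejections) + 1L]] <-
          data.frame(sequence = tags@sequence[i],
                     location = .locusString(locus),
                     reason = "no stable hairpin")
        next
      }
      for (hp in cands) {
        hp2 <- tryCatch(findStar(hp), error = function(e) NULL)
        if (is.null(hp2)) {
          rejections[[length(rejections) + 1L]] <-
            data.frame(sequence = tags@sequence[i],
                       location = .locusString(locus),
                       reason = "no star definable")
          next
        }
        ev <- evaluateMeyers(hp2, tags, mfeThreshold = mfeThreshold)
        if (ev$accepted) {
          novel[[length(novel) + 1L]] <- data.frame(
            sequence = ev$mature,
            countControl = tags@countControl[i],
            countDrought = tags@countDrought[i],
            star = ev$star,
            starCountControl = ev$starCounts[["control"]],
            starCountDrought = ev$starCounts[["drought"]],
            location = .locusString(hp2@locus),
            arm = hp2@arm, lp = precursorLength(hp2), mfe = hp2@mfe,
            structure = hp2@structure)
        } else {
          rejections[[length(rejections) + 1L]] <-
            data.frame(sequence = tags@sequence[i],
                       location = .locusString(locus), reason = ev$reason)
        }
      }
    }
  }
  novel <- if (length(novel)) unique(do.call(rbind, novel)) else
    data.frame(sequence = character(0), countControl = integer(0),
               countDrought = integer(0), star = character(0),
               starCountControl = integer(0), starCountDrought = integer(0),
               location = character(0), arm = character(0), lp = integer(0),
               mfe = numeric(0), structure = character(0))
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(sequence = character(0), location = character(0),
               reason = character(0))
  ## one record per precursor locus: overlapping accepted hairpins (the
  ## mature/star mirror pairs of one duplex, and the antisense hairpin of
  ## an inverted repeat) collapse to the most abundant mature
  if (nrow(novel) > 1L) {
    gr <- parseLocusString(novel$location)
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    cl <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      gr, red, ignore.strand = TRUE))
    total <- novel$countControl + novel$countDrought
    o <- order(cl, -total, novel$sequence)
    novel <- novel[o[!duplicated(cl[o])], , drop = FALSE]
  }
  ## family grouping: identical mature sequence => one family; lettered
  ## variants for distinct loci of one family
  if (nrow(novel)) {
    novel <- novel[order(novel$location), , drop = FALSE]
    fam <- match(novel$sequence, unique(novel$sequence))
    novel <- novel[order(fam), , drop = FALSE]
    fam <- fam[order(fam)]
    withinFam <- stats::ave(seq_len(nrow(novel)), fam, FUN = seq_along)
    famSize <- stats::ave(seq_len(nrow(novel)), fam, FUN = length)
    novel$name <- sprintf("miRn%d%s", fam,
                          ifelse(famSize > 1L, letters[withinFam], ""))
    novel <- novel[, c("name", setdiff(names(novel), "name"))]
    rownames(novel) <- NULL
  } else novel$name <- character(0)
  list(novel = novel, rejections = rejections)
}

#' Summarize a set of novel miRNAs
#'
#' @param novel a data.frame with at least columns \code{name},
#'   \code{sequence}, \code{lp}, \code{mfe} (the \code{novel} element of
#'   \code{\link{discoverNovelMirnas}}, or the packaged reference table).
#' @return list: \code{n} (entries), \code{lengthHist} (named integer
#'   vector, mature length to count), \code{firstNt} (named fractions of
#'   A/C/G/U at position 1), \code{nFamilies} (distinct mature
#'   sequences), \code{lpRange}, \code{mfeRange} (min, max).
#' @export
summarizeNovel <- function(novel) {
  lens <- nchar(novel$sequence)
  lengthHist <- table(factor(lens, levels = sort(unique(lens))))
  first <- substr(novel$sequence, 1L, 1L)
  firstNt <- table(factor(first, levels = .RNA_ALPHABET)) / max(1L, nrow(novel))
  list(n = nrow(novel),
       lengthHist = setNames(as.integer(lengthHist), names(lengthHist)),
       firstNt = setNames(as.numeric(firstNt), names(firstNt)),
       nFamilies = length(unique(novel$sequence)),
       lpRange = if (nrow(novel)) range(novel$lp) else c(NA, NA),
       mfeRange = if (nrow(novel)) range(novel$mfe) else c(NA, NA))
}

#' Load the packaged novel-miRNA reference table
#'
#' A 65-entry table of published novel poplar miRNAs (name, mature
#' sequence, mature and star read counts, precursor location serialized
#' as \code{scaffold:start:end:strand} with 1-based inclusive
#' coordinates, arm, precursor length LP, and the published hairpin MFE).
#' The MFE column is external annotation from the original
#' thermodynamic folding; it is fixture data, not recomputed by
#' \code{\link{foldRNA}}.
#'
#' @return data.frame with columns \code{name}, \code{sequence},
#'   \code{countMature}, \code{countStar}, \code{location}, \code{arm},
#'   \code{lp}, \code{mfe}, \code{foundBy}.
#' @export
readNovelMirnaTable <- function() {
  path <- system.file("extdata", "novel_mirna_table.tsv", package = "mirpare")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$sequence <- asRna(tab$sequence)
  tab
}

#' Parse "scaffold:start:end:strand" location strings
#'
#' @param x character vector of serialized loci.
#' @return GRanges (1-based inclusive).
#' @export
parseLocusString <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  GRanges(vapply(parts, `[`, "", 1L),
          IRanges(as.integer(vapply(parts, `[`, "", 2L)),
                  as.integer(vapply(parts, `[`, "", 3L))),
          strand = vapply(parts, `[`, "", 4L))
}
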