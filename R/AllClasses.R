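#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults define the
#' standard study conditions used throughout the test suite: a small
#' multi-scaffold genome carrying perfect-stem hairpin precursors, two
#' small-RNA libraries (control and drought) with negative-binomial count
#' noise, structural-RNA contaminant loci, and a degradome library whose
#' signal reads start exactly at the planted cleavage positions.
#'
#' @slot seed integer root seed; all randomness derives from it.
#' @slot nScaffolds,scaffoldLength genome dimensions (nt).
#' @slot nHairpins number of planted miRNA precursors.
#' @slot stemLength,loopLength,matureLength hairpin geometry (nt).
#' @slot nTranscripts number of synthetic transcripts; the first
#'   \code{nHairpins} each carry one planted target site.
#' @slot readDepth expected reads per small-RNA library.
#' @slot degradomeDepth expected reads in the degradome library.
#' @slot adapter 3' adapter appended to every simulated small-RNA read.
#' @slot deFoldChanges numeric vector of drought/control fold changes,
#'   named by miRNA index; unnamed miRNAs have fold 1.
#' @slot nbDispersion negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2).
#' @slot contaminantFraction fraction of reads drawn from rRNA/tRNA loci.
#' @slot junkFraction fraction of junk reads (<18 nt or low quality).
#' @slot degradomeSignalFraction fraction of degradome reads whose 5' end
#'   sits exactly at a true cleavage position.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", nScaffolds = "integer", scaffoldLength = "integer",
  nHairpins = "integer", stemLength = "integer", loopLength = "integer",
  matureLength = "integer", nTranscripts = "integer", readDepth = "integer",
  degradomeDepth = "integer", adapter = "character",
  deFoldChanges = "numeric", nbDispersion = "numeric",
  contaminantFraction = "numeric", junkFraction = "numeric",
  degradomeSignalFraction = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@stemLength < object@matureLength)
    msg <- c(msg, "stemLength must be >= matureLength")
  if (nchar(object@adapter) < 8L)
    msg <- c(msg, "adapter must be at least 8 nt")
  fr <- c(object@contaminantFraction, object@junkFraction,
          object@degradomeSignalFraction)
  if (any(fr < 0) || any(fr > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@contaminantFraction + object@junkFraction >= 1)
    msg <- c(msg, "contaminantFraction + junkFraction must be < 1")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (any(c(object@nScaffolds, object@scaffoldLength, object@nHairpins,
            object@nTranscripts, object@readDepth, object@degradomeDepth) < 1L))
    msg <- c(msg, "sizes and depths must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class constructor with the default study
#'   conditions.
#' @param seed,nScaffolds,scaffoldLength,nHairpins,stemLength,loopLength
#'   see slots.
#' @param matureLength,nTranscripts,readDepth,degradomeDepth,adapter
#'   see slots.
#' @param deFoldChanges,nbDispersion,contaminantFraction,junkFraction
#'   see slots.
#' @param degradomeSignalFraction see slots.
#' @export
SimulationConfig <- function(seed = 1L,
                             nScaffolds = 2L,
                             scaffoldLength = 40000L,
                             nHairpins = 20L,
                             stemLength = 30L,
                             loopLength = 8L,
                             matureLength = 21L,
                             nTranscripts = 20L,
                             readDepth = 50000L,
                             degradomeDepth = 10000L,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             deFoldChanges = c("1" = 4, "2" = 4,
                                               "3" = 0.25, "4" = 0.25),
                             nbDispersion = 0.01,
                             contaminantFraction = 0.08,
                             junkFraction = 0.02,
                             degradomeSignalFraction = 0.5) {
  new("SimulationConfig", seed = as.integer(seed),
      nScaffolds = as.integer(nScaffolds),
      scaffoldLength = as.integer(scaffoldLength),
      nHairpins = as.integer(nHairpins), stemLength = as.integer(stemLength),
      loopLength = as.integer(loopLength),
      matureLength = as.integer(matureLength),
      nTranscripts = as.integer(nTranscripts),
      readDepth = as.integer(readDepth),
      degradomeDepth = as.integer(degradomeDepth),
      adapter = asDna(adapter), deFoldChanges = deFoldChanges,
      nbDispersion = nbDispersion, contaminantFraction = contaminantFraction,
      junkFraction = junkFraction,
      degradomeSignalFraction = degradomeSignalFraction)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|", object@nScaffolds,
      "scaffold(s) x", object@scaffoldLength, "nt |", object@nHairpins,
      "hairpins |", object@readDepth, "reads/library\n")
})

#' Ground truth of a simulated dataset
#'
#' @slot mirna DataFrame of planted miRNAs: name, mature and star
#'   sequences, locus (scaffold/start/end/strand, 1-based inclusive), arm,
#'   precursor-relative mature/star offsets, and expected per-library
#'   counts.
#' @slot targets DataFrame of planted target sites: miRNA name, transcript
#'   id, site start/end (transcript coordinates) and true cleavage
#'   position (the base paired to miRNA position 10).
#' @slot contaminants GRanges of structural-RNA (rRNA/tRNA) loci.
#' @export
setClass("GroundTruth", representation(
  mirna = "DataFrame", targets = "DataFrame", contaminants = "GRanges"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@mirna), "planted miRNAs,",
      nrow(object@targets), "target sites,",
      length(object@contaminants), "contaminant loci\n")
})

#' @describeIn GroundTruth-class planted miRNA table.
#' @param x a GroundTruth.
#' @export
truthMirna <- function(x) x@mirna

#' @describeIn GroundTruth-class planted target-site table.
#' @export
truthTargets <- function(x) x@targets

#' @describeIn GroundTruth-class structural-RNA contaminant loci.
#' @export
truthContaminants <- function(x) x@contaminants

#' Collapsed unique small-RNA tags
#'
#' One record per distinct cleaned sequence, with per-library counts,
#' an annotation label assigned once by precedence
#' (structural > known miRNA > siRNA candidate > candidate; unmapped when
#' no acceptable genome hit), and the perfect-match genome hits.
#'
#' @slot sequence character, RNA alphabet, 18-30 nt.
#' @slot countControl,countDrought integer read counts per library.
#' @slot annotation character label per tag.
#' @slot hits GRangesList of perfect-match loci (may be empty before
#'   mapping).
#' @export
setClass("TagSet", representation(
  sequence = "character", countControl = "integer", countDrought = "integer",
  annotation = "character", hits = "GRangesList"))

setValidity("TagSet", function(object) {
  n <- length(object@sequence)
  if (length(object@countControl) != n || length(object@countDrought) != n ||
      length(object@annotation) != n || length(object@hits) != n)
    return("all slots must have one entry per tag")
  if (any(grepl("[^ACGU]", object@sequence)))
    return("tag sequences must be uppercase RNA (A, C, G, U)")
  if (any(object@countControl < 0L) || any(object@countDrought < 0L))
    return("counts must be non-negative")
  TRUE
})

#' @describeIn TagSet-class build a TagSet from per-library collapsed
#'   count tables as returned by \code{\link{cleanAndCollapse}}.
#' @param control,drought data.frames with columns \code{seq},
#'   \code{count}.
#' @export
TagSet <- function(control, drought) {
  seqs <- sort(unique(c(control$seq, drought$seq)))
  cc <- setNames(integer(length(seqs)), seqs)
  cd <- cc
  cc[control$seq] <- as.integer(control$count)
  cd[drought$seq] <- as.integer(drought$count)
  new("TagSet", sequence = seqs, countControl = unname(cc),
      countDrought = unname(cd),
      annotation = rep("candidate", length(seqs)),
      hits = GRangesList(rep(list(GRanges()), length(seqs))))
}

setMethod("length", "TagSet", function(x) length(x@sequence))

setMethod("show", "TagSet", function(object) {
  cat("TagSet with", length(object), "unique tags;",
      sum(object@countControl), "control /", sum(object@countDrought),
      "drought reads\n")
  if (length(object))
    print(table(annotation = object@annotation))
})

setMethod("[", "TagSet", function(x, i, j, ..., drop = TRUE) {
  new("TagSet", sequence = x@sequence[i], countControl = x@countControl[i],
      countDrought = x@countDrought[i], annotation = x@annotation[i],
      hits = x@hits[i])
})

#' @describeIn TagSet-class tag sequences (RNA alphabet).
#' @param x a TagSet.
#' @export
tagSequences <- function(x) x@sequence

#' @describeIn TagSet-class two-column matrix of per-library counts.
#' @export
tagCounts <- function(x)
  cbind(control = x@countControl, drought = x@countDrought)

#' @describeIn TagSet-class annotation labels.
#' @export
tagAnnotation <- function(x) x@annotation

#' @describeIn TagSet-class perfect-match genome hits.
#' @export
tagHits <- function(x) x@hits

#' Candidate miRNA hairpin precursor
#'
#' @slot sequence precursor RNA sequence.
#' @slot structure dot-bracket string, same length as the sequence.
#' @slot mfe minimum free energy under the configured folding backend
#'   (kcal/mol, model units; <= 0).
#' @slot locus GRanges of the precursor (1-based inclusive, stranded).
#' @slot matureStart,matureLength 1-based offset/length of the mature
#'   within the precursor.
#' @slot starStart,starLength offset/length of the star (NA before
#'   \code{\link{findStar}}).
#' @slot arm which arm carries the mature: "5p" or "3p".
#' @export
setClass("HairpinCandidate", representation(
  sequence = "character", structure = "character", mfe = "numeric",
  locus = "GRanges", matureStart = "integer", matureLength = "integer",
  starStart = "integer", starLength = "integer", arm = "character"))

setValidity("HairpinCandidate", function(object) {
  if (nchar(object@structure) != nchar(object@sequence))
    return("structure and sequence lengths differ")
  op <- lengths(regmatches(object@structure,
                           gregexpr("(", object@structure, fixed = TRUE)))
  cl <- lengths(regmatches(object@structure,
                           gregexpr(")", object@structure, fixed = TRUE)))
  if (op != cl) return("unbalanced dot-bracket structure")
  if (length(object@locus) == 1L &&
      width(object@locus) != nchar(object@sequence))
    return("precursor length (LP) must equal end - start + 1")
  TRUE
})

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf("HairpinCandidate %s arm=%s LP=%d MFE=%.1f mature@%d+%d\n",
              if (length(object@locus)) .locusString(object@locus) else "?",
              object@arm, nchar(object@sequence), object@mfe,
              object@matureStart, object@matureLength))
})

#' @describeIn HairpinCandidate-class precursor length in nt (the LP
#'   column of the novel-miRNA table).
#' @param x a HairpinCandidate.
#' @export
precursorLength <- function(x) nchar(x@sequence)

#' @describeIn HairpinCandidate-class minimum free energy.
#' @export
hairpinMfe <- function(x) x@mfe

#' @describeIn HairpinCandidate-class dot-bracket structure.
#' @export
hairpinStructure <- function(x) x@structure

#' miRNA::target duplex alignment
#'
#' Anti-parallel alignment of a miRNA (5'->3') against a transcript window
#' (sense strand). Each alignment column has a state (match, mismatch, GU,
#' gap), a miRNA position index counted from the miRNA 5' end, and the
#' transcript coordinate physically opposite that column (NA for a column
#' bulged out of the transcript).
#'
#' @slot mirnaName,mirna miRNA identifier and sequence.
#' @slot transcript transcript identifier.
#' @slot siteStart,siteEnd transcript coordinates of the bound window,
#'   1-based inclusive; the miRNA 5' end pairs near \code{siteEnd}.
#' @slot states character vector of per-column states.
#' @slot positions integer miRNA position index per column.
#' @slot targetPos integer transcript coordinate per column (NA for a
#'   miRNA-side bulge).
#' @slot penalty position penalty (alignment) score; lower is better.
#' @slot mfeDuplex,mfePerfect,mfeRatio duplex energy, the energy of the
#'   miRNA bound to its perfect complement, and their ratio.
#' @export
setClass("DuplexAlignment", representation(
  mirnaName = "character", mirna = "character", transcript = "character",
  siteStart = "integer", siteEnd = "integer", states = "character",
  positions = "integer", targetPos = "integer", penalty = "numeric",
  mfeDuplex = "numeric", mfePerfect = "numeric", mfeRatio = "numeric"))

setMethod("show", "DuplexAlignment", function(object) {
  cat(sprintf(
    "DuplexAlignment %s -> %s:%d-%d score=%.2f mfeRatio=%.2f\n  states: %s\n",
    object@mirnaName, object@transcript, object@siteStart, object@siteEnd,
    object@penalty, object@mfeRatio,
    paste(substr(object@states, 1L, 2L), collapse = " ")))
})

#' @describeIn DuplexAlignment-class the penalty (alignment) score.
#' @param x a DuplexAlignment.
#' @export
alignmentPenalty <- function(x) x@penalty

## "scaffold:start:end:strand" serialization used by the novel-miRNA table
.locusString <- function(gr) {
  sprintf("%s:%d:%d:%s", as.character(seqnames(gr)), start(gr), end(gr),
          as.character(strand(gr)))
}
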