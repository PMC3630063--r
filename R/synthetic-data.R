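## Synthetic-data generator: seeded genomes with planted hairpin
## precursors, two-condition small-RNA libraries, transcriptomes with
## planted target sites, and degradome libraries. Identical config + seed
## gives byte-identical outputs.

#' Build a genome carrying planted miRNA hairpins
#'
#' Generates \code{nScaffolds} random scaffolds and plants
#' \code{nHairpins} precursors: perfect inverted repeats (all Watson-Crick
#' stems, which satisfies the >= 80 percent pairing the discovery stage
#' requires) whose stem length is drawn so every precursor is 80-280 nt
#' long, matching the length range of published novel-miRNA precursors.
#' Each precursor carries a mature/star duplex with 2-nt 3' overhangs on
#' both ends; the mature arm and strand are random. Structural-RNA
#' (rRNA/tRNA) contaminant loci are placed in the remaining sequence and
#' reported as a GFF3-style annotation.
#'
#' Coordinates are 1-based inclusive with explicit strand, so the
#' precursor length LP always equals end - start + 1.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return a list with elements \code{genome} (DNAStringSet),
#'   \code{truth} (\code{\link[=GroundTruth-class]{GroundTruth}}; target
#'   sites are filled in by \code{\link{buildTranscriptome}}) and
#'   \code{annotation} (GRanges of contaminant loci with a \code{type}
#'   column).
#' @export
buildGenomeWithHairpins <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(.deriveSeed(config@seed, 1L))
  L <- config@matureLength
  loop <- config@loopLength
  stemMin <- max(config@stemLength, as.integer(ceiling((80 - loop) / 2)), L + 3L)
  stemMax <- stemMin + 24L

  nper <- ceiling(config@nHairpins / config@nScaffolds)
  slot <- config@scaffoldLength %/% (nper + 1L)
  if (slot < 2L * stemMax + loop + 200L)
    stop("scaffolds too short to host ", config@nHairpins,
         " hairpins: need at least ",
         (2L * stemMax + loop + 200L) * (nper + 1L), " nt per scaffold",
         call. = FALSE)

  scaffolds <- vapply(seq_len(config@nScaffolds), function(i)
    paste(sample(c("A", "C", "G", "T"), config@scaffoldLength,
                 replace = TRUE), collapse = ""), character(1))
  names(scaffolds) <- paste0("scaffold_", seq_len(config@nScaffolds))

  rec <- vector("list", config@nHairpins)
  occupied <- GRanges()
  for (k in seq_len(config@nHairpins)) {
    sc <- ((k - 1L) %% config@nScaffolds) + 1L
    slotIdx <- (k - 1L) %/% config@nScaffolds
    S <- sample(stemMin:stemMax, 1L)
    lp <- 2L * S + loop
    arm5 <- paste(sample(c("A", "C", "G", "U"), S, replace = TRUE,
                         prob = c(.28, .22, .22, .28)), collapse = "")
    loopSeq <- paste(sample(c("A", "C", "U"), loop, replace = TRUE),
                     collapse = "")
    precursor <- paste0(arm5, loopSeq, revCompRna(arm5))
    C <- 2L * S + loop + 1L
    arm <- sample(c("5p", "3p"), 1L)
    if (arm == "5p") {
      m <- sample(3L:(S - L + 1L), 1L)
      starStart <- C - m - L + 3L
      starEnd <- C - m + 2L
    } else {
      m <- sample((S + loop + 3L):(2L * S + loop - L + 1L), 1L)
      starStart <- C - m - L + 3L
      starEnd <- C - m + 2L
    }
    mature <- substr(precursor, m, m + L - 1L)
    star <- substr(precursor, starStart, starEnd)
    strand <- sample(c("+", "-"), 1L)
    gStart <- as.integer(slotIdx * slot + sample(50:(slot - lp - 50L), 1L))
    gEnd <- gStart + lp - 1L
    genomic <- if (strand == "+") asDna(precursor) else
      asDna(revCompRna(precursor))
    substr(scaffolds[sc], gStart, gEnd) <- genomic
    rec[[k]] <- data.frame(
      name = sprintf("mir-%02d", k), mature = mature, star = star,
      scaffold = names(scaffolds)[sc], start = gStart, end = gEnd,
      strand = strand, arm = arm, lp = lp,
      matureStart = m, matureLength = L,
      starStart = starStart, starLength = starEnd - starStart + 1L)
    occupied <- suppressWarnings(
      c(occupied, GRanges(names(scaffolds)[sc], IRanges(gStart, gEnd))))
  }
  mirna <- do.call(rbind, rec)

  ## expected per-library counts: log-uniform relative abundances; star
  ## expression is one tenth of the mature's
  ab <- exp(runif(config@nHairpins, log(1), log(20)))
  usable <- 1 - config@contaminantFraction - config@junkFraction
  scale <- usable * config@readDepth / sum(ab * 1.1)
  mirna$expMatureControl <- ab * scale
  mirna$expStarControl <- 0.1 * ab * scale
  fold <- rep(1, config@nHairpins)
  idx <- as.integer(names(config@deFoldChanges))
  fold[idx[idx <= config@nHairpins]] <-
    config@deFoldChanges[idx <= config@nHairpins]
  mirna$foldChange <- fold
  mirna$expMatureDrought <- mirna$expMatureControl * fold
  mirna$expStarDrought <- mirna$expStarControl * fold

  ## contaminant structural-RNA loci in unoccupied sequence
  nCont <- 8L
  cont <- vector("list", nCont)
  for (k in seq_len(nCont)) {
    repeat {
      sc <- sample(names(scaffolds), 1L)
      w <- sample(120:300, 1L)
      s <- sample(seq_len(config@scaffoldLength - w), 1L)
      gr <- GRanges(sc, IRanges(s, s + w - 1L),
                    strand = sample(c("+", "-"), 1L))
      if (!length(IRanges::findOverlaps(gr, occupied))) break
    }
    mcols(gr)$type <- if (k %% 2L) "rRNA" else "tRNA"
    mcols(gr)$ID <- sprintf("%s_%d", mcols(gr)$type, k)
    cont[[k]] <- gr
    occupied <- suppressWarnings(
      c(occupied, GRanges(seqnames(gr), IRanges(start(gr), end(gr)))))
  }
  contaminants <- suppressWarnings(do.call(c, cont))

  truth <- new("GroundTruth", mirna = DataFrame(mirna),
               targets = DataFrame(mirna = character(0),
                                   transcript = character(0),
                                   siteStart = integer(0),
                                   siteEnd = integer(0),
                                   cleavage = integer(0)),
               contaminants = contaminants)
  list(genome = Biostrings::DNAStringSet(scaffolds), truth = truth,
       annotation = contaminants)
}

#' Build a transcriptome with planted miRNA target sites
#'
#' Generates \code{nTranscripts} random transcripts; the first
#' \code{nHairpins} transcripts each carry the exact reverse complement of
#' one planted mature miRNA (one site per transcript, so each true
#' cleavage site is the only signal peak on its transcript). The true
#' cleavage position is the transcript base paired to miRNA position 10:
#' \code{siteEnd - 9} for a contiguous site whose 3' end pairs the miRNA
#' 5' end.
#'
#' @param truth GroundTruth from \code{\link{buildGenomeWithHairpins}}.
#' @param config the same \code{\link{SimulationConfig}}.
#' @return list with \code{transcripts} (DNAStringSet) and \code{truth}
#'   (GroundTruth with the target table filled).
#' @export
buildTranscriptome <- function(truth, config) {
  set.seed(.deriveSeed(config@seed, 2L))
  n <- config@nTranscripts
  lens <- sample(1200:2000, n, replace = TRUE)
  tx <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  names(tx) <- sprintf("TX%04d", seq_len(n))
  mir <- truth@mirna
  nSites <- min(nrow(mir), n)
  tgt <- vector("list", nSites)
  for (k in seq_len(nSites)) {
    L <- nchar(mir$mature[k])
    s <- sample(200:(lens[k] - 200L - L), 1L)
    e <- s + L - 1L
    substr(tx[k], s, e) <- asDna(revCompRna(mir$mature[k]))
    tgt[[k]] <- data.frame(mirna = mir$name[k], transcript = names(tx)[k],
                           siteStart = s, siteEnd = e, cleavage = e - 9L)
  }
  truth@targets <- DataFrame(do.call(rbind, tgt))
  list(transcripts = Biostrings::DNAStringSet(tx), truth = truth)
}

## NB count draw; dispersion 0 degenerates to Poisson
.rcounts <- function(mu, dispersion) {
  if (dispersion <= 0) stats::rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate per-miRNA counts for the two libraries
#'
#' Draws control and drought counts from the generator's negative-binomial
#' model around expected means, without materialising reads. This is the
#' same count model \code{\link{simulateSmallRnaLibraries}} uses.
#'
#' @param means expected control counts, one per miRNA.
#' @param folds drought/control fold changes (recycled).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed integer seed.
#' @return DataFrame with columns \code{name}, \code{x} (control),
#'   \code{y} (drought).
#' @export
simulateMirnaCounts <- function(means, folds = 1, dispersion = 0.01,
                                seed = 1L) {
  set.seed(as.integer(seed))
  folds <- rep_len(folds, length(means))
  DataFrame(name = sprintf("mir-%02d", seq_along(means)),
            x = .rcounts(means, dispersion),
            y = .rcounts(means * folds, dispersion))
}

#' Simulate the two small-RNA FASTQ libraries
#'
#' Emits mature and star reads (insert plus 3' adapter) with counts drawn
#' from the negative-binomial model; drought means are the control means
#' scaled by the configured fold changes. A configurable fraction of reads
#' comes from the structural-RNA contaminant loci, and a small junk
#' fraction (<18 nt inserts and low-quality reads) exercises the cleaning
#' stage.
#'
#' @param genome DNAStringSet from \code{\link{buildGenomeWithHairpins}}.
#' @param truth the matching GroundTruth.
#' @param config the \code{\link{SimulationConfig}}.
#' @return list of two data.frames (\code{control}, \code{drought}) with
#'   columns \code{id}, \code{seq}, \code{qual}, ready for
#'   \code{\link{writeFastq}}.
#' @export
simulateSmallRnaLibraries <- function(genome, truth, config) {
  mkLib <- function(which, seedOffset) {
    set.seed(.deriveSeed(config@seed, seedOffset))
    mir <- truth@mirna
    mu <- if (which == "control")
      c(mir$expMatureControl, mir$expStarControl)
    else c(mir$expMatureDrought, mir$expStarDrought)
    counts <- .rcounts(mu, config@nbDispersion)
    inserts <- rep(c(mir$mature, mir$star), counts)

    nCont <- round(config@contaminantFraction * config@readDepth)
    if (nCont > 0) {
      loci <- truth@contaminants[sample(length(truth@contaminants), nCont,
                                        replace = TRUE)]
      w <- sample(18:28, nCont, replace = TRUE)
      off <- floor(runif(nCont) * (width(loci) - w)) + 1L
      seqs <- as.character(Biostrings::subseq(
        genome[as.character(seqnames(loci))],
        start = start(loci) + off - 1L, width = w))
      minus <- as.character(strand(loci)) == "-"
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
      inserts <- c(inserts, asRna(seqs))
    }
    reads <- paste0(asDna(inserts), config@adapter)
    quals <- strrep("I", nchar(reads))

    nJunk <- round(config@junkFraction * config@readDepth)
    if (nJunk > 0) {
      short <- vapply(sample(10:17, ceiling(nJunk / 2), replace = TRUE),
                      function(w) paste(sample(c("A", "C", "G", "T"), w,
                                               replace = TRUE),
                                        collapse = ""), character(1))
      lowq <- vapply(rep(21L, floor(nJunk / 2)),
                     function(w) paste(sample(c("A", "C", "G", "T"), w,
                                              replace = TRUE),
                                       collapse = ""), character(1))
      junkReads <- paste0(c(short, lowq), config@adapter)
      junkQuals <- c(strrep("I", nchar(short) + nchar(config@adapter)),
                     strrep("#", nchar(lowq) + nchar(config@adapter)))
      reads <- c(reads, junkReads)
      quals <- c(quals, junkQuals)
    }
    data.frame(id = sprintf("%s_%07d", which, seq_along(reads)),
               seq = reads, qual = quals)
  }
  list(control = mkLib("control", 3L), drought = mkLib("drought", 4L))
}

#' Simulate a degradome (PARE) library
#'
#' A \code{degradomeSignalFraction} share of reads has its 5' end exactly
#' at a true cleavage position (split equally across planted sites); the
#' remainder starts uniformly over transcript positions. Reads are 20-21
#' nt from the transcript sense strand. Sites closer than 20 nt to a
#' transcript 3' end are skipped with a warning.
#'
#' @param transcripts DNAStringSet from \code{\link{buildTranscriptome}}.
#' @param truth GroundTruth with the target table filled.
#' @param config the \code{\link{SimulationConfig}}.
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
simulateDegradomeLibrary <- function(transcripts, truth, config) {
  set.seed(.deriveSeed(config@seed, 5L))
  txChar <- as.character(transcripts)
  txLen <- nchar(txChar)
  names(txLen) <- names(txChar)
  tgt <- as.data.frame(truth@targets)
  if (nrow(tgt)) {
    tooClose <- tgt$cleavage > txLen[tgt$transcript] - 20L
    if (any(tooClose)) {
      warning(sum(tooClose), " cleavage site(s) within 20 nt of the ",
              "transcript 3' end skipped")
      tgt <- tgt[!tooClose, , drop = FALSE]
    }
  }
  depth <- config@degradomeDepth
  nSignal <- if (nrow(tgt)) round(config@degradomeSignalFraction * depth) else 0L
  reads <- character(0)
  if (nSignal > 0) {
    siteIdx <- rep_len(seq_len(nrow(tgt)), nSignal)
    w <- sample(20:21, nSignal, replace = TRUE)
    w <- pmin(w, txLen[tgt$transcript[siteIdx]] - tgt$cleavage[siteIdx] + 1L)
    reads <- substr(txChar[tgt$transcript[siteIdx]],
                    tgt$cleavage[siteIdx],
                    tgt$cleavage[siteIdx] + w - 1L)
  }
  nBg <- depth - nSignal
  if (nBg > 0) {
    ti <- sample(length(txChar), nBg, replace = TRUE)
    w <- sample(20:21, nBg, replace = TRUE)
    s <- floor(runif(nBg) * (txLen[ti] - w)) + 1L
    reads <- c(reads, substr(txChar[ti], s, s + w - 1L))
  }
  data.frame(id = sprintf("deg_%07d", seq_along(reads)), seq = reads,
             qual = strrep("I", nchar(reads)))
}

#' Serialize / restore a GroundTruth as JSON
#'
#' \code{truthToJson} writes \code{truth.json};
#' \code{truthFromJson} restores an identical object
#' (load(write(x)) == x).
#'
#' @param truth a GroundTruth.
#' @param path output (input) JSON path.
#' @return \code{truthFromJson}: a GroundTruth.
#' @export
truthToJson <- function(truth, path) {
  cont <- truth@contaminants
  obj <- list(
    mirna = as.data.frame(truth@mirna),
    targets = as.data.frame(truth@targets),
    contaminants = data.frame(
      scaffold = as.character(seqnames(cont)), start = start(cont),
      end = end(cont), strand = as.character(strand(cont)),
      type = mcols(cont)$type, ID = mcols(cont)$ID))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname truthToJson
#' @export
truthFromJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cont <- GRanges(obj$contaminants$scaffold,
                  IRanges(obj$contaminants$start, obj$contaminants$end),
                  strand = obj$contaminants$strand)
  mcols(cont)$type <- obj$contaminants$type
  mcols(cont)$ID <- obj$contaminants$ID
  new("GroundTruth", mirna = DataFrame(obj$mirna),
      targets = DataFrame(obj$targets), contaminants = cont)
}

#' Write a complete synthetic fixture bundle
#'
#' Runs the full generator and writes genome.fa, transcripts.fa,
#' annotation.gff3, control.fastq, drought.fastq, degradome.fastq,
#' truth.json, plus a copy of the packaged novel-miRNA reference table
#' (novel_mirna_table.tsv).
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param outdir output directory (created if missing).
#' @return named character vector of the 8 written paths (the manifest).
#' @export
writeFixtureBundle <- function(config, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", outdir, "'", call. = FALSE)
  gen <- buildGenomeWithHairpins(config)
  txb <- buildTranscriptome(gen$truth, config)
  libs <- simulateSmallRnaLibraries(gen$genome, txb$truth, config)
  deg <- simulateDegradomeLibrary(txb$transcripts, txb$truth, config)

  paths <- c(genome = file.path(outdir, "genome.fa"),
             transcripts = file.path(outdir, "transcripts.fa"),
             annotation = file.path(outdir, "annotation.gff3"),
             control = file.path(outdir, "control.fastq"),
             drought = file.path(outdir, "drought.fastq"),
             degradome = file.path(outdir, "degradome.fastq"),
             truth = file.path(outdir, "truth.json"),
             novelTable = file.path(outdir, "novel_mirna_table.tsv"))
  Biostrings::writeXStringSet(gen$genome, paths[["genome"]])
  Biostrings::writeXStringSet(txb$transcripts, paths[["transcripts"]])
  rtracklayer::export(gen$annotation, paths[["annotation"]], format = "gff3")
  writeFastq(libs$control$id, libs$control$seq, libs$control$qual,
             paths[["control"]])
  writeFastq(libs$drought$id, libs$drought$seq, libs$drought$qual,
             paths[["drought"]])
  writeFastq(deg$id, deg$seq, deg$qual, paths[["degradome"]])
  truthToJson(txb$truth, paths[["truth"]])
  file.copy(system.file("extdata", "novel_mirna_table.tsv",
                        package = "mirpare"),
            paths[["novelTable"]], overwrite = TRUE)
  paths
}
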