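## Internal sequence helpers. The package works on the RNA alphabet
## {A,C,G,U}; T is accepted on input and mapped to U.

.RNA_ALPHABET <- c("A", "C", "G", "U")

#' Convert sequences to the internal RNA alphabet
#'
#' Uppercases and maps T to U. Used on every sequence input boundary.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over \{A,C,G,U\}.
#' @export
asRna <- function(x) chartr("t", "u", chartr("T", "U", toupper(x)))

#' @rdname asRna
#' @export
asDna <- function(x) chartr("u", "t", chartr("U", "T", toupper(x)))

#' Reverse complement of RNA sequences
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
revCompRna <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(asRna(x))))
}

.checkRnaChars <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop(what, " contains non-RNA characters (allowed: A, C, G, U/T): ",
         x[which(bad)[1L]], call. = FALSE)
  invisible(TRUE)
}

## integer encoding used by the C++ folding core: A=0, C=1, G=2, U=3
.encodeRna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- match(v, .RNA_ALPHABET) - 1L
  if (anyNA(m)) stop("sequence contains non-RNA characters", call. = FALSE)
  m
}

## Watson-Crick / wobble classification of one miRNA base against one
## target base (both given 5'->3'; the target base is the one physically
## opposite the miRNA base in the antiparallel duplex).
.pairClass <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

## pair stability magnitude under the stacking model (0 = not paired)
.pairValue <- function(cls, a) {
  ifelse(cls == "match", ifelse(a %in% c("G", "C"), 3, 2),
         ifelse(cls == "GU", 1, 0))
}

#' Read a FASTQ file
#'
#' Minimal strict 4-line FASTQ reader (Sanger/Phred+33). Malformed records
#' raise an error naming the 1-based record index, which downstream
#' cleaning relies on for diagnostics.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (record ",
         length(lines) %/% 4L + 1L, ")", call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  idx <- seq_len(n)
  hd <- lines[4L * idx - 3L]
  sq <- lines[4L * idx - 2L]
  pl <- lines[4L * idx - 1L]
  ql <- lines[4L * idx]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))[1L]
  if (!is.na(bad))
    stop("malformed FASTQ record ", bad, " in '", path, "'", call. = FALSE)
  data.frame(id = sub("^@", "", hd), seq = sq, qual = ql)
}

#' Write a FASTQ file
#'
#' @param ids,seqs,quals parallel character vectors; \code{quals} defaults
#'   to uniform Phred 40 ("I").
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastq <- function(ids, seqs, quals = NULL, path) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  out <- character(4L * length(ids))
  if (length(ids)) {
    idx <- seq_along(ids)
    out[4L * idx - 3L] <- paste0("@", ids)
    out[4L * idx - 2L] <- seqs
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- quals
  }
  writeLines(out, path)
  invisible(path)
}

## mean Phred score (offset 33) per quality string
.meanPhred <- function(qual) {
  vapply(qual, function(q) if (nchar(q) == 0L) 0 else
    mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

## deterministic per-stage seed derived from a root seed (kept < 2^31)
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 97L * as.integer(offset)) %% 2147483399L
}
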