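#' Fold an RNA sequence under the stacking energy model
#'
#' Computes a nested (pseudoknot-free) secondary structure minimising the
#' stacking energy. Allowed pairs are G:C, A:U and G:U with a minimum
#' hairpin loop of 3 unpaired bases. Energy is carried entirely by stacks
#' of adjacent pairs: a stack of two G:C pairs contributes -3.0 kcal/mol,
#' two A:U pairs -2.0, two G:U pairs -1.0, and a mixed stack the mean of
#' the two pairs' values. Isolated pairs contribute 0, so the returned
#' energy is always <= 0. Ties are broken deterministically toward the
#' pairing whose 5' index is smallest.
#'
#' This deliberately simplified model is exhaustively checkable against
#' enumeration of all nested structures at short lengths; it is not a
#' full nearest-neighbour (Turner/MFOLD) energy model, and hairpin
#' energies from those programs are treated as external annotation, never
#' recomputed. An alternative backend honouring the same contract
#' (a function taking a sequence and returning \code{list(structure,
#' mfe)}) can be supplied via \code{backend}.
#'
#' @param sequence a single RNA (or DNA; T is mapped to U) string of
#'   length >= 10.
#' @param backend optional replacement folding function.
#' @return a list with elements \code{structure} (dot-bracket string) and
#'   \code{mfe} (numeric, <= 0).
#' @examples
#' foldRNA("GGGAAACCC")  # (((...))), mfe -6
#' @export
foldRNA <- function(sequence, backend = NULL) {
  stopifnot(length(sequence) == 1L)
  seq <- asRna(sequence)
  .checkRnaChars(seq)
  if (!is.null(backend)) return(backend(seq))
  res <- .fold_rna_cpp(.encodeRna(seq))
  list(structure = res$structure, mfe = res$mfe)
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector p of the structure's length; p[i] is the
#'   1-based partner of position i, or NA when unpaired.
#' @export
pairingTable <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  partner
}
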