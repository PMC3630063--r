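## Exact count-based differential expression between two libraries
## without replicates, plus RPM normalisation, log2 ratios and the
## 2^-ddCt RT-qPCR relative-expression helper.

#' Reads-per-million normalisation
#'
#' @param count read count(s).
#' @param libraryTotal total reads in the library (> 0).
#' @return count / libraryTotal * 1e6.
#' @export
rpmNormalize <- function(count, libraryTotal) {
  if (any(libraryTotal <= 0)) stop("library total must be > 0", call. = FALSE)
  count / libraryTotal * 1e6
}

#' Log2 expression ratio (drought over control)
#'
#' Undefined (NA, not an error) when either RPM is zero or negative:
#' on/off miRNAs are flagged rather than dropped.
#'
#' @param rpmDrought,rpmControl normalised expression values.
#' @return log2(rpmDrought / rpmControl), or NA where undefined.
#' @export
log2Ratio <- function(rpmDrought, rpmControl) {
  ifelse(rpmDrought > 0 & rpmControl > 0, log2(rpmDrought / rpmControl),
         NA_real_)
}

## log of the conditional term p(k | x) = (N2/N1)^k * (x+k)!/(x! k!)
## * (1 + N2/N1)^-(x+k+1), vectorised over k
.logTerm <- function(k, x, logRatio, log1pRatio) {
  k * logRatio + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1pRatio
}

## compensated (Kahan) summation
.kahanSum <- function(v) {
  s <- 0
  c <- 0
  for (t in v) {
    y <- t - c
    u <- s + y
    c <- (u - s) - y
    s <- u
  }
  s
}

#' Exact two-tail p-value for comparing one tag between two libraries
#'
#' Implements the classic exact test for observing counts x and y of the
#' same sequence in two libraries of totals N1 and N2. The conditional
#' distribution of y given x is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!}
#'   \left(1 + \frac{N2}{N1}\right)^{-(x+y+1)}}
#' and the two-tail p-value is the smaller of the lower tail
#' \eqn{\sum_{k \le y} p(k|x)} and the upper tail
#' \eqn{\sum_{k \ge y} p(k|x)}. The upper tail is evaluated as the
#' complement \eqn{1 - \sum_{k < y} p(k|x)} with compensated summation;
#' when that complement falls below 0.01 - where cancellation against 1
#' and the accumulated rounding of the summed terms would dominate the
#' result - it is recomputed by direct forward summation of the tail terms, preserving 1e-10 relative accuracy into
#' the deep tail. Terms are computed in log space; the result is clamped
#' to (0, 1].
#'
#' The construction conditions on the first library's count x, so it is
#' not symmetric: exchanging (x, N1) with (y, N2) generally changes the
#' p-value (e.g. p(3, 7) = 11/64 but p(7, 3) = 29/256 at equal totals).
#' The formula is applied literally as printed; no symmetrisation is
#' attempted.
#'
#' @param x,y read counts in the control and treatment libraries.
#' @param N1,N2 total library sizes (control, treatment).
#' @return the two-tail p-value in (0, 1]. Vectorised over x, y.
#' @examples
#' acPvalue(0, 0, 1e6, 1e6)  # 0.5
#' acPvalue(5, 0, 1e6, 1e6)  # 1/64
#' @export
acPvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0))
    stop("library totals must be > 0", call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  ## max-shifted summation keeps tiny tail sums accurate where the raw
  ## terms would underflow
  shiftedSum <- function(logTerms) {
    m <- max(logTerms)
    if (!is.finite(m)) return(0)
    exp(m) * .kahanSum(exp(logTerms - m))
  }
  vapply(seq_len(n), function(i) {
    r <- N2[i] / N1[i]
    logRatio <- log(N2[i]) - log(N1[i])
    log1pRatio <- log1p(r)
    ltLower <- .logTerm(0:y[i], x[i], logRatio, log1pRatio)
    lower <- shiftedSum(ltLower)
    upper <- 1 - .kahanSum(exp(ltLower[-length(ltLower)]))
    if (upper < 1e-2) {
      ## deep tail: sum the terms k = y, y+1, ... directly
      nbMean <- (x[i] + 1) * r
      nbSd <- sqrt((x[i] + 1) * r * (1 + r))
      kMax <- max(y[i] + 1000, ceiling(nbMean + 50 * nbSd + 1000))
      upper <- shiftedSum(.logTerm(y[i]:kMax, x[i], logRatio, log1pRatio))
    }
    p <- min(lower, upper, 1)
    max(p, .Machine$double.xmin)
  }, numeric(1))
}

#' Build an expression table and call differentially expressed miRNAs
#'
#' Normalises counts to RPM, computes log2 ratios and exact p-values,
#' filters records whose RPM is below \code{minRpm} in \emph{both}
#' libraries (records passing in either library are kept, preserving
#' on/off miRNAs), and calls a record up- or down-regulated when
#' |log2 ratio| >= log2(fold) and p <= alpha. A Benjamini-Hochberg
#' adjusted column is reported for reference but not used for calls.
#'
#' @param records data.frame with columns \code{name}, \code{x},
#'   \code{y} (counts in control and drought).
#' @param N1,N2 library totals.
#' @param minRpm abundance filter (RPM).
#' @param fold minimum fold change called.
#' @param alpha p-value threshold.
#' @return data.frame: name, x, y, N1, N2, rpmControl, rpmDrought,
#'   log2Ratio, pValue, qValue, call ("up", "down" or "ns").
#' @export
callDE <- function(records, N1, N2, minRpm = 1, fold = 2, alpha = 0.01) {
  records <- as.data.frame(records)
  out <- data.frame(name = records$name, x = records$x, y = records$y,
                    N1 = N1, N2 = N2,
                    rpmControl = rpmNormalize(records$x, N1),
                    rpmDrought = rpmNormalize(records$y, N2))
  out <- out[out$rpmControl >= minRpm | out$rpmDrought >= minRpm, ,
             drop = FALSE]
  out$log2Ratio <- log2Ratio(out$rpmDrought, out$rpmControl)
  out$pValue <- if (nrow(out)) acPvalue(out$x, out$y, out$N1, out$N2) else
    numeric(0)
  out$qValue <- p.adjust(out$pValue, method = "BH")
  called <- !is.na(out$log2Ratio) & abs(out$log2Ratio) >= log2(fold) &
    out$pValue <= alpha
  out$call <- ifelse(called & out$log2Ratio > 0, "up",
                     ifelse(called, "down", "ns"))
  rownames(out) <- NULL
  out
}

#' RT-qPCR relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,treat - Ct_ref,treat) - (Ct_target,ctrl -
#' Ct_ref,ctrl); relative expression = 2^-ddCt, normalised to the
#' reference gene and the control condition.
#'
#' @param ctTargetTreat,ctRefTreat,ctTargetCtrl,ctRefCtrl cycle-threshold
#'   values (finite).
#' @return data.frame with columns \code{ddCt} and
#'   \code{relativeExpression}.
#' @export
ddct <- function(ctTargetTreat, ctRefTreat, ctTargetCtrl, ctRefCtrl) {
  vals <- c(ctTargetTreat, ctRefTreat, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  dd <- (ctTargetTreat - ctRefTreat) - (ctTargetCtrl - ctRefCtrl)
  data.frame(ddCt = dd, relativeExpression = 2^(-dd))
}
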