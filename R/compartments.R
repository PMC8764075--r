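#' Call A/B compartments from a 100 kb observed/expected matrix
#'
#' Labels come from the sign of the first eigenvector of the Pearson
#' correlation matrix of the obs/exp contacts. The per-chromosome sign is
#' oriented so that A-labelled bins have the higher mean gene density;
#' optionally a mean-expression vector can be supplied as a secondary
#' orientation criterion used when gene density does not discriminate.
#' Bins that are all-NA or zero-variance are excluded and labelled `NA`;
#' a degenerate (near-zero-variance) eigenvector yields an all-NA track.
#'
#' @param x a [ContactMatrix-class] with obs/exp computed (see
#'   [observedOverExpected()]), typically at 100 kb.
#' @param geneDensity genes per bin (same length as bins).
#' @param expression optional per-bin mean expression for the secondary
#'   orientation check (off unless supplied).
#' @return data.frame with `bin`, `start`, `end`, `eigen`, `label`
#'   (`"A"`, `"B"` or `NA`).
#' @export
callCompartments <- function(x, geneDensity, expression = NULL) {
  oe <- oeMatrix(x)
  if (is.null(oe)) stop("obs/exp matrix required; run observedOverExpected()")
  n <- nrow(oe)
  if (length(geneDensity) != n) stop("geneDensity length must match bins")
  out <- data.frame(bin = seq_len(n) - 1L, start = binTable(x)$start,
                    end = binTable(x)$end, eigen = NA_real_,
                    label = NA_character_, stringsAsFactors = FALSE)
  ok <- apply(oe, 1, function(r) sum(!is.na(r)) >= 3 && stats::sd(r, na.rm = TRUE) > 0)
  if (sum(ok) < 3) return(out)
  sub <- oe[ok, ok, drop = FALSE]
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  if (stats::sd(cc[upper.tri(cc)]) < 1e-10) return(out)
  ev <- eigen(cc, symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  # degenerate leading eigenvector: no compartment signal
  if (stats::sd(e1) < 1e-12) return(out)
  gd <- geneDensity[ok]
  mA <- mean(gd[e1 > 0]); mB <- mean(gd[e1 < 0])
  if (is.finite(mA) && is.finite(mB) && mA != mB) {
    if (mA < mB) e1 <- -e1
  } else if (!is.null(expression)) {
    ex <- expression[ok]
    if (mean(ex[e1 > 0], na.rm = TRUE) < mean(ex[e1 < 0], na.rm = TRUE))
      e1 <- -e1
  }
  out$eigen[ok] <- e1
  out$label[ok] <- ifelse(e1 > 0, "A", ifelse(e1 < 0, "B", NA))
  out
}

#' Classify compartment flips across the four-stage series
#'
#' Per-bin category from the A/B label sequence: no change gives
#' `stable-A`/`stable-B`; changes in a single direction give `A-to-B` or
#' `B-to-A` (net first-to-last direction); changes in both directions give
#' `transient` (this includes sequences that return to the starting label,
#' e.g. A,B,A,A). Bins with an `NA` label at any stage are excluded from
#' the denominator. The flip fraction is
#' (A-to-B + B-to-A + transient) / classified bins.
#'
#' @param labelMatrix stages x bins character matrix of "A"/"B"/NA labels
#'   (exactly 4 stages).
#' @return list with `category` (per-bin factor, NA for excluded bins),
#'   `counts` (named category counts), `classified` (denominator) and
#'   `flipFraction`.
#' @export
classifyFlips <- function(labelMatrix) {
  if (nrow(labelMatrix) != 4L)
    stop("flip classification is defined for exactly 4 stages")
  nb <- ncol(labelMatrix)
  cats <- c("stable-A", "stable-B", "A-to-B", "B-to-A", "transient")
  category <- rep(NA_character_, nb)
  for (j in seq_len(nb)) {
    s <- labelMatrix[, j]
    if (anyNA(s)) next
    ch <- s[-1] != s[-length(s)]
    if (!any(ch)) {
      category[j] <- paste0("stable-", s[1])
    } else {
      dirAB <- any(s[-length(s)] == "A" & s[-1] == "B")
      dirBA <- any(s[-length(s)] == "B" & s[-1] == "A")
      category[j] <- if (dirAB && dirBA) "transient"
                     else if (dirAB) "A-to-B" else "B-to-A"
    }
  }
  counts <- table(factor(category, levels = cats))
  classified <- sum(counts)
  flip <- sum(counts[c("A-to-B", "B-to-A", "transient")])
  list(category = factor(category, levels = cats),
       counts = as.vector(counts) |> stats::setNames(cats),
       classified = classified,
       flipFraction = if (classified) flip / classified else NA_real_)
}
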