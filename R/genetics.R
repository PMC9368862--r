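# Mendelian segregation-ratio chi-square testing and inheritance-mode
# classification.

#' Chi-square goodness-of-fit to a Mendelian ratio
#'
#' Tests observed class counts against an expected ratio:
#' \code{E_i = N * ratio_i / sum(ratio)},
#' \code{chi2 = sum((O_i - E_i)^2 / E_i)}, df = classes - 1. The decision is
#' \code{"fits"} iff the statistic does not exceed the upper-alpha critical
#' value. No continuity correction by default; set \code{yates = TRUE} for the
#' Yates-corrected statistic.
#'
#' @param observed Non-negative class counts (length >= 2, total > 0).
#' @param ratio Positive ratio weights, same length (e.g. \code{c(1, 2, 1)}).
#' @param alpha Significance level for the decision (default 0.05).
#' @param yates Apply the Yates continuity correction.
#' @return A [SegregationResult].
#' @examples
#' chiSquareGof(c(48, 94, 42), c(1, 2, 1))
#' @export
chiSquareGof <- function(observed, ratio, alpha = 0.05, yates = FALSE) {
  k <- length(observed)
  if (k < 2) stop("need at least 2 classes")
  if (length(ratio) != k) stop("ratio must have one weight per class")
  if (any(ratio <= 0)) stop("ratio class with 0 weight")
  if (any(observed < 0)) stop("counts must be non-negative")
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  expected <- n * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- k - 1L
  critical <- stats::qchisq(1 - alpha, df)
  methods::new("SegregationResult",
               observed = as.numeric(observed), ratio = as.numeric(ratio),
               expected = expected, statistic = statistic, df = df,
               pValue = stats::pchisq(statistic, df, lower.tail = FALSE),
               alpha = alpha, critical = critical,
               decision = if (statistic <= critical) "fits" else "rejected")
}

.CANDIDATE_RATIOS <- list(
  "3:1" = c(3, 1), "1:2:1" = c(1, 2, 1), "15:1" = c(15, 1),
  "13:3" = c(13, 3), "9:7" = c(9, 7))

#' Classify the inheritance mode from segregation counts
#'
#' Tests the observed phenotype class counts against the classical Mendelian
#' candidate ratios 3:1, 1:2:1, 15:1, 13:3 and 9:7 (three-class ratios only
#' when three classes are observed) and returns the non-rejected ratio with
#' the largest p-value, or \code{"none"} when every candidate is rejected.
#'
#' @param observed Class counts (length 2 or 3).
#' @param alpha Significance level.
#' @param yates Apply the Yates continuity correction.
#' @return A list: \code{best} (ratio label or \code{"none"}), \code{results}
#'   (one [SegregationResult] per candidate), and \code{table}, a data.frame
#'   summarising every test.
#' @examples
#' classifyInheritance(c(48, 94, 42))$best
#' @export
classifyInheritance <- function(observed, alpha = 0.05, yates = FALSE) {
  k <- length(observed)
  if (!k %in% c(2L, 3L)) stop("need 2 or 3 phenotype classes")
  cand <- Filter(function(r) length(r) == k, .CANDIDATE_RATIOS)
  if (!length(cand)) stop("no candidate ratio with ", k, " classes")
  results <- lapply(cand, chiSquareGof, observed = observed, alpha = alpha,
                    yates = yates)
  tab <- data.frame(
    ratio = names(cand),
    chisq = vapply(results, function(r) r@statistic, numeric(1)),
    df = vapply(results, function(r) r@df, numeric(1)),
    pValue = vapply(results, function(r) r@pValue, numeric(1)),
    decision = vapply(results, function(r) r@decision, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  ok <- tab$decision == "fits"
  best <- if (any(ok)) tab$ratio[ok][which.max(tab$pValue[ok])] else "none"
  list(best = best, results = results, table = tab)
}
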