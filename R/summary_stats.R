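## Cohort-level summaries and the contingency statistics used in enrichment
## analyses (e.g. ClinVar benign enrichment among variants predicted to
## evade LoF).

#' Summarize curation results
#'
#' @param results List of `curation_result`s.
#' @return List with `n`, `verdict_counts`, `verdict_proportions`,
#'   `flag_counts` (by flag name), `flag_category_counts`,
#'   `primary_reasons`, and `evasion_rate` (proportion of likely not LoF /
#'   not LoF verdicts).
#' @export
summarize_results <- function(results) {
  if (!length(results)) {
    warning("no results to summarize")
    return(list(n = 0, verdict_counts = setNames(integer(5), VERDICT_LEVELS),
                verdict_proportions = setNames(numeric(5), VERDICT_LEVELS),
                flag_counts = integer(), flag_category_counts = integer(),
                primary_reasons = integer(), evasion_rate = NA_real_))
  }
  verdicts <- vapply(results, function(r) r$verdict, character(1))
  vc <- table(factor(verdicts, levels = VERDICT_LEVELS))
  flags <- do.call(rbind, c(lapply(results, function(r) r$flags),
                            list(no_flags())))
  pr <- vapply(results, function(r) r$primary_reason, character(1))
  list(n = length(results),
       verdict_counts = as.list(vc),
       verdict_proportions = as.list(vc / length(results)),
       flag_counts = as.list(table(flags$name)),
       flag_category_counts = as.list(table(flags$category)),
       primary_reasons = as.list(table(pr)),
       evasion_rate = unname((vc["likely_not_LoF"] + vc["not_LoF"]) / length(results)))
}

#' 2x2 contingency table
#' @param a,b,c,d Non-negative integer counts (rows = groups, columns =
#'   outcome yes/no).
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  structure(as.list(counts), class = "contingency_2x2")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities, over all tables with the observed
#' margins, of every table whose probability does not exceed that of the
#' observed table (the probability-mass definition of the two-sided
#' p-value, as used by [stats::fisher.test()]).
#'
#' @param t A [contingency_2x2()].
#' @return Two-sided p-value. Degenerate margins give `p = 1`.
#' @examples
#' fisher_exact_2x2(contingency_2x2(16, 109, 2, 344))  # < 1e-4
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  r1 <- t$a + t$b; c1 <- t$a + t$c; n <- t$a + t$b + t$c + t$d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1.0)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(t$a, c1, n - c1, r1)
  ## relative tolerance guards against ties lost to floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form `N (ad - bc)^2 / (r1 r2 c1 c2)` with df = 1, optionally with
#' the Yates continuity correction.
#'
#' @param t A [contingency_2x2()].
#' @param continuity_correction Apply Yates correction (default FALSE).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(t, continuity_correction = FALSE) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin")
  num <- abs(a * d - b * c_)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni adjustment helper
#' @param p Raw p-value(s).
#' @param m Number of tests.
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m) pmin(1, p * m)
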