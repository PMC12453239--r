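# Cohort contingency statistics: exact two-sided Fisher tests on 2x2
# tables of demographic/clinical categories and two-sided matched t-tests
# on paired continuous variables.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates every table compatible with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (with a 1e-7 relative slack for floating-point ties) - the
#' standard two-sided convention.
#'
#' @param table 2x2 integer matrix (rows = category levels, columns =
#'   FRI/control), or the four counts \code{a, b, c, d} row-wise.
#' @param a,b,c,d alternative scalar interface.
#' @return list with \code{p} (two-sided), \code{odds_ratio} (sample OR)
#'   and \code{method}.
#' @export
fisherExact2x2 <- function(table = NULL, a = NULL, b = NULL, c = NULL,
                           d = NULL) {
  if (is.null(table)) table <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("value error: a 2x2 table of non-negative integer counts is required")
  m <- rowSums(table); n <- colSums(table)
  if (any(m == 0) || any(n == 0))
    stop("value error: zero margin")
  N <- sum(table)
  kObs <- table[1, 1]
  kMin <- max(0, m[1] - n[2]); kMax <- min(m[1], n[1])
  k <- kMin:kMax
  pk <- stats::dhyper(k, n[1], n[2], m[1])
  pObs <- stats::dhyper(kObs, n[1], n[2], m[1])
  p <- sum(pk[pk <= pObs * (1 + 1e-7)])
  orr <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p = min(1, p), odds_ratio = orr, method = "Fisher exact (two-sided)")
}

#' Two-sided matched (paired) t-test
#'
#' One-sample t on the within-pair differences against zero, df = n - 1.
#'
#' @param caseValues,controlValues equal-length numeric vectors, aligned by
#'   matched pair.
#' @return list with \code{statistic}, \code{p}, \code{df}, \code{method}.
#' @export
matchedTTest <- function(caseValues, controlValues) {
  if (length(caseValues) != length(controlValues))
    stop("value error: paired vectors must have equal length")
  n <- length(caseValues)
  if (n < 2) stop("value error: >= 2 pairs required")
  d <- caseValues - controlValues
  s <- stats::sd(d)
  if (s == 0) stop("value error: zero variance of paired differences")
  t <- mean(d) / (s / sqrt(n))
  list(statistic = t, p = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
       method = "matched t-test (two-sided)")
}

#' Cohort description table with inferential statistics
#'
#' Builds one row per variable: Fisher exact p for two-level categorical
#' counts, matched-t p for paired continuous measurements. The packaged
#' fixture \code{system.file("extdata", "table2_counts.csv", package =
#' "ftirms")} carries the printed categorical counts of the study cohort.
#'
#' @param counts data.frame with columns \code{variable}, \code{level},
#'   \code{fri}, \code{control} (two rows per variable), or \code{NULL}.
#' @param paired named list of \code{list(case =, control =)} numeric
#'   vectors for continuous variables, or \code{NULL}.
#' @return data.frame with \code{variable}, \code{p}, \code{method},
#'   rows in input order (categorical first).
#' @export
cohortReport <- function(counts = NULL, paired = NULL) {
  rows <- list()
  if (!is.null(counts)) {
    need <- c("variable", "level", "fri", "control")
    if (!all(need %in% colnames(counts)))
      stop("counts must have columns: ", paste(need, collapse = ", "))
    for (v in unique(counts$variable)) {
      sub <- counts[counts$variable == v, , drop = FALSE]
      if (nrow(sub) != 2)
        stop("value error: variable '", v, "' must have exactly 2 levels")
      ft <- fisherExact2x2(as.matrix(sub[, c("fri", "control")]))
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, p = ft$p, method = ft$method)
    }
  }
  if (!is.null(paired)) {
    for (v in names(paired)) {
      tt <- matchedTTest(paired[[v]]$case, paired[[v]]$control)
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, p = tt$p, method = tt$method)
    }
  }
  if (!length(rows)) stop("nothing to test")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
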