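#' Cross-tabulate a cohort variable against the outcome
#'
#' @param data a `cohort_table`.
#' @param variable row variable name.
#' @param outcome column variable name (default "ascvd").
#' @return Integer matrix, one row per state of `variable`, one column per
#'   outcome state; row sums equal the state frequencies.
#' @export
crosstab <- function(data, variable, outcome = "ascvd") {
  for (v in c(variable, outcome))
    if (!v %in% names(data))
      stop("unknown variable '", v, "'", call. = FALSE)
  tab <- table(data[[variable]], data[[outcome]])
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Two-sided Fisher's exact test p-value
#'
#' For 2x2 tables the two-sided p-value sums the probabilities of all
#' tables (under the hypergeometric null with fixed margins) no more
#' probable than the observed one — the convention of mainstream
#' implementations. r x 2 tables are handled by the exact network
#' algorithm.
#'
#' @param counts non-negative integer matrix of contingency counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  stats::fisher.test(counts)$p.value
}

#' Risk difference between two exposure groups, with 95% CI
#'
#' The risk difference is 100 * (case proportion among exposed - case
#' proportion among unexposed), in percentage points. The default interval
#' is Newcombe's hybrid score method (square-and-add of Wilson limits),
#' which remains sensible with zero cells; a Wald interval is available.
#'
#' @param counts 2x2 matrix: rows = exposed, unexposed; columns = case,
#'   non-case. (Or a vector `c(case_exposed, noncase_exposed,
#'   case_unexposed, noncase_unexposed)`.)
#' @param method "newcombe" (default) or "wald".
#' @param conf confidence level.
#' @return Object of class `risk_difference`: list with `rd`, `ci_low`,
#'   `ci_high` (percentage points), `method`, and the two group risks.
#' @export
risk_difference <- function(counts, method = c("newcombe", "wald"),
                            conf = 0.95) {
  method <- match.arg(method)
  if (!is.matrix(counts)) counts <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  n1 <- sum(counts[1, ]); n2 <- sum(counts[2, ])
  if (n1 == 0 || n2 == 0)
    stop("risk undefined: a group has zero total", call. = FALSE)
  p1 <- counts[1, 1] / n1
  p2 <- counts[2, 1] / n2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  d <- p1 - p2
  if (method == "wald") {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lo <- d - z * se; hi <- d + z * se
  } else {
    w <- function(p, n) {
      c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
          (1 + z^2 / n),
        (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
          (1 + z^2 / n))
    }
    w1 <- w(p1, n1); w2 <- w(p2, n2)
    lo <- d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)
    hi <- d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)
  }
  out <- list(rd = 100 * d, ci_low = 100 * max(-1, lo),
              ci_high = 100 * min(1, hi), method = method,
              risk_exposed = 100 * p1, risk_unexposed = 100 * p2)
  class(out) <- "risk_difference"
  out
}

#' @export
print.risk_difference <- function(x, ...) {
  cat(sprintf("risk difference %.1f pp (%.1f to %.1f, %s)\n",
              x$rd, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Prevalence with exact (Clopper-Pearson) confidence interval
#'
#' @param k case count.
#' @param n total count.
#' @param conf confidence level.
#' @return List with `estimate`, `ci_low`, `ci_high` (percent), `k`, `n`.
#' @export
prevalence_ci <- function(k, n, conf = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0", call. = FALSE)
  a <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  list(estimate = 100 * k / n, ci_low = 100 * lo, ci_high = 100 * hi,
       k = k, n = n, conf = conf)
}

#' Descriptive summary of the cohort by outcome status
#'
#' For every variable other than the outcome: state counts and column
#' percents overall and within outcome groups, an exact test of
#' association (Fisher), and the risk difference of each non-reference
#' state against the variable's reference state with its confidence
#' interval. Mirrors the layout of a standard baseline-characteristics
#' table.
#'
#' @param data a `cohort_table`.
#' @param outcome outcome variable (default "ascvd"); its last state is
#'   treated as the case state.
#' @param method CI method for [risk_difference()].
#' @param schema cohort schema (supplies reference states). Variables not
#'   in the schema use their first level as reference.
#' @return Data frame of class `table1_report`, one row per variable state:
#'   `variable`, `state`, `n_all`, `pct_all`, `n_case`, `pct_case`,
#'   `n_noncase`, `pct_noncase`, `rd`, `rd_low`, `rd_high`, `p_value`
#'   (repeated within a variable), `reference` (logical).
#' @export
table1_report <- function(data, outcome = "ascvd", method = "newcombe",
                          schema = cohort_schema()) {
  vars <- setdiff(names(data), outcome)
  case_state <- utils::tail(levels(as.factor(data[[outcome]])), 1)
  rows <- list()
  for (v in vars) {
    ct <- crosstab(data, v, outcome)
    states <- rownames(ct)
    ref <- if (v %in% names(schema)) schema[[v]]$reference else states[1]
    case_col <- match(case_state, colnames(ct))
    cases <- ct[, case_col]
    noncases <- rowSums(ct) - cases
    p <- if (sum(ct) > 0 && nrow(ct) > 1) fisher_exact_p(ct) else NA_real_
    for (s in states) {
      rd <- rd_lo <- rd_hi <- NA_real_
      if (s != ref && sum(ct[s, ]) > 0 && sum(ct[ref, ]) > 0) {
        r <- risk_difference(matrix(c(cases[s], noncases[s],
                                      cases[ref], noncases[ref]),
                                    2, 2, byrow = TRUE), method = method)
        rd <- r$rd; rd_lo <- r$ci_low; rd_hi <- r$ci_high
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, state = s,
        n_all = cases[s] + noncases[s],
        pct_all = if (sum(ct) > 0) 100 * (cases[s] + noncases[s]) / sum(ct)
                  else NA_real_,
        n_case = cases[s],
        pct_case = if (sum(cases) > 0) 100 * cases[s] / sum(cases)
                   else NA_real_,
        n_noncase = noncases[s],
        pct_noncase = if (sum(noncases) > 0)
          100 * noncases[s] / sum(noncases) else NA_real_,
        rd = rd, rd_low = rd_lo, rd_high = rd_hi,
        p_value = p, reference = s == ref,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table1_report", "data.frame")
  out
}

#' @export
print.table1_report <- function(x, digits = 1, ...) {
  cat("Cohort characteristics by outcome status\n")
  for (v in unique(x$variable)) {
    sub <- x[x$variable == v, ]
    cat(sprintf("%s (p = %s)\n", v,
                format.pval(sub$p_value[1], digits = 3)))
    for (i in seq_len(nrow(sub))) {
      rdtxt <- if (sub$reference[i]) "reference"
               else if (is.na(sub$rd[i])) ""
               else sprintf("%.*f (%.*f to %.*f)", digits, sub$rd[i],
                            digits, sub$rd_low[i], digits, sub$rd_high[i])
      cat(sprintf("  %-16s %4d (%4.1f)  cases %3d  %s\n", sub$state[i],
                  sub$n_all[i], sub$pct_all[i], sub$n_case[i], rdtxt))
    }
  }
  invisible(x)
}

#' Published contingency counts of the source cohort
#'
#' Case / non-case counts per risk-factor state for the cross-sectional
#' cohort of 491 health-care workers (38 ASCVD cases) that this package's
#' synthetic generator emulates, as printed in the study's baseline
#' characteristics table. These counts are the input from which the
#' descriptive statistics (prevalence, exact CI, per-state risk
#' differences) are recomputed.
#'
#' @return Data frame with columns `variable`, `state`, `reference`
#'   (logical), `case`, `noncase`.
#' @export
reference_cohort_counts <- function() {
  df <- function(variable, state, reference, case, noncase)
    data.frame(variable = variable, state = state, reference = reference,
               case = case, noncase = noncase, stringsAsFactors = FALSE)
  rbind(
    df("age", "under45", TRUE, 4, 309),
    df("age", "over45", FALSE, 34, 114),
    df("sex", "female", TRUE, 0, 178),
    df("sex", "male", FALSE, 38, 275),
    df("diabetes", "no", TRUE, 31, 440),
    df("diabetes", "yes", FALSE, 7, 13),
    df("smoking", "never", TRUE, 28, 409),
    df("smoking", "past-or-current", FALSE, 10, 38),
    df("hypertension", "no", TRUE, 32, 421),
    df("hypertension", "yes", FALSE, 6, 32),
    df("mets", "no", TRUE, 20, 357),
    df("mets", "yes", FALSE, 18, 96),
    df("bmi", "normal", TRUE, 7, 99),
    df("bmi", "overweight", FALSE, 18, 235),
    df("bmi", "obesity", FALSE, 13, 118),
    df("fbs", "normal", TRUE, 30, 405),
    df("fbs", "high", FALSE, 8, 48),
    df("tg", "normal", TRUE, 21, 350),
    df("tg", "high", FALSE, 17, 103),
    df("tc", "normal", TRUE, 20, 332),
    df("tc", "high", FALSE, 18, 121),
    df("hdl", "normal", TRUE, 10, 172),
    df("hdl", "low", FALSE, 22, 155),
    df("hdl", "high", FALSE, 6, 126),
    df("ldl", "normal", TRUE, 19, 356),
    df("ldl", "high", FALSE, 19, 97)
  )
}

#' Published cohort totals
#'
#' The source study reports 491 completers with 38 ASCVD cases. (The
#' published per-state non-case counts sum to slightly different totals —
#' an internal inconsistency of the printed table — so prevalence is
#' computed from these reported totals while risk differences use the
#' per-state counts, mirroring the study's own arithmetic.)
#'
#' @return List with `n` (completers) and `cases`.
#' @export
reference_cohort_size <- function() list(n = 491L, cases = 38L)

#' Risk differences recomputed from the published counts
#'
#' Applies [risk_difference()] to every non-reference state of
#' [reference_cohort_counts()] against its reference state.
#'
#' @param method CI method.
#' @return Data frame `variable`, `state`, `rd`, `ci_low`, `ci_high`.
#' @export
reference_risk_differences <- function(method = "newcombe") {
  counts <- reference_cohort_counts()
  rows <- counts[!counts$reference, ]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    v <- rows$variable[i]
    ref <- counts[counts$variable == v & counts$reference, ]
    r <- risk_difference(matrix(c(rows$case[i], rows$noncase[i],
                                  ref$case, ref$noncase), 2, 2, byrow = TRUE),
                         method = method)
    data.frame(variable = v, state = rows$state[i], rd = r$rd,
               ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
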