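#' Leave-one-out cross-validated outcome scores
#'
#' For each record, the CPTs are refitted (same structure, same
#' pseudo-count) on the remaining n-1 records and the exact posterior of
#' the target given the record's other variables is computed. Because every
#' other variable is observed, the posterior factorizes over the families
#' containing the target, which lets the n refits be done by subtracting
#' each record's own contribution from the full count tables; the result is
#' identical to refitting from scratch and is deterministic.
#'
#' @param structure a `bn_dag`.
#' @param data a `cohort_table` (or data frame of factors), n >= 2.
#' @param target outcome node (default "ascvd").
#' @param alpha Dirichlet pseudo-count used in each fold's refit. With
#'   `alpha = 0` a held-out record can have zero probability under both
#'   target states; such records score `NA` with a warning.
#' @return Numeric vector of length n: posterior probability of the
#'   target's last state ("yes") for each record, in row order.
#' @export
loocv_scores <- function(structure, data, target = "ascvd", alpha = 1) {
  stopifnot(nrow(data) >= 2)
  if (!target %in% names(data)) stop("no '", target, "' column", call. = FALSE)
  nodes <- structure$nodes
  lev <- lapply(nodes, function(v) levels(as.factor(data[[v]])))
  names(lev) <- nodes
  r_t <- length(lev[[target]])
  n <- nrow(data)
  codes <- vapply(nodes, function(v) as.integer(factor(data[[v]], lev[[v]])),
                  integer(n))
  t_code <- codes[, target]
  logp <- matrix(0, n, r_t)
  fams <- Filter(function(v) target %in% c(v, dag_parents(structure, v)), nodes)
  for (child in fams) {
    pa <- dag_parents(structure, child)
    fam <- c(child, pa)
    card <- vapply(fam, function(u) length(lev[[u]]), 1L)
    r_c <- card[1]
    N <- tabulate(linear_index(codes[, fam, drop = FALSE], card),
                  nbins = prod(card))
    Np <- colSums(matrix(N, nrow = r_c))
    for (k in seq_len(r_t)) {
      ck <- codes[, fam, drop = FALSE]
      ck[, match(target, fam)] <- k
      idx <- linear_index(ck, card)
      pidx <- (idx - 1L) %/% r_c + 1L
      own <- if (child == target) 1 else as.numeric(k == t_code)
      num <- N[idx] - as.numeric(k == t_code) + alpha
      den <- Np[pidx] - own + alpha * r_c
      logp[, k] <- logp[, k] + log(num) - log(den)
    }
  }
  mx <- apply(logp, 1, max)
  post <- exp(logp - mx)
  tot <- rowSums(post)
  bad <- !is.finite(mx) | tot == 0
  if (any(bad)) {
    warning(sum(bad), " record(s) had zero probability under every target ",
            "state (use alpha > 0); scored NA", call. = FALSE)
    post[bad, ] <- NA_real_
  }
  (post / tot)[, r_t]
}

#' Area under the ROC curve
#'
#' Rank statistic (probability that a random positive outscores a random
#' negative, ties counted one half); identical to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric predictions.
#' @param labels outcome per record: logical, 0/1, or a factor whose last
#'   level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (length(pos) != length(scores)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(scores)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " NA score(s)", call. = FALSE)
    scores <- scores[keep]; pos <- pos[keep]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[nlevels(labels)])
  if (is.numeric(labels)) return(labels == 1)
  labels == "yes"
}

#' Empirical ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return Data frame `threshold`, `fpr`, `tpr`, one row per distinct
#'   threshold (descending), beginning at (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  pos <- as_positive(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), 1),
    tpr = vapply(th, function(t) mean(scores[pos] >= t), 1))
}

#' Likelihood ratios from sensitivity and specificity
#'
#' LR+ = sensitivity / (1 - specificity); LR- = (1 - sensitivity) /
#' specificity. Inputs above 1 are interpreted as percentages.
#'
#' @param sensitivity,specificity proportions in `[0, 1]` (or percentages).
#' @return List with `lr_plus` and `lr_minus` (ratio scale).
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  if (sensitivity > 1) sensitivity <- sensitivity / 100
  if (specificity > 1) specificity <- specificity / 100
  list(lr_plus = if (specificity < 1) sensitivity / (1 - specificity) else Inf,
       lr_minus = if (specificity > 0) (1 - sensitivity) / specificity else NaN)
}

#' Diagnostic index panel at a classification threshold
#'
#' Classifies score >= threshold as positive and reports the confusion
#' counts together with AUC, accuracy, sensitivity, specificity, NPV, PPV
#' and the likelihood ratios. Proportion-type indices are on the 0-1 scale
#' (multiply by 100 for percent display, as the print method does);
#' likelihood ratios are on the ratio scale. Ratios with a zero denominator
#' are reported as `NaN` with a warning.
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold classification threshold in (0, 1), or `"prevalence"`
#'   (the default: the sample prevalence of the positive class) or
#'   `"youden"` (the cut maximizing sensitivity + specificity - 1). The
#'   printed report states the threshold used.
#' @return Object of class `diagnostic_report`: a list of indices plus the
#'   confusion counts (`tp`, `fp`, `tn`, `fn`) and the threshold.
#' @export
diagnostic_indices <- function(scores, labels, threshold = NULL) {
  pos <- as_positive(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; pos <- pos[keep]
  if (is.null(threshold) || identical(threshold, "prevalence"))
    threshold <- mean(pos)
  else if (identical(threshold, "youden"))
    threshold <- youden_threshold(scores, pos)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  out <- list(
    auc = roc_auc(scores, pos),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = sens,
    specificity = spec,
    ppv = safe(tp, tp + fp, "PPV"),
    npv = safe(tn, tn + fn, "NPV"),
    lr_plus = if (is.finite(spec) && spec < 1) sens / (1 - spec)
              else { warning("LR+ undefined", call. = FALSE); NaN },
    lr_minus = if (is.finite(spec) && spec > 0) (1 - sens) / spec
               else { warning("LR- undefined", call. = FALSE); NaN },
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- "diagnostic_report"
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic indices (threshold = %.4f):\n", x$threshold))
  cat(sprintf("  AUC %.1f  accuracy %.1f  sensitivity %.1f  specificity %.1f\n",
              100 * x$auc, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  cat(sprintf("  PPV %.1f  NPV %.1f  LR+ %.2f  LR- %.2f\n",
              100 * x$ppv, 100 * x$npv, x$lr_plus, x$lr_minus))
  cat(sprintf("  confusion: tp %d fp %d tn %d fn %d\n", x$tp, x$fp, x$tn,
              x$fn))
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' The score cut maximizing Youden's J = sensitivity + specificity - 1 on
#' the empirical ROC curve; ties resolve to the highest such cut, so the
#' result is deterministic.
#'
#' @param scores,labels as in [roc_auc()].
#' @return A threshold (one of the observed scores, clamped inside (0, 1)).
#' @export
youden_threshold <- function(scores, labels) {
  pts <- roc_points(scores, as_positive(labels))
  j <- pts$tpr - pts$fpr
  th <- pts$threshold[which.max(j)]
  if (!is.finite(th)) th <- max(scores)
  min(max(th, 1e-12), 1 - 1e-12)
}

#' Side-by-side comparison of evaluated models
#'
#' Tabulates the eight diagnostic indices and the information criteria for
#' two or more models and flags the model with the highest AUC and the
#' lowest AIC/BIC (ties flagged as such).
#'
#' @param reports named list of `diagnostic_report` objects.
#' @param criteria named list of [information_criteria()] results (same
#'   names), optional.
#' @return Data frame, one row per model, with a `best` annotation column;
#'   attribute `flags` holds the per-criterion winners.
#' @export
compare_models <- function(reports, criteria = NULL) {
  stopifnot(length(reports) >= 2)
  nm <- names(reports)
  tab <- do.call(rbind, lapply(nm, function(m) {
    r <- reports[[m]]
    data.frame(model = m, auc = r$auc, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               npv = r$npv, ppv = r$ppv, lr_plus = r$lr_plus,
               lr_minus = r$lr_minus)
  }))
  flags <- list()
  pick <- function(vals, take_max) {
    best <- if (take_max) max(vals) else min(vals)
    w <- nm[abs(vals - best) < 1e-12]
    if (length(w) > 1) paste0("tie (", paste(w, collapse = ", "), ")") else w
  }
  flags$auc <- pick(tab$auc, TRUE)
  if (!is.null(criteria)) {
    tab$aic <- vapply(nm, function(m) criteria[[m]]$aic, 1)
    tab$bic <- vapply(nm, function(m) criteria[[m]]$bic, 1)
    flags$aic <- pick(tab$aic, FALSE)
    flags$bic <- pick(tab$bic, FALSE)
  }
  tab$best <- vapply(nm, function(m)
    paste(names(flags)[vapply(flags, identical, TRUE, m)], collapse = ","),
    "")
  attr(tab, "flags") <- flags
  tab
}
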