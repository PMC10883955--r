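test_that("AUC: closed cases, pair-counting oracle, and rank invariances", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(77)
  scores <- round(runif(200), 2)   # induce ties
  labels <- runif(200) < 0.3
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
               tolerance = 1e-12)
  # complement identity and invariance under monotone transforms
  expect_equal(roc_auc(scores, labels) + roc_auc(1 - scores, labels), 1,
               tolerance = 1e-12)
  expect_equal(roc_auc(scores, labels), roc_auc(qlogis(pmin(pmax(scores, 1e-6),
                                                            1 - 1e-6)), labels),
               tolerance = 1e-12)
  expect_equal(roc_auc(scores, labels), roc_auc(scores^3, labels),
               tolerance = 1e-12)
  expect_error(roc_auc(scores, rep(TRUE, 200)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(5)
  scores <- runif(300)
  labels <- runif(300) < plogis(3 * scores - 2)
  got <- roc_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("ROC points trace the empirical curve from (0,0) to (1,1)", {
  set.seed(8)
  scores <- runif(50); labels <- runif(50) < 0.4
  pts <- roc_points(scores, labels)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoidal area under the curve equals the rank-statistic AUC
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(area, roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("likelihood-ratio identities reproduce the published index pairs", {
  lr_k <- likelihood_ratios(62.5, 77.8)
  expect_equal(round(lr_k$lr_minus, 2), 0.48)
  expect_equal(round(lr_k$lr_plus, 1), 2.8)
  lr_s <- likelihood_ratios(17.5, 98.9)
  expect_equal(round(lr_s$lr_minus, 2), 0.83)
  # proportion and percentage inputs agree
  expect_equal(likelihood_ratios(0.625, 0.778), lr_k)
})

test_that("diagnostic indices are internally consistent with the confusion counts", {
  set.seed(21)
  scores <- runif(400)
  labels <- runif(400) < plogis(4 * scores - 2.5)
  di <- diagnostic_indices(scores, labels, threshold = 0.5)
  n <- di$tp + di$fp + di$tn + di$fn
  expect_identical(n, 400L)
  expect_equal(di$accuracy, (di$tp + di$tn) / n)
  expect_equal(di$sensitivity, di$tp / (di$tp + di$fn))
  expect_equal(di$specificity, di$tn / (di$tn + di$fp))
  expect_equal(di$ppv, di$tp / (di$tp + di$fp))
  expect_equal(di$npv, di$tn / (di$tn + di$fn))
  expect_equal(di$lr_plus, di$sensitivity / (1 - di$specificity))
  expect_equal(di$lr_minus, (1 - di$sensitivity) / di$specificity)
  # default threshold is the sample prevalence
  di2 <- diagnostic_indices(scores, labels)
  expect_equal(di2$threshold, mean(labels))
  expect_error(diagnostic_indices(scores, labels, threshold = 1.5),
               "threshold")
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  set.seed(33)
  scores <- runif(300)
  labels <- runif(300) < plogis(4 * scores - 2.5)
  th <- youden_threshold(scores, labels)
  di <- diagnostic_indices(scores, labels, "youden")
  expect_equal(di$threshold, th)
  j_star <- di$sensitivity + di$specificity
  for (t in seq(0.05, 0.95, by = 0.05)) {
    di_t <- suppressWarnings(diagnostic_indices(scores, labels, t))
    expect_lte(di_t$sensitivity + di_t$specificity, j_star + 1e-12)
  }
  expect_equal(diagnostic_indices(scores, labels, "prevalence")$threshold,
               mean(labels))
})

test_that("a perfect classifier saturates the panel", {
  labels <- rep(c(TRUE, FALSE), c(20, 80))
  scores <- ifelse(labels, 0.99, 0.01)
  # perfect specificity leaves LR+ with a zero denominator, which is flagged
  expect_warning(di <- diagnostic_indices(scores, labels, threshold = 0.5),
                 "LR")
  expect_equal(di$sensitivity, 1)
  expect_equal(di$specificity, 1)
  expect_equal(di$accuracy, 1)
  expect_equal(di$lr_minus, 0)
  expect_output(print(di), "sensitivity 100.0")
})

test_that("LOOCV equals explicit per-fold refitting", {
  bn <- random_net(4, seed = 41, max_card = 2)
  d <- sample_cohort(60, seed = 42, bn = bn)
  target <- bn$dag$nodes[4]
  got <- loocv_scores(bn$dag, d, target = target, alpha = 1)
  for (i in c(1, 17, 33, 60)) {
    refit <- suppressMessages(fit_bayes_net(bn$dag, d[-i, , drop = FALSE],
                                            alpha = 1))
    ev_vars <- setdiff(bn$dag$nodes, target)
    ev <- stats::setNames(vapply(ev_vars, function(v)
      as.character(d[[v]][i]), ""), ev_vars)
    want <- bn_query(refit, target, ev)
    expect_equal(got[i], unname(want[length(want)]), tolerance = 1e-10)
  }
})

test_that("LOOCV posteriors track a perfectly informative parent", {
  set.seed(3)
  parent <- factor(sample(c("no", "yes"), 200, TRUE), levels = c("no", "yes"))
  d <- data.frame(p = parent, o = factor(as.character(parent),
                                         levels = c("no", "yes")))
  g <- dag(c("p", "o"), rbind(c("p", "o")))
  sc <- loocv_scores(g, d, target = "o", alpha = 1)
  expect_true(all(sc[d$o == "yes"] > 0.9))
  expect_true(all(sc[d$o == "no"] < 0.1))
})

test_that("LOOCV degenerate cases: constant outcome and zero-probability folds", {
  d <- test_cohort(50, seed = 51)
  d$ascvd <- factor("no", levels = c("no", "yes"))
  sc <- loocv_scores(dag(names(d)), d, alpha = 1)
  # all mass near "no": P(yes) is within smoothing distance of 0
  expect_true(all(sc <= 2 / 51))
  # alpha = 0 flags impossible folds instead of crashing
  d2 <- data.frame(p = factor(c("a", "a", "b"), levels = c("a", "b")),
                   o = factor(c("x", "x", "y"), levels = c("x", "y")))
  g <- dag(c("p", "o"), rbind(c("p", "o")))
  expect_warning(sc2 <- loocv_scores(g, d2, target = "o", alpha = 0),
                 "zero probability")
  expect_true(is.na(sc2[3]))
})

test_that("LOOCV is deterministic and detects informative structure", {
  tab <- test_cohort(500, seed = 42)
  s1 <- loocv_scores(knowledge_dag(), tab, alpha = 1)
  s2 <- loocv_scores(knowledge_dag(), tab, alpha = 1)
  expect_identical(s1, s2)
  tab2 <- sample_cohort(1000, seed = 314)
  sc <- loocv_scores(knowledge_dag(), tab2, alpha = 1)
  auc <- roc_auc(sc, tab2$ascvd)
  n1 <- sum(tab2$ascvd == "yes"); n0 <- sum(tab2$ascvd == "no")
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))   # null-AUC standard error
  expect_gt(auc, 0.5 + 3 * se)
})

test_that("model comparison tabulates indices and flags winners and ties", {
  set.seed(61)
  scores <- runif(300); labels <- runif(300) < plogis(5 * scores - 3)
  a <- diagnostic_indices(scores, labels, 0.5)
  b <- diagnostic_indices(pmin(scores + 0.3 * runif(300), 1), labels, 0.5)
  crit <- list(m1 = list(aic = 100, bic = 120), m2 = list(aic = 90, bic = 130))
  cmp <- compare_models(list(m1 = a, m2 = b), crit)
  expect_identical(nrow(cmp), 2L)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity", "npv",
                    "ppv", "lr_plus", "lr_minus", "aic", "bic") %in%
                  names(cmp)))
  flags <- attr(cmp, "flags")
  expect_identical(flags$aic, "m2")
  expect_identical(flags$bic, "m1")
  expect_identical(flags$auc, c("m1", "m2")[which.max(c(a$auc, b$auc))])
  tie <- compare_models(list(m1 = a, m2 = a))
  expect_match(attr(tie, "flags")$auc, "tie")
})
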