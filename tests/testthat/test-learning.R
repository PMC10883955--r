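make_one_node <- function(yes, no, alpha) {
  d <- data.frame(A = factor(rep(c("yes", "no"), c(yes, no)),
                             levels = c("no", "yes")))
  fit_bayes_net(dag("A"), d, alpha = alpha)
}

test_that("CPT estimation: maximum likelihood and Laplace arithmetic", {
  f0 <- make_one_node(3, 7, alpha = 0)
  expect_equal(as.vector(f0$cpts$A[c("yes", "no")]), c(0.3, 0.7))
  f1 <- make_one_node(3, 7, alpha = 1)
  expect_equal(as.vector(f1$cpts$A[c("yes", "no")]), c(4 / 12, 8 / 12))
  expect_error(fit_bayes_net(dag("A"),
                             data.frame(A = factor(character(0),
                                                   levels = c("no", "yes"))),
                             alpha = 0),
               "empty data")
})

test_that("unseen parent configurations fall back to uniform, smoothed fits validate", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  d <- data.frame(A = factor(c("a1", "a1"), levels = c("a1", "a2")),
                  B = factor(c("b1", "b2"), levels = c("b1", "b2")))
  expect_message(fit <- fit_bayes_net(g, d, alpha = 0), "unseen")
  expect_equal(unname(fit$cpts$B[, "a2"]), c(0.5, 0.5))
  tab <- test_cohort(491, seed = 42)
  fit2 <- suppressMessages(fit_bayes_net(knowledge_dag(), tab, alpha = 1))
  expect_true(validate_network(fit2)$valid)
  expect_true(all(as.vector(fit2$cpts$ascvd) > 0))
})

test_that("log-likelihood matches closed forms and a joint-table oracle", {
  f <- make_one_node(1, 1, alpha = 0)   # P = (0.5, 0.5)
  d2 <- data.frame(A = factor(c("yes", "no"), levels = c("no", "yes")))
  expect_equal(loglikelihood(f, d2), 2 * log(0.5), tolerance = 1e-12)
  expect_identical(loglikelihood(f, d2[0, , drop = FALSE]), 0)
  bn <- random_net(4, seed = 6)
  d <- sample_cohort(100, seed = 8, bn = bn)
  joint <- oracle_joint(bn)
  key <- do.call(paste, joint[bn$dag$nodes])
  want <- sum(log(joint$prob[match(do.call(paste, lapply(d, as.character)),
                                   key)]))
  expect_equal(loglikelihood(bn, d), want, tolerance = 1e-9)
})

test_that("information criteria use -2logL + penalty with the family parameter count", {
  f <- make_one_node(1, 1, alpha = 0)
  ic <- information_criteria(f, data.frame(A = factor(c("yes", "no"),
                                                      levels = c("no", "yes"))))
  expect_identical(ic$k, 1)
  expect_equal(ic$aic, 4.7726, tolerance = 1e-4)
  expect_equal(ic$bic, -2 * 2 * log(0.5) + log(2), tolerance = 1e-12)
  expect_equal(stats::AIC(f), ic$aic, tolerance = 1e-12)
})

test_that("adding arcs never decreases the maximum-likelihood fit", {
  d <- test_cohort(300, seed = 13)
  nodes <- c("age", "smoking", "bmi", "ascvd")
  arcs <- rbind(c("age", "smoking"), c("age", "bmi"), c("smoking", "bmi"),
                c("age", "ascvd"), c("bmi", "ascvd"))
  last <- -Inf
  for (k in 0:nrow(arcs)) {
    g <- dag(nodes, arcs[seq_len(k), , drop = FALSE])
    ll <- loglikelihood(suppressMessages(fit_bayes_net(g, d[nodes], alpha = 0)),
                        d[nodes])
    expect_gte(ll, last - 1e-9)
    last <- ll
  }
})

test_that("BIC identifies the generating structure once n outweighs its penalty", {
  # the outcome family alone costs (1151/2) log n, so consistency needs a
  # large sample; n = 20000 gives the generating DAG a decisive margin
  d <- sample_cohort(20000, seed = 3)
  ic_k <- information_criteria(
    suppressMessages(fit_bayes_net(knowledge_dag(), d, alpha = 0)), d)
  ic_e <- information_criteria(
    fit_bayes_net(dag(names(cohort_schema())), d, alpha = 0), d)
  expect_lt(ic_k$bic, ic_e$bic)
  expect_lt(ic_k$aic, ic_e$aic)
})

test_that("BDeu is decomposable: per-family scores sum to the total and
           single-arc changes touch one family", {
  d <- test_cohort(400, seed = 19)
  g1 <- dag(c("age", "bmi", "fbs"), rbind(c("age", "bmi")))
  g2 <- dag(c("age", "bmi", "fbs"), rbind(c("age", "bmi"), c("bmi", "fbs")))
  s1 <- bdeu_score(g1, d[c("age", "bmi", "fbs")])
  s2 <- bdeu_score(g2, d[c("age", "bmi", "fbs")])
  expect_equal(s1$total, sum(s1$per_family), tolerance = 1e-6)
  expect_equal(s2$total, sum(s2$per_family), tolerance = 1e-6)
  expect_equal(s1$per_family[["age"]], s2$per_family[["age"]])
  expect_equal(s1$per_family[["bmi"]], s2$per_family[["bmi"]])
  expect_false(isTRUE(all.equal(s1$per_family[["fbs"]],
                                s2$per_family[["fbs"]])))
})

test_that("hill climbing finds the exhaustive-search optimum on 3 nodes", {
  bn <- collider_net()
  d <- sample_cohort(2000, seed = 5, bn = bn)
  found <- bayesian_search(d, learning_config(restarts = 5, seed = 5))
  candidates <- all_dags(c("X", "Y", "Z"))
  expect_identical(length(candidates), 25L)
  scores <- vapply(candidates, function(g) bdeu_score(g, d)$total, 1)
  expect_equal(attr(found, "score"), max(scores), tolerance = 1e-6)
})

test_that("independent variables yield the empty graph", {
  set.seed(9)
  d <- data.frame(A = factor(sample(c("x", "y"), 10000, TRUE)),
                  B = factor(sample(c("x", "y"), 10000, TRUE)),
                  C = factor(sample(c("x", "y"), 10000, TRUE)))
  g <- bayesian_search(d, learning_config(restarts = 3, seed = 2))
  expect_identical(nrow(g$edges), 0L)
  # empty graph outscores every single-arc graph by direct evaluation
  empty_score <- bdeu_score(dag(c("A", "B", "C")), d)$total
  for (from in c("A", "B", "C")) for (to in setdiff(c("A", "B", "C"), from)) {
    g1 <- dag(c("A", "B", "C"), rbind(c(from, to)))
    expect_gte(empty_score, bdeu_score(g1, d)$total)
  }
})

test_that("search is deterministic given a seed and logs a monotone trace", {
  d <- test_cohort(300, seed = 23)
  cfg <- learning_config(restarts = 4, seed = 11)
  g1 <- bayesian_search(d, cfg, trace = TRUE)
  g2 <- bayesian_search(d, cfg, trace = TRUE)
  expect_identical(g1$edges, g2$edges)
  expect_identical(attr(g1, "score"), attr(g2, "score"))
  tr <- attr(g1, "trace")
  expect_true(!is.null(tr) && nrow(tr) > 0)
  for (r in unique(tr$restart))
    expect_true(all(diff(tr$score[tr$restart == r]) > 0))
  # max_parents is respected
  g3 <- bayesian_search(d, learning_config(restarts = 2, max_parents = 2,
                                           seed = 1))
  indeg <- table(factor(g3$edges[, 2], levels = g3$nodes))
  expect_true(all(indeg <= 2))
})

test_that("refitting a well-supported 5-node net recovers every CPT cell", {
  # chain/tree structure: every family has at most 4 parent configurations,
  # so all cells are estimated from thousands of records
  g <- dag(c("A", "B", "C", "D", "E"),
           rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D"),
                 c("D", "E")))
  lv <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"),
             D = c("d1", "d2"), E = c("e1", "e2"))
  mk <- function(v, vals) {
    pa <- dag_parents(g, v)
    card <- c(2L, rep(2L, length(pa)))
    arr <- array(vals, dim = card, dimnames = c(lv[v], lv[pa]))
    attr(arr, "parents") <- pa
    arr
  }
  bn <- bayes_net(g, list(
    A = mk("A", c(0.5, 0.5)),
    B = mk("B", c(0.75, 0.25, 0.3, 0.7)),
    C = mk("C", c(0.15, 0.85, 0.6, 0.4)),
    D = mk("D", c(0.9, 0.1, 0.75, 0.25, 0.25, 0.75, 0.1, 0.9)),
    E = mk("E", c(0.25, 0.75, 0.65, 0.35))), lv)
  d <- sample_cohort(50000, seed = 11, bn = bn)
  fit <- fit_bayes_net(g, d, alpha = 0)
  for (v in g$nodes)
    expect_lt(max(abs(as.vector(fit$cpts[[v]]) - as.vector(bn$cpts[[v]]))),
              0.01)
})

test_that("smoothed fits keep held-out likelihood finite", {
  train <- test_cohort(200, seed = 31)
  test <- sample_cohort(200, seed = 32)
  fit <- suppressMessages(fit_bayes_net(knowledge_dag(), train, alpha = 1))
  expect_true(is.finite(loglikelihood(fit, test)))
})
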