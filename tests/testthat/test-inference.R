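test_that("a root's posterior with no evidence is its prior CPT row", {
  bn <- two_node_net()
  expect_equal(unname(bn_query(bn, "X")), c(0.6, 0.4), tolerance = 1e-12)
})

test_that("two-node worked example: forward and inverted queries", {
  bn <- two_node_net()
  expect_equal(bn_query(bn, "Y")[["y1"]], 0.62, tolerance = 1e-12)
  expect_equal(bn_query(bn, "X", c(Y = "y1"))[["x1"]], 0.54 / 0.62,
               tolerance = 1e-12)
})

test_that("variable elimination equals full-joint enumeration on small nets", {
  for (seed in 1:10) {
    n_nodes <- 3 + (seed %% 4)
    bn <- random_net(n_nodes, seed = seed)
    nodes <- bn$dag$nodes
    set.seed(1000 + seed)
    for (rep in 1:3) {
      target <- sample(nodes, 1)
      n_ev <- sample(0:(n_nodes - 1), 1)
      ev_nodes <- sample(setdiff(nodes, target), n_ev)
      ev <- vapply(ev_nodes, function(v) sample(bn$levels[[v]], 1), "")
      got <- tryCatch(bn_query(bn, target, ev), error = function(e) e)
      want <- oracle_posterior(bn, target, as.list(ev))
      if (inherits(got, "error")) {
        expect_true(all(is.nan(want)))  # zero-probability evidence
      } else {
        expect_equal(unname(got), unname(want), tolerance = 1e-10)
        expect_equal(sum(got), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("posteriors are identical across elimination orders", {
  bn <- random_net(6, seed = 21)
  nodes <- bn$dag$nodes
  target <- nodes[3]
  ev <- stats::setNames(bn$levels[[nodes[1]]][1], nodes[1])
  elim <- setdiff(nodes, c(target, names(ev)))
  base <- bn_query(bn, target, ev)
  set.seed(99)
  for (i in 1:8) {
    perm <- sample(elim)
    expect_equal(bn_query(bn, target, ev, elim_order = perm), base,
                 tolerance = 1e-9)
  }
  expect_error(bn_query(bn, target, ev, elim_order = elim[-1]),
               "permutation")
})

test_that("impossible evidence raises an error rather than returning NaN", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  ca <- array(c(1, 0), 2, dimnames = list(c("a1", "a2")))
  attr(ca, "parents") <- character(0)
  cb <- array(c(1, 0, 0.5, 0.5), c(2, 2),
              dimnames = list(c("b1", "b2"), c("a1", "a2")))
  attr(cb, "parents") <- "A"
  bn <- bayes_net(g, list(A = ca, B = cb))
  expect_error(bn_query(bn, "A", c(B = "b2")), "zero probability")
  expect_error(bn_query(bn, "A", c(B = "nope")), "not a state")
  expect_error(bn_query(bn, "A", c(A = "a1")), "evidence")
})

test_that("empty-evidence queries match forward-sampled marginals", {
  gt <- default_ground_truth()
  samp <- sample_cohort(100000, seed = 314)
  for (v in c("ascvd", "mets", "hdl")) {
    exact <- bn_query(gt, v)
    emp <- table(samp[[v]]) / nrow(samp)
    for (s in names(exact)) {
      se <- sqrt(exact[[s]] * (1 - exact[[s]]) / nrow(samp))
      expect_lt(abs(emp[[s]] - exact[[s]]), 3 * se + 1e-12)
    }
  }
})

test_that("strength of influence matches hand-computed distances", {
  g <- dag(c("P", "C"), rbind(c("P", "C")))
  cp <- array(c(0.5, 0.5), 2, dimnames = list(c("p1", "p2")))
  attr(cp, "parents") <- character(0)
  cc <- array(c(0.9, 0.1, 0.2, 0.8), c(2, 2),
              dimnames = list(c("c1", "c2"), c("p1", "p2")))
  attr(cc, "parents") <- "P"
  bn <- bayes_net(g, list(P = cp, C = cc))
  expect_equal(strength_of_influence(bn, "P", "C"), sqrt(2 * 0.7^2),
               tolerance = 1e-12)
  expect_equal(strength_of_influence(bn, "P", "C", metric = "tv"), 0.7,
               tolerance = 1e-12)
  expect_equal(strength_of_influence(bn, "P", "C", metric = "hellinger"),
               sqrt(sum((sqrt(c(0.9, 0.1)) - sqrt(c(0.2, 0.8)))^2)) / sqrt(2),
               tolerance = 1e-12)
  # identical conditionals: zero influence
  cc0 <- array(c(0.3, 0.7, 0.3, 0.7), c(2, 2),
               dimnames = list(c("c1", "c2"), c("p1", "p2")))
  attr(cc0, "parents") <- "P"
  bn0 <- bayes_net(g, list(P = cp, C = cc0))
  expect_equal(strength_of_influence(bn0, "P", "C"), 0)
  expect_error(strength_of_influence(bn, "C", "P"), "no arc")
})

test_that("doubling a CPT contrast never shrinks the strength", {
  g <- dag(c("P", "C"), rbind(c("P", "C")))
  cp <- array(c(0.5, 0.5), 2, dimnames = list(c("p1", "p2")))
  attr(cp, "parents") <- character(0)
  mk <- function(d) {
    cc <- array(c(0.5 + d, 0.5 - d, 0.5 - d, 0.5 + d), c(2, 2),
                dimnames = list(c("c1", "c2"), c("p1", "p2")))
    attr(cc, "parents") <- "P"
    bayes_net(g, list(P = cp, C = cc))
  }
  for (metric in c("euclidean", "hellinger", "tv")) {
    last <- -1
    for (d in c(0.05, 0.1, 0.2, 0.25)) {
      s <- strength_of_influence(mk(d), "P", "C", metric = metric)
      expect_gt(s, last)
      last <- s
    }
  }
})

test_that("the strength table covers every arc and ranks the strong ones first", {
  bn <- suppressMessages(fit_bayes_net(ground_truth_dag(), test_cohort(2000, 17),
                                       alpha = 1))
  st <- strength_table(bn)
  expect_identical(nrow(st), nrow(bn$dag$edges))
  expect_true(all(st$strength >= 0))
  gt <- default_ground_truth()
  st_gt <- strength_table(gt)
  # tc -> ldl carries the generator's largest single effect (logit +2.5);
  # it should outrank the weak bmi -> ascvd arc
  expect_gt(st_gt$strength[st_gt$from == "tc" & st_gt$to == "ldl"],
            st_gt$strength[st_gt$from == "bmi" & st_gt$to == "ascvd"])
})

test_that("cp_report instantiates risk states and rows sum to 100", {
  bn <- suppressMessages(fit_bayes_net(knowledge_dag(), test_cohort(491, 42),
                                       alpha = 1))
  rep <- cp_report(bn)
  expect_identical(dim(rep), c(12L, 7L))
  expect_equal(rep$cp_no + rep$cp_yes, rep(100, 12), tolerance = 1e-9)
  sm <- rep[rep$var1 == "smoking" & rep$var2 == "hypertension", ]
  expect_identical(sm$state1, "past-or-current")
  expect_identical(sm$state2, "yes")
  hd <- rep[rep$var2 == "hdl", ]
  expect_true(all(hd$state2 == "low"))
  ag <- rep[rep$var1 == "age", ]
  expect_true(all(ag$state1 == "over45"))
  expect_error(cp_report(bn, pairs = rbind(c("ascvd", "bmi"))), "distinct")
})
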