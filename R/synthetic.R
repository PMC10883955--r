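# Package-local cache (the calibrated ground-truth network is deterministic,
# so it is built once per session).
.ascvdbn_cache <- new.env(parent = emptyenv())

# Log-odds contributions of each parent state to a child's non-reference
# states. These encode the generator's epidemiological assumptions: smoking
# is strongly male-dominated; age raises blood pressure, glucose and
# diabetes; adiposity raises glucose, triglycerides and metabolic syndrome
# and depresses HDL-C; LDL-C tracks total cholesterol; ASCVD risk is
# concentrated in over-45 males with adverse metabolic and lipid profiles.
# Intercepts are not listed here: they are solved exactly so that each
# node's marginal matches the published cohort margins.
gt_effect_table <- function() {
  list(
    smoking = list("past-or-current" = list(sex = c(0, 3.4), age = c(0, 0.3))),
    bmi = list(
      overweight = list(age = c(0, 0.5), smoking = c(0, -0.2)),
      obesity = list(age = c(0, 0.8), smoking = c(0, -0.3))),
    fbs = list(high = list(age = c(0, 1.0), bmi = c(0, 0.6, 1.2))),
    tg = list(high = list(bmi = c(0, 0.5, 0.9), fbs = c(0, 1.0),
                          sex = c(0, 0.7), smoking = c(0, 0.5))),
    hdl = list(
      low = list(sex = c(0, 1.0), bmi = c(0, 0.5, 0.9), fbs = c(0, 0.4),
                 smoking = c(0, 0.5), tg = c(0, 0.9)),
      high = list(sex = c(0, -0.8), bmi = c(0, -0.4, -0.8), fbs = c(0, -0.3),
                  smoking = c(0, -0.4), tg = c(0, -0.8))),
    tc = list(high = list(hdl = c(0.2, 0, 0.7))),
    ldl = list(high = list(tc = c(0, 2.5), smoking = c(0, 0.4))),
    diabetes = list(yes = list(age = c(0, 1.3), bmi = c(0, 0.5, 1.0),
                               sex = c(0, 0.8), tg = c(0, 0.8))),
    hypertension = list(yes = list(age = c(0, 1.4), bmi = c(0, 0.5, 1.0),
                                   fbs = c(0, 0.8), sex = c(0, 0.7),
                                   smoking = c(0, 0.4))),
    mets = list(yes = list(bmi = c(0, 1.2, 2.4), fbs = c(0, 1.6),
                           tg = c(0, 1.8))),
    ascvd = list(yes = list(age = c(0, 2.9), sex = c(0, 3.2),
                            smoking = c(0, 1.0), diabetes = c(0, 1.2),
                            hypertension = c(0, 0.8), bmi = c(0, 0.2, 0.5),
                            tc = c(0, 0.5), ldl = c(0, 0.8), fbs = c(0, 0.5),
                            hdl = c(0.5, 0, -0.4)))
  )
}

# Published "All" column margins the generator is calibrated to (proportion
# of each non-reference state).
gt_margin_targets <- function() {
  list(
    age = c(over45 = 0.362), sex = c(male = 0.638),
    smoking = c("past-or-current" = 0.098),
    bmi = c(overweight = 0.514, obesity = 0.266),
    fbs = c(high = 0.112), tg = c(high = 0.242), tc = c(high = 0.280),
    hdl = c(low = 0.360, high = 0.266), ldl = c(high = 0.234),
    diabetes = c(yes = 0.042), hypertension = c(yes = 0.076),
    mets = c(yes = 0.228), ascvd = c(yes = 0.077)
  )
}

#' Structure of the default synthetic ground truth
#'
#' The literature-derived 13-node DAG augmented with one direct sex -> ASCVD
#' arc. The augmentation is needed because in the source cohort every ASCVD
#' case was male: with sex acting only through its mediators (smoking,
#' diabetes, hypertension, HDL-C, TG), no choice of CPTs can concentrate the
#' outcome in males that strongly, so the generator gives sex a direct
#' effect on the outcome.
#'
#' @return A `bn_dag` with 13 nodes and 40 arcs.
#' @export
ground_truth_dag <- function() {
  g <- knowledge_dag()
  dag(g$nodes, rbind(g$edges, c("sex", "ascvd")))
}

# Build one node's CPT from effects, solving intercepts so that the exact
# marginal (under `parent_joint`, a probability vector over the parent grid
# in CPT parent order) matches `targets`.
calibrate_cpt <- function(states, ref, parent_levels, effects, targets,
                          parent_joint) {
  r <- length(states)
  card <- vapply(parent_levels, length, 1L)
  q <- if (length(card)) prod(card) else 1L
  nonref <- setdiff(states, ref)
  # utility matrix rows = parent configs, cols = non-reference states
  u <- matrix(0, q, length(nonref), dimnames = list(NULL, nonref))
  if (length(card)) {
    grid <- arrayInd(seq_len(q), card)
    for (s in nonref) {
      for (p in names(effects[[s]]))
        u[, s] <- u[, s] + effects[[s]][[p]][grid[, match(p, names(parent_levels))]]
    }
  }
  b <- stats::setNames(rep(0, length(nonref)), nonref)
  probs <- NULL
  for (it in 1:200) {
    eu <- exp(sweep(u, 2, b, "+"))
    denom <- 1 + rowSums(eu)
    probs <- cbind(ref = 1 / denom, eu / denom)
    marg <- as.vector(parent_joint %*% probs)[-1]
    names(marg) <- nonref
    if (max(abs(marg - targets[nonref])) < 1e-12) break
    b <- b + log(targets[nonref] / marg)
  }
  # assemble CPT array in state order (ref goes back to its position)
  colnames(probs) <- c(ref, nonref)
  arr <- array(0, dim = c(r, card),
               dimnames = c(list(states), parent_levels))
  pm <- t(probs[, states, drop = FALSE])
  arr[] <- as.vector(pm)
  attr(arr, "parents") <- names(parent_levels)
  arr
}

#' The default calibrated ground-truth network
#'
#' A fully specified discrete Bayesian network over the 13 cohort
#' variables, used to generate synthetic cohorts. CPTs are built from
#' logistic (multinomial-logit for the three-level variables) parent
#' effects with intercepts solved exactly, node by node in topological
#' order, so that every marginal matches the published cohort margins
#' (male 63.8%, over-45 36.2%, smoking 9.8%, diabetes 4.2%, hypertension
#' 7.6%, metabolic syndrome 22.8%, overweight 51.4%, obesity 26.6%, high
#' FBS 11.2%, high TG 24.2%, high T-C 28.0%, low HDL-C 36.0%, high HDL-C
#' 26.6%, high LDL-C 23.4%, ASCVD 7.7%) to numerical precision, and the
#' outcome is concentrated in over-45 males (P(ASCVD | female) < 0.02).
#'
#' @return A `dbn` over [ground_truth_dag()].
#' @export
default_ground_truth <- function() {
  if (!is.null(.ascvdbn_cache$gt)) return(.ascvdbn_cache$gt)
  g <- ground_truth_dag()
  schema <- cohort_schema()
  levels <- cohort_levels(schema)
  targets <- gt_margin_targets()
  effects <- gt_effect_table()
  refs <- lapply(schema, `[[`, "reference")
  ord <- topo_sort(g)
  joint <- NULL
  cpts <- list()
  for (v in ord) {
    pa <- dag_parents(g, v)
    if (length(pa)) {
      pj <- joint
      for (u in setdiff(pj$vars, pa)) pj <- factor_marginalize(pj, u)
      # reorder to CPT parent order
      card <- vapply(pa, function(p) length(levels[[p]]), 1L)
      coords <- arrayInd(seq_len(prod(card)), card)
      parent_joint <- pj$values[factor_lin_index(coords, pa, pj)]
    } else {
      parent_joint <- 1
    }
    cpt <- calibrate_cpt(levels[[v]], refs[[v]], levels[pa],
                         effects[[v]] %||% list(), targets[[v]], parent_joint)
    cpts[[v]] <- cpt
    f <- new_factor(c(v, pa),
                    vapply(c(v, pa), function(u) length(levels[[u]]), 1L),
                    as.vector(cpt))
    joint <- if (is.null(joint)) f else factor_product(joint, f)
  }
  bn <- bayes_net(g, cpts[g$nodes], levels)
  .ascvdbn_cache$gt <- bn
  bn
}

#' Ancestral sampling from a discrete Bayesian network
#'
#' Draws records node by node in topological order, each node sampled from
#' its CPT at the already-sampled parent states. Bitwise reproducible for a
#' given seed; the global RNG state is left untouched.
#'
#' @param object a `dbn`.
#' @param nsim number of records.
#' @param seed integer seed.
#' @param ... unused.
#' @return A `cohort_table` data frame of factors (column order follows the
#'   network's node order).
#' @export
simulate.dbn <- function(object, nsim = 1, seed = 1, ...) {
  ord <- topo_sort(object$dag)
  n <- as.integer(nsim)
  codes <- matrix(0L, n, length(object$dag$nodes),
                  dimnames = list(NULL, object$dag$nodes))
  with_seed(seed, {
    for (v in ord) {
      pa <- object$parents[[v]]
      r <- length(object$levels[[v]])
      m <- matrix(as.vector(object$cpts[[v]]), nrow = r)
      cfg <- if (length(pa)) {
        card <- vapply(pa, function(p) length(object$levels[[p]]), 1L)
        linear_index(codes[, pa, drop = FALSE], card)
      } else rep(1L, n)
      if (n > 0) {
        u <- stats::runif(n)
        acc <- rep(0, n)
        st <- rep(r, n)
        assigned <- rep(FALSE, n)
        for (k in seq_len(r - 1)) {
          acc <- acc + m[k, cfg]
          hit <- !assigned & u < acc
          st[hit] <- k
          assigned <- assigned | hit
        }
        codes[, v] <- st
      }
    }
  })
  out <- data.frame(row.names = seq_len(n))
  for (v in object$dag$nodes)
    out[[v]] <- factor(object$levels[[v]][codes[, v]],
                       levels = object$levels[[v]])
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Generate a synthetic cohort
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param bn generating network (default [default_ground_truth()]).
#' @param continuous if TRUE, back-fill raw numeric values for the
#'   continuous variables (age, BMI, lipids, glucose) by drawing from
#'   truncated normal distributions inside each sampled category's bin, so
#'   that discretization recovers the categories exactly.
#' @return A `cohort_table`; with `continuous = TRUE` a plain data frame
#'   with numeric measurement columns.
#' @export
sample_cohort <- function(n, seed = 1, bn = default_ground_truth(),
                          continuous = FALSE) {
  tab <- simulate.dbn(bn, nsim = n, seed = seed)
  if (continuous) tab <- backfill_continuous(tab, seed = seed + 1L)
  tab
}

# bin -> (lo, hi, mean, sd) for the truncated-normal back-fill. Bounds sit
# strictly inside each category so discretization is exact; means/SDs are
# round clinical values (age uses the cohort's reported mean and SD).
backfill_bins <- function() {
  list(
    age = list(under45 = c(24, 44.99, 43.2, 7.2), over45 = c(45, 67, 43.2, 7.2)),
    bmi = list(normal = c(18.6, 24.99, 22.5, 2.0),
               overweight = c(25.0, 29.99, 27.0, 1.5),
               obesity = c(30.0, 44, 32.5, 2.5)),
    fbs = list(normal = c(70, 99.4, 90, 8), high = c(100, 250, 115, 20)),
    tg = list(normal = c(50, 149.4, 110, 25), high = c(150, 500, 200, 55)),
    tc = list(normal = c(120, 199.4, 172, 18), high = c(200, 320, 222, 20)),
    hdl = list(low = c(25, 44.4, 39, 4), normal = c(45, 55, 50, 3),
               high = c(55.2, 95, 62, 6)),
    ldl = list(normal = c(40, 129.4, 100, 18), high = c(130, 220, 152, 18))
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Back-fill raw continuous measurements inside sampled categories
#'
#' @param data a `cohort_table` of factors.
#' @param seed integer seed.
#' @return Data frame where the continuous variables hold numeric values
#'   consistent with their sampled categories.
#' @export
backfill_continuous <- function(data, seed = 1) {
  bins <- backfill_bins()
  out <- as.data.frame(data)
  with_seed(seed, {
    for (v in names(bins)) {
      x <- numeric(nrow(out))
      for (s in names(bins[[v]])) {
        b <- bins[[v]][[s]]
        i <- which(as.character(data[[v]]) == s)
        x[i] <- rtrunc_norm(length(i), b[3], b[4], b[1], b[2])
      }
      out[[v]] <- round(x, 2)
    }
  })
  out
}
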