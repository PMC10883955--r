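#' Fit the conditional probability tables of a network to cohort data
#'
#' Parametric learning: every CPT cell is estimated as
#' (count + alpha) / (configuration total + alpha * number of child states),
#' i.e. maximum likelihood for `alpha = 0` and Dirichlet (Laplace for
#' `alpha = 1`) smoothing otherwise. Parent configurations never observed in
#' the data receive the uniform distribution; with a 13-variable network and
#' a few hundred records this fallback is routinely exercised for
#' high-fan-in nodes, so smoothing (`alpha > 0`) is the recommended default
#' whenever the fit is used for prediction.
#'
#' @param structure a `bn_dag` whose nodes all appear as columns of `data`.
#' @param data a `cohort_table` (or any data frame of factors).
#' @param alpha Dirichlet pseudo-count per CPT cell (>= 0).
#' @return Object of class `c("dbn_fit", "dbn")`; in addition to the `dbn`
#'   fields it stores `n`, `alpha`, `loglik` (training log-likelihood under
#'   the fitted CPTs) and `df` (free-parameter count).
#' @export
fit_bayes_net <- function(structure, data, alpha = 1) {
  stopifnot(inherits(structure, "bn_dag"), alpha >= 0)
  missing <- setdiff(structure$nodes, names(data))
  if (length(missing))
    stop("data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0 && alpha == 0)
    stop("cannot estimate probabilities from empty data with alpha = 0",
         call. = FALSE)
  levels <- lapply(structure$nodes, function(v) levels(as.factor(data[[v]])))
  names(levels) <- structure$nodes
  cpts <- list()
  unseen <- 0L
  for (v in structure$nodes) {
    pa <- dag_parents(structure, v)
    tab <- table(data[c(v, pa)])
    m <- array(as.numeric(tab) + alpha, dim = dim(tab), dimnames = dimnames(tab))
    r <- dim(m)[1]
    cm <- matrix(as.vector(m), nrow = r)
    tot <- colSums(cm)
    zero <- tot == 0
    unseen <- unseen + sum(colSums(matrix(as.numeric(tab), nrow = r)) == 0)
    cm <- sweep(cm, 2, ifelse(zero, 1, tot), "/")
    cm[, zero] <- 1 / r
    arr <- array(as.vector(cm), dim = dim(m), dimnames = dimnames(m))
    attr(arr, "parents") <- pa
    cpts[[v]] <- arr
  }
  bn <- bayes_net(structure, cpts, levels)
  if (unseen > 0)
    message("fit_bayes_net: ", unseen,
            " unseen parent configuration(s) set to the uniform distribution")
  bn$n <- nrow(data)
  bn$alpha <- alpha
  bn$df <- n_free_parameters(bn)
  class(bn) <- c("dbn_fit", "dbn")
  bn$loglik <- if (nrow(data)) loglikelihood(bn, data) else 0
  bn
}

# integer code matrix for data under a network's level sets
code_matrix <- function(bn, data) {
  m <- vapply(bn$dag$nodes, function(v) {
    codes <- match(as.character(data[[v]]), bn$levels[[v]])
    if (anyNA(codes))
      stop("data contains states outside the network's state space for '",
           v, "'", call. = FALSE)
    codes
  }, integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L,
                                    dimnames = list(NULL, bn$dag$nodes))
  m
}

#' Log-likelihood of data under a discrete Bayesian network
#'
#' Sum over records of the log of the factorized joint probability.
#' Returns `-Inf` when a record hits a zero-probability CPT cell; empty data
#' gives 0.
#'
#' @param bn a `dbn`.
#' @param data data frame of factors matching the network's state spaces.
#' @return Single number (log-probability, natural log).
#' @export
loglikelihood <- function(bn, data) {
  if (nrow(data) == 0) return(0)
  codes <- code_matrix(bn, data)
  ll <- 0
  for (v in bn$dag$nodes) {
    fam <- c(v, bn$parents[[v]])
    card <- vapply(fam, function(u) length(bn$levels[[u]]), 1L)
    idx <- linear_index(codes[, fam, drop = FALSE], card)
    ll <- ll + sum(log(as.vector(bn$cpts[[v]])[idx]))
  }
  ll
}

#' @export
logLik.dbn_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' Information criteria for comparing network structures
#'
#' AIC = -2 log L + 2 k and BIC = -2 log L + k log n, with k the number of
#' free parameters (sum over nodes of (states - 1) x parent configurations).
#' Smaller values indicate the better structure. By convention the criteria
#' are computed from a maximum-likelihood fit (`alpha = 0`); pass a fitted
#' network to score it on (held-out or training) data.
#'
#' @param bn a `dbn`.
#' @param data data frame of factors.
#' @return List with `aic`, `bic`, `loglik`, `k`, `n`.
#' @export
information_criteria <- function(bn, data) {
  ll <- loglikelihood(bn, data)
  k <- n_free_parameters(bn)
  n <- nrow(data)
  list(aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
       loglik = ll, k = k, n = n)
}

#' Posterior prediction for new records
#'
#' For each row of `newdata`, all observed non-target columns are entered
#' as evidence and the exact posterior of the target is computed by
#' variable elimination.
#'
#' @param object a fitted `dbn`.
#' @param newdata data frame of factors (target column, if present, is
#'   ignored as evidence).
#' @param target node to predict (default "ascvd").
#' @param type "prob" for the posterior matrix, "state" for the maximum
#'   posterior state.
#' @param ... unused.
#' @return Matrix n x states of posterior probabilities, or a character
#'   vector of states.
#' @export
predict.dbn <- function(object, newdata, target = "ascvd", type = "prob",
                        ...) {
  ev_vars <- intersect(setdiff(object$dag$nodes, target), names(newdata))
  states <- object$levels[[target]]
  probs <- matrix(NA_real_, nrow(newdata), length(states),
                  dimnames = list(NULL, states))
  for (i in seq_len(nrow(newdata))) {
    ev <- stats::setNames(
      vapply(ev_vars, function(v) as.character(newdata[[v]][i]), ""),
      ev_vars)
    probs[i, ] <- bn_query(object, target, ev)
  }
  if (type == "state") states[max.col(probs)] else probs
}
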