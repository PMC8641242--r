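#' Exact Bayesian posterior over causes
#'
#' Applies Bayes' rule on a finite generative model:
#' `p(theta | x) = p(x | theta) p(theta) / p(x)`.
#'
#' @param model a [discrete_generative_model()].
#' @param x observed sensory symbol, as a column index or label.
#' @return the posterior as a [discrete_distribution()].
#' @export
exact_posterior <- function(model, x) {
  j <- symbol_index(model, x)
  lik <- model$likelihood[, j]
  joint <- lik * unclass(model$prior)
  marginal <- sum(joint)
  if (marginal <= 0) {
    stop_arousal(
      sprintf("observation '%s' has zero marginal probability under the model",
              colnames(model$likelihood)[j]),
      "arousalfe_impossible_observation"
    )
  }
  discrete_distribution(joint / marginal, labels = rownames(model$likelihood))
}

# KL(p || q) on common finite support, with 0 log 0 = 0 and +Inf where p puts
# mass on q's zeros.
discrete_kl <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (any(p > 0 & q <= 0)) return(Inf)
  sum(xlogy(p, p) - xlogy(p, q))
}

discrete_entropy <- function(p) -sum(xlogy(as.numeric(p), as.numeric(p)))

check_recognition <- function(model, q) {
  if (!inherits(q, "discrete_distribution")) q <- discrete_distribution(q)
  if (length(q) != length(model$prior)) {
    stop_arousal("recognition density and cause support differ in length",
                 "arousalfe_support_mismatch")
  }
  q
}

#' Variational free energy of a recognition density
#'
#' The free energy of sensory symbol `x` under recognition density `q` is the
#' recognition-averaged difference between recognition and generative joint,
#' in nats:
#' \deqn{F = \langle \ln q(\theta) - \ln p(x, \theta) \rangle_{q(\theta)}.}
#' It is bounded below by the surprisal `-ln p(x)`, with equality exactly at
#' the Bayesian posterior.  If `q` places mass where the joint is zero, `F`
#' is `+Inf` (returned, not raised).
#'
#' @inheritParams exact_posterior
#' @param q recognition density over causes ([discrete_distribution()] or
#'   bare probability vector of matching length).
#' @return free energy in nats (possibly `Inf`).
#' @examples
#' m <- discrete_generative_model(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.4, 0.6)))
#' free_energy(m, exact_posterior(m, 1), 1)  # equals -log(0.6)
#' @export
free_energy <- function(model, q, x) {
  q <- check_recognition(model, q)
  j <- symbol_index(model, x)
  joint <- model$likelihood[, j] * unclass(model$prior)
  qv <- as.numeric(q)
  if (any(qv > 0 & joint <= 0)) return(Inf)
  sum(xlogy(qv, qv) - xlogy(qv, joint))
}

#' Both exact decompositions of free energy
#'
#' Free energy admits two exact additive decompositions:
#' posterior form `F = KL(q || p(theta|x)) + (-ln p(x))`
#' (divergence from the exact posterior, plus surprisal) and
#' arousal form `F = KL(q || p(theta)) + <-ln p(x|theta)>_q`
#' (Bayesian surprise / information gain, plus inverse accuracy, i.e. the
#' uncertainty).  The second form is the arousal-potential reading: novelty
#' plus perceived uncertainty.
#'
#' @inheritParams free_energy
#' @return a list of class `decomposition_record` with components
#'   `free_energy`, `kl_to_posterior`, `surprisal`, `bayesian_surprise`,
#'   `inverse_accuracy` (all in nats).
#' @examples
#' m <- discrete_generative_model(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.4, 0.6)))
#' decompose_free_energy(m, exact_posterior(m, 1), 1)
#' @export
decompose_free_energy <- function(model, q, x) {
  q <- check_recognition(model, q)
  j <- symbol_index(model, x)
  lik <- model$likelihood[, j]
  prior <- unclass(model$prior)
  marginal <- sum(lik * prior)
  if (marginal <= 0) {
    stop_arousal("observation has zero marginal probability",
                 "arousalfe_impossible_observation")
  }
  posterior <- lik * prior / marginal
  qv <- as.numeric(q)
  inv_acc <- if (any(qv > 0 & lik <= 0)) Inf else -sum(xlogy(qv, lik))
  rec <- list(
    free_energy = free_energy(model, q, x),
    kl_to_posterior = discrete_kl(qv, posterior),
    surprisal = -log(marginal),
    bayesian_surprise = discrete_kl(qv, prior),
    inverse_accuracy = inv_acc
  )
  class(rec) <- "decomposition_record"
  rec
}

#' @export
print.decomposition_record <- function(x, ...) {
  cat("<decomposition_record> (nats)\n")
  cat(sprintf("  free energy        F  = %.6f\n", x$free_energy))
  cat(sprintf("  KL(q || posterior)    = %.6f\n", x$kl_to_posterior))
  cat(sprintf("  surprisal  -ln p(x)   = %.6f\n", x$surprisal))
  cat(sprintf("  Bayesian surprise  G  = %.6f\n", x$bayesian_surprise))
  cat(sprintf("  inverse accuracy   U  = %.6f\n", x$inverse_accuracy))
  invisible(x)
}

#' Uncertainty before and after recognition
#'
#' The uncertainty (inverse accuracy) of an observation is the expected
#' surprise of the data given a cause, averaged over a recognition density.
#' Before recognition the density is the prior (`u_pri`); after recognition
#' it is the exact posterior (`u_post`); replacing the prior by the posterior
#' and predicting yields the predictive surprisal
#' `u_star = -ln <p(x|theta)>_posterior`.  The drop `u_pri - u_post` equals
#' the symmetrized Kullback-Leibler divergence between prior and posterior
#' and is therefore never negative, and `u_post >= u_star` by Jensen's
#' inequality: recognition and prior updating both shed uncertainty.
#'
#' @inheritParams exact_posterior
#' @return a list of class `uncertainty_record` with components `u_pri`,
#'   `u_post`, `u_star`, `reduction` (nats).
#' @export
uncertainty_reduction <- function(model, x) {
  j <- symbol_index(model, x)
  lik <- model$likelihood[, j]
  prior <- unclass(model$prior)
  posterior <- as.numeric(exact_posterior(model, x))
  u_pri <- if (any(prior > 0 & lik <= 0)) Inf else -sum(xlogy(prior, lik))
  u_post <- if (any(posterior > 0 & lik <= 0)) Inf else
    -sum(xlogy(posterior, lik))
  rec <- list(
    u_pri = u_pri,
    u_post = u_post,
    u_star = -log(sum(posterior * lik)),
    reduction = u_pri - u_post
  )
  class(rec) <- "uncertainty_record"
  rec
}

#' @export
print.uncertainty_record <- function(x, ...) {
  cat("<uncertainty_record> (nats)\n")
  cat(sprintf("  prior uncertainty     U_pri  = %.6f\n", x$u_pri))
  cat(sprintf("  posterior uncertainty U_post = %.6f\n", x$u_post))
  cat(sprintf("  predictive surprisal  U*     = %.6f\n", x$u_star))
  cat(sprintf("  reduction (symmetrized KL)   = %.6f\n", x$reduction))
  invisible(x)
}

#' Cross entropy of a predictive distribution against observed counts
#'
#' With `n` observations summarized as per-symbol counts, the predictive
#' surprisal of the whole sample is `n` times the cross entropy between the
#' empirical distribution `f` and the predictive distribution `p*`:
#' \deqn{-\ln p^*(D^n) = n \, \langle -\ln p^*(x) \rangle_{f(x)}.}
#' The cross entropy splits exactly into `KL(f || p*) + H(f)`, so the sample
#' entropy `H(f)` is its lower bound: once the model prediction matches the
#' empirical distribution, only the intrinsic complexity of the data remains.
#'
#' @param predictive a [discrete_distribution()] (or probability vector) over
#'   the sensory alphabet.
#' @param counts non-negative integer counts per symbol, total `>= 1`.
#' @return a list of class `cross_entropy_record` with components
#'   `u_star_total`, `cross_entropy`, `kl_to_empirical`, `empirical_entropy`
#'   (nats).  A predictive zero at an observed symbol yields `Inf` in the
#'   cross-entropy terms rather than an error.
#' @export
predictive_cross_entropy <- function(predictive, counts) {
  if (!inherits(predictive, "discrete_distribution")) {
    predictive <- discrete_distribution(predictive)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_arousal("`counts` must be non-negative integers",
                 "arousalfe_invalid_counts")
  }
  if (length(counts) != length(predictive)) {
    stop_arousal("`counts` and `predictive` must share the sensory alphabet",
                 "arousalfe_support_mismatch")
  }
  n <- sum(counts)
  if (n < 1) {
    stop_arousal("at least one observation is required",
                 "arousalfe_invalid_counts")
  }
  f <- counts / n
  p <- as.numeric(predictive)
  ce <- if (any(f > 0 & p <= 0)) Inf else -sum(xlogy(f, p))
  rec <- list(
    u_star_total = n * ce,
    cross_entropy = ce,
    kl_to_empirical = discrete_kl(f, p),
    empirical_entropy = discrete_entropy(f)
  )
  class(rec) <- "cross_entropy_record"
  rec
}

#' @export
print.cross_entropy_record <- function(x, ...) {
  cat("<cross_entropy_record> (nats)\n")
  cat(sprintf("  total predictive surprisal = %.6f\n", x$u_star_total))
  cat(sprintf("  cross entropy              = %.6f\n", x$cross_entropy))
  cat(sprintf("  KL(empirical || predictive)= %.6f\n", x$kl_to_empirical))
  cat(sprintf("  empirical entropy          = %.6f\n", x$empirical_entropy))
  invisible(x)
}
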