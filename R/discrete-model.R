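#' Discrete probability distribution over a finite labeled support
#'
#' A plain probability vector with optional support labels, validated at
#' construction: entries must be non-negative and sum to one (within `1e-12`
#' by default).  Used for priors, posteriors, recognition densities and
#' predictive distributions on finite cause/sensory alphabets.
#'
#' @param probs numeric vector of non-negative probabilities summing to 1.
#' @param labels optional character vector of support labels; defaults to
#'   the names of `probs` or `"s1"`, `"s2"`, ....
#' @param tol tolerance on the sum-to-one check.
#' @return an object of class `discrete_distribution`: the probability
#'   vector, named by its support labels.
#' @examples
#' discrete_distribution(c(0.5, 0.5))
#' @export
discrete_distribution <- function(probs, labels = NULL, tol = 1e-12) {
  if (!is.numeric(probs) || length(probs) < 1L) {
    stop_arousal("`probs` must be a non-empty numeric vector",
                 "arousalfe_invalid_distribution")
  }
  if (anyNA(probs) || any(probs < 0)) {
    stop_arousal("probabilities must be non-negative and non-missing",
                 "arousalfe_invalid_distribution")
  }
  if (abs(sum(probs) - 1) > tol) {
    stop_arousal(
      sprintf("probabilities must sum to 1 (got %.15g)", sum(probs)),
      "arousalfe_invalid_distribution"
    )
  }
  if (is.null(labels)) {
    labels <- if (!is.null(names(probs))) names(probs) else
      paste0("s", seq_along(probs))
  }
  if (length(labels) != length(probs)) {
    stop_arousal("`labels` must match `probs` in length",
                 "arousalfe_invalid_distribution")
  }
  structure(setNames(as.numeric(probs), as.character(labels)),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat("<discrete_distribution> over", length(x), "states\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Finite discrete generative model
#'
#' Joint belief over causes and sensory symbols, factored as an observation
#' model `p(x | theta)` (one likelihood row per cause) and a prior `p(theta)`.
#' Each likelihood row must itself be a probability distribution over the
#' sensory alphabet, so the implied joint sums to one exactly.
#'
#' @param prior a [discrete_distribution()] over causes, or a bare numeric
#'   probability vector.
#' @param likelihood numeric matrix of conditional probabilities
#'   `p(x | theta)`; rows index causes, columns sensory symbols, each row
#'   summing to 1.
#' @param causes,symbols optional label vectors; default to the prior names
#'   and the likelihood column names (or `"x1"`, `"x2"`, ...).
#' @param tol tolerance for the row-sum checks.
#' @return an object of class `discrete_generative_model` with elements
#'   `prior` and `likelihood`.
#' @seealso [exact_posterior()], [decompose_free_energy()],
#'   [read_discrete_model()]
#' @examples
#' m <- discrete_generative_model(
#'   prior = c(0.5, 0.5),
#'   likelihood = rbind(c(0.8, 0.2), c(0.4, 0.6))
#' )
#' exact_posterior(m, 1)
#' @export
discrete_generative_model <- function(prior, likelihood, causes = NULL,
                                      symbols = NULL, tol = 1e-12) {
  if (!inherits(prior, "discrete_distribution")) {
    prior <- discrete_distribution(prior, labels = causes, tol = tol)
  }
  likelihood <- as.matrix(likelihood)
  if (nrow(likelihood) != length(prior)) {
    stop_arousal("likelihood must have one row per cause",
                 "arousalfe_invalid_model")
  }
  if (anyNA(likelihood) || any(likelihood < 0)) {
    stop_arousal("likelihood entries must be non-negative",
                 "arousalfe_invalid_model")
  }
  row_sums <- rowSums(likelihood)
  bad <- which(abs(row_sums - 1) > tol)
  if (length(bad)) {
    stop_arousal(
      sprintf("likelihood row %d sums to %.15g, not 1", bad[1L],
              row_sums[bad[1L]]),
      "arousalfe_invalid_model"
    )
  }
  if (is.null(causes)) causes <- names(prior)
  if (is.null(symbols)) {
    symbols <- if (!is.null(colnames(likelihood))) colnames(likelihood) else
      paste0("x", seq_len(ncol(likelihood)))
  }
  dimnames(likelihood) <- list(causes, symbols)
  structure(
    list(prior = discrete_distribution(unclass(prior), labels = causes),
         likelihood = likelihood),
    class = "discrete_generative_model"
  )
}

#' @export
print.discrete_generative_model <- function(x, ...) {
  cat("<discrete_generative_model>",
      nrow(x$likelihood), "causes x", ncol(x$likelihood), "symbols\n")
  cat("prior:\n")
  print(unclass(x$prior))
  cat("likelihood p(x | theta):\n")
  print(x$likelihood)
  invisible(x)
}

# resolve a sensory symbol (index or label) to a column index
symbol_index <- function(model, x) {
  symbols <- colnames(model$likelihood)
  if (is.character(x)) {
    idx <- match(x, symbols)
    if (is.na(idx)) {
      stop_arousal(sprintf("unknown sensory symbol '%s'", x),
                   "arousalfe_unknown_symbol")
    }
    return(idx)
  }
  idx <- as.integer(x)
  if (is.na(idx) || idx < 1L || idx > length(symbols)) {
    stop_arousal("sensory symbol index out of range",
                 "arousalfe_unknown_symbol")
  }
  idx
}

#' Read or write a discrete generative model as JSON
#'
#' The on-disk schema is
#' `{"causes": [...], "symbols": [...], "prior": [...], "likelihood": [[...]]}`
#' with one likelihood row per cause.  Validation errors name the offending
#' row.
#'
#' @param path file path (or connection for `read_discrete_model`).
#' @return `read_discrete_model()` returns a `discrete_generative_model`;
#'   `write_discrete_model()` invisibly returns `path`.
#' @export
read_discrete_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (field in c("causes", "symbols", "prior", "likelihood")) {
    if (is.null(obj[[field]])) {
      stop_arousal(sprintf("model JSON is missing field '%s'", field),
                   "arousalfe_invalid_model")
    }
  }
  lik <- obj$likelihood
  if (is.list(lik)) lik <- do.call(rbind, lik)
  discrete_generative_model(
    prior = as.numeric(obj$prior),
    likelihood = lik,
    causes = as.character(obj$causes),
    symbols = as.character(obj$symbols)
  )
}

#' @rdname read_discrete_model
#' @param model a `discrete_generative_model`.
#' @export
write_discrete_model <- function(model, path) {
  stopifnot(inherits(model, "discrete_generative_model"))
  obj <- list(
    causes = rownames(model$likelihood),
    symbols = colnames(model$likelihood),
    prior = as.numeric(unclass(model$prior)),
    likelihood = unname(apply(model$likelihood, 1L, as.numeric,
                              simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Random discrete generative models for property checks
#'
#' Draws the prior and every likelihood row from the flat (uniform) Dirichlet
#' distribution on the simplex.  Intended as the generator behind
#' property-style tests of the free-energy identities.
#'
#' @param n_causes,n_symbols support sizes.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a `discrete_generative_model`.
#' @export
random_discrete_model <- function(n_causes, n_symbols, seed = NULL) {
  draw <- function() {
    simplex <- function(k) {
      g <- rexp(k)
      g / sum(g)
    }
    discrete_generative_model(
      prior = simplex(n_causes),
      likelihood = t(vapply(seq_len(n_causes), function(i) simplex(n_symbols),
                            numeric(n_symbols)))
    )
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
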