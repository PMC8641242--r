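#' Quadratic arousal forms in prediction error
#'
#' Under the conjugate Gaussian model, each arousal quantity is an exact
#' quadratic in the prediction error `delta = xbar - eta` (sample mean minus
#' prior mean): `value = A * delta^2 + B`.  Writing `T = n s_p + s_l`:
#'
#' * information gain (Bayesian surprise, novelty):
#'   `A_G = n^2 s_p / (2 T^2)`,
#'   `B_G = -(log(s_l / T) + n s_p / T) / 2`;
#' * uncertainty (inverse accuracy, perceived complexity to-be):
#'   `A_U = n s_l / (2 T^2)`,
#'   `B_U = (n/2) (s_p / T + log(2 pi s_l) + S / s_l)`;
#' * free energy (arousal potential): `A_F = n / (2 T)`,
#'   `B_F = (log T + (n - 1) log s_l + n log 2 pi + n S / s_l) / 2`,
#'   with `A_F = A_G + A_U` and `B_F = B_G + B_U` exactly.
#'
#' The gain form equals `gaussian_kl(posterior, prior)` at `xbar = eta +
#' delta`; the uncertainty form equals the posterior expectation of the
#' sample negative log-likelihood.  All gradients `A` are non-negative, so
#' larger prediction errors never lower arousal.
#'
#' @param n positive integer sample count.
#' @param s_p positive prior variance (prior uncertainty).
#' @param s_l positive sensory variance.
#' @param S non-negative MLE sample variance (ignored by the gain, which does
#'   not depend on it).
#' @return an object of class `arousal_quadratic` with fields
#'   `gradient_coeff` (A), `intercept` (B), `quantity` (one of `"gain"`,
#'   `"uncertainty"`, `"free_energy"`) and the generating parameters.
#'   Evaluate it at prediction errors with [predict()][predict.arousal_quadratic].
#' @examples
#' f <- free_energy_quadratic(n = 1, s_p = 3, s_l = 0.5, S = 0.5)
#' predict(f, delta = c(0, 1, 2))
#' @name arousal_quadratics
NULL

check_quadratic_params <- function(n, s_p, s_l, S = 0) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop_arousal("`n` must be a positive integer", "arousalfe_invalid_params")
  }
  if (!is.finite(s_p) || s_p <= 0 || !is.finite(s_l) || s_l <= 0) {
    stop_arousal("`s_p` and `s_l` must be positive",
                 "arousalfe_invalid_params")
  }
  if (!is.finite(S) || S < 0) {
    stop_arousal("`S` must be non-negative", "arousalfe_invalid_params")
  }
  invisible(TRUE)
}

new_quadratic <- function(A, B, quantity, n, s_p, s_l, S = NA_real_) {
  structure(
    list(gradient_coeff = A, intercept = B, quantity = quantity,
         n = n, s_p = s_p, s_l = s_l, S = S),
    class = "arousal_quadratic"
  )
}

#' @export
print.arousal_quadratic <- function(x, ...) {
  cat(sprintf("<arousal_quadratic> %s(delta) = %.6g * delta^2 + %.6g\n",
              x$quantity, x$gradient_coeff, x$intercept))
  cat(sprintf("  n = %d, s_p = %.6g, s_l = %.6g%s\n", x$n, x$s_p, x$s_l,
              if (is.na(x$S)) "" else sprintf(", S = %.6g", x$S)))
  invisible(x)
}

#' Evaluate a quadratic arousal form at prediction errors
#'
#' @param object an `arousal_quadratic`.
#' @param delta numeric vector of prediction errors `xbar - eta`.
#' @param ... unused.
#' @return numeric vector `A * delta^2 + B` (nats).
#' @export
predict.arousal_quadratic <- function(object, delta, ...) {
  object$gradient_coeff * delta^2 + object$intercept
}

#' @rdname arousal_quadratics
#' @export
information_gain_quadratic <- function(n, s_p, s_l) {
  check_quadratic_params(n, s_p, s_l)
  T_ <- n * s_p + s_l
  new_quadratic(
    A = n^2 * s_p / (2 * T_^2),
    B = -0.5 * (log(s_l / T_) + n * s_p / T_),
    quantity = "gain", n = n, s_p = s_p, s_l = s_l
  )
}

#' @rdname arousal_quadratics
#' @export
uncertainty_quadratic <- function(n, s_p, s_l, S) {
  check_quadratic_params(n, s_p, s_l, S)
  T_ <- n * s_p + s_l
  new_quadratic(
    A = n * s_l / (2 * T_^2),
    B = n / 2 * (s_p / T_ + log(2 * pi * s_l) + S / s_l),
    quantity = "uncertainty", n = n, s_p = s_p, s_l = s_l, S = S
  )
}

#' @rdname arousal_quadratics
#' @export
free_energy_quadratic <- function(n, s_p, s_l, S) {
  check_quadratic_params(n, s_p, s_l, S)
  T_ <- n * s_p + s_l
  new_quadratic(
    A = n / (2 * T_),
    B = 0.5 * (log(T_) + (n - 1) * log(s_l) + n * log(2 * pi) + n * S / s_l),
    quantity = "free_energy", n = n, s_p = s_p, s_l = s_l, S = S
  )
}

#' Serialize a quadratic arousal form to JSON
#'
#' Writes `{"quantity", "n", "s_p", "s_l", "S", "A", "B"}`.
#'
#' @param form an `arousal_quadratic`.
#' @param path file path, or `NULL` to return the JSON string.
#' @export
write_quadratic <- function(form, path = NULL) {
  stopifnot(inherits(form, "arousal_quadratic"))
  obj <- list(quantity = form$quantity, n = form$n, s_p = form$s_p,
              s_l = form$s_l, S = form$S,
              A = form$gradient_coeff, B = form$intercept)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}

#' Staged two-batch arousal measures
#'
#' After updating the prior `N(eta, s_p)` with `n` samples, a further batch
#' of `m` samples from the same stimulus source yields (with `delta` and `S`
#' referring to that common source, and `T_k = k s_p + s_l`):
#' \deqn{G_{n+m} = KL\!\big(N(\eta_{n+m}, s_{n+m}) \,\|\, N(\eta_n, s_n)\big),}
#' \deqn{U_{n+m} = \frac{m}{2}\left[\frac{s_l\,\delta^2}{T_{n+m}^2} +
#'   \frac{s_p}{T_{n+m}} + \ln 2\pi s_l + \frac{S}{s_l}\right],}
#' where `eta_k = eta + k s_p delta / T_k` and `s_k = s_p s_l / T_k`.  At
#' `n = 0` both reduce exactly to the single-stage quadratics at count `m`.
#' As `n` grows the gain vanishes and the uncertainty falls monotonically to
#' `m` times the stimulus-source entropy (see [asymptotic_limits()]).
#'
#' The second bracket term of the uncertainty is the staged posterior
#' variance contribution `s_p / T_{n+m}`, the direct evaluation of
#' `<(mu - xbar)^2>` under the staged posterior; a Monte-Carlo test pins this
#' form down.
#'
#' @param n non-negative integer: samples already absorbed into the belief.
#' @param m positive integer: size of the new batch.
#' @param s_p,s_l positive prior and sensory variances.
#' @param S non-negative sample variance of the source data.
#' @param delta prediction error `xbar - eta` (vectorized).
#' @return a list of class `staged_measures` with components `gain`,
#'   `uncertainty`, `free_energy` (each along `delta`), and the parameters.
#' @export
staged_measures <- function(n, m, s_p, s_l, S, delta) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n)) {
    stop_arousal("`n` must be a non-negative integer",
                 "arousalfe_invalid_params")
  }
  check_quadratic_params(m, s_p, s_l, S)
  t_n <- n * s_p + s_l
  t_nm <- (n + m) * s_p + s_l
  # KL between staged beliefs N(eta_{n+m}, s_{n+m}) and N(eta_n, s_n);
  # mean gap (m s_p s_l / (t_n t_nm)) delta, variance ratio t_n / t_nm
  mean_gap <- m * s_p * s_l * delta / (t_n * t_nm)
  gain <- 0.5 * (log(t_nm / t_n) + t_n / t_nm - 1 +
                   mean_gap^2 * t_n / (s_p * s_l))
  uncertainty <- m / 2 * (s_l * delta^2 / t_nm^2 + s_p / t_nm +
                            log(2 * pi * s_l) + S / s_l)
  structure(
    list(gain = gain, uncertainty = uncertainty,
         free_energy = gain + uncertainty,
         n = n, m = m, s_p = s_p, s_l = s_l, S = S, delta = delta),
    class = "staged_measures"
  )
}

#' @export
print.staged_measures <- function(x, ...) {
  cat(sprintf("<staged_measures> n = %g, m = %d (nats)\n", x$n, x$m))
  print(data.frame(delta = x$delta, gain = x$gain,
                   uncertainty = x$uncertainty, free_energy = x$free_energy),
        row.names = FALSE, ...)
  invisible(x)
}

#' Large-sample limits of the staged measures
#'
#' As the absorbed sample count grows without bound, the information gain of
#' a further `m`-sample batch converges to zero (nothing novel remains) and
#' its uncertainty converges to `m` times the entropy of the stimulus
#' source, `m * gaussian_entropy(s_l)` — the perceived complexity of the
#' stimulus.
#'
#' @param m positive integer batch size.
#' @param s_l positive sensory variance.
#' @return list with `gain_limit` (always 0) and `uncertainty_limit` (nats).
#' @export
asymptotic_limits <- function(m, s_l) {
  check_quadratic_params(m, s_p = 1, s_l = s_l)
  list(gain_limit = 0, uncertainty_limit = m * gaussian_entropy(s_l))
}
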