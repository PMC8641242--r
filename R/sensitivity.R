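#' Analytic sensitivity of the quadratic coefficients
#'
#' Exact partial derivatives of the six quadratic coefficients (gradient `A`
#' and intercept `B` of gain, uncertainty and free energy) with respect to
#' the prior variance `s_p` and the sensory variance `s_l`.  Writing
#' `T = n s_p + s_l`:
#'
#' | quantity | dA/ds_p | dB/ds_p | dA/ds_l | dB/ds_l |
#' |---|---|---|---|---|
#' | gain | `n^2 (s_l - n s_p) / (2 T^3)` | `n^2 s_p / (2 T^2)` | `-n^2 s_p / T^3` | `-n^2 s_p^2 / (2 s_l T^2)` |
#' | uncertainty | `-n^2 s_l / T^3` | `n s_l / (2 T^2)` | `n (n s_p - s_l) / (2 T^3)` | `n (T^2 - s_p s_l) / (2 s_l T^2)` |
#' | free energy | `-n^2 / (2 T^2)` | `n / (2 T)` | `-n / (2 T^2)` | `(1 / T + (n - 1) / s_l) / 2` |
#'
#' Because the sensory variance is calibrated to the stimulus source
#' (`s_l ~ sigma^2`, with the sample variance tracking it), derivatives with
#' respect to `s_l` hold the ratio `S / s_l` fixed; the intercepts' `S/s_l`
#' terms therefore contribute nothing.  Under this convention the intercept
#' sensitivities to sensory variance are unconditionally positive for
#' uncertainty and free energy and unconditionally negative for gain.  The
#' signs that genuinely depend on the parameters are the gain gradient in
#' `s_p` (sign of `s_l - n s_p`) and the uncertainty gradient in `s_l`
#' (sign of `n s_p - s_l`).
#'
#' @param n positive integer sample count.
#' @param s_p,s_l positive prior and sensory variances.
#' @param S non-negative sample variance; carried for interface symmetry with
#'   the coefficient constructors (no derivative depends on it under the
#'   fixed-ratio convention).
#' @return a data frame with one row per (quantity, parameter, coefficient):
#'   columns `quantity`, `parameter` (`"prior_variance"` or
#'   `"sensory_variance"`), `coefficient` (`"gradient"` or `"intercept"`),
#'   `derivative`, `predicted_sign` (`"negative"`, `"positive"` or
#'   `"conditional"`), `condition` (text predicate for conditional signs,
#'   `NA` otherwise) and `condition_holds`.
#' @examples
#' g <- coefficient_gradients(n = 1, s_p = 3, s_l = 0.5, S = 0.5)
#' subset(g, quantity == "free_energy" & parameter == "prior_variance")
#' @export
coefficient_gradients <- function(n, s_p, s_l, S = 0) {
  check_quadratic_params(n, s_p, s_l, S)
  T_ <- n * s_p + s_l
  row <- function(quantity, parameter, coefficient, derivative,
                  predicted_sign, condition = NA_character_) {
    data.frame(quantity = quantity, parameter = parameter,
               coefficient = coefficient, derivative = derivative,
               predicted_sign = predicted_sign, condition = condition,
               condition_holds = if (is.na(condition)) NA else
                 eval(str2lang(condition),
                      list(n = n, s_p = s_p, s_l = s_l)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    # --- with respect to the prior variance s_p ---
    row("gain", "prior_variance", "gradient",
        n^2 * (s_l - n * s_p) / (2 * T_^3),
        "conditional", "s_l > n * s_p"),
    row("gain", "prior_variance", "intercept",
        n^2 * s_p / (2 * T_^2), "positive"),
    row("uncertainty", "prior_variance", "gradient",
        -n^2 * s_l / T_^3, "negative"),
    row("uncertainty", "prior_variance", "intercept",
        n * s_l / (2 * T_^2), "positive"),
    row("free_energy", "prior_variance", "gradient",
        -n^2 / (2 * T_^2), "negative"),
    row("free_energy", "prior_variance", "intercept",
        n / (2 * T_), "positive"),
    # --- with respect to the sensory variance s_l (S/s_l held fixed) ---
    row("gain", "sensory_variance", "gradient",
        -n^2 * s_p / T_^3, "negative"),
    row("gain", "sensory_variance", "intercept",
        -n^2 * s_p^2 / (2 * s_l * T_^2), "negative"),
    row("uncertainty", "sensory_variance", "gradient",
        n * (n * s_p - s_l) / (2 * T_^3),
        "conditional", "n * s_p > s_l"),
    row("uncertainty", "sensory_variance", "intercept",
        n * (T_^2 - s_p * s_l) / (2 * s_l * T_^2), "positive"),
    row("free_energy", "sensory_variance", "gradient",
        -n / (2 * T_^2), "negative"),
    row("free_energy", "sensory_variance", "intercept",
        0.5 * (1 / T_ + (n - 1) / s_l), "positive")
  )
  rownames(out) <- NULL
  out
}

#' Qualitative effect of sensory variance on the arousal quadratics
#'
#' Classifies, per arousal quantity, whether increasing the sensory variance
#' increases or decreases the gradient (sensitivity to prediction error) and
#' the intercept (value at zero prediction error), at the given parameters.
#' Directions come from the exact derivatives of [coefficient_gradients()];
#' the classically stated governing conditions are evaluated and reported
#' alongside (`n s_p > s_l` for the uncertainty gradient,
#' `n s_p + s_l >= 1` for the uncertainty intercept, `s_p > s_l` for the
#' gain intercept; the remaining effects are unconditional).  For free
#' energy the pattern — gradient down, intercept up — holds regardless of
#' parameters, which is what produces the crossover of free-energy curves at
#' large prediction errors.
#'
#' @inheritParams coefficient_gradients
#' @return data frame with columns `quantity`, `coefficient`, `effect`
#'   (`"increase"`/`"decrease"`), `condition`, `condition_holds`.
#' @export
sign_classification <- function(n, s_p, s_l) {
  check_quadratic_params(n, s_p, s_l)
  g <- coefficient_gradients(n, s_p, s_l, S = 0)
  g <- g[g$parameter == "sensory_variance", ]
  stated <- c(gain.gradient = NA, gain.intercept = "s_p > s_l",
              uncertainty.gradient = "n * s_p > s_l",
              uncertainty.intercept = "n * s_p + s_l >= 1",
              free_energy.gradient = NA, free_energy.intercept = NA)
  out <- data.frame(
    quantity = g$quantity,
    coefficient = g$coefficient,
    effect = ifelse(g$derivative >= 0, "increase", "decrease"),
    condition = unname(stated[paste(g$quantity, g$coefficient, sep = ".")]),
    stringsAsFactors = FALSE
  )
  out$condition_holds <- vapply(out$condition, function(cond) {
    if (is.na(cond)) return(NA)
    eval(str2lang(cond), list(n = n, s_p = s_p, s_l = s_l))
  }, logical(1))
  rownames(out) <- NULL
  out
}

#' Crossover prediction error between two quadratic forms
#'
#' Two quadratics of the same arousal quantity under different parameter
#' settings cross at `delta* = sqrt((B_b - B_a) / (A_a - A_b))` when that
#' ratio is positive and finite.  A positive crossover is the interaction
#' signature: the setting with the higher intercept but flatter gradient
#' yields the larger arousal below `delta*` and the smaller one above it.
#'
#' @param form_a,form_b `arousal_quadratic` objects describing the same
#'   quantity.
#' @return list of class `crossover_result` with components `delta_star`
#'   (non-negative real, or `NA` when the curves are parallel or nested with
#'   no positive crossing), `ordering_below` (`"a"` or `"b"`: which form is
#'   larger for `delta < delta*`; `NA` when degenerate) and `degenerate`
#'   (`TRUE` when the forms are identical).
#' @export
crossover_prediction_error <- function(form_a, form_b) {
  stopifnot(inherits(form_a, "arousal_quadratic"),
            inherits(form_b, "arousal_quadratic"))
  if (!identical(form_a$quantity, form_b$quantity)) {
    stop_arousal("both forms must describe the same arousal quantity",
                 "arousalfe_invalid_params")
  }
  dA <- form_a$gradient_coeff - form_b$gradient_coeff
  dB <- form_b$intercept - form_a$intercept
  degenerate <- dA == 0 && dB == 0
  res <- list(delta_star = NA_real_, ordering_below = NA_character_,
              degenerate = degenerate)
  if (!degenerate && dA != 0) {
    ratio <- dB / dA
    if (is.finite(ratio) && ratio > 0) {
      res$delta_star <- sqrt(ratio)
      # below the crossing, the form with the larger intercept dominates
      res$ordering_below <- if (form_a$intercept > form_b$intercept) "a"
                            else "b"
    }
  }
  class(res) <- "crossover_result"
  res
}

#' @export
print.crossover_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<crossover_result> identical forms (degenerate)\n")
  } else if (is.na(x$delta_star)) {
    cat("<crossover_result> no positive crossing (parallel or nested)\n")
  } else {
    cat(sprintf(
      "<crossover_result> delta* = %.6g; form '%s' larger below delta*\n",
      x$delta_star, x$ordering_below))
  }
  invisible(x)
}
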