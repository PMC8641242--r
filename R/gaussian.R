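#' Gaussian belief over a scalar cause
#'
#' A mean/variance pair standing for a prior, posterior or staged posterior
#' over the cause of sensory data.  The variance must be strictly positive.
#'
#' @param mean real; the belief mean (eta).
#' @param variance positive real; the belief variance (s_p, s_post, ...).
#' @return an object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop_arousal("`mean` must be a finite number", "arousalfe_invalid_belief")
  }
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0) {
    stop_arousal("`variance` must be a positive number",
                 "arousalfe_invalid_belief")
  }
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> N(mean = %.6g, variance = %.6g)\n",
              x$mean, x$variance))
  invisible(x)
}

#' Sensory observation model
#'
#' Carries the sensory variance `s_l`, the variance of the Gaussian
#' observation model `p(x | mu)`.  `s_l` is treated as a model parameter that
#' estimates the stimulus-source variance (`s_l ~ sigma^2`); it is supplied,
#' not fitted.  For convenience [sensory_model_from_samples()] sets it to the
#' maximum-likelihood sample variance of a calibration sample.
#'
#' @param sensory_variance positive real.
#' @return an object of class `sensory_model`.
#' @export
sensory_model <- function(sensory_variance) {
  if (!is.numeric(sensory_variance) || length(sensory_variance) != 1L ||
      !is.finite(sensory_variance) || sensory_variance <= 0) {
    stop_arousal("`sensory_variance` must be a positive number",
                 "arousalfe_invalid_sensory_model")
  }
  structure(list(sensory_variance = as.numeric(sensory_variance)),
            class = "sensory_model")
}

#' @rdname sensory_model
#' @param samples numeric vector of calibration samples (length >= 2 so the
#'   variance is positive unless the samples are constant).
#' @export
sensory_model_from_samples <- function(samples) {
  s <- summarize_samples(samples)
  sensory_model(s$sample_variance)
}

#' @export
print.sensory_model <- function(x, ...) {
  cat(sprintf("<sensory_model> sensory variance s_l = %.6g\n",
              x$sensory_variance))
  invisible(x)
}

#' Sufficient statistics of a sensory sample
#'
#' Reduces a sample vector to `(n, sample mean, sample variance)`.  The
#' sample variance uses the maximum-likelihood divisor `n`, not `n - 1`: the
#' Gaussian likelihood of the whole sample factorizes as
#' `n (mu - xbar)^2 + n S` only under that convention.
#'
#' @param samples numeric vector, length >= 1.
#' @return a list of class `sample_summary` with components `n`,
#'   `sample_mean`, `sample_variance`.
#' @examples
#' summarize_samples(c(1, 2, 3))  # n = 3, mean 2, S = 2/3
#' @export
summarize_samples <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 1L || anyNA(samples)) {
    stop_arousal("`samples` must be a non-empty numeric vector without NAs",
                 "arousalfe_invalid_samples")
  }
  n <- length(samples)
  m <- mean(samples)
  structure(
    list(n = n, sample_mean = m, sample_variance = sum((samples - m)^2) / n),
    class = "sample_summary"
  )
}

#' @rdname summarize_samples
#' @param n,sample_mean,sample_variance build a summary directly from known
#'   sufficient statistics; `n = 0` denotes "no data yet" and leaves the
#'   moments unset.
#' @export
sample_summary <- function(n, sample_mean = NA_real_,
                           sample_variance = NA_real_) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) {
    stop_arousal("`n` must be a non-negative integer",
                 "arousalfe_invalid_samples")
  }
  if (n > 0L) {
    if (!is.finite(sample_mean)) {
      stop_arousal("`sample_mean` must be finite when n > 0",
                   "arousalfe_invalid_samples")
    }
    if (!is.finite(sample_variance) || sample_variance < 0) {
      stop_arousal("`sample_variance` must be non-negative when n > 0",
                   "arousalfe_invalid_samples")
    }
  }
  structure(list(n = n, sample_mean = as.numeric(sample_mean),
                 sample_variance = as.numeric(sample_variance)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  if (x$n == 0L) {
    cat("<sample_summary> n = 0 (no data)\n")
  } else {
    cat(sprintf("<sample_summary> n = %d, mean = %.6g, variance (MLE) = %.6g\n",
                x$n, x$sample_mean, x$sample_variance))
  }
  invisible(x)
}

#' Read a raw sample vector from CSV
#'
#' Expects a single numeric column; a header row is optional and detected by
#' attempting to parse the first field as a number.
#'
#' @param path path to the CSV file.
#' @return numeric vector of samples.
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first,
                                                           ",")[[1L]][1L])))
  df <- read.csv(path, header = has_header)
  x <- as.numeric(df[[1L]])
  if (length(x) < 1L || anyNA(x)) {
    stop_arousal("CSV must contain one non-empty numeric column",
                 "arousalfe_invalid_samples")
  }
  x
}

#' Negative log-likelihood of a sample under a Gaussian observation model
#'
#' For `n` samples with mean `xbar` and MLE variance `S`, and observation
#' variance `s_l`,
#' \deqn{-\ln p(x^n \mid \mu) = \frac{n}{2}\ln(2\pi s_l) +
#'   \frac{n(\mu - \bar{x})^2 + nS}{2 s_l}.}
#' Vectorized over `mu`.
#'
#' @param summary a [sample_summary()] with `n >= 1`.
#' @param mu candidate cause (mean of the observation model); may be a vector.
#' @param sensory a [sensory_model()].
#' @return negative log-likelihood in nats (vector along `mu`).
#' @export
neg_log_likelihood <- function(summary, mu, sensory) {
  stopifnot(inherits(summary, "sample_summary"),
            inherits(sensory, "sensory_model"))
  if (summary$n < 1L) {
    stop_arousal("`summary` must contain at least one sample",
                 "arousalfe_invalid_samples")
  }
  n <- summary$n
  s_l <- sensory$sensory_variance
  n / 2 * log(2 * pi * s_l) +
    (n * (mu - summary$sample_mean)^2 + n * summary$sample_variance) /
      (2 * s_l)
}

#' Conjugate posterior update of a Gaussian belief
#'
#' Known-variance Gaussian conjugacy: with prior `N(eta, s_p)`, `n` samples
#' of mean `xbar`, and sensory variance `s_l`, the posterior is Gaussian with
#' \deqn{\eta_{post} = \frac{n s_p \bar{x} + s_l \eta}{n s_p + s_l}, \qquad
#'   s_{post} = \frac{s_p s_l}{n s_p + s_l}.}
#' An empty summary (`n = 0`) returns the prior unchanged.
#'
#' @param prior a [gaussian_belief()].
#' @param summary a [sample_summary()].
#' @param sensory a [sensory_model()].
#' @return the posterior [gaussian_belief()].
#' @examples
#' posterior_update(gaussian_belief(0, 1), summarize_samples(2),
#'                  sensory_model(1))  # N(1, 0.5)
#' @export
posterior_update <- function(prior, summary, sensory) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(summary, "sample_summary"),
            inherits(sensory, "sensory_model"))
  n <- summary$n
  if (n == 0L) return(prior)
  s_p <- prior$variance
  s_l <- sensory$sensory_variance
  denom <- n * s_p + s_l
  gaussian_belief(
    mean = (n * s_p * summary$sample_mean + s_l * prior$mean) / denom,
    variance = s_p * s_l / denom
  )
}

#' Kullback-Leibler divergence between two Gaussian beliefs
#'
#' \deqn{KL(a \| b) = \frac12\left[\ln\frac{v_b}{v_a} +
#'   \frac{v_a + (m_a - m_b)^2}{v_b} - 1\right] \ge 0.}
#'
#' @param a,b [gaussian_belief()] objects.
#' @return divergence in nats.
#' @export
gaussian_kl <- function(a, b) {
  stopifnot(inherits(a, "gaussian_belief"), inherits(b, "gaussian_belief"))
  0.5 * (log(b$variance / a$variance) +
           (a$variance + (a$mean - b$mean)^2) / b$variance - 1)
}

#' Differential entropy of a Gaussian
#'
#' `H = (ln(2 pi sigma^2) + 1) / 2` nats: proportional to the logarithm of
#' the variance, which is why sensory-source entropy — the perceived
#' complexity of a stimulus — grows with sensory variance.
#'
#' @param variance positive real (may be a vector).
#' @return entropy in nats.
#' @export
gaussian_entropy <- function(variance) {
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop_arousal("`variance` must be positive", "arousalfe_invalid_belief")
  }
  0.5 * (log(2 * pi * variance) + 1)
}
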