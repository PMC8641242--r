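#' Gaussian stimulus source
#'
#' The world: a stimulus whose sensory data are i.i.d. draws from
#' `N(mu, sigma^2)`.  A seed is mandatory so that every simulation is
#' reproducible without touching global RNG state.
#'
#' @param true_mean real; the source mean `mu` (the hidden cause).
#' @param true_variance positive real; the source variance `sigma^2`.
#' @param seed integer seed.
#' @return an object of class `stimulus_source`.
#' @export
stimulus_source <- function(true_mean, true_variance, seed) {
  if (!is.finite(true_variance) || true_variance <= 0) {
    stop_arousal("`true_variance` must be positive",
                 "arousalfe_invalid_source")
  }
  if (!is.finite(true_mean)) {
    stop_arousal("`true_mean` must be finite", "arousalfe_invalid_source")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) {
    stop_arousal("`seed` must be an integer", "arousalfe_invalid_source")
  }
  structure(list(true_mean = as.numeric(true_mean),
                 true_variance = as.numeric(true_variance), seed = seed),
            class = "stimulus_source")
}

#' @export
print.stimulus_source <- function(x, ...) {
  cat(sprintf("<stimulus_source> N(%.6g, %.6g), seed = %d\n",
              x$true_mean, x$true_variance, x$seed))
  invisible(x)
}

#' Draw sensory samples from a stimulus source
#'
#' Deterministic in the source seed: the same source yields the same sample
#' vector, and the caller's RNG state is untouched.
#'
#' @param source a [stimulus_source()].
#' @param n positive integer number of draws.
#' @return numeric vector of `n` samples.
#' @export
sample_source <- function(source, n) {
  stopifnot(inherits(source, "stimulus_source"))
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop_arousal("`n` must be a positive integer", "arousalfe_invalid_params")
  }
  with_local_seed(source$seed,
                  rnorm(n, source$true_mean, sqrt(source$true_variance)))
}

#' Bayesian-updating trajectory of the arousal measures
#'
#' Simulates repeated perception of one stimulus source: at each step a
#' batch of `m` samples is drawn, merged into running sufficient statistics
#' (count, mean, MLE variance), the staged arousal measures of the batch are
#' evaluated against the belief carried in from the previous steps, and the
#' belief is updated by conjugate Bayes.  Gain, uncertainty and free energy
#' follow the staged closed forms ([staged_measures()]) evaluated at the
#' running prediction error `xbar_cum - eta0` and running sample variance,
#' so `free_energy = gain + uncertainty` holds exactly at every step.
#'
#' When the sensory variance matches the source variance (`s_l = sigma^2`),
#' the gain decays to zero and `uncertainty / m` converges to the source
#' entropy `gaussian_entropy(s_l)` — the stimulus is fully learned and only
#' its perceived complexity keeps contributing to arousal.
#'
#' @param prior a [gaussian_belief()]: the initial belief `N(eta, s_p)`.
#' @param sensory a [sensory_model()].
#' @param source a [stimulus_source()]; its seed drives the whole
#'   trajectory.
#' @param m positive integer batch size per step.
#' @param steps positive integer number of updating steps.
#' @return a data frame of class `arousal_trajectory` with columns `step`,
#'   `cumulative_n`, `gain`, `uncertainty`, `free_energy`, `posterior_mean`,
#'   `posterior_variance`.
#' @examples
#' tr <- bayesian_trajectory(gaussian_belief(0, 3), sensory_model(0.5),
#'                           stimulus_source(2, 0.5, seed = 1),
#'                           m = 10, steps = 20)
#' tail(tr, 3)
#' @export
bayesian_trajectory <- function(prior, sensory, source, m, steps) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(sensory, "sensory_model"),
            inherits(source, "stimulus_source"))
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m)) {
    stop_arousal("`m` must be a positive integer", "arousalfe_invalid_params")
  }
  if (length(steps) != 1L || !is.finite(steps) || steps < 1 ||
      steps != round(steps)) {
    stop_arousal("`steps` must be a positive integer",
                 "arousalfe_invalid_params")
  }
  x <- sample_source(source, m * steps)
  boundary <- m * seq_len(steps)
  cum_mean <- cumsum(x)[boundary] / boundary
  cum_var <- cumsum(x^2)[boundary] / boundary - cum_mean^2
  cum_var[cum_var < 0] <- 0  # guard tiny negative round-off
  s_p <- prior$variance
  s_l <- sensory$sensory_variance
  delta <- cum_mean - prior$mean
  n_prev <- boundary - m
  t_prev <- n_prev * s_p + s_l
  t_now <- boundary * s_p + s_l
  # staged measures at each step, vectorized (see staged_measures())
  mean_gap <- m * s_p * s_l * delta / (t_prev * t_now)
  gain <- 0.5 * (log(t_now / t_prev) + t_prev / t_now - 1 +
                   mean_gap^2 * t_prev / (s_p * s_l))
  uncertainty <- m / 2 * (s_l * delta^2 / t_now^2 + s_p / t_now +
                            log(2 * pi * s_l) + cum_var / s_l)
  out <- data.frame(
    step = seq_len(steps),
    cumulative_n = boundary,
    gain = gain,
    uncertainty = uncertainty,
    free_energy = gain + uncertainty,
    posterior_mean = (boundary * s_p * cum_mean + s_l * prior$mean) / t_now,
    posterior_variance = s_p * s_l / t_now
  )
  class(out) <- c("arousal_trajectory", "data.frame")
  attr(out, "params") <- list(prior = prior, sensory = sensory,
                              source = source, m = m, steps = steps)
  out
}

#' Sweep the arousal quadratics over a parameter grid
#'
#' Evaluates gain, uncertainty and free energy over a prediction-error grid
#' for each value of a swept variance parameter (`"s_p"` or `"s_l"`),
#' holding the other parameters fixed.  When `s_l` is swept and `S` is not
#' given, `S = s_l` is used (the sensory variance estimates the source
#' variance and the sample variance tracks it); when `s_p` is swept, `S`
#' defaults to the fixed `s_l`.
#'
#' Interaction flags are computed per quantity with
#' [crossover_prediction_error()] between the forms at the smallest and
#' largest swept values: the flag is `TRUE` when the two curves cross at a
#' `delta*` inside `(0, max(delta_grid)]`.
#'
#' @param sweep_parameter `"s_p"` or `"s_l"`.
#' @param sweep_values positive numeric vector of swept variance values.
#' @param delta_grid numeric vector of prediction errors.
#' @param n positive integer sample count (default 1: a single glance at the
#'   stimulus).
#' @param s_p,s_l the fixed value of whichever variance is not swept.
#' @param S optional sample variance override.
#' @return an object of class `arousal_sweep`: a list with `records` (data
#'   frame with columns `delta`, `n`, `s_p`, `s_l`, `S`, `gain`,
#'   `uncertainty`, `free_energy`; one row per (delta, swept value) pair)
#'   `interactions` (named logical for `gain`, `uncertainty`,
#'   `free_energy`) and `delta_star` (the crossover locations, `NA` where
#'   the extreme curves do not cross).
#' @examples
#' sw <- sweep_quadratics("s_p", sweep_values = c(1, 5),
#'                        delta_grid = seq(0, 4, by = 0.5), s_l = 0.5)
#' sw$interactions
#' @export
sweep_quadratics <- function(sweep_parameter = c("s_p", "s_l"),
                             sweep_values, delta_grid, n = 1,
                             s_p = 3, s_l = 0.5, S = NULL) {
  sweep_parameter <- match.arg(sweep_parameter)
  if (length(sweep_values) < 1L || any(!is.finite(sweep_values)) ||
      any(sweep_values <= 0)) {
    stop_arousal("`sweep_values` must be positive and non-empty",
                 "arousalfe_invalid_params")
  }
  if (length(delta_grid) < 1L || any(!is.finite(delta_grid))) {
    stop_arousal("`delta_grid` must be finite and non-empty",
                 "arousalfe_invalid_params")
  }
  forms_at <- function(v) {
    sp <- if (sweep_parameter == "s_p") v else s_p
    sl <- if (sweep_parameter == "s_l") v else s_l
    Sv <- if (!is.null(S)) S else sl
    list(gain = information_gain_quadratic(n, sp, sl),
         uncertainty = uncertainty_quadratic(n, sp, sl, Sv),
         free_energy = free_energy_quadratic(n, sp, sl, Sv))
  }
  records <- do.call(rbind, lapply(sweep_values, function(v) {
    f <- forms_at(v)
    data.frame(
      delta = delta_grid,
      n = n,
      s_p = f$gain$s_p,
      s_l = f$gain$s_l,
      S = f$uncertainty$S,
      gain = predict(f$gain, delta_grid),
      uncertainty = predict(f$uncertainty, delta_grid),
      free_energy = predict(f$free_energy, delta_grid)
    )
  }))
  rownames(records) <- NULL
  lo <- forms_at(min(sweep_values))
  hi <- forms_at(max(sweep_values))
  delta_max <- max(abs(delta_grid))
  quantities <- c("gain", "uncertainty", "free_energy")
  delta_star <- vapply(quantities, function(q) {
    crossover_prediction_error(lo[[q]], hi[[q]])$delta_star
  }, numeric(1))
  interactions <- !is.na(delta_star) & delta_star > 0 &
    delta_star <= delta_max
  names(interactions) <- quantities
  structure(
    list(records = records, interactions = interactions,
         delta_star = delta_star,
         sweep_parameter = sweep_parameter, sweep_values = sweep_values),
    class = "arousal_sweep"
  )
}

#' @export
print.arousal_sweep <- function(x, ...) {
  cat(sprintf("<arousal_sweep> %s in {%s}, %d records\n",
              x$sweep_parameter, paste(x$sweep_values, collapse = ", "),
              nrow(x$records)))
  cat("interactions (crossover within delta range):\n")
  print(x$interactions)
  invisible(x)
}

#' Write simulation records as CSV
#'
#' Fixed column order (as produced by [bayesian_trajectory()] and
#' [sweep_quadratics()]), floats printed with 12 significant digits so that
#' identical configurations and seeds give byte-identical files.
#'
#' @param x an `arousal_trajectory`, `arousal_sweep`, or plain data frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_records <- function(x, path) {
  if (inherits(x, "arousal_sweep")) x <- x$records
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation/sweep configuration file
#'
#' JSON or YAML (by file extension), with any of the keys `n`, `m`, `s_p`,
#' `s_l`, `S`, `delta_grid`, `sweep_parameter`, `sweep_values`, `mu`,
#' `sigma2`, `seed`, `steps`.  A `seed` is mandatory: simulations never rely
#' on implicit global RNG state.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return named list of configuration values.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_arousal("the 'yaml' package is required for YAML configs",
                   "arousalfe_invalid_config")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  known <- c("n", "m", "s_p", "s_l", "S", "delta_grid", "sweep_parameter",
             "sweep_values", "mu", "sigma2", "seed", "steps")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_arousal(paste("unknown config keys:",
                       paste(unknown, collapse = ", ")),
                 "arousalfe_invalid_config")
  }
  if (is.null(cfg$seed)) {
    stop_arousal("config must set an integer `seed`",
                 "arousalfe_invalid_config")
  }
  cfg
}
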