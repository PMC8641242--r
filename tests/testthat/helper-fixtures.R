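# Shared fixtures and independent oracles, built in code at test time.

# two-cause / two-symbol model with prior (1/2, 1/2) and likelihood column
# (0.8, 0.4) for the first symbol; posterior for symbol 1 is (2/3, 1/3)
toy_model <- function() {
  discrete_generative_model(
    prior = c(0.5, 0.5),
    likelihood = rbind(c(0.8, 0.2), c(0.4, 0.6))
  )
}

# flat draw on the probability simplex
random_simplex <- function(k) {
  g <- rexp(k)
  g / sum(g)
}

# brute-force free energy by direct enumeration of the defining sum,
# independent of the package implementation
enum_free_energy <- function(model, q, j) {
  joint <- model$likelihood[, j] * as.numeric(model$prior)
  qv <- as.numeric(q)
  keep <- qv > 0
  if (any(keep & joint <= 0)) return(Inf)
  sum(qv[keep] * (log(qv[keep]) - log(joint[keep])))
}

# numerical-quadrature KL between two scalar Gaussians
quadrature_gaussian_kl <- function(a, b) {
  integrand <- function(t) {
    da <- dnorm(t, a$mean, sqrt(a$variance))
    db <- dnorm(t, b$mean, sqrt(b$variance))
    val <- da * (log(pmax(da, .Machine$double.xmin)) -
                   log(pmax(db, .Machine$double.xmin)))
    val[da == 0] <- 0
    val
  }
  integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
}

# central finite difference; when scale_S is TRUE the sample-variance ratio
# S / s_l is held fixed while perturbing s_l (the calibrated convention)
fd_gradient <- function(fun, n, s_p, s_l, S, wrt, field, h = NULL) {
  val <- function(sp, sl, Sv) fun(n, sp, sl, Sv)[[field]]
  if (wrt == "s_p") {
    h <- if (is.null(h)) 1e-5 * s_p else h
    (val(s_p + h, s_l, S) - val(s_p - h, s_l, S)) / (2 * h)
  } else {
    h <- if (is.null(h)) 1e-5 * s_l else h
    r <- S / s_l
    (val(s_p, s_l + h, r * (s_l + h)) -
       val(s_p, s_l - h, r * (s_l - h))) / (2 * h)
  }
}

# wrappers with a uniform (n, s_p, s_l, S) signature returning A and B
coeff_fun <- function(quantity) {
  switch(quantity,
    gain = function(n, s_p, s_l, S) {
      f <- information_gain_quadratic(n, s_p, s_l)
      list(gradient = f$gradient_coeff, intercept = f$intercept)
    },
    uncertainty = function(n, s_p, s_l, S) {
      f <- uncertainty_quadratic(n, s_p, s_l, S)
      list(gradient = f$gradient_coeff, intercept = f$intercept)
    },
    free_energy = function(n, s_p, s_l, S) {
      f <- free_energy_quadratic(n, s_p, s_l, S)
      list(gradient = f$gradient_coeff, intercept = f$intercept)
    }
  )
}
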