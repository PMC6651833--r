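# Worked five-point dataset used across the regression tests:
# Sxx = Syy = 10, Sxy = 9.
worked_points <- function() {
  bivariate_data(c(1, 2, 3, 4, 5), c(2, 3, 5, 4, 6))
}

# Independent oracle for the vertical-deviation (OLS) problem: numeric
# minimization of sum((y - B*x - A)^2) by quasi-Newton descent.
oracle_vertical <- function(x, y) {
  f <- function(p) sum((y - p[1] * x - p[2])^2)
  fit <- stats::optim(c(0, mean(y)), f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(B = fit$par[1], A = fit$par[2])
}

# Independent oracle for the perpendicular-distance (MA) problem: the line
# is parametrized by its angle theta; for each theta the optimal offset is
# closed-form, and theta is found by enumeration plus 1-D refinement.
oracle_perpendicular <- function(x, y) {
  sse <- function(theta) {
    d <- x * sin(theta) - y * cos(theta)
    sum((d - mean(d))^2)
  }
  thetas <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 721)
  vals <- vapply(thetas, sse, numeric(1))
  i <- which.min(vals)
  lo <- thetas[max(1, i - 1)]; hi <- thetas[min(length(thetas), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  theta <- opt$minimum
  B <- tan(theta)
  A <- mean(y) - B * mean(x)
  list(B = B, A = A)
}

# Random correlated dataset with reproducible structure.
random_dataset <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:50, 1)
  slope <- stats::runif(1, -3, 3)
  x <- stats::rnorm(n, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.5, 2))
  y <- slope * x + stats::rnorm(n, sd = stats::runif(1, 0.1, 1.5))
  bivariate_data(x, y)
}

# A short synthetic profile with a smooth quadratic baseline.
smooth_profile <- function(n = 50, time = 1) {
  z <- seq(1, n)
  bbp_profile(z, 1e-3 + 1e-6 * z + 1e-8 * z^2, time = time)
}
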