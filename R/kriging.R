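#' @name kriging
#' @title Ordinary Kriging of productivity over the factor space
#' @description
#' Ordinary Kriging treats productivity as a Gaussian process with an
#' unknown constant trend: y(x) = beta0 + Z(x) + eps, where Z has variance
#' sigma^2 and anisotropic correlation (one length-scale theta_d per
#' dimension) and eps is measurement noise absorbed by a nugget tau^2.
#' beta0 and sigma^2 are profiled out in closed form; the length-scales and
#' the nugget ratio maximize the concentrated log-likelihood via seeded
#' multistart L-BFGS-B. Inputs are rescaled to [-1, 1] per dimension and
#' responses are centered and scaled internally.
NULL

KRIG_JITTER <- 1e-10

corr_matrix <- function(Xs, theta, kernel) {
  n <- nrow(Xs)
  R <- matrix(1, n, n)
  for (d in seq_len(ncol(Xs))) {
    h <- outer(Xs[, d], Xs[, d], "-") / theta[d]
    if (kernel == "gauss") {
      R <- R * exp(-0.5 * h * h)
    } else {
      a <- sqrt(5) * abs(h)
      R <- R * (1 + a + a * a / 3) * exp(-a)
    }
  }
  R
}

corr_cross <- function(Xs_new, Xs, theta, kernel) {
  K <- matrix(1, nrow(Xs_new), nrow(Xs))
  D2 <- matrix(0, nrow(Xs_new), nrow(Xs))
  for (d in seq_len(ncol(Xs))) {
    h0 <- outer(Xs_new[, d], Xs[, d], "-")
    D2 <- D2 + h0 * h0
    h <- h0 / theta[d]
    if (kernel == "gauss") {
      K <- K * exp(-0.5 * h * h)
    } else {
      a <- sqrt(5) * abs(h)
      K <- K * (1 + a + a * a / 3) * exp(-a)
    }
  }
  # the stabilizing jitter is part of the model's correlation, so queries
  # that coincide with a training input must see it too (re-interpolation)
  K[D2 == 0] <- K[D2 == 0] + KRIG_JITTER
  K
}

# concentrated negative log-likelihood; par = c(log theta, log g)
krig_nll <- function(par, Xs, ys, kernel, fixed_g = NULL) {
  d <- ncol(Xs)
  theta <- exp(par[seq_len(d)])
  g <- if (is.null(fixed_g)) exp(par[d + 1L]) else fixed_g
  n <- nrow(Xs)
  K <- corr_matrix(Xs, theta, kernel)
  diag(K) <- diag(K) + g + KRIG_JITTER
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  ldet <- 2 * sum(log(diag(L)))
  Ki1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  Kiy <- backsolve(L, forwardsolve(t(L), ys))
  b0 <- sum(Ki1 * ys) / sum(Ki1)
  resid <- ys - b0
  Kir <- Kiy - b0 * Ki1
  s2 <- sum(resid * Kir) / n
  if (s2 <= 0) s2 <- 1e-300
  0.5 * (n * log(s2) + ldet)
}

# analytic gradient of the concentrated nll (squared-exponential kernel).
# With beta0 and sigma2 profiled out,
#   d nll = 0.5 * [ tr(K^-1 dK) - alpha' dK alpha / sigma2_hat ]
# where alpha = K^-1 (y - beta0_hat); dK/dlog(theta_d) = R o D_d / theta_d^2
# and dK/dlog(g) = g I.
krig_nll_grad <- function(par, Xs, ys, kernel, fixed_g = NULL) {
  d <- ncol(Xs)
  theta <- exp(par[seq_len(d)])
  g <- if (is.null(fixed_g)) exp(par[d + 1L]) else fixed_g
  n <- nrow(Xs)
  R <- corr_matrix(Xs, theta, kernel)
  K <- R
  diag(K) <- diag(K) + g + KRIG_JITTER
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(rep(0, length(par)))
  Ki <- chol2inv(L)
  Kiy <- drop(Ki %*% ys)
  Ki1 <- rowSums(Ki)
  b0 <- sum(Kiy) / sum(Ki1)
  alpha <- Kiy - b0 * Ki1
  s2 <- sum((ys - b0) * alpha) / n
  if (s2 <= 0) s2 <- 1e-300
  A <- Ki - tcrossprod(alpha) / s2
  out <- numeric(length(par))
  for (j in seq_len(d)) {
    Dj <- outer(Xs[, j], Xs[, j], "-")^2
    out[j] <- 0.5 * sum(A * (R * Dj)) / theta[j]^2
  }
  if (is.null(fixed_g)) out[d + 1L] <- 0.5 * g * sum(diag(A))
  out
}

#' Fit an ordinary-Kriging model
#'
#' @param obs an [observation_set()], or a numeric matrix/data.frame of
#'   inputs (then `y` must be given).
#' @param y responses when `obs` is a plain matrix.
#' @param factors optional subset of factor columns to use as model inputs
#'   (defaults to all factor-space variables present).
#' @param kernel correlation family: `"gauss"` (squared-exponential,
#'   default — media response surfaces are smooth) or `"matern52"`.
#' @param nugget `NULL` to estimate the nugget jointly (default), or a
#'   fixed non-negative value in response-variance units.
#' @param nugget_ratio advanced: fix the nugget-to-process-variance ratio
#'   `g = tau2 / sigma2` directly (dimensionless; takes precedence over
#'   `nugget`). Used for cross-implementation comparisons at fully fixed
#'   hyperparameters.
#' @param multistart number of seeded optimizer starts (default 8).
#' @param theta optional fixed correlation lengths (in the scaled [-1, 1]
#'   coordinate frame); skips hyperparameter optimization.
#' @param seed seed for the multistart draws.
#' @param box optional 2 x d matrix of input bounds used for internal
#'   scaling; defaults to the factor-space bounds or the data range.
#' @param transform `"none"` (default) or `"log1p"`: fit the surrogate on
#'   `log(1 + y)`. With multiplicative measurement noise the log scale is
#'   variance-stabilizing, so a single homoscedastic nugget is adequate
#'   across the whole response range; predictions are back-transformed
#'   (median back-transform for the mean, delta method for the SD).
#' @return a `kriging_model` with trend constant `beta0`, process variance
#'   `sigma2`, correlation lengths `theta` (in scaled [-1,1] coordinates),
#'   nugget `tau2`, the training data, the log-likelihood and the
#'   correlation-matrix condition number.
#' @export
krig_fit <- function(obs, y = NULL, factors = NULL,
                     kernel = c("gauss", "matern52"),
                     nugget = NULL, multistart = 8L, theta = NULL,
                     nugget_ratio = NULL, seed = 1L, box = NULL,
                     transform = c("none", "log1p")) {
  kernel <- match.arg(kernel)
  transform <- match.arg(transform)
  ref_var <- NA_real_
  if (inherits(obs, "observation_set")) {
    sp <- attr(obs, "space")
    factors <- factors %||% intersect(factor_names(sp), names(obs))
    X <- as.matrix(as.data.frame(obs)[, factors, drop = FALSE])
    y <- obs$response
    if (is.null(box)) {
      i <- match(factors, factor_names(sp))
      box <- rbind(lower = sp$factors$lower[i], upper = sp$factors$upper[i])
      colnames(box) <- factors
    }
    ref_vals <- obs$response[obs$role == "reference"]
  } else {
    ref_vals <- numeric()
    X <- as.matrix(obs)
    if (is.null(y)) stop_krigdoe("y required when obs is a matrix")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    factors <- colnames(X)
  }
  if (any(!is.finite(y))) stop_krigdoe("non-finite responses")
  if (transform == "log1p") {
    if (any(y < 0)) stop_krigdoe("log1p transform needs non-negative responses")
    y <- log1p(y)
    ref_vals <- log1p(ref_vals)
  }
  if (length(ref_vals) >= 2L) ref_var <- stats::var(ref_vals)
  n <- nrow(X); d <- ncol(X)
  min_pts <- if (is.null(theta)) 3L else 2L
  if (nrow(unique(X)) < min_pts)
    stop_krigdoe(sprintf("at least %d distinct input points are required", min_pts))
  if (is.null(box)) {
    box <- apply(X, 2L, range)
  }
  rownames(box) <- c("lower", "upper")
  if (is.null(colnames(box))) colnames(box) <- factors
  lo <- box[1L, ]; hi <- box[2L, ]
  span <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2L, lo, "-"), 2L, span / 2, "/") - 1

  my <- mean(y); sy <- stats::sd(y)
  constant_y <- !is.finite(sy) || sy < 1e-12
  if (constant_y) sy <- 1
  ys <- (y - my) / sy

  # noise floor: with replicated references the nugget must at least cover
  # the observed pure-error variance (in standardized units)
  g_lo <- 1e-8
  fixed_g <- NULL
  if (!is.null(nugget_ratio)) {
    fixed_g <- max(nugget_ratio, 0)
  } else if (!is.null(nugget)) {
    fixed_g <- nugget / sy^2              # ratio set after sigma2 known below
  } else if (is.finite(ref_var) && ref_var > 0) {
    g_lo <- max(g_lo, 0.5 * ref_var / sy^2)
  }
  dup <- duplicated(Xs) | duplicated(Xs, fromLast = TRUE)
  if (any(dup) && !is.null(nugget) && nugget == 0) {
    ydup <- split(ys[dup], apply(Xs[dup, , drop = FALSE], 1L, paste, collapse = ","))
    if (any(vapply(ydup, function(v) max(v) - min(v), 0) > 1e-12)) {
      warning("duplicated inputs with differing responses: forcing a positive nugget")
      fixed_g <- NULL
      g_lo <- 1e-6
    }
  }

  # nugget given in absolute units tau2: g = tau2 / sigma2 depends on the
  # estimate of sigma2; treat the supplied value relative to var(y) instead
  if (!is.null(fixed_g)) fixed_g <- max(fixed_g, 0)

  if (is.null(theta)) {
    multistart <- max(1L, as.integer(multistart))
    lower <- c(rep(log(0.05), d), log(g_lo))
    upper <- c(rep(log(20), d), log(10))
    n_par <- if (is.null(fixed_g)) d + 1L else d
    starts <- with_seed(seed, {
      s <- matrix(stats::runif(multistart * (d + 1L)), multistart)
      t(apply(s, 1L, function(u) lower + u * (upper - lower)))
    })
    if (multistart == 1L) starts <- matrix(starts, 1L)
    starts[1L, ] <- c(rep(log(0.7), d), log(max(g_lo * 2, 0.01)))

    best <- NULL
    for (i in seq_len(multistart)) {
      par0 <- starts[i, seq_len(d + 1L)]
      if (!is.null(fixed_g)) par0 <- par0[seq_len(d)]
      o <- tryCatch(stats::optim(par0, krig_nll,
                                 gr = if (kernel == "gauss") krig_nll_grad,
                                 method = "L-BFGS-B",
                                 lower = lower[seq_len(n_par)],
                                 upper = upper[seq_len(n_par)],
                                 Xs = Xs, ys = ys, kernel = kernel,
                                 fixed_g = fixed_g,
                                 control = list(maxit = 200, factr = 1e10)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop_krigdoe("hyperparameter optimization failed")
    theta <- exp(best$par[seq_len(d)])
    g <- if (is.null(fixed_g)) exp(best$par[d + 1L]) else fixed_g
    nll_val <- best$value
    convergence <- best$convergence
  } else {
    theta <- rep_len(as.numeric(theta), d)
    g <- fixed_g %||% g_lo
    nll_val <- krig_nll(log(theta), Xs, ys, kernel, fixed_g = g)
    convergence <- 0L
  }

  K <- corr_matrix(Xs, theta, kernel)
  diag(K) <- diag(K) + g + KRIG_JITTER
  L <- chol(K)
  Ki1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  Kiy <- backsolve(L, forwardsolve(t(L), ys))
  one_Ki1 <- sum(Ki1)
  b0s <- sum(Ki1 * ys) / one_Ki1
  Kir <- Kiy - b0s * Ki1
  s2s <- max(sum((ys - b0s) * Kir) / n, 1e-300)
  if (constant_y) s2s <- 0

  structure(list(
    factors = factors, kernel = kernel, transform = transform,
    X = X, y = y, box = box,
    Xs = Xs, ys = ys, my = my, sy = sy,
    theta = theta, g = g,
    beta0 = my + sy * b0s,
    sigma2 = s2s * sy^2,
    tau2 = g * s2s * sy^2,
    b0s = b0s, s2s = s2s,
    L = L, Ki1 = Ki1, Kir = Kir, one_Ki1 = one_Ki1,
    loglik = -nll_val - 0.5 * n * (log(2 * pi) + 1) - n * log(sy),
    cond = kappa(K, exact = (n <= 200)),
    convergence = convergence,
    ref_var = ref_var
  ), class = "kriging_model")
}

#' @export
print.kriging_model <- function(x, ...) {
  cat(sprintf("Ordinary Kriging (%s kernel): n = %d, d = %d\n",
              x$kernel, nrow(x$X), length(x$theta)))
  cat(sprintf("  beta0 = %.4g, sigma2 = %.4g, tau2 = %.4g\n",
              x$beta0, x$sigma2, x$tau2))
  cat("  theta (scaled):", paste(sprintf("%.3g", x$theta), collapse = ", "), "\n")
  cat(sprintf("  log-likelihood = %.4g, cond(K) = %.3g\n", x$loglik, x$cond))
  invisible(x)
}

scale_inputs <- function(model, X) {
  lo <- model$box[1L, ]; hi <- model$box[2L, ]
  span <- ifelse(hi > lo, hi - lo, 1)
  sweep(sweep(as.matrix(X), 2L, lo, "-"), 2L, span / 2, "/") - 1
}

# core predictor on a natural-unit matrix; returns list(mean, sd)
km_predict_core <- function(model, Xnew, type = "observation") {
  Xns <- scale_inputs(model, Xnew)
  r <- corr_cross(Xns, model$Xs, model$theta, model$kernel)
  mu_s <- model$b0s + drop(r %*% model$Kir)
  if (type == "mean")
    return(list(mean = model$my + model$sy * mu_s, sd = NULL))
  Kir_t <- backsolve(model$L, forwardsolve(t(model$L), t(r)))
  rKir <- colSums(t(r) * Kir_t)
  oneKir <- colSums(Kir_t * 1)
  trend <- (1 - oneKir)^2 / model$one_Ki1
  g_add <- if (type == "observation") model$g else 0
  s2_s <- model$s2s * pmax(1 + g_add - rKir + trend, 0)
  mu <- model$my + model$sy * mu_s
  sd <- model$sy * sqrt(s2_s)
  if (identical(model$transform, "log1p")) {
    sd <- sd * exp(mu)
    mu <- expm1(mu)
  }
  list(mean = mu, sd = sd)
}

# fast single-point predictor used in tight loops (MCMC); returns a
# closure x_natural_vector -> list(mean, sd)
km_predictor <- function(model, with_sd = TRUE) {
  lo <- model$box[1L, ]; hi <- model$box[2L, ]
  span <- ifelse(hi > lo, hi - lo, 1)
  tXs <- t(model$Xs)
  theta <- model$theta
  tL <- t(model$L)
  s2s <- model$s2s; g <- model$g
  b0s <- model$b0s; one_Ki1 <- model$one_Ki1
  Kir <- model$Kir
  my <- model$my; sy <- model$sy
  gauss <- model$kernel == "gauss"
  logt <- identical(model$transform, "log1p")
  function(x) {
    xs <- 2 * (x - lo) / span - 1
    h <- (tXs - xs) / theta
    r <- if (gauss) {
      exp(-0.5 * .colSums(h * h, nrow(h), ncol(h)))
    } else {
      a <- sqrt(5) * abs(h)
      apply((1 + a + a * a / 3) * exp(-a), 2L, prod)
    }
    mu <- my + sy * (b0s + sum(r * Kir))
    if (!with_sd) {
      if (logt) mu <- expm1(mu)
      return(list(mean = mu, sd = NA_real_))
    }
    v <- backsolve(model$L, forwardsolve(tL, r))
    trend <- (1 - sum(v))^2 / one_Ki1
    s2 <- s2s * max(1 + g - sum(r * v) + trend, 0)
    sd <- sy * sqrt(s2)
    if (logt) {
      sd <- sd * exp(mu)
      mu <- expm1(mu)
    }
    list(mean = mu, sd = sd)
  }
}

#' Predict productivity at new compositions
#'
#' Standard ordinary-Kriging predictive mean and standard deviation,
#' including the trend-estimation uncertainty term. By default the
#' prediction refers to a new observation (the nugget is included in the
#' variance); `type = "latent"` predicts the noise-free surface.
#'
#' @param object a `kriging_model`.
#' @param newdata data.frame or matrix of compositions (xRef units) with
#'   the model's factor columns.
#' @param type `"observation"` (default) or `"latent"`.
#' @param ... unused.
#' @return data.frame with columns `mean` and `sd`; rows outside the fitted
#'   box are flagged in the logical attribute `extrapolated`.
#' @export
predict.kriging_model <- function(object, newdata,
                                  type = c("observation", "latent"), ...) {
  type <- match.arg(type)
  if (is.null(object$L)) stop_krigdoe("model is not fitted")
  newdata <- as.data.frame(newdata)
  if (!all(object$factors %in% names(newdata))) {
    if (ncol(newdata) == length(object$factors))
      names(newdata) <- object$factors
    else
      stop_krigdoe("newdata lacks the model's factor columns")
  }
  X <- as.matrix(newdata[, object$factors, drop = FALSE])
  pr <- km_predict_core(object, X, type)
  out <- data.frame(mean = pr$mean, sd = pr$sd)
  tolr <- 1e-9
  lo <- object$box[1L, ]; hi <- object$box[2L, ]
  extra <- apply(X, 1L, function(row)
    any(row < lo - tolr - 0.05 * (hi - lo)) ||
      any(row > hi + tolr + 0.05 * (hi - lo)))
  attr(out, "extrapolated") <- extra
  out
}

#' Evaluate the Kriging surface on a dense grid slice
#'
#' Produces the mean/SD grids behind the contour plots of a campaign
#' report: two or three factors span the grid, all remaining model factors
#' are fixed at stated levels.
#'
#' @param model a `kriging_model`.
#' @param axes 2 or 3 factor names spanning the grid.
#' @param fixed named numeric vector of levels for the remaining factors.
#' @param resolution grid points per axis (default 41).
#' @return data.frame with one row per grid node: the axis levels, `mean`
#'   and `sd`; the mean's argmax row index is in attribute `argmax`.
#' @export
grid_evaluate <- function(model, axes, fixed = numeric(), resolution = 41L) {
  if (!all(axes %in% model$factors))
    stop_krigdoe("axes must be model factors")
  if (any(axes %in% names(fixed)))
    stop_krigdoe("a grid axis cannot also be fixed: ",
                 paste(intersect(axes, names(fixed)), collapse = ", "))
  rest <- setdiff(model$factors, axes)
  if (!all(rest %in% names(fixed)))
    stop_krigdoe("missing fixed levels for: ",
                 paste(setdiff(rest, names(fixed)), collapse = ", "))
  seqs <- lapply(axes, function(a) {
    lo <- model$box[1L, a]; hi <- model$box[2L, a]
    if (resolution == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = resolution)
  })
  names(seqs) <- axes
  grid <- expand.grid(seqs, KEEP.OUT.ATTRS = FALSE)
  for (nm in rest) grid[[nm]] <- fixed[[nm]]
  pr <- predict(model, grid[, model$factors, drop = FALSE])
  out <- cbind(grid[, c(axes, rest), drop = FALSE], pr)
  attr(out, "argmax") <- which.max(pr$mean)
  attr(out, "fixed") <- fixed
  out
}

#' Leave-one-out residuals standardized by the Kriging SD
#'
#' Closed-form virtual leave-one-out for a Gaussian process: on
#' well-specified data the standardized residuals have variance close to 1.
#'
#' @param model a `kriging_model`.
#' @return numeric vector of standardized LOO residuals.
#' @export
loo_standardized <- function(model) {
  n <- nrow(model$Xs)
  Kinv <- chol2inv(model$L)
  e <- drop(Kinv %*% (model$ys - model$b0s))
  dKi <- diag(Kinv)
  (e / dKi) / sqrt(model$s2s / dKi)
}

#' Maximize the Kriging mean over a box
#'
#' Dense-grid argmax (up to 4 dimensions) followed by an L-BFGS-B polish;
#' in higher dimensions a seeded multistart local search replaces the grid.
#'
#' @param model a `kriging_model`.
#' @param box optional 2 x d bounds (defaults to the fitted box).
#' @param resolution grid points per axis (default 21).
#' @param seed seed for multistart in high dimension.
#' @return list with `x` (named composition), `value` (predicted mean) and
#'   `sd` (predicted SD at the optimum).
#' @export
optimize_mean <- function(model, box = model$box, resolution = 21L,
                          seed = 1L) {
  d <- length(model$factors)
  lo <- box[1L, ]; hi <- box[2L, ]
  pred1 <- km_predictor(model, with_sd = FALSE)
  fmean <- function(x) pred1(x)$mean
  starts <- if (d <= 4L) {
    seqs <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = resolution))
    grid <- as.matrix(expand.grid(seqs, KEEP.OUT.ATTRS = FALSE))
    colnames(grid) <- model$factors
    means <- numeric(nrow(grid))
    chunk <- 20000L
    for (i0 in seq(1L, nrow(grid), by = chunk)) {
      ii <- i0:min(i0 + chunk - 1L, nrow(grid))
      means[ii] <- km_predict_core(model, grid[ii, , drop = FALSE],
                                   type = "mean")$mean
    }
    ord <- order(means, decreasing = TRUE)[seq_len(min(3L, nrow(grid)))]
    grid[ord, , drop = FALSE]
  } else {
    s <- with_seed(seed, matrix(stats::runif(10L * d), 10L))
    st <- sweep(sweep(s, 2L, hi - lo, "*"), 2L, lo, "+")
    colnames(st) <- model$factors
    rbind(st, matrix(model$X[which.max(model$y), model$factors], 1L,
                     dimnames = list(NULL, model$factors)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(stats::optim(starts[i, ], function(x) -fmean(x),
                               method = "L-BFGS-B", lower = lo, upper = hi),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  x <- stats::setNames(best$par, model$factors)
  pr <- km_predict_core(model, matrix(x, 1L, dimnames = list(NULL, model$factors)))
  list(x = x, value = pr$mean, sd = pr$sd)
}
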