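#' Expected Improvement of a Kriging prediction
#'
#' For a maximization target, the expected improvement of a Gaussian
#' prediction with mean `mu` and standard deviation `s` over the incumbent
#' `f_best` is `EI = (mu - f_best) * Phi(z) + s * phi(z)` with
#' `z = (mu - f_best) / s`; for `s = 0` it degenerates to
#' `max(mu - f_best, 0)`. EI balances exploitation (high predicted
#' productivity) against exploration (high prediction uncertainty).
#'
#' @param mean predictive mean(s), or a data.frame with columns `mean` and
#'   `sd` as returned by [predict.kriging_model()].
#' @param sd predictive standard deviation(s), `>= 0`.
#' @param f_best incumbent value the improvement is measured against.
#' @return data.frame with columns `ei` (>= 0) and `z` (the standardized
#'   improvement, `NA` where `sd = 0`), plus `f_best` as an attribute.
#' @examples
#' expected_improvement(1, 1, 1)$ei  # dnorm(0) = 0.3989
#' @export
expected_improvement <- function(mean, sd = NULL, f_best) {
  if (is.data.frame(mean)) {
    sd <- mean$sd
    mean <- mean$mean
  }
  if (any(sd < 0)) stop_krigdoe("negative predictive standard deviation")
  z <- ifelse(sd > 0, (mean - f_best) / sd, NA_real_)
  ei <- ifelse(sd > 0,
               (mean - f_best) * stats::pnorm(z) + sd * stats::dnorm(z),
               pmax(mean - f_best, 0))
  ei <- pmax(ei, 0)  # guard against roundoff at extreme z
  structure(data.frame(ei = ei, z = z), f_best = f_best)
}

#' Noise-robust incumbent value
#'
#' The plug-in incumbent: the maximum of the Kriging mean over the observed
#' inputs. With a positive nugget this shrinks noisy outliers toward the
#' trend, so the incumbent never chases a lucky measurement; with a zero
#' nugget it equals the maximum raw observation.
#'
#' @param model a fitted `kriging_model`.
#' @param obs optional [observation_set()]; defaults to the model's own
#'   training inputs.
#' @return the incumbent value `f_best`.
#' @export
incumbent <- function(model, obs = NULL) {
  X <- if (is.null(obs)) model$X else
    as.matrix(as.data.frame(obs)[, model$factors, drop = FALSE])
  if (nrow(X) == 0L) stop_krigdoe("no observations to take the incumbent from")
  max(km_predict_core(model, X)$mean)
}

#' MCMC configuration for EI sampling
#'
#' Defaults follow common delayed-rejection adaptive-Metropolis practice:
#' a 10,000-element chain whose first 1,000 draws are discarded, proposal
#' covariance adaptation from iteration 200 on, a delayed-rejection
#' fallback proposal shrunk by a factor 5, and an initial proposal SD of
#' 0.1 times the box range per dimension.
#'
#' @param chain_length total draws (default 10000).
#' @param burn_in discarded initial draws (default 1000), `< chain_length`.
#' @param scale initial proposal SD per dimension as a fraction of the box
#'   range (default 0.1).
#' @param adapt_start iteration at which covariance adaptation begins.
#' @param dr_shrink delayed-rejection proposal shrink factor (default 0.2).
#' @param seed RNG seed.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 10000L, burn_in = 1000L,
                        scale = 0.1, adapt_start = 200L,
                        dr_shrink = 0.2, seed = 1L) {
  if (burn_in >= chain_length) stop_krigdoe("burn_in must be < chain_length")
  if (scale <= 0 || dr_shrink <= 0) stop_krigdoe("scales must be positive")
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), scale = scale,
                 adapt_start = as.integer(adapt_start),
                 dr_shrink = dr_shrink, seed = as.integer(seed)),
            class = "mcmc_config")
}

box_from <- function(box) {
  if (inherits(box, "factor_space")) return(fs_box(box))
  box <- as.matrix(box)
  if (nrow(box) != 2L) stop_krigdoe("box must be a 2 x d matrix of bounds")
  box
}

#' Sample compositions with probability proportional to Expected Improvement
#'
#' A delayed-rejection adaptive Metropolis (DRAM) chain targeting the
#' unnormalized density EI(x) on the given box. Proposals are Gaussian;
#' from `adapt_start` on, the proposal covariance is adapted from the chain
#' history (scaled by 2.38^2/d); after a first-stage rejection, a second
#' proposal with covariance shrunk by `dr_shrink^2` is tried with the
#' delayed-rejection acceptance correction. Proposals outside the box or
#' with zero EI have density zero and are always rejected, so zero-EI
#' regions receive no samples.
#'
#' @param model a fitted `kriging_model`.
#' @param f_best incumbent value (see [incumbent()]).
#' @param box 2 x d bounds matrix or a [factor_space()].
#' @param cfg an [mcmc_config()].
#' @param target optional override of the target function `f(x) -> density`
#'   (used for sampler diagnostics); defaults to the model's EI.
#' @return post-burn-in chain as a matrix (rows = draws, columns = factors)
#'   with attributes `acceptance_rate`, `ei` (target value per draw) and
#'   `cfg`.
#' @export
dram_sample <- function(model, f_best, box, cfg = mcmc_config(),
                        target = NULL) {
  box <- box_from(box)
  d <- ncol(box)
  lo <- box[1L, ]; hi <- box[2L, ]
  if (is.null(target)) {
    pred1 <- km_predictor(model)
    target <- function(x) {
      pr <- pred1(x)
      if (pr$sd > 0) {
        z <- (pr$mean - f_best) / pr$sd
        max((pr$mean - f_best) * stats::pnorm(z) + pr$sd * stats::dnorm(z), 0)
      } else max(pr$mean - f_best, 0)
    }
  }
  dens <- function(x) {
    if (any(x < lo) || any(x > hi)) return(0)
    target(x)
  }

  # coarse-grid feasibility check: EI must not vanish everywhere
  res <- max(3L, min(6L, floor(3000^(1 / d))))
  seqs <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = res))
  grid <- as.matrix(expand.grid(seqs, KEEP.OUT.ATTRS = FALSE))
  gvals <- apply(grid, 1L, dens)
  if (max(gvals) <= 1e-14)
    stop_krigdoe("EI is (numerically) zero everywhere on the box; maximize the predicted mean directly instead")

  n <- cfg$chain_length
  chain <- matrix(NA_real_, n, d)
  eivals <- numeric(n)
  with_seed(cfg$seed, {
    x <- grid[which.max(gvals), ]
    px <- max(gvals)
    sd0 <- cfg$scale * (hi - lo)
    C <- diag(sd0^2, d)
    cholC <- chol(C)
    # running moments for adaptation
    mean_run <- x
    cov_run <- matrix(0, d, d)
    acc <- 0L
    ldmvn <- function(y, m, ch) {
      z <- backsolve(ch, y - m, transpose = TRUE)
      -sum(log(diag(ch))) - 0.5 * sum(z * z)
    }
    for (i in seq_len(n)) {
      y1 <- x + drop(crossprod(cholC, stats::rnorm(d)))
      py1 <- dens(y1)
      a1 <- if (px > 0) min(1, py1 / px) else as.numeric(py1 > 0)
      if (stats::runif(1) < a1) {
        x <- y1; px <- py1; acc <- acc + 1L
      } else {
        # delayed rejection: shrunk second-stage proposal
        ch2 <- cholC * cfg$dr_shrink
        y2 <- x + drop(crossprod(ch2, stats::rnorm(d)))
        py2 <- dens(y2)
        if (py2 > 0) {
          a1_rev <- if (py2 > 0) min(1, py1 / py2) else 0
          num <- log(py2) + ldmvn(y1, y2, cholC) + log(max(1 - a1_rev, 1e-300))
          den <- log(px) + ldmvn(y1, x, cholC) + log(max(1 - a1, 1e-300))
          a2 <- exp(min(0, num - den))
          if (stats::runif(1) < a2) {
            x <- y2; px <- py2; acc <- acc + 1L
          }
        }
      }
      chain[i, ] <- x
      eivals[i] <- px
      # incremental mean/covariance update over the whole history
      delta <- x - mean_run
      mean_run <- mean_run + delta / i
      cov_run <- cov_run + tcrossprod(delta, x - mean_run)
      if (i >= cfg$adapt_start) {
        Cad <- (2.38^2 / d) * (cov_run / (i - 1L) + 1e-10 * diag(d))
        ch_try <- tryCatch(chol(Cad), error = function(e) NULL)
        if (!is.null(ch_try)) cholC <- ch_try
      }
    }
    keep <- (cfg$burn_in + 1L):n
    out <- chain[keep, , drop = FALSE]
    colnames(out) <- colnames(box)
    structure(out, acceptance_rate = acc / n, ei = eivals[keep], cfg = cfg)
  })
}

#' Distill an experiment batch from an EI chain
#'
#' Farthest-point subsampling seeded at the maximum-EI state: each next
#' point maximizes its minimal distance (in box-scaled coordinates) to the
#' points already chosen, which avoids near-duplicate culture wells. Plain
#' thinning is available as an alternative.
#'
#' @param chain matrix returned by [dram_sample()].
#' @param n_batch number of experiments to select.
#' @param min_separation minimal pairwise distance in box-scaled
#'   coordinates (advisory; a warning is issued where infeasible).
#' @param box 2 x d bounds used to scale distances (defaults to the range
#'   of the chain).
#' @param method `"maximin"` (default) or `"thin"`.
#' @return data.frame of selected compositions with a `role` column set to
#'   `ei_proposed`.
#' @export
select_batch <- function(chain, n_batch, min_separation = 0,
                         box = NULL, method = c("maximin", "thin")) {
  method <- match.arg(method)
  if (n_batch > nrow(chain)) stop_krigdoe("n_batch exceeds chain length")
  ei <- attr(chain, "ei")
  states <- unique(cbind(chain, .ei = ei %||% rep(0, nrow(chain))))
  if (nrow(states) < n_batch)
    stop_krigdoe(sprintf("only %d distinct chain states for a batch of %d",
                         nrow(states), n_batch))
  d <- ncol(chain)
  pts <- states[, seq_len(d), drop = FALSE]
  eiv <- states[, d + 1L]
  if (is.null(box)) box <- apply(chain, 2L, range)
  span <- pmax(box[2L, ] - box[1L, ], 1e-12)
  scaled <- sweep(pts, 2L, span, "/")
  if (method == "thin") {
    idx <- round(seq(1L, nrow(pts), length.out = n_batch))
  } else {
    idx <- which.max(eiv)
    dmin <- sqrt(colSums((t(scaled) - scaled[idx, ])^2))
    dmin[idx] <- -Inf
    while (length(idx) < n_batch) {
      j <- which.max(dmin)
      idx <- c(idx, j)
      dj <- sqrt(colSums((t(scaled) - scaled[j, ])^2))
      dmin <- pmin(dmin, dj)
      dmin[j] <- -Inf
    }
  }
  sel <- pts[idx, , drop = FALSE]
  if (min_separation > 0 && n_batch > 1L) {
    dd <- stats::dist(sweep(sel, 2L, span, "/"))
    if (min(dd) < min_separation)
      warning("min_separation not achievable for the requested batch size")
  }
  out <- as.data.frame(sel)
  colnames(out) <- colnames(chain)
  out$role <- "ei_proposed"
  out$ei <- eiv[idx]
  out
}

#' Uniform space-filling experiments over a box
#'
#' @param box 2 x d bounds matrix or a [factor_space()].
#' @param n number of runs (>= 0).
#' @param seed RNG seed.
#' @return data.frame of compositions with `role = "random_uniform"`.
#' @export
uniform_space_filling <- function(box, n, seed = 1L) {
  box <- box_from(box)
  d <- ncol(box)
  if (n < 0L) stop_krigdoe("n must be >= 0")
  u <- with_seed(seed, matrix(stats::runif(n * d), n, d))
  pts <- sweep(sweep(u, 2L, box[2L, ] - box[1L, ], "*"), 2L, box[1L, ], "+")
  out <- as.data.frame(pts)
  colnames(out) <- colnames(box)
  if (n > 0L) out$role <- "random_uniform" else out$role <- character(0)
  out
}
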