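test_that("zero-nugget models interpolate their training data", {
  m <- quick_model(nugget = 0)
  pr <- predict(m, m$X)
  expect_lt(max(abs(pr$mean - m$y)), 1e-8)
  expect_lt(max(pr$sd^2), 1e-8)
})

test_that("two-point prediction matches an explicit hand solve", {
  # y = (0, 1) at x = (0, 1), Gaussian correlation theta = 1, tau2 = 0;
  # the box is chosen so internal scaling is the identity
  m <- krig_fit(matrix(c(0, 1), 2, 1), c(0, 1), theta = 1, nugget_ratio = 0,
                box = matrix(c(-1, 1), 2, 1))
  r12 <- exp(-0.5)
  K <- matrix(c(1, r12, r12, 1), 2) + 1e-10 * diag(2)
  Ki <- solve(K)
  one <- c(1, 1); y <- c(0, 1)
  b0 <- drop(one %*% Ki %*% y / (one %*% Ki %*% one))
  rv <- rep(exp(-0.5 * 0.25), 2)
  mu_hand <- b0 + drop(rv %*% Ki %*% (y - b0))
  s2_hand <- drop((y - b0) %*% Ki %*% (y - b0)) / 2 *
    (1 - rv %*% Ki %*% rv + (1 - rv %*% Ki %*% one)^2 / (one %*% Ki %*% one))
  pr <- predict(m, matrix(0.5, 1, 1))
  expect_equal(pr$mean, mu_hand, tolerance = 1e-10)
  expect_equal(pr$sd^2, drop(s2_hand), tolerance = 1e-10)
})

test_that("far from all data the prediction reverts to the trend", {
  m <- quick_model(nugget = 0)
  far <- predict(m, matrix(c(60, -55), 1, 2))
  expect_equal(far$mean, m$beta0, tolerance = 1e-6)
  # correlation -> 0 limit: sigma2 + tau2 plus the trend-estimation term
  expect_gte(far$sd^2, m$sigma2 + m$tau2 - 1e-8)
  expect_true(attr(far, "extrapolated"))
  inside <- predict(m, matrix(0, 1, 2))
  expect_false(attr(inside, "extrapolated"))
})

test_that("predictive variance is bounded and non-negative", {
  m <- quick_model(n = 30, seed = 8)
  qs <- withr::with_seed(13, matrix(runif(2e5, -1.2, 1.2), ncol = 2))
  pr <- predict(m, qs)
  expect_true(all(pr$sd >= 0))
  # ordinary-Kriging variance: process + nugget + trend-estimation share
  bound <- (m$sigma2 + m$tau2) * (1 + 1 / m$one_Ki1 / m$sigma2 * m$sy^2) + 1e-8
  bound <- m$sigma2 + m$tau2 + m$sigma2 / m$one_Ki1 + 1e-8
  expect_true(all(pr$sd^2 <= bound))
})

test_that("implementation agrees with the numpy/scikit-learn oracle", {
  # 10 seeded datasets, fixed hyperparameters, identity scaling box
  for (seed in 1:10) {
    dat <- withr::with_seed(100 + seed, {
      n <- 12 + seed
      X <- matrix(runif(2 * n, -1, 1), n, 2)
      list(X = X, y = drop(2 + sin(2 * X[, 1]) - X[, 2]^2 +
                             0.1 * rnorm(n)),
           Xnew = matrix(runif(10, -0.95, 0.95), 5, 2),
           theta = runif(2, 0.3, 2), g = runif(1, 0, 0.2))
    })
    m <- krig_fit(dat$X, dat$y, theta = dat$theta, nugget_ratio = dat$g,
                  box = rbind(c(-1, -1), c(1, 1)))
    pr <- predict(m, dat$Xnew)
    o <- gp_oracle(dat$X, dat$y, dat$Xnew, dat$theta, dat$g)
    expect_lt(max(abs(pr$mean - o$mean)), 1e-6)
    expect_lt(max(abs(pr$sd^2 - o$var)), 1e-6)
  }
})

test_that("hyperparameters are recovered from seeded GP draws", {
  # data from a known anisotropic GP: theta = (0.3, 0.7), tau2 = 0.01
  theta_true <- c(0.3, 0.7)
  hit <- 0L
  for (rep in 1:25) {
    dat <- withr::with_seed(500 + rep, {
      X <- matrix(runif(80, -1, 1), 40, 2)
      R <- krigdoe:::corr_matrix(2 * (X + 1) / 2 - 1, theta_true, "gauss")
      K <- R + 0.01 * diag(40)
      y <- drop(2 + t(chol(K)) %*% rnorm(40))
      list(X = X, y = y)
    })
    m <- krig_fit(dat$X, dat$y, box = rbind(c(-1, -1), c(1, 1)),
                  multistart = 6, seed = rep)
    ok <- abs(log10(m$theta) - log10(theta_true)) <= 0.3
    hit <- hit + all(ok)
  }
  expect_gte(hit, 20L)  # >= 80% of 25 replicates
})

test_that("degenerate inputs are handled", {
  # duplicated inputs with differing responses and a forbidden nugget
  X <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0.5, 0.2))
  y <- c(1, 2, 3, 2.5)
  expect_warning(m <- krig_fit(X, y, nugget = 0, multistart = 2,
                               box = rbind(c(0, 0), c(1, 1))),
                 "positive nugget")
  expect_gt(m$tau2, 0)
  # constant responses give a flat, certain surface
  mc <- krig_fit(matrix(runif(20), 10, 2), rep(5, 10), multistart = 2)
  prc <- predict(mc, matrix(0.5, 1, 2))
  expect_equal(prc$mean, 5)
  expect_equal(prc$sd, 0)
  # non-finite responses and too-few points
  expect_error(krig_fit(matrix(1:4, 2, 2), c(1, NA)), "distinct|finite")
  expect_error(krig_fit(matrix(c(0, 0, 1, 1), 2, 2), c(1, 2)), "distinct")
})

test_that("the nugget floor reflects reference replicate variance", {
  s <- default_surface()
  d <- add_reference_replicates(
    nested_round3_design(refine_space(), c(0.5, 1.7, 2.9)), 4)
  obs <- suppressWarnings(evaluate_design(s, d, seed = 3))
  m <- krig_fit(obs, seed = 3)
  ref_var <- var(obs$response[obs$role == "reference"])
  expect_gte(m$tau2, 0)
  expect_equal(m$ref_var, ref_var)
  # the fitted nugget ratio respects the replicate-variance floor
  expect_gte(m$g, 0.5 * ref_var / m$sy^2 - 1e-12)
})

test_that("grid evaluation slices the surface correctly", {
  m <- refined_model()
  g <- grid_evaluate(m, c("MgSO4", "NaNO3"),
                     fixed = c(CaCl2 = 0.82, Trace = 1), resolution = 11)
  expect_equal(nrow(g), 121L)
  expect_true(all(g$CaCl2 == 0.82))
  am <- attr(g, "argmax")
  expect_equal(g$mean[am], max(g$mean))
  # resolution 1 equals a point prediction at the box center
  g1 <- grid_evaluate(m, c("MgSO4", "NaNO3"),
                      fixed = c(CaCl2 = 0.82, Trace = 1), resolution = 1)
  expect_equal(nrow(g1), 1L)
  ctr <- (m$box[1, c("MgSO4", "NaNO3")] + m$box[2, c("MgSO4", "NaNO3")]) / 2
  pr <- predict(m, data.frame(MgSO4 = ctr[1], NaNO3 = ctr[2],
                              CaCl2 = 0.82, Trace = 1))
  expect_equal(g1$mean, pr$mean)
  # error paths
  expect_error(grid_evaluate(m, c("MgSO4", "NaNO3"),
                             fixed = c(MgSO4 = 1, CaCl2 = 0.8, Trace = 1)),
               "cannot also be fixed")
  expect_error(grid_evaluate(m, c("MgSO4", "NaNO3"), fixed = c(CaCl2 = 0.8)),
               "missing fixed")
})

test_that("a zero-nugget mean slice passes through on-slice training points", {
  withr::with_seed(21, {
    X <- cbind(a = runif(15, 0, 1), b = runif(15, 0, 1))
    X[1:3, "b"] <- 0.5
    y <- drop(sin(3 * X[, "a"]) + X[, "b"])
    m <- krig_fit(X, y, nugget = 0, multistart = 4,
                  box = rbind(c(0, 0), c(1, 1)))
    g <- grid_evaluate(m, "a", fixed = c(b = 0.5), resolution = 5)
    pr <- predict(m, X[1:3, , drop = FALSE])
    expect_lt(max(abs(pr$mean - y[1:3])), 1e-7)
  })
})

test_that("grid argmax tracks the truth's restricted optimum", {
  s <- default_surface()
  m <- cached("noiseless_r3", suppressWarnings({
    s0 <- s; s0$noise$value <- 0
    sp <- refine_space()
    d <- add_reference_replicates(
      nested_round3_design(sp, c(0.5, 1.7, 2.9)), 4)
    # densify with space-filling runs so the interpolant is accurate
    extra <- uniform_space_filling(fs_box_for_test(sp), 60, seed = 9)
    nat <- rbind(natural_levels(d),
                 as.matrix(extra[, factor_names(sp)]))
    dd <- new_design_for_test(nat, sp, roles = c(d$role, extra$role))
    krig_fit(evaluate_design(s0, dd), seed = 2)
  }))
  fx <- c(MgSO4 = 1.7, CaCl2 = 0.82)
  g <- grid_evaluate(m, c("Trace", "NaNO3"), fixed = fx, resolution = 21)
  am <- g[attr(g, "argmax"), ]
  # truth restricted to the same slice, on the same grid
  tv <- surface_value(s, transform(g, MgSO4 = fx["MgSO4"], CaCl2 = fx["CaCl2"]))
  tm <- g[which.max(tv), ]
  step <- c(diff(sort(unique(g$Trace)))[1], diff(sort(unique(g$NaNO3)))[1])
  expect_lte(abs(am$Trace - tm$Trace), step[1] + 1e-9)
  expect_lte(abs(am$NaNO3 - tm$NaNO3), step[2] + 1e-9)
})

test_that("standardized leave-one-out residuals have unit-scale variance", {
  withr::with_seed(99, {
    X <- matrix(runif(120, -1, 1), 60, 2)
    R <- krigdoe:::corr_matrix(X, c(0.5, 0.8), "gauss")
    y <- drop(3 + t(chol(R + 0.02 * diag(60))) %*% rnorm(60))
    m <- krig_fit(X, y, box = rbind(c(-1, -1), c(1, 1)), multistart = 4)
    v <- var(loo_standardized(m))
    expect_gt(v, 0.5); expect_lt(v, 2)
  })
})

test_that("model serialization round-trips exactly", {
  m <- refined_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_kriging_model(m, path)
  m2 <- read_kriging_model(path)
  expect_identical(m2$theta, m$theta)
  expect_identical(m2$y, m$y)
  expect_identical(unname(m2$X), unname(m$X))
  qs <- withr::with_seed(4, {
    lo <- m$box[1, ]; hi <- m$box[2, ]
    sweep(sweep(matrix(runif(40), 10, 4), 2, hi - lo, "*"), 2, lo, "+")
  })
  colnames(qs) <- m$factors
  p1 <- predict(m, qs); p2 <- predict(m2, qs)
  expect_equal(p2$mean, p1$mean, tolerance = 1e-12)
  expect_equal(p2$sd, p1$sd, tolerance = 1e-12)
})

test_that("matern52 kernel is selectable and sane", {
  withr::with_seed(31, {
    X <- matrix(runif(60, -1, 1), 30, 2)
    y <- drop(sin(2 * X[, 1]) + X[, 2])
    m <- krig_fit(X, y, kernel = "matern52", nugget = 0, multistart = 3,
                  box = rbind(c(-1, -1), c(1, 1)))
    pr <- predict(m, X)
    expect_lt(max(abs(pr$mean - y)), 1e-6)
  })
})
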