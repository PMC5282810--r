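test_that("expected improvement matches its closed form and oracles", {
  # mu = f_best, s = 1: EI equals the standard normal density at 0
  expect_equal(expected_improvement(1, 1, 1)$ei, dnorm(0), tolerance = 1e-4)
  # deterministic prediction below the incumbent improves nothing
  expect_equal(expected_improvement(5, 0, 7)$ei, 0)
  expect_equal(expected_improvement(9, 0, 7)$ei, 2)
  # Monte-Carlo oracle on a named case and on 100 random cases
  mc <- mc_ei(1.0, 0.5, 1.2, n = 1e6, seed = 42)
  expect_lt(abs(expected_improvement(1.0, 0.5, 1.2)$ei - mc$est), 3 * mc$se)
  # random cases constrained to |z| <= 4 so a 2e4-draw check has power
  # (the full 100 x 1e6 sweep lives in the acceptance suite)
  cases <- withr::with_seed(7, {
    mu <- rnorm(30, 0, 2); s <- runif(30, 0.05, 2)
    data.frame(mu = mu, s = s, fb = mu - s * runif(30, -3, 4))
  })
  draws <- withr::with_seed(8, matrix(rnorm(30 * 2e4), 30))
  for (i in seq_len(nrow(cases))) {
    y <- cases$mu[i] + cases$s[i] * draws[i, ]
    imp <- pmax(y - cases$fb[i], 0)
    mc_se <- sd(imp) / sqrt(length(imp))
    ei <- expected_improvement(cases$mu[i], cases$s[i], cases$fb[i])$ei
    expect_lt(abs(ei - mean(imp)), 3 * mc_se + 1e-8)
  }
  expect_error(expected_improvement(1, -0.1, 0), "negative")
})

test_that("EI is non-negative and monotone where theory says so", {
  z <- withr::with_seed(3, data.frame(mu = runif(1e6, -5, 5),
                                      s = runif(1e6, 0, 3),
                                      fb = runif(1e6, -5, 5)))
  ei <- expected_improvement(z$mu, z$s, 0)$ei
  expect_true(all(ei >= 0))
  # nondecreasing in s at mu <= f_best
  s_grid <- seq(0, 2, length.out = 50)
  ei_s <- expected_improvement(rep(-0.5, 50), s_grid, 0)$ei
  expect_true(all(diff(ei_s) >= -1e-12))
  # increasing in mu at fixed s > 0
  mu_grid <- seq(-2, 2, length.out = 50)
  ei_mu <- expected_improvement(mu_grid, rep(0.7, 50), 0)$ei
  expect_true(all(diff(ei_mu) > 0))
})

test_that("incumbent is the plug-in maximum of the model mean", {
  # zero nugget: equals the maximum raw observation
  m0 <- quick_model(nugget = 0)
  expect_equal(incumbent(m0), max(m0$y), tolerance = 1e-8)
  # heavy noise with a replicated outlier: shrunk below the raw maximum
  m <- withr::with_seed(17, {
    X <- matrix(runif(60, 0, 1), 30, 2)
    y <- 5 + rnorm(30, 0, 2)
    y[7] <- 20  # lucky outlier
    krig_fit(X, y, multistart = 4, box = rbind(c(0, 0), c(1, 1)))
  })
  expect_lt(incumbent(m), max(m$y))
  empty <- as.data.frame(m$X)[0, , drop = FALSE]
  expect_error(incumbent(m, obs = empty), "no observations")
})

flat_ei_chain <- function(seed = 5) {
  cached(paste0("flatchain", seed), {
    box <- rbind(c(0, 0), c(1, 2))
    colnames(box) <- c("u", "v")
    m <- quick_model(n = 10, seed = 2)
    dram_sample(m, 0, box, mcmc_config(seed = seed),
                target = function(x) 1)
  })
}

test_that("DRAM with a flat target samples the box uniformly", {
  chain <- flat_ei_chain()
  expect_equal(nrow(chain), 9000L)
  expect_true(all(chain[, "u"] >= 0 & chain[, "u"] <= 1))
  expect_true(all(chain[, "v"] >= 0 & chain[, "v"] <= 2))
  # per-dimension mean within +/-0.02 of the box center (coded units)
  expect_lt(abs(mean(chain[, "u"]) - 0.5), 0.02)
  expect_lt(abs(mean(chain[, "v"]) - 1.0), 0.02 * 2)
  # Kolmogorov-Smirnov against uniform on a thinned, near-independent
  # subsample (the raw chain is a random walk, so iid critical values
  # do not apply to it)
  thin <- chain[seq(1, nrow(chain), by = 20), ]
  expect_gt(suppressWarnings(ks.test(thin[, "u"], "punif")$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(thin[, "v"] / 2, "punif")$p.value), 0.01)
  expect_gt(attr(chain, "acceptance_rate"), 0.05)
})

test_that("chain frequencies are proportional to a 1-D EI density", {
  # 1-D model with a known EI curve: bin the chain against the EI integral
  m <- withr::with_seed(23, {
    x <- matrix(seq(0, 1, length.out = 8), 8, 1)
    y <- drop(2 + sin(2.5 * x) + 0.2 * rnorm(8))
    krig_fit(x, y, multistart = 4, box = matrix(c(0, 1), 2, 1))
  })
  fb <- incumbent(m)
  box <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, m$factors))
  chain <- dram_sample(m, fb, box, mcmc_config(seed = 31))
  thin <- chain[seq(1, nrow(chain), by = 20), 1]
  breaks <- seq(0, 1, length.out = 11)
  obs <- table(cut(thin, breaks))
  # expected bin masses: EI integrated on a fine grid
  xs <- seq(0.0005, 0.9995, by = 0.001)
  pr <- predict(m, matrix(xs, ncol = 1))
  ei <- expected_improvement(pr, f_best = fb)$ei
  mass <- tapply(ei, cut(xs, breaks), sum)
  p_exp <- as.numeric(mass / sum(mass))
  expect_gt(g_test(as.numeric(obs), p_exp), 0.01)
})

test_that("zero-EI regions receive no samples", {
  # deterministic plateau: s = 0 and mu < f_best on half the box
  box <- rbind(c(0, 0), c(1, 1))
  colnames(box) <- c("u", "v")
  m <- quick_model(n = 10, seed = 2)
  target <- function(x) if (x[1] > 0.5) 1 else 0
  chain <- dram_sample(m, 0, box, mcmc_config(seed = 9), target = target)
  expect_true(all(chain[, "u"] > 0.5))
  # EI identically zero: refuse with advice
  expect_error(dram_sample(m, 0, box, mcmc_config(seed = 9),
                           target = function(x) 0),
               "zero everywhere")
})

test_that("batch selection distills distinct, high-EI proposals", {
  m <- refined_model()
  fb <- incumbent(m)
  box <- fs_box_for_test(refine_space(4.0))
  chain <- cached("r4chain", dram_sample(m, fb, box, mcmc_config(seed = 11)))
  # n = 1: the chain's maximum-EI state
  b1 <- select_batch(chain, 1, box = box)
  ei <- attr(chain, "ei")
  expect_equal(b1$ei, max(ei))
  expect_equal(as.numeric(b1[1, m$factors]),
               as.numeric(chain[which.max(ei), ]))
  # n = 12: distinct points, all with positive EI
  b12 <- select_batch(chain, 12, box = box)
  expect_equal(nrow(b12), 12L)
  expect_equal(nrow(unique(b12[, m$factors])), 12L)
  expect_true(all(b12$ei > 0))
  # infeasible requests error clearly
  tiny <- chain[rep(1, 5), , drop = FALSE]
  attr(tiny, "ei") <- rep(1, 5)
  expect_error(select_batch(tiny, 3), "distinct")
  expect_error(select_batch(chain, nrow(chain) + 1), "exceeds")
})

test_that("uniform space filling covers the box", {
  box <- rbind(c(0.5, 0.16), c(4, 1))
  colnames(box) <- c("MgSO4", "NaNO3")
  u <- uniform_space_filling(box, 23, seed = 3)
  expect_equal(nrow(u), 23L)
  expect_true(all(u$MgSO4 >= 0.5 & u$MgSO4 <= 4))
  expect_true(all(u$role == "random_uniform"))
  expect_equal(nrow(uniform_space_filling(box, 0)), 0L)
  big <- uniform_space_filling(box, 1e4, seed = 4)
  ctr <- colMeans(big[, c("MgSO4", "NaNO3")])
  span <- box[2, ] - box[1, ]
  expect_lt(abs(ctr[1] - 2.25) / span[1], 0.02)
  expect_lt(abs(ctr[2] - 0.58) / span[2], 0.02)
  # reproducible bit-for-bit
  expect_identical(uniform_space_filling(box, 23, seed = 3), u)
})

test_that("the proposal pipeline is reproducible bit-for-bit", {
  m <- refined_model()
  fb <- incumbent(m)
  box <- fs_box_for_test(refine_space(4.0))
  cfg <- mcmc_config(chain_length = 600, burn_in = 100, seed = 77)
  c1 <- dram_sample(m, fb, box, cfg)
  c2 <- dram_sample(m, fb, box, cfg)
  expect_identical(c1, c2)
  expect_identical(select_batch(c1, 5, box = box),
                   select_batch(c2, 5, box = box))
})

test_that("mcmc_config validates its fields", {
  expect_error(mcmc_config(chain_length = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(scale = 0), "positive")
  cfg <- mcmc_config()
  expect_equal(cfg$chain_length, 10000L)
  expect_equal(cfg$burn_in, 1000L)
})
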