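# shared fixtures, all generated in code

# thin wrappers over internals used by several test files
new_design_for_test <- function(nat, space, roles = "factorial")
  krigdoe:::new_design(nat, roles, space)
fs_box_for_test <- function(space) krigdoe:::fs_box(space)

space2 <- function() factor_space(c("A", "B"), c(0, 0), c(1, 2))

space_k <- function(k, lower = 0.3, upper = 1.7)
  factor_space(if (k > 0) paste0("F", 1:k) else character(0), lower, upper)

refine_space <- function(mg_upper = 2.9) {
  update_bounds(
    subset_space(reduce_components(enbbm_components()),
                 c("MgSO4", "CaCl2", "Trace", "NaNO3")),
    list(MgSO4 = c(0.5, mg_upper), CaCl2 = c(0.527, 1.7),
         Trace = c(0.0833, 3.75), NaNO3 = c(0.16, 1.0)))
}

# small, fast kriging model on a smooth 2-D function
quick_model <- function(n = 25, seed = 5, nugget = NULL, multistart = 4) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(2 * n, -1, 1), n, 2,
                dimnames = list(NULL, c("x1", "x2")))
    y <- drop(1 + sin(2 * X[, 1]) + 0.6 * X[, 2]^2)
    krig_fit(X, y, nugget = nugget, multistart = multistart, seed = seed,
             box = rbind(c(-1, -1), c(1, 1)))
  })
}

# a round-3-style model of the default surface, reused by EI/DRAM tests
refined_model <- function(seed = 7) {
  s <- default_surface()
  sp <- refine_space()
  d <- add_reference_replicates(
    nested_round3_design(sp, c(0.5, 1.7, 2.9)), 4)
  obs <- suppressWarnings(evaluate_design(s, d, seed = seed))
  krig_fit(obs, seed = seed)
}

cached <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, env)) assign(key, force(expr), env)
    get(key, env)
  }
})

# the fixture campaign is expensive; build it once per test run
fixture_campaign <- function(seed = 1)
  cached(paste0("fixture", seed), suppressWarnings(make_fixture_campaign(seed)))
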