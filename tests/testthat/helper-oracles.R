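# independent oracles used to freeze expected values

# ordinary-Kriging oracle via numpy + scikit-learn (pre-installed python)
gp_oracle <- function(X, y, Xnew, theta, g) {
  script <- system.file("oracle", "gp_oracle.py", package = "krigdoe")
  if (script == "") script <- file.path("..", "..", "inst", "oracle", "gp_oracle.py")
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(list(X = X, y = y, Xnew = Xnew, theta = theta, g = g),
                       fin, digits = NA, auto_unbox = FALSE)
  status <- system2("python", c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

# Monte-Carlo oracle for expected improvement under maximization
mc_ei <- function(mu, s, f_best, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    draws <- stats::rnorm(n, mu, s)
    imp <- pmax(draws - f_best, 0)
    list(est = mean(imp), se = stats::sd(imp) / sqrt(n))
  })
}

# G-test of observed counts against expected proportions
g_test <- function(obs, p_exp) {
  keep <- obs > 0
  e <- sum(obs) * p_exp
  G <- 2 * sum(obs[keep] * log(obs[keep] / e[keep]))
  df <- length(obs) - 1L
  stats::pchisq(G, df, lower.tail = FALSE)
}
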