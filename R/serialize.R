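#' Serialize a Kriging model to flat text
#'
#' Scalar fields are written as `key = value` lines (full `%.17g`
#' precision, so numeric round-trips are exact); arrays are written as
#' named CSV blocks delimited by `[name]`. [read_kriging_model()] rebuilds
#' the model, recomputing the factorizations from the stored data.
#'
#' @param model a `kriging_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kriging_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("format = krigdoe-model-1")
  wl("kernel = %s", model$kernel)
  wl("transform = %s", model$transform %||% "none")
  wl("factors = %s", paste(model$factors, collapse = ","))
  for (key in c("my", "sy", "b0s", "s2s", "g", "beta0", "sigma2", "tau2",
                "loglik", "cond"))
    wl("%s = %s", key, fmt_num(model[[key]]))
  wl("theta = %s", paste(fmt_num(model$theta), collapse = ","))
  wl("[X]")
  utils::write.table(apply(model$X, 2L, fmt_num), con, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  wl("[y]")
  writeLines(fmt_num(model$y), con)
  wl("[box]")
  utils::write.table(apply(model$box, 2L, fmt_num), con, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kriging_model
#' @return `read_kriging_model` returns the reconstructed `kriging_model`.
#' @export
read_kriging_model <- function(path) {
  lines <- readLines(path)
  secs <- grep("^\\[", lines)
  kv <- lines[seq_len(if (length(secs)) secs[1L] - 1L else length(lines))]
  kv <- kv[grepl("=", kv)]
  keys <- sub(" *=.*$", "", kv)
  vals <- sub("^[^=]*= *", "", kv)
  names(vals) <- keys
  if (!identical(vals[["format"]], "krigdoe-model-1"))
    stop_krigdoe("unrecognized model file format")

  read_block <- function(name) {
    i <- match(sprintf("[%s]", name), lines)
    j <- c(secs[secs > i], length(lines) + 1L)[1L] - 1L
    lines[(i + 1L):j]
  }
  X <- as.matrix(utils::read.csv(text = paste(read_block("X"), collapse = "\n")))
  y <- as.numeric(read_block("y"))
  box <- as.matrix(utils::read.csv(text = paste(read_block("box"), collapse = "\n")))
  rownames(box) <- c("lower", "upper")

  factors <- strsplit(vals[["factors"]], ",", fixed = TRUE)[[1L]]
  colnames(X) <- factors; colnames(box) <- factors
  theta <- as.numeric(strsplit(vals[["theta"]], ",", fixed = TRUE)[[1L]])
  num <- function(k) as.numeric(vals[[k]])

  lo <- box[1L, ]; hi <- box[2L, ]
  span <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2L, lo, "-"), 2L, span / 2, "/") - 1
  my <- num("my"); sy <- num("sy")
  ys <- (y - my) / sy
  g <- num("g")
  K <- corr_matrix(Xs, theta, vals[["kernel"]])
  diag(K) <- diag(K) + g + KRIG_JITTER
  L <- chol(K)
  n <- nrow(Xs)
  Ki1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  Kiy <- backsolve(L, forwardsolve(t(L), ys))
  one_Ki1 <- sum(Ki1)
  b0s <- num("b0s")
  Kir <- Kiy - b0s * Ki1

  structure(list(
    factors = factors, kernel = vals[["kernel"]],
    transform = if (is.na(vals["transform"])) "none" else vals[["transform"]],
    X = X, y = y, box = box, Xs = Xs, ys = ys, my = my, sy = sy,
    theta = theta, g = g, beta0 = num("beta0"), sigma2 = num("sigma2"),
    tau2 = num("tau2"), b0s = b0s, s2s = num("s2s"),
    L = L, Ki1 = Ki1, Kir = Kir, one_Ki1 = one_Ki1,
    loglik = num("loglik"), cond = num("cond"),
    convergence = 0L, ref_var = NA_real_
  ), class = "kriging_model")
}

#' Serialize a ground-truth surface to flat text
#'
#' @param surface a `ground_truth_surface`.
#' @param path output file.
#' @return `path` invisibly; `read_surface` returns the surface.
#' @export
write_surface <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("format = krigdoe-surface-1")
  wl("# synthetic ground-truth surface (no measured data)")
  wl("baseline = %s", fmt_num(surface$baseline))
  wl("ratio = %s", fmt_num(surface$ratio))
  wl("noise_cv = %s", fmt_num(surface$noise$value))
  wl("active = %s", paste(surface$active, collapse = ","))
  wl("optimum = %s", paste(fmt_num(surface$optimum), collapse = ","))
  wl("curvature = %s", paste(fmt_num(surface$curvature), collapse = ","))
  ut <- which(upper.tri(surface$G) & surface$G != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(ut)))
    wl("interaction = %s,%s,%s", surface$active[ut[r, 1L]],
       surface$active[ut[r, 2L]], fmt_num(surface$G[ut[r, 1L], ut[r, 2L]]))
  for (nm in names(surface$extra_linear))
    wl("extra_linear = %s,%s", nm, fmt_num(surface$extra_linear[[nm]]))
  wl("box_lower = %s", paste(fmt_num(surface$box[1L, ]), collapse = ","))
  wl("box_upper = %s", paste(fmt_num(surface$box[2L, ]), collapse = ","))
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & grepl("=", lines)]
  keys <- sub(" *=.*$", "", lines)
  vals <- sub("^[^=]*= *", "", lines)
  get1 <- function(k) vals[keys == k][1L]
  nums <- function(k) as.numeric(strsplit(get1(k), ",")[[1L]])
  act <- strsplit(get1("active"), ",")[[1L]]
  inter <- list()
  for (v in vals[keys == "interaction"]) {
    p <- strsplit(v, ",")[[1L]]
    inter <- c(inter, list(list(pair = p[1:2], gamma = as.numeric(p[3L]))))
  }
  extra <- numeric()
  for (v in vals[keys == "extra_linear"]) {
    p <- strsplit(v, ",")[[1L]]
    extra[p[1L]] <- as.numeric(p[2L])
  }
  box <- rbind(lower = nums("box_lower"), upper = nums("box_upper"))
  colnames(box) <- act
  ground_truth_surface(
    baseline = as.numeric(get1("baseline")),
    optimum = stats::setNames(nums("optimum"), act),
    curvature = stats::setNames(nums("curvature"), act),
    interactions = inter,
    ratio = as.numeric(get1("ratio")),
    extra_linear = extra,
    noise_cv = as.numeric(get1("noise_cv")),
    box = box
  )
}

#' Write or read an observation set as CSV
#' @param obs an [observation_set()].
#' @param path file path.
#' @return `path` invisibly; the reader returns the `observation_set`.
#' @export
write_observations_csv <- function(obs, path) {
  sp <- attr(obs, "space")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# factor,%s,%s,%s", sp$factors$name,
                     fmt_num(sp$factors$lower), fmt_num(sp$factors$upper)), con)
  ow <- as.data.frame(obs)
  for (nm in c(factor_names(sp), "response"))
    ow[[nm]] <- fmt_num(ow[[nm]])
  utils::write.csv(ow, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  fac <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), ",")[[1L]]
    if (parts[1L] == "factor") fac[[parts[2L]]] <- as.numeric(parts[3:4])
  }
  sp <- factor_space(names(fac),
                     vapply(fac, `[`, 0, 1L), vapply(fac, `[`, 0, 2L))
  structure(df, class = c("observation_set", "data.frame"),
            space = sp, normalized = FALSE)
}
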