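#' Bundle a design with its measured responses
#'
#' @param design a `doe_design`.
#' @param response numeric vector of volumetric lipid productivities
#'   (mg L^-1 d^-1), one per design row; must be non-negative.
#' @return an `observation_set`: a data.frame with `run_id`, `role`,
#'   `plate`, the natural xRef levels and `response`, carrying the factor
#'   space as an attribute.
#' @export
observation_set <- function(design, response) {
  if (length(response) != nrow(design))
    stop_krigdoe("one response per design row required")
  if (any(!is.finite(response)))
    stop_krigdoe("responses must be finite")
  if (any(response < 0))
    stop_krigdoe("responses must be non-negative")
  sp <- attr(design, "space")
  df <- as.data.frame(design)[, c("run_id", "role", "plate", factor_names(sp))]
  df$response <- as.numeric(response)
  structure(df, class = c("observation_set", "data.frame"),
            space = sp, round_id = attr(design, "round_id"),
            normalized = FALSE)
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d runs (%d reference)%s\n", nrow(x),
              sum(x$role == "reference"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

# rbind observation sets, keeping the (possibly wider) factor columns
bind_observations <- function(...) {
  parts <- list(...)
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0L, parts)
  cols <- unique(unlist(lapply(parts, names)))
  aligned <- lapply(parts, function(p) {
    missing <- setdiff(cols, names(p))
    for (nm in missing) p[[nm]] <- NA_real_
    as.data.frame(p)[, cols, drop = FALSE]
  })
  out <- do.call(rbind, aligned)
  out$run_id <- seq_len(nrow(out))
  structure(out, class = c("observation_set", "data.frame"),
            space = attr(parts[[length(parts)]], "space"),
            normalized = FALSE)
}

#' Normalize responses to the plate-wise reference mean
#'
#' Divides every response by the mean response of the reference wells on
#' the same plate, so responses become fold-of-reference and plates are
#' comparable despite batch effects. The reference wells of each plate have
#' normalized mean exactly 1.
#'
#' @param obs an [observation_set()] with at least one reference row per
#'   plate.
#' @return the normalized `observation_set`.
#' @export
normalize_to_reference <- function(obs) {
  if (isTRUE(attr(obs, "normalized"))) return(obs)
  for (pl in unique(obs$plate)) {
    on_plate <- obs$plate == pl
    refs <- on_plate & obs$role == "reference"
    if (!any(refs))
      stop_krigdoe(sprintf("plate %s has no reference wells to normalize against", pl))
    m <- mean(obs$response[refs])
    if (!is.finite(m) || m <= 0)
      stop_krigdoe(sprintf("plate %s reference mean is not positive", pl))
    obs$response[on_plate] <- obs$response[on_plate] / m
  }
  attr(obs, "normalized") <- TRUE
  obs
}

expand_interactions <- function(interactions, space, focus_hint = NULL) {
  nms <- factor_names(space)
  if (is.null(interactions)) return(list())
  if (is.character(interactions)) interactions <- as.list(interactions)
  out <- list()
  for (it in interactions) {
    if (is.character(it) && length(it) == 1L && grepl(":", it))
      it <- strsplit(it, ":", fixed = TRUE)[[1L]]
    if (length(it) != 2L) stop_krigdoe("interactions must be factor pairs")
    if (it[2L] == "*") {
      for (other in setdiff(nms, it[1L]))
        out <- c(out, list(sort(c(it[1L], other))))
    } else {
      out <- c(out, list(sort(it)))
    }
  }
  out <- unique(out)
  for (pr in out)
    if (!all(pr %in% nms))
      stop_krigdoe("interaction names not in factor space: ",
                   paste(setdiff(pr, nms), collapse = ", "))
  out
}

#' Estimate single-component and interaction effects from a two-level design
#'
#' Least-squares fit of the (by default reference-normalized) response on
#' the intercept, all coded main effects and the requested coded two-factor
#' interactions, using the non-reference runs. The reported effect of a
#' term is the expected response change between the factor's minimal and
#' maximal level, i.e. twice the coded regression coefficient. Standard
#' errors use the residual variance pooled with the reference-replicate
#' variance (the references carry pure measurement error), and each term
#' gets a two-sided t test.
#'
#' @param obs an [observation_set()].
#' @param interactions interaction terms: a list of factor-name pairs, or
#'   strings like `"MgSO4:NaNO3"`; `"MgSO4:*"` expands to all pairs with
#'   that factor.
#' @param alpha significance level for the `significant` flag (default 0.1,
#'   deliberately liberal: during screening a false negative is costlier
#'   than a false positive).
#' @param normalize divide by the plate reference mean first (default
#'   `TRUE`, giving relative, fold-of-reference effects).
#' @return data.frame of class `effect_table`: `term`, `effect`, `se`,
#'   `df`, `t`, `p`, `significant`.
#' @export
estimate_effects <- function(obs, interactions = NULL, alpha = 0.1,
                             normalize = TRUE) {
  sp <- attr(obs, "space")
  nms <- factor_names(sp)
  if (normalize) obs <- normalize_to_reference(obs)
  pairs <- expand_interactions(interactions, sp)

  runs <- obs[obs$role != "reference", , drop = FALSE]
  refs <- obs[obs$role == "reference", , drop = FALSE]
  coded <- coded_from_natural(runs[, nms, drop = FALSE], sp)

  X <- cbind(`(Intercept)` = 1, coded)
  for (pr in pairs) {
    cn <- paste(pr, collapse = ":")
    X <- cbind(X, coded[, pr[1L]] * coded[, pr[2L]])
    colnames(X)[ncol(X)] <- cn
  }
  n <- nrow(X); pterms <- ncol(X)
  if (n <= pterms)
    stop_krigdoe("saturated model: more terms than non-reference runs")
  qrX <- qr(X)
  if (qrX$rank < pterms) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):pterms]]
    stop_krigdoe("requested terms are aliased in this design: ",
                 paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, runs$response)
  rss <- sum(fit$residuals^2)
  df_res <- n - pterms
  # pool pure-error information from the reference replicates
  df_ref <- 0; ss_ref <- 0
  if (nrow(refs) >= 2L) {
    for (pl in unique(refs$plate)) {
      r <- refs$response[refs$plate == pl]
      if (length(r) >= 2L) {
        ss_ref <- ss_ref + sum((r - mean(r))^2)
        df_ref <- df_ref + length(r) - 1L
      }
    }
  }
  s2 <- (rss + ss_ref) / (df_res + df_ref)
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))
  se_coef <- sqrt(s2 * XtXinv_diag)
  coefs <- fit$coefficients
  keep <- colnames(X) != "(Intercept)"
  eff <- 2 * coefs[keep]
  se <- 2 * se_coef[keep]
  tt <- eff / se
  dfree <- df_res + df_ref
  p <- 2 * stats::pt(abs(tt), dfree, lower.tail = FALSE)
  out <- data.frame(term = colnames(X)[keep], effect = unname(eff),
                    se = unname(se), df = dfree, t = unname(tt),
                    p = unname(p), significant = unname(p < alpha),
                    stringsAsFactors = FALSE)
  structure(out, class = c("effect_table", "data.frame"),
            alpha = alpha, sigma2 = s2,
            relative = normalize)
}

#' Partition factors into keep/drop after a screening round
#'
#' A factor is kept if its main effect is significant or if it takes part
#' in any significant interaction; everything else is dropped from further
#' rounds.
#'
#' @param estimates an `effect_table` from [estimate_effects()].
#' @param alpha significance level (defaults to the table's own).
#' @return list with character vectors `keep` and `drop`.
#' @export
screen_components <- function(estimates, alpha = attr(estimates, "alpha") %||% 0.1) {
  sig <- estimates$p < alpha
  mains <- !grepl(":", estimates$term)
  all_factors <- estimates$term[mains]
  keep <- estimates$term[mains & sig]
  for (i in which(!mains & sig))
    keep <- union(keep, strsplit(estimates$term[i], ":", fixed = TRUE)[[1L]])
  keep <- intersect(all_factors, keep)  # preserve roster order
  list(keep = keep, drop = setdiff(all_factors, keep))
}

#' Write an effect table as CSV
#' @param estimates an `effect_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}
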