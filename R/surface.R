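#' @name synthetic-surface
#' @title Synthetic ground-truth response surface
#' @description
#' An in-silico stand-in for the micro-photobioreactor: a parametric
#' medium-composition to lipid-productivity surface plus a measurement
#' noise model. The noiseless surface is an additive quadratic in each
#' active factor plus bilinear interaction terms, chosen as the simplest
#' family that reproduces the qualitative findings of a screening
#' campaign — a negative nitrate main effect, positive trace-element and
#' calcium effects, an antagonistic magnesium-by-nitrate interaction, a
#' negative calcium-by-trace interaction, and an interior optimum. All
#' quantities are synthetic; file outputs are labelled accordingly.
NULL

#' Construct a ground-truth surface
#'
#' The quadratic/bilinear shape is parameterized by the optimum location,
#' per-factor curvatures and interaction coefficients; the linear terms and
#' the overall scale are then solved in closed form so that the noiseless
#' value at the all-reference composition equals `baseline` and the value
#' at the optimum equals `ratio * baseline`.
#'
#' @param baseline noiseless productivity at the reference composition
#'   (mg L^-1 d^-1).
#' @param optimum named vector: the surface's interior maximizer in xRef.
#' @param curvature named vector of positive curvatures (response units per
#'   xRef^2) for the active factors.
#' @param interactions list of `list(pair = c(a, b), gamma = ...)` bilinear
#'   coefficients.
#' @param ratio optimum-to-baseline productivity ratio.
#' @param extra_linear named vector of weak linear slopes for inactive
#'   factors (zero contribution at 1 xRef).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise.
#' @param box 2 x d bounds matrix declaring where the surface is meant to
#'   be evaluated.
#' @return an object of class `ground_truth_surface`.
#' @export
ground_truth_surface <- function(baseline, optimum, curvature,
                                 interactions = list(), ratio = 3,
                                 extra_linear = numeric(),
                                 noise_cv = 0.07, box = NULL) {
  if (noise_cv < 0) stop_krigdoe("noise_cv must be >= 0")
  act <- names(optimum)
  if (!setequal(act, names(curvature)))
    stop_krigdoe("optimum and curvature must name the same factors")
  curvature <- curvature[act]
  q <- -curvature
  G <- matrix(0, length(act), length(act), dimnames = list(act, act))
  for (it in interactions) {
    G[it$pair[1L], it$pair[2L]] <- it$gamma
    G[it$pair[2L], it$pair[1L]] <- it$gamma
  }
  hess <- 2 * diag(q) + G
  if (any(eigen(hess, symmetric = TRUE, only.values = TRUE)$values >= 0))
    stop_krigdoe("curvatures/interactions do not give a strict interior maximum")
  # stationarity at the optimum fixes the linear coefficients
  b <- -2 * q * optimum - drop(G %*% optimum)
  qshape <- function(x) {
    x <- x[act]
    sum(q * x^2) + sum(b * x) + 0.5 * sum(x * drop(G %*% x))
  }
  ref <- stats::setNames(rep(1, length(act)), act)
  delta0 <- qshape(optimum) - qshape(ref)
  if (delta0 <= 0) stop_krigdoe("optimum is not above the reference")
  scale <- baseline * (ratio - 1) / delta0
  const <- baseline - scale * qshape(ref)
  if (is.null(box)) {
    box <- rbind(lower = pmax(0, optimum - 1), upper = optimum + 1)
    colnames(box) <- act
  }
  structure(list(
    baseline = baseline, optimum = optimum, curvature = curvature,
    q = q, b = b, G = G, scale = scale, const = const, ratio = ratio,
    extra_linear = extra_linear, noise = list(type = "cv", value = noise_cv),
    box = box, active = act
  ), class = "ground_truth_surface")
}

#' @export
print.ground_truth_surface <- function(x, ...) {
  cat("Synthetic ground-truth surface (quadratic + bilinear)\n")
  cat(sprintf("  baseline %.3g mg/L/d at reference; optimum ratio %.3g\n",
              x$baseline, x$ratio))
  cat("  optimum:", paste(sprintf("%s=%.3g", names(x$optimum), x$optimum),
                          collapse = ", "), "\n")
  cat(sprintf("  noise: multiplicative, CV = %.3g\n", x$noise$value))
  invisible(x)
}

#' The packaged default surface
#'
#' Emulates the response structure of a four-factor medium-optimization
#' campaign: interior optimum at magnesium 3.25, calcium 1.25, trace
#' elements 2.5 and nitrate 0.45 xRef; baseline 73 mg L^-1 d^-1 at the
#' reference (deliberately *not* a measured value, to mark the surface as
#' synthetic); optimum-to-baseline ratio 3.03; antagonistic MgSO4 x NaNO3
#' and CaCl2 x Trace interactions; weak negative linear trends for the MES
#' buffer and the EDTA chelator; 7 % multiplicative measurement noise.
#'
#' @return a [ground_truth_surface()].
#' @examples
#' s <- default_surface()
#' surface_value(s, data.frame(MgSO4 = 1, CaCl2 = 1, Trace = 1, NaNO3 = 1))
#' @export
default_surface <- function() {
  ground_truth_surface(
    baseline = 73,
    optimum = c(MgSO4 = 3.25, CaCl2 = 1.25, Trace = 2.5, NaNO3 = 0.45),
    curvature = c(MgSO4 = 5, CaCl2 = 40, Trace = 5, NaNO3 = 60),
    interactions = list(list(pair = c("MgSO4", "NaNO3"), gamma = -6),
                        list(pair = c("CaCl2", "Trace"), gamma = -3)),
    ratio = 3.03,
    extra_linear = c(MES = -1.5, Na2EDTA = -2),
    noise_cv = 0.07,
    box = rbind(lower = c(MgSO4 = 0.5, CaCl2 = 0.527, Trace = 0.0833,
                          NaNO3 = 0.16),
                upper = c(MgSO4 = 4.0, CaCl2 = 1.7, Trace = 3.75,
                          NaNO3 = 1.0))
  )
}

#' Noiseless surface value at given compositions
#'
#' Factors absent from a row default to the reference level 1 xRef; the
#' value may be negative far from the optimum (productivity measurements
#' are floored at zero only when the surface is *observed* via
#' [evaluate_design()]).
#'
#' @param surface a `ground_truth_surface`.
#' @param x data.frame or matrix of compositions in xRef units.
#' @return numeric vector of productivities.
#' @export
surface_value <- function(surface, x) {
  x <- as.data.frame(x)
  act <- surface$active
  X <- matrix(1, nrow(x), length(act), dimnames = list(NULL, act))
  for (nm in act) if (nm %in% names(x)) X[, nm] <- x[[nm]]
  val <- surface$const +
    surface$scale * (X^2 %*% surface$q + X %*% surface$b +
                       0.5 * rowSums((X %*% surface$G) * X))
  for (nm in names(surface$extra_linear)) {
    lv <- if (nm %in% names(x)) x[[nm]] else 1
    val <- val + surface$extra_linear[[nm]] * (lv - 1)
  }
  drop(val)
}

#' Box-constrained maximizer of the noiseless surface
#'
#' Dense grid search plus local refinement, exposed so that optimizer
#' recovery can be measured against an independent answer.
#'
#' @param surface a `ground_truth_surface`.
#' @param box 2 x d bounds (defaults to the surface's declared box).
#' @param resolution grid points per axis.
#' @return list with `x` (named composition) and `value`.
#' @export
surface_argmax <- function(surface, box = surface$box, resolution = 21L) {
  act <- surface$active
  seqs <- lapply(act, function(nm) seq(box[1L, nm], box[2L, nm],
                                       length.out = resolution))
  grid <- expand.grid(seqs, KEEP.OUT.ATTRS = FALSE)
  colnames(grid) <- act
  vals <- surface_value(surface, grid)
  x0 <- as.numeric(grid[which.max(vals), ])
  o <- stats::optim(x0, function(z) {
    df <- as.data.frame(matrix(z, 1L, dimnames = list(NULL, act)))
    -surface_value(surface, df)
  }, method = "L-BFGS-B", lower = box[1L, act], upper = box[2L, act])
  list(x = stats::setNames(o$par, act), value = -o$value)
}

#' Observe a design on the synthetic cultivation platform
#'
#' Evaluates the noiseless surface at every design row and applies seeded
#' multiplicative lognormal noise with the surface's coefficient of
#' variation (mean-one noise, so replicates scatter around the true value).
#' Reference rows receive independent noise draws, which is what lets a
#' nugget be estimated from them. Negative raw values are clipped to zero
#' with a warning.
#'
#' @param surface a `ground_truth_surface`.
#' @param design a `doe_design` (rows outside the surface's declared box
#'   are evaluated anyway; a note is attached).
#' @param seed RNG seed; evaluation is deterministic given seed and row
#'   order.
#' @return an [observation_set()].
#' @export
evaluate_design <- function(surface, design, seed = 1L) {
  nat <- as.data.frame(natural_levels(design))
  f <- surface_value(surface, nat)
  cv <- surface$noise$value
  y <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    fac <- with_seed(seed, stats::rlnorm(length(f), -sdlog^2 / 2, sdlog))
    f * fac
  } else f
  clipped <- y < 0
  if (any(clipped)) {
    warning(sprintf("%d negative raw draws clipped to 0", sum(clipped)))
    y[clipped] <- 0
  }
  obs <- observation_set(design, y)
  act <- intersect(surface$active, colnames(surface$box))
  inb <- vapply(seq_len(nrow(nat)), function(i) {
    row <- nat[i, ]
    all(vapply(intersect(act, names(row)), function(nm)
      row[[nm]] >= surface$box[1L, nm] - 1e-9 &&
        row[[nm]] <= surface$box[2L, nm] + 1e-9, TRUE))
  }, TRUE)
  attr(obs, "outside_surface_box") <- sum(!inb)
  attr(obs, "noise_cv") <- cv
  obs
}
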