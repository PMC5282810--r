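#' Define the factor space of a medium-optimization campaign
#'
#' A factor space is the ordered set of free input variables (medium
#' components or clusters of components), each with per-round bounds
#' expressed as multiples of the reference medium concentration ("xRef").
#' Components that are co-varied from one stock solution are recorded as
#' tied groups; components held constant are recorded with their fixed
#' level.
#'
#' @param names character vector of free-variable names (unique).
#' @param lower,upper numeric bounds in xRef units; `lower >= 0`,
#'   `upper > lower`, recycled to `length(names)`.
#' @param reference_concentration optional named numeric vector of natural
#'   reference concentrations (mass per volume) used only as metadata for
#'   xRef-to-natural-unit conversion.
#' @param tied_groups list of character vectors; the first element of each
#'   group is the representative free variable, the rest follow it.
#' @param fixed data.frame with columns `name` and `level` (xRef) for
#'   components held constant.
#' @return an object of class `factor_space`.
#' @examples
#' fs <- factor_space(c("MgSO4", "NaNO3"), lower = 0.3, upper = 1.7)
#' n_free(fs)
#' @export
factor_space <- function(names, lower = 0.3, upper = 1.7,
                         reference_concentration = NULL,
                         tied_groups = list(),
                         fixed = data.frame(name = character(),
                                            level = numeric())) {
  names <- as.character(names)
  k <- length(names)
  if (anyDuplicated(names)) stop_krigdoe("factor names must be unique")
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  if (k > 0L) {
    if (any(lower < 0)) stop_krigdoe("lower bounds must be >= 0 xRef")
    if (any(upper <= lower)) stop_krigdoe("each upper bound must exceed its lower bound")
  }
  refc <- rep(NA_real_, k)
  if (!is.null(reference_concentration)) {
    idx <- match(names, names(reference_concentration))
    refc <- as.numeric(reference_concentration)[idx]
  }
  for (g in tied_groups) {
    if (length(g) < 2L) stop_krigdoe("tied groups need >= 2 members")
    if (!(g[[1L]] %in% names))
      stop_krigdoe(sprintf("tied group representative '%s' is not a free variable", g[[1L]]))
  }
  out <- structure(list(
    factors = data.frame(name = names, lower = lower, upper = upper,
                         reference_concentration = refc,
                         stringsAsFactors = FALSE),
    tied_groups = tied_groups,
    fixed = fixed
  ), class = "factor_space")
  ref_out <- with(out$factors, 1 < lower | 1 > upper)
  if (any(ref_out))
    attr(out, "reference_outside_bounds") <- names[ref_out]
  out
}

#' @export
print.factor_space <- function(x, ...) {
  cat(sprintf("Factor space: %d free variable(s)\n", n_free(x)))
  if (n_free(x) > 0L) print(x$factors, row.names = FALSE)
  if (length(x$tied_groups))
    cat("Tied:", paste(vapply(x$tied_groups, paste, "", collapse = "<-"),
                       collapse = ", "), "\n")
  if (nrow(x$fixed))
    cat("Fixed:", paste(sprintf("%s=%g", x$fixed$name, x$fixed$level),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Number of free variables in a factor space
#' @param space a `factor_space`.
#' @return integer count.
#' @export
n_free <- function(space) nrow(space$factors)

#' Factor names of a factor space
#' @param space a `factor_space`.
#' @return character vector.
#' @export
factor_names <- function(space) space$factors$name

# 2 x k matrix of bounds, columns named by factor
fs_box <- function(space) {
  rbind(lower = space$factors$lower, upper = space$factors$upper) |>
    `colnames<-`(space$factors$name)
}

#' Replace the bounds of selected factors
#'
#' Used to apply per-round bound updates (e.g. lowering the nitrate ceiling
#' after a screening round). Updates are logged in the returned object's
#' `bound_log` attribute.
#'
#' @param space a `factor_space`.
#' @param bounds named list of `c(lower, upper)` pairs in xRef units.
#' @return the updated `factor_space`.
#' @export
update_bounds <- function(space, bounds) {
  log <- attr(space, "bound_log") %||% character()
  for (nm in names(bounds)) {
    i <- match(nm, space$factors$name)
    if (is.na(i)) stop_krigdoe(sprintf("unknown factor '%s'", nm))
    b <- as.numeric(bounds[[nm]])
    log <- c(log, sprintf("%s: [%g, %g] -> [%g, %g]", nm,
                          space$factors$lower[i], space$factors$upper[i],
                          b[1L], b[2L]))
    space$factors$lower[i] <- b[1L]
    space$factors$upper[i] <- b[2L]
  }
  if (any(space$factors$upper <= space$factors$lower))
    stop_krigdoe("bound update leaves upper <= lower")
  attr(space, "bound_log") <- log
  space
}

#' Restrict a factor space to a subset of its free variables
#' @param space a `factor_space`.
#' @param keep character vector of factor names to retain.
#' @return the reduced `factor_space`.
#' @export
subset_space <- function(space, keep) {
  miss <- setdiff(keep, space$factors$name)
  if (length(miss))
    stop_krigdoe("unknown factor(s): ", paste(miss, collapse = ", "))
  space$factors <- space$factors[match(keep, space$factors$name), , drop = FALSE]
  rownames(space$factors) <- NULL
  space$tied_groups <- Filter(function(g) g[[1L]] %in% keep, space$tied_groups)
  space
}

#' Component roster of the enriched Bold's Basal reference medium
#'
#' The 17 components of the enriched Bold's Basal Medium (phosphate salts
#' counted as one compound because of their pH-dependent equilibrium),
#' together with the variation decision taken for each before screening:
#' vary it freely, fix it, cluster it with other components into one input
#' variable, or tie it to the component sharing its stock solution.
#'
#' @return data.frame with columns `component`, `decision`
#'   (`"vary"`, `"fix"`, `"cluster-with"`, `"tie-with"`), `partner`
#'   (cluster variable or tie target), `reference_concentration`
#'   (mg per litre) and `fixed_level` (xRef, for fixed components).
#' @seealso [reduce_components()]
#' @export
enbbm_components <- function() {
  tbl <- data.frame(
    component = c("MES", "Phosphate", "NaNO3", "MgSO4", "NaCl", "CaCl2",
                  "ZnSO4", "MnCl2", "Na2MoO4", "CuSO4", "CoSO4", "H3BO3",
                  "FeSO4", "H2SO4", "Na2EDTA", "KOH", "PenicillinG"),
    decision = c("vary", "vary", "vary", "vary", "vary", "vary",
                 "cluster-with", "cluster-with", "cluster-with",
                 "cluster-with", "cluster-with", "cluster-with",
                 "vary", "tie-with", "vary", "tie-with", "fix"),
    partner = c(NA, NA, NA, NA, NA, NA,
                "Trace", "Trace", "Trace", "Trace", "Trace", "Trace",
                NA, "FeSO4", NA, "Na2EDTA", NA),
    reference_concentration = c(9760, 2000, 1500, 187.5, 6.25, 125,
                                17.64, 2.88, 2.4, 3.14, 0.94, 22.8,
                                9.96, 3.68, 100, 62, 100),
    fixed_level = c(rep(NA_real_, 16), 1),
    stringsAsFactors = FALSE
  )
  tbl
}

#' Default screening bounds for medium components, in xRef units
#'
#' The screening box used in the first two campaign rounds. Most components
#' vary between 0.3 and 1.7 times their reference concentration; the
#' clustered trace elements extend to 2.5 xRef (little amounts are
#' essential but high levels are cytotoxic, so a wider ceiling is probed);
#' components that the organism can do without (NaCl, the MES buffer, the
#' EDTA chelator) may be diluted to zero, and phosphate down to 0.125 xRef.
#'
#' @param names character vector of free-variable names.
#' @return named list of `c(lower, upper)` pairs.
#' @export
screening_bounds <- function(names) {
  default <- c(0.3, 1.7)
  special <- list(
    Trace    = c(0.3, 2.5),
    NaCl     = c(0, 1.7),
    MES      = c(0, 1.7),
    Na2EDTA  = c(0, 1.7),
    Phosphate = c(0.125, 1.7)
  )
  out <- lapply(names, function(nm) special[[nm]] %||% default)
  names(out) <- names
  out
}

#' Reduce a component roster to the free variables of a screening design
#'
#' Applies the variation decisions of a component table (such as
#' [enbbm_components()]): varied components become free variables, clustered
#' components are merged into a single representative variable, tied
#' components follow the free variable that shares their stock solution,
#' and fixed components are recorded at their constant level. The number of
#' free variables equals the number of varied components minus cluster
#' merges minus ties.
#'
#' @param component_table data.frame with columns `component`, `decision`,
#'   `partner`, and optionally `reference_concentration`, `fixed_level`.
#' @param bounds named list of `c(lower, upper)` bounds in xRef for the free
#'   variables; defaults to [screening_bounds()].
#' @return a [factor_space()].
#' @examples
#' fs <- reduce_components(enbbm_components())
#' n_free(fs)  # 9
#' @export
reduce_components <- function(component_table, bounds = NULL) {
  tbl <- component_table
  need <- c("component", "decision")
  if (!all(need %in% names(tbl)))
    stop_krigdoe("component table needs columns 'component' and 'decision'")
  if (!"partner" %in% names(tbl)) tbl$partner <- NA_character_
  ok <- c("vary", "fix", "cluster-with", "tie-with")
  bad <- setdiff(unique(tbl$decision), ok)
  if (length(bad))
    stop_krigdoe("unknown decision keyword(s): ", paste(bad, collapse = ", "))

  varied <- tbl$component[tbl$decision == "vary"]

  # ties must point at a varied component
  ties <- tbl[tbl$decision == "tie-with", , drop = FALSE]
  for (i in seq_len(nrow(ties))) {
    tgt <- ties$partner[i]
    if (is.na(tgt) || !(tgt %in% varied))
      stop_krigdoe(sprintf(
        "component '%s' is tied to '%s', which is not a varied component",
        ties$component[i], tgt))
  }

  # clusters: all members merge into one representative variable,
  # placed at the first member's position in the roster
  free <- character()
  cluster_seen <- character()
  for (i in seq_len(nrow(tbl))) {
    d <- tbl$decision[i]
    if (d == "vary") {
      free <- c(free, tbl$component[i])
    } else if (d == "cluster-with") {
      rep_name <- tbl$partner[i]
      if (is.na(rep_name)) stop_krigdoe("cluster-with requires a partner name")
      if (!(rep_name %in% cluster_seen)) {
        free <- c(free, rep_name)
        cluster_seen <- c(cluster_seen, rep_name)
      }
    }
  }

  tied_groups <- lapply(seq_len(nrow(ties)), function(i)
    c(ties$partner[i], ties$component[i]))
  fixed <- tbl[tbl$decision == "fix", , drop = FALSE]
  fixed_df <- data.frame(name = fixed$component,
                         level = if ("fixed_level" %in% names(fixed))
                           ifelse(is.na(fixed$fixed_level), 1, fixed$fixed_level)
                         else rep(1, nrow(fixed)),
                         stringsAsFactors = FALSE)

  if (length(free) == 0L)
    return(factor_space(character(), numeric(), numeric(),
                        tied_groups = tied_groups, fixed = fixed_df))

  if (is.null(bounds)) bounds <- screening_bounds(free)
  lo <- vapply(free, function(nm) (bounds[[nm]] %||% c(0.3, 1.7))[1L], 0)
  hi <- vapply(free, function(nm) (bounds[[nm]] %||% c(0.3, 1.7))[2L], 0)

  refc <- NULL
  if ("reference_concentration" %in% names(tbl)) {
    refc <- stats::setNames(tbl$reference_concentration, tbl$component)
    # a clustered variable has no single natural concentration
  }
  factor_space(free, lo, hi, reference_concentration = refc,
               tied_groups = tied_groups, fixed = fixed_df)
}
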