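#' @name design
#' @title Experimental designs on microtiter plates
#' @description
#' Designs are data frames with one row per culture well: a `run_id`, a
#' `role` (`factorial`, `center`, `space_filling`, `ei_proposed`,
#' `random_uniform` or `reference`), a `plate` number and `well` position
#' (rows A-F x columns 1-8 on a 48-well FlowerPlate), followed by one
#' column per free variable holding the natural level in xRef units. The
#' generating [factor_space()] and the round index travel along as
#' attributes, so coded (-1/+1) levels can always be recovered exactly.
NULL

PLATE_ROWS <- LETTERS[1:6]
PLATE_COLS <- 1:8

new_design <- function(natural, roles, space, round_id = NA_integer_,
                       capacity = 48L, ...) {
  natural <- as.data.frame(natural)
  if (ncol(natural) != n_free(space) && n_free(space) > 0L)
    stop_krigdoe("design columns do not match factor space")
  if (n_free(space) > 0L) colnames(natural) <- factor_names(space)
  n <- nrow(natural)
  d <- cbind(data.frame(run_id = seq_len(n),
                        role = rep_len(roles, n),
                        stringsAsFactors = FALSE),
             natural)
  d <- assign_wells(d, capacity)
  structure(d, class = c("doe_design", "data.frame"),
            space = space, round_id = round_id, capacity = capacity, ...)
}

assign_wells <- function(d, capacity = 48L) {
  n <- nrow(d)
  idx <- seq_len(n) - 1L
  wells <- paste0(rep(PLATE_ROWS, each = length(PLATE_COLS)), PLATE_COLS)
  d$plate <- idx %/% capacity + 1L
  d$well <- wells[(idx %% capacity) %% 48L + 1L]
  d[, c("run_id", "role", "plate", "well",
        setdiff(names(d), c("run_id", "role", "plate", "well")))]
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("DoE design: %d runs, %d free variable(s), round %s\n",
              nrow(x), n_free(attr(x, "space")),
              format(attr(x, "round_id"))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Natural levels of the free variables of a design
#' @param design a `doe_design`.
#' @return numeric matrix (runs x factors) in xRef units.
#' @export
natural_levels <- function(design) {
  sp <- attr(design, "space")
  as.matrix(as.data.frame(design)[, factor_names(sp), drop = FALSE])
}

#' Convert natural xRef levels to coded -1/+1 levels (and back)
#'
#' Coded level -1 maps to a factor's lower bound, +1 to its upper bound,
#' affinely in between. The mapping is an exact bijection for the bounds
#' recorded in the factor space.
#'
#' @param x numeric matrix or data.frame of levels (columns = factors).
#' @param space the [factor_space()] providing bounds.
#' @return numeric matrix of the same shape.
#' @export
coded_from_natural <- function(x, space) {
  x <- as.matrix(as.data.frame(x)[, factor_names(space), drop = FALSE])
  lo <- space$factors$lower
  hi <- space$factors$upper
  sweep(sweep(x, 2L, lo, "-"), 2L, (hi - lo) / 2, "/") - 1
}

#' @rdname coded_from_natural
#' @export
natural_from_coded <- function(x, space) {
  x <- as.matrix(x)
  lo <- space$factors$lower
  hi <- space$factors$upper
  out <- sweep(sweep(x + 1, 2L, (hi - lo) / 2, "*"), 2L, lo, "+")
  colnames(out) <- factor_names(space)
  out
}

#' Coded levels of a design
#' @param design a `doe_design`.
#' @return numeric matrix of coded levels in [-1, 1].
#' @export
coded_levels <- function(design)
  coded_from_natural(natural_levels(design), attr(design, "space"))

#' Two-level full factorial design
#'
#' All 2^k combinations of the factor bounds, one run each, in standard
#' (Yates) order. Every coded column is balanced (sums to zero) and any two
#' columns are orthogonal.
#'
#' @param space a [factor_space()] with `k >= 0` free variables.
#' @param round_id integer round label.
#' @param capacity wells per plate (default 48).
#' @return a `doe_design` with `2^k` rows of role `factorial`.
#' @examples
#' d <- full_factorial(factor_space(c("A", "B"), 0, 1))
#' nrow(d)  # 4
#' @export
full_factorial <- function(space, round_id = NA_integer_, capacity = 48L) {
  k <- n_free(space)
  if (k == 0L) {
    nat <- data.frame(row.names = 1L)  # single empty run
    return(new_design(nat, "factorial", space, round_id, capacity))
  }
  coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  dimnames(coded) <- list(NULL, factor_names(space))
  new_design(natural_from_coded(coded, space), "factorial", space,
             round_id, capacity)
}

# ---- regular fraction machinery -------------------------------------------
# A regular 2^(k-p) fraction is defined by assigning each of the k factors a
# word in GF(2)^q over q basis factors (basis factor i -> e_i, added factors
# -> generator words with >= 2 letters). The effect column of a term equals
# the XOR of its factors' words; a set of terms is jointly estimable iff all
# effect words are distinct and non-zero (plus the zero word for the
# intercept). This is exact for regular fractions and verified by a model
# matrix rank check on the accepted design.

word_candidates <- function(q, min_letters = 2L) {
  w <- seq_len(2L^q - 1L)
  w[vapply(w, function(x) sum(bitwAnd(x, 2L^(0:(q - 1L))) > 0L), 0L) >= min_letters]
}

terms_estimable <- function(words, k, focus) {
  eff <- c(0L, words)                       # intercept + mains
  for (j in seq_len(k)) if (j != focus)
    eff <- c(eff, bitwXor(words[focus], words[j]))
  !anyDuplicated(eff) && all(eff[-1L] != 0L)
}

# Search generator sets in lexicographic order; generator words with at
# least 3 letters are tried first (when such a set exists the fraction has
# resolution >= IV, so no main effect is aliased with any two-factor
# interaction), then the search falls back to 2-letter words.
search_generators <- function(k, q, focus) {
  p <- k - q
  if (p == 0L) return(integer())
  basis_words <- 2L^(seq_len(q) - 1L)
  for (min_letters in c(3L, 2L)) {
    cand <- word_candidates(q, min_letters)
    if (length(cand) < p) next
    combos <- utils::combn(cand, p)
    for (j in seq_len(ncol(combos))) {
      words <- c(basis_words, combos[, j])
      if (terms_estimable(words, k, focus)) return(combos[, j])
    }
  }
  NULL
}

word_string <- function(word, q) {
  letters_used <- LETTERS[seq_len(q)]
  paste(letters_used[bitwAnd(word, 2L^(0:(q - 1L))) > 0L], collapse = "")
}

#' Regular two-level fractional factorial with a focus factor
#'
#' Searches regular 2^(k-p) fractions of increasing run count (powers of
#' two) for the smallest one in which all `k` main effects and all `k - 1`
#' two-factor interactions involving `focus_factor` are estimable free of
#' mutual aliasing. Generator words are searched in lexicographic order and
#' the first compliant set is accepted; the defining words are recorded in
#' the design's `generators` attribute.
#'
#' @param space a [factor_space()].
#' @param focus_factor name of the factor whose pairwise interactions must
#'   remain estimable (e.g. magnesium when probing interactions with the
#'   acetyl-CoA carboxylase effector).
#' @param n_ref number of reference replicates that must still fit on the
#'   plate after augmentation (capacity check only; use
#'   [add_reference_replicates()] to append them).
#' @param capacity wells per plate.
#' @inheritParams full_factorial
#' @return a `doe_design` of factorial rows.
#' @examples
#' fs <- reduce_components(enbbm_components())
#' d <- fractional_factorial(fs, "MgSO4")
#' nrow(d)  # 32
#' @export
fractional_factorial <- function(space, focus_factor,
                                 n_ref = 5L, capacity = 48L,
                                 round_id = NA_integer_) {
  k <- n_free(space)
  focus <- match(focus_factor, factor_names(space))
  if (is.na(focus)) stop_krigdoe(sprintf("unknown focus factor '%s'", focus_factor))
  n_terms <- 1L + k + (k - 1L)
  q_min <- max(1L, ceiling(log2(n_terms)))
  for (q in q_min:k) {
    n_runs <- 2L^q
    if (n_runs + n_ref > capacity && q < k) {
      # keep searching only to report a meaningful deficit below
    }
    gen <- search_generators(k, q, focus)
    if (!is.null(gen)) {
      if (n_runs + n_ref > capacity)
        stop_krigdoe(sprintf(
          "smallest compliant regular fraction needs %d runs; with %d references it exceeds plate capacity %d by %d wells",
          n_runs, n_ref, capacity, n_runs + n_ref - capacity))
      base <- as.matrix(expand.grid(rep(list(c(-1, 1)), q)))
      cols <- matrix(0, n_runs, k)
      basis_words <- 2L^(seq_len(q) - 1L)
      words <- c(basis_words, gen)
      for (j in seq_len(k)) {
        bits <- which(bitwAnd(words[j], basis_words) > 0L)
        cols[, j] <- apply(base[, bits, drop = FALSE], 1L, prod)
      }
      dimnames(cols) <- list(NULL, factor_names(space))
      def <- if (length(gen))
        sprintf("%s=%s", LETTERS[(q + 1L):k],
                vapply(gen, word_string, "", q = q))
      else character()
      return(new_design(natural_from_coded(cols, space), "factorial",
                        space, round_id, capacity,
                        generators = def, n_basis = q))
    }
  }
  stop_krigdoe("no regular fraction up to the full factorial satisfies the estimability requirement")
}

#' Nested three-level refinement design around a focus factor
#'
#' The refinement-round geometry: the focus factor (magnesium by default)
#' is varied over three levels; at each level the remaining three cube
#' variables form a 2^3 full factorial. At the middle level the cube
#' shrinks to half ranges (coded +/-0.5 in the round's coding frame).
#' Cube center points (default 2) are placed at the cube center, cycling
#' through the focus levels, and a deterministic maximin-spread set of edge
#' points (default 9) is distributed over the cube edges.
#'
#' @param space a [factor_space()] with exactly 4 free variables.
#' @param mg_levels three strictly increasing focus-factor levels in xRef.
#' @param inner_half_range if `TRUE` (default) the middle level's cube uses
#'   half ranges.
#' @param mg_factor name of the three-level factor.
#' @param n_centers number of cube center points (default 2, so that the
#'   35 design rows plus 4 reference replicates fill 39 wells).
#' @param n_edge number of space-filling edge points (default 9).
#' @inheritParams full_factorial
#' @return a `doe_design` with roles `factorial`, `center`, `space_filling`.
#' @export
nested_round3_design <- function(space, mg_levels, inner_half_range = TRUE,
                                 mg_factor = "MgSO4", n_centers = 2L,
                                 n_edge = 9L, round_id = 3L,
                                 capacity = 48L) {
  if (n_free(space) != 4L)
    stop_krigdoe("nested refinement design needs exactly 4 free variables")
  if (length(mg_levels) < 1L || is.unsorted(mg_levels, strictly = TRUE))
    stop_krigdoe("mg_levels must be strictly increasing")
  i_mg <- match(mg_factor, factor_names(space))
  if (is.na(i_mg)) stop_krigdoe(sprintf("unknown factor '%s'", mg_factor))
  cube_vars <- setdiff(factor_names(space), mg_factor)
  m <- length(mg_levels)
  mid <- if (m >= 3L && m %% 2L == 1L) (m + 1L) %/% 2L else NA_integer_

  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), 3L)))
  coded <- NULL; roles <- character()
  mg_coded_of <- function(lv) {
    lo <- space$factors$lower[i_mg]; hi <- space$factors$upper[i_mg]
    2 * (lv - lo) / (hi - lo) - 1
  }
  for (i in seq_len(m)) {
    s <- if (inner_half_range && !is.na(mid) && i == mid) 0.5 else 1
    blk <- cbind(mg = mg_coded_of(mg_levels[i]), corners * s)
    coded <- rbind(coded, blk)
    roles <- c(roles, rep("factorial", nrow(corners)))
  }
  if (n_centers > 0L) {
    lv <- mg_levels[((seq_len(n_centers) - 1L) %% m) + 1L]
    coded <- rbind(coded, cbind(mg = mg_coded_of(lv),
                                matrix(0, n_centers, 3L)))
    roles <- c(roles, rep("center", n_centers))
  }
  if (n_edge > 0L) {
    cand <- NULL
    for (i in seq_len(m)) {
      s <- if (inner_half_range && !is.na(mid) && i == mid) 0.5 else 1
      # edges: two cube coordinates at +/-s, the third free of the corners
      for (free_dim in 1:3) for (a in c(-s, s)) for (b in c(-s, s))
        for (t in c(-0.5, 0, 0.5) * s) {
          pt <- numeric(3); pt[free_dim] <- t
          pt[setdiff(1:3, free_dim)] <- c(a, b)
          cand <- rbind(cand, c(mg_coded_of(mg_levels[i]), pt))
        }
    }
    sel <- maximin_select(cand, n_edge, existing = coded)
    coded <- rbind(coded, sel)
    roles <- c(roles, rep("space_filling", nrow(sel)))
  }
  colnames(coded) <- c(mg_factor, cube_vars)
  coded <- coded[, factor_names(space), drop = FALSE]
  new_design(natural_from_coded(coded, space), roles, space, round_id,
             capacity, mg_levels = mg_levels)
}

# greedy farthest-point (maximin) selection from a candidate matrix,
# deterministic: ties broken by candidate index
maximin_select <- function(cand, n, existing = NULL) {
  cand <- unique(cand)
  n <- min(n, nrow(cand))
  picked <- integer()
  dmin <- if (is.null(existing) || nrow(existing) == 0L)
    rep(Inf, nrow(cand))
  else apply(cand, 1L, function(p)
    min(sqrt(colSums((t(existing) - p)^2))))
  for (i in seq_len(n)) {
    j <- which.max(dmin)
    picked <- c(picked, j)
    dj <- sqrt(colSums((t(cand) - cand[j, ])^2))
    dmin <- pmin(dmin, dj)
    dmin[j] <- -Inf
  }
  cand[picked, , drop = FALSE]
}

#' Append reference-medium replicate wells to a design
#'
#' Reference wells run the unmodified reference medium (all free variables
#' at 1.0 xRef). Replicating them on every plate quantifies measurement
#' noise and anchors plate-wise normalization.
#'
#' @param design a `doe_design`.
#' @param n_ref number of reference replicates to append (>= 0).
#' @param capacity wells per plate; exceeding it is an error.
#' @return the augmented `doe_design`.
#' @export
add_reference_replicates <- function(design, n_ref,
                                     capacity = attr(design, "capacity") %||% 48L) {
  if (n_ref < 0L) stop_krigdoe("n_ref must be >= 0")
  if (n_ref == 0L) return(design)
  sp <- attr(design, "space")
  total <- nrow(design) + n_ref
  if (total > capacity)
    stop_krigdoe(sprintf(
      "design of %d runs plus %d references exceeds plate capacity %d (overflow %d)",
      nrow(design), n_ref, capacity, total - capacity))
  nat <- rbind(natural_levels(design),
               matrix(1, n_ref, n_free(sp),
                      dimnames = list(NULL, factor_names(sp))))
  at <- attributes(design)
  d <- new_design(nat, c(design$role, rep("reference", n_ref)), sp,
                  attr(design, "round_id"), capacity)
  for (extra in setdiff(names(at), c("names", "class", "row.names", "space",
                                     "round_id", "capacity")))
    attr(d, extra) <- at[[extra]]
  d
}

#' Number of plates needed for a run count
#' @param n_runs number of culture wells required (>= 0).
#' @param capacity wells per plate (>= 1, default 48).
#' @return smallest integer `p` with `p * capacity >= n_runs`.
#' @examples
#' plates_required(2^9)  # 11
#' @export
plates_required <- function(n_runs, capacity = 48L) {
  if (n_runs < 0) stop_krigdoe("n_runs must be >= 0")
  if (capacity < 1) stop_krigdoe("capacity must be >= 1")
  as.integer(ceiling(n_runs / capacity))
}

#' Snap design levels to what the liquid handler can pipette
#'
#' Stock-solution volumes are restricted to multiples of the minimum
#' pipetting volume (10 uL by default); a requested level below half an
#' aliquot snaps to zero. Snapping is advisory: the snapped design and the
#' per-row relative snap error are returned, nothing errors.
#'
#' @param design a `doe_design`.
#' @param stock_concentrations named numeric vector: the xRef-equivalents
#'   added to the well by 1 uL of each component's stock solution.
#' @param well_volume culture-well working volume in uL (default 2500).
#' @param min_pipette smallest pipettable volume in uL (default 10).
#' @return the snapped `doe_design`, with a numeric matrix attribute
#'   `snap_error` of relative errors (|snapped - requested| / increment of
#'   one aliquot).
#' @export
snap_to_pipetting_grid <- function(design, stock_concentrations,
                                   well_volume = 2500, min_pipette = 10) {
  sp <- attr(design, "space")
  nat <- natural_levels(design)
  err <- matrix(0, nrow(nat), ncol(nat), dimnames = dimnames(nat))
  for (nm in colnames(nat)) {
    conc <- stock_concentrations[[nm]]
    if (is.null(conc) || is.na(conc)) next
    vol <- nat[, nm] / conc                      # requested stock volume, uL
    snapped_vol <- round(vol / min_pipette) * min_pipette
    if (any(snapped_vol > well_volume))
      warning(sprintf("snapped stock volume of '%s' exceeds the well volume", nm))
    err[, nm] <- abs(snapped_vol - vol) * conc / (min_pipette * conc)
    nat[, nm] <- snapped_vol * conc
  }
  at <- attributes(design)
  d <- new_design(nat, design$role, sp, attr(design, "round_id"),
                  attr(design, "capacity") %||% 48L)
  for (extra in setdiff(names(at), c("names", "class", "row.names", "space",
                                     "round_id", "capacity")))
    attr(d, extra) <- at[[extra]]
  attr(d, "snap_error") <- err
  d
}

#' Write or read a design as CSV
#'
#' One row per run with columns `run_id`, `round`, `role`, `plate`, `well`,
#' then one column per free variable in xRef units. Factor bounds are kept
#' in `#`-prefixed header comments so the file round-trips exactly.
#'
#' @param design a `doe_design`.
#' @param path file path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns the `doe_design`.
#' @export
write_design_csv <- function(design, path) {
  sp <- attr(design, "space")
  hdr <- sprintf("# factor,%s,%s,%s", sp$factors$name,
                 fmt_num(sp$factors$lower), fmt_num(sp$factors$upper))
  hdr <- c(sprintf("# round,%s", format(attr(design, "round_id"))), hdr)
  df <- as.data.frame(design)
  df$round <- attr(design, "round_id")
  df <- df[, c("run_id", "round", "role", "plate", "well", factor_names(sp))]
  for (nm in factor_names(sp)) df[[nm]] <- fmt_num(df[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  round_id <- NA_integer_
  fac <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), ",")[[1L]]
    if (parts[1L] == "round") {
      round_id <- suppressWarnings(as.integer(parts[2L]))
    } else if (parts[1L] == "factor") {
      fac[[parts[2L]]] <- as.numeric(parts[3:4])
    }
  }
  nms <- names(fac)
  sp <- factor_space(nms,
                     vapply(fac, `[`, 0, 1L),
                     vapply(fac, `[`, 0, 2L))
  d <- new_design(df[, nms, drop = FALSE], df$role, sp, round_id)
  d$plate <- df$plate; d$well <- df$well; d$run_id <- df$run_id
  d
}
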