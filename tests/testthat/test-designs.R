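test_that("full factorial enumerates balanced orthogonal designs", {
  # k = 5: the confirmation round's 32 corner runs
  expect_equal(nrow(full_factorial(space_k(5))), 32L)
  # k = 1 degenerate
  d1 <- full_factorial(space_k(1))
  expect_equal(unname(sort(coded_levels(d1)[, 1])), c(-1, 1))
  # k = 0: a single empty run
  expect_equal(nrow(full_factorial(space_k(0))), 1L)
  # balance and pairwise orthogonality by enumeration up to k = 9
  for (k in c(2, 4, 9)) {
    C <- coded_levels(full_factorial(space_k(k)))
    expect_equal(nrow(C), 2L^k)
    expect_equal(colSums(C), rep(0, k), ignore_attr = TRUE)
    expect_equal(crossprod(C), diag(2^k, k), ignore_attr = TRUE)
    expect_equal(nrow(unique(C)), 2L^k)
  }
})

alias_model_matrix <- function(design, focus) {
  C <- coded_levels(design)
  M <- cbind(1, C)
  i <- match(focus, colnames(C))
  for (j in setdiff(seq_len(ncol(C)), i)) M <- cbind(M, C[, i] * C[, j])
  M
}

test_that("fractional factorial: 9 factors collapse to an estimable 32-run fraction", {
  fs <- space_k(9)
  d <- fractional_factorial(fs, "F1")
  expect_equal(nrow(d), 32L)
  # mains + focus interactions + intercept estimable: full column rank
  M <- alias_model_matrix(d, "F1")
  expect_equal(qr(M)$rank, ncol(M))
  # regular fraction: model matrix orthogonal up to scaling
  expect_equal(crossprod(M), diag(32, ncol(M)), ignore_attr = TRUE)
  expect_length(attr(d, "generators"), 4L)
  # resolution >= IV: all generator words have >= 3 letters
  expect_true(all(nchar(sub(".*=", "", attr(d, "generators"))) >= 3L))
})

test_that("no 4-run fraction can carry 3 mains plus 2 focus interactions", {
  # brute force: every 4-run regular fraction of 3 factors aliases the
  # model terms, so the generator falls back to the 8-run full factorial
  base <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  for (wordsign in c(1, -1)) {
    third <- wordsign * base[, 1] * base[, 2]
    M <- cbind(1, base, third, base[, 1] * base[, 2], base[, 1] * third)
    expect_lt(qr(M)$rank, ncol(M))
  }
  d3 <- fractional_factorial(space_k(3), "F1")
  expect_equal(nrow(d3), 8L)
  # k = 2: the full factorial is already minimal
  expect_equal(nrow(fractional_factorial(space_k(2), "F2")), 4L)
})

test_that("reference augmentation and plate capacity", {
  fs <- space_k(9)
  d <- fractional_factorial(fs, "F1")
  d37 <- add_reference_replicates(d, 5)
  expect_equal(nrow(d37), 37L)
  expect_equal(sum(d37$role == "reference"), 5L)
  # reference rows sit at 1 xRef for every free variable
  refs <- natural_levels(d37)[d37$role == "reference", ]
  expect_equal(unname(refs), matrix(1, 5, 9), ignore_attr = TRUE)
  # n_ref = 0 is a no-op
  expect_identical(nrow(add_reference_replicates(d, 0)), 32L)
  # overflow arithmetic
  big <- full_factorial(space_k(5), capacity = 48L)  # 32 rows
  d46 <- add_reference_replicates(big, 14)           # 46 rows
  expect_error(add_reference_replicates(d46, 5), "overflow 3")
})

test_that("plates_required does ceiling division", {
  expect_equal(plates_required(2^9, 48), 11L)
  expect_equal(plates_required(48, 48), 1L)
  expect_equal(plates_required(49, 48), 2L)
  expect_equal(plates_required(0, 48), 0L)
  expect_error(plates_required(-1), ">= 0")
})

test_that("coded/natural conversion round-trips exactly", {
  fs <- factor_space(c("A", "B", "C"), c(0, 0.125, 0.3), c(1.7, 2.5, 3.75))
  set.seed(11)
  for (rep in 1:20) {
    coded <- matrix(runif(15, -1, 1), 5, 3,
                    dimnames = list(NULL, factor_names(fs)))
    back <- coded_from_natural(natural_from_coded(coded, fs), fs)
    expect_lt(max(abs(back - coded)), 1e-12)
  }
  # the endpoints map exactly to the bounds
  nat <- natural_from_coded(rbind(c(-1, -1, -1), c(1, 1, 1)), fs)
  expect_equal(unname(nat[1, ]), fs$factors$lower)
  expect_equal(unname(nat[2, ]), fs$factors$upper)
})

test_that("nested refinement design has the printed geometry", {
  sp <- refine_space()
  d <- nested_round3_design(sp, c(0.5, 1.7, 2.9))
  # 3 cubes x 8 corners + 2 centers + 9 edge points
  expect_equal(nrow(d), 35L)
  expect_equal(sum(d$role == "factorial"), 24L)
  expect_equal(sum(d$role == "center"), 2L)
  expect_equal(sum(d$role == "space_filling"), 9L)
  expect_equal(nrow(add_reference_replicates(d, 4)), 39L)

  # middle cube uses half ranges: coded cube coordinates +/- 0.5
  C <- coded_levels(d)
  cube <- setdiff(colnames(C), "MgSO4")
  mid <- d$role == "factorial" &
    abs(natural_levels(d)[, "MgSO4"] - 1.7) < 1e-9
  expect_equal(unique(round(abs(as.vector(C[mid, cube])), 12)), 0.5)

  # edge points: exactly two cube coordinates at their cube's bounds
  edges <- C[d$role == "space_filling", cube, drop = FALSE]
  at_bound <- abs(abs(edges) - 1) < 1e-9 | abs(abs(edges) - 0.5) < 1e-9
  n_fixed <- rowSums(at_bound)
  expect_true(all(n_fixed == 2L))

  # degenerate reduction: one level, no extras = a plain 2^3 factorial
  d0 <- nested_round3_design(sp, 1.7, n_centers = 0, n_edge = 0)
  expect_equal(nrow(d0), 8L)
  expect_equal(sort(unique(round(as.vector(coded_levels(d0)[, cube]), 12))),
               c(-1, 1))

  expect_error(nested_round3_design(sp, c(2, 1, 3)), "strictly increasing")
})

test_that("all generated designs respect bounds and capacity", {
  fs <- reduce_components(enbbm_components())
  designs <- list(
    add_reference_replicates(fractional_factorial(fs, "MgSO4"), 5),
    full_factorial(subset_space(fs, c("NaNO3", "MgSO4", "CaCl2", "NaCl", "Trace"))),
    add_reference_replicates(nested_round3_design(refine_space(), c(0.5, 1.7, 2.9)), 4)
  )
  for (d in designs) {
    sp <- attr(d, "space")
    nat <- natural_levels(d)
    for (j in seq_len(ncol(nat))) {
      expect_gte(min(nat[, j]), sp$factors$lower[j] - 1e-9)
      expect_lte(max(nat[, j]), sp$factors$upper[j] + 1e-9)
    }
    expect_lte(nrow(d), 48L)
    expect_true(all(d$well %in% paste0(rep(LETTERS[1:6], each = 8), 1:8)))
  }
})

test_that("pipetting-grid snapping", {
  fs <- factor_space(c("A", "B"), 0, 4)
  # stock strength: 1 uL adds 0.002 xRef, so one 10 uL aliquot = 0.02 xRef
  stocks <- c(A = 0.002, B = 0.002)
  d <- new_design_for_test(rbind(c(0.02, 0.001), c(1.0, 0.0305)), fs)
  snapped <- snap_to_pipetting_grid(d, stocks)
  nat <- natural_levels(snapped)
  expect_equal(nat[1, "A"], 0.02)        # exactly realizable: unchanged
  expect_equal(nat[1, "B"], 0)           # below half an aliquot: snap to 0
  expect_equal(nat[2, "B"], 0.04)        # nearest aliquot multiple
  err <- attr(snapped, "snap_error")
  expect_equal(err[1, "A"], 0)
  # property: snap error never exceeds half an aliquot's increment
  set.seed(9)
  d2 <- new_design_for_test(matrix(runif(40, 0, 4), 20, 2), fs)
  s2 <- snap_to_pipetting_grid(d2, stocks)
  expect_lte(max(attr(s2, "snap_error")), 0.5 + 1e-12)
  expect_lte(max(abs(natural_levels(s2) - natural_levels(d2))), 0.02 / 2 + 1e-12)
})

test_that("design CSV serialization round-trips", {
  fs <- refine_space()
  d <- add_reference_replicates(nested_round3_design(fs, c(0.5, 1.7, 2.9)), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  d2 <- read_design_csv(path)
  expect_equal(unname(natural_levels(d2)), unname(natural_levels(d)),
               ignore_attr = TRUE)
  expect_equal(d2$role, d$role)
  expect_equal(d2$well, d$well)
  expect_equal(fs_box_for_test(attr(d2, "space")), fs_box_for_test(fs))
})
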