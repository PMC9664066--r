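test_that("identical samples show no separation", {
  g <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(g$p_value, 0.99)
})

test_that("fully separated tiny samples give the enumerated exact p", {
  g <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(g$u_statistic, 0)
  expect_true(g$exact)
  # both tails of the C(6,3) = 20 equally likely rank assignments
  expect_equal(g$p_value, 0.1)
})

test_that("well-separated large samples are overwhelmingly significant", {
  set.seed(71)
  g <- mann_whitney_u(rnorm(500, 0, 1), rnorm(500, 5, 1))
  expect_lt(g$p_value, 1e-10)
  expect_gt(g$p_value, 0)
})

test_that("U complement identity holds on random inputs", {
  set.seed(72)
  for (i in 1:25) {
    na <- sample(3:40, 1)
    nb <- sample(3:40, 1)
    a <- round(rnorm(na, 0, 5), sample(0:2, 1))  # induce occasional ties
    b <- round(rnorm(nb, 1, 5), sample(0:2, 1))
    expect_equal(mann_whitney_u(a, b)$u_statistic +
                   mann_whitney_u(b, a)$u_statistic, na * nb)
  }
})

test_that("exact and approximate branches agree on tie-free 10+10 data", {
  set.seed(73)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10, 0.8)
    p_exact <- mann_whitney_u(a, b, exact_limit = 20L)$p_value
    p_approx <- mann_whitney_u(a, b, exact_limit = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("group summaries carry valid medians, quartiles and bounds", {
  set.seed(74)
  a <- rexp(40); b <- rexp(55, 0.5)
  g <- mann_whitney_u(a, b)
  expect_true(g$iqr_a[1] <= g$median_a && g$median_a <= g$iqr_a[2])
  expect_true(g$iqr_b[1] <= g$median_b && g$median_b <= g$iqr_b[2])
  expect_gte(g$u_statistic, 0)
  expect_lte(g$u_statistic, g$n_a * g$n_b)
  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("median_iqr follows the interpolated order-statistic convention", {
  q <- median_iqr(c(1, 2, 3))
  expect_equal(q$median, 2)
  expect_equal(q$q1, 1.5)
  expect_equal(q$q3, 2.5)
  s <- median_iqr(5)
  expect_identical(c(s$q1, s$median, s$q3), c(5, 5, 5))
  cst <- median_iqr(rep(3.7, 9))
  expect_identical(c(cst$q1, cst$median, cst$q3), rep(3.7, 3))
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("volumes convert to mL and index by Mosteller BSA", {
  m <- array(FALSE, c(50, 50, 40))
  m[seq_len(36100) + 10] <- TRUE
  stopifnot(sum(m) == 36100)
  v <- volume_and_index(m, c(1, 1, 1), height_cm = 180, weight_kg = 80)
  expect_identical(v$volume_mL, 36.1)
  expect_identical(v$bsa_m2, 2)           # sqrt(180*80/3600) = sqrt(4)
  expect_identical(v$indexed_mL_per_m2, 18.05)
  d <- volume_and_index(m, c(1, 1, 1), height_cm = 180, weight_kg = 80,
                        bsa_method = "dubois")
  expect_lt(abs(d$bsa_m2 - 1.9963), 0.001)
})

test_that("z-slab restriction counts whole slices", {
  m <- array(TRUE, c(10, 10, 20))  # uniform slab, 2 mL total
  full <- volume_and_index(m, c(1, 1, 1))
  half <- volume_and_index(m, c(1, 1, 1), z_slab = c(0, 10))
  expect_identical(full$volume_mL, 2)
  expect_identical(half$volume_mL, 1)
  expect_error(volume_and_index(m, c(1, 1, 1), z_slab = c(100, 120)),
               "outside")
  expect_identical(volume_and_index(array(FALSE, c(4, 4, 4)),
                                    c(1, 1, 1))$volume_mL, 0)
})

make_strata <- function(dF, dN, vF = dF, vN = dN, r = 5) {
  structure(list(fibrotic = list(d_eat = dF, v_eat = vF,
                                 coverage = as.integer(dF <= r)),
                 non_fibrotic = list(d_eat = dN, v_eat = vN,
                                     coverage = as.integer(dN <= r)),
                 radius_mm = r, empty_group = NULL),
            class = "coloc_strata")
}

test_that("single-case aggregation equals the per-case comparison", {
  set.seed(75)
  s <- make_strata(rexp(40, 0.2), rexp(60, 0.5))
  agg <- aggregate_cohort(list(s))
  direct <- mann_whitney_u(s$fibrotic$d_eat, s$non_fibrotic$d_eat)
  expect_identical(agg$comparisons$d_eat$p_value, direct$p_value)
  expect_identical(agg$comparisons$d_eat$u_statistic, direct$u_statistic)
})

test_that("cohort aggregation is invariant to case order", {
  set.seed(76)
  cases <- lapply(1:5, function(i) make_strata(rexp(30, 0.2), rexp(40, 0.4)))
  a <- aggregate_cohort(cases)
  b <- aggregate_cohort(rev(cases))
  expect_identical(a$comparisons$d_eat$p_value, b$comparisons$d_eat$p_value)
  expect_identical(a$comparisons$v_eat$u_statistic,
                   b$comparisons$v_eat$u_statistic)
  expect_identical(a$coverage$pooled_percent, b$coverage$pooled_percent)
  expect_identical(sum(a$pooled_n), 5L * 70L)
})

test_that("per-case aggregation reduces cases to medians first", {
  set.seed(77)
  cases <- lapply(1:6, function(i) make_strata(rexp(30, 0.2), rexp(40, 0.4)))
  agg <- aggregate_cohort(cases, mode = "per_case")
  expect_identical(agg$comparisons$d_eat$n_a, 6L)
  expect_identical(agg$comparisons$d_eat$n_b, 6L)
})

test_that("aggregation refuses a cohort with no complete case", {
  s <- make_strata(rexp(10), rexp(10))
  s$non_fibrotic <- list(d_eat = numeric(0), v_eat = numeric(0),
                         coverage = integer(0))
  s$empty_group <- "non_fibrotic"
  expect_error(aggregate_cohort(list(s)), "no case")
})
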