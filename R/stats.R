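#' Mann-Whitney U comparison of two samples
#'
#' Rank-sum test with mid-ranks for ties. The U statistic reported is that
#' of `sample_a` (number of pairs where a beats b, ties counting 1/2). The
#' two-sided p-value uses exact null enumeration when
#' `n_a + n_b <= exact_limit` and the pooled sample is tie-free, otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_limit maximal pooled size for the exact branch (default
#'   20).
#' @return object of class `group_comparison`: sample sizes, medians and
#'   quartiles per group, `u_statistic`, `p_value`, and whether the exact
#'   branch was used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_limit = 20L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("samples contain NA", call. = FALSE)
  na <- as.numeric(length(sample_a))  # numeric: n_a * n_b can exceed 2^31
  nb <- as.numeric(length(sample_b))
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  n <- na + nb

  if (!ties && n <= exact_limit) {
    exact <- TRUE
    # P(U <= u) and P(U >= u) under full enumeration (pwilcox is the exact
    # Mann-Whitney null distribution)
    p_lo <- pwilcox(u, na, nb)
    p_hi <- 1 - pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    exact <- FALSE
    mu <- na * nb / 2
    tt <- as.numeric(table(pooled))
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (abs(u - mu) < 0.5) z <- 0
      # keep p strictly positive even when pnorm underflows
      p <- max(min(1, 2 * pnorm(-abs(z))), .Machine$double.xmin)
    }
  }
  qa <- median_iqr(sample_a)
  qb <- median_iqr(sample_b)
  structure(list(n_a = length(sample_a), n_b = length(sample_b),
                 median_a = qa$median, median_b = qb$median,
                 iqr_a = c(qa$q1, qa$q3), iqr_b = c(qb$q1, qb$q3),
                 u_statistic = u, p_value = p, exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> n = %d vs %d | medians %.4g ",
                     "(%.4g, %.4g) vs %.4g (%.4g, %.4g) | U = %.1f | ",
                     "p = %.3g%s\n"),
              x$n_a, x$n_b, x$median_a, x$iqr_a[1], x$iqr_a[2],
              x$median_b, x$iqr_b[1], x$iqr_b[2], x$u_statistic,
              x$p_value, if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation of order statistics (R's default
#' type-7 convention).
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3))  # median 2, Q1 1.5, Q3 2.5
#' @export
median_iqr <- function(values) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Mask volume in mL, optionally indexed to body surface area
#'
#' Volume is voxel count (optionally restricted to a world-mm z-slab) times
#' voxel volume, reported in mL (1 mL = 1000 mm^3). When height and weight
#' are given the volume is also indexed to BSA; Mosteller
#' (`sqrt(height_cm * weight_kg / 3600)`) is the default, DuBois is
#' available.
#'
#' @param mask binary 3D array (or [label_volume], non-zero = in mask).
#' @param spacing per-axis voxel size (mm).
#' @param z_slab optional world-mm interval `c(lo, hi)`; voxels whose
#'   centroid z lies in `[lo, hi]` are counted. Must overlap the grid.
#' @param height_cm,weight_kg optional body habitus for BSA indexing.
#' @param origin world position of the grid corner (mm).
#' @param bsa_method `"mosteller"` or `"dubois"`.
#' @return list with `volume_mL`, `bsa_m2` (NA if not indexed) and
#'   `indexed_mL_per_m2`.
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' volume_and_index(m, c(1, 1, 1))$volume_mL  # 1 mL
#' @export
volume_and_index <- function(mask, spacing, z_slab = NULL,
                             height_cm = NULL, weight_kg = NULL,
                             origin = c(0, 0, 0),
                             bsa_method = c("mosteller", "dubois")) {
  bsa_method <- match.arg(bsa_method)
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- as_mask(mask)
  }
  mask <- as_mask(mask)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (!is.null(z_slab)) {
    stopifnot(length(z_slab) == 2L)
    zc <- origin[3] + (seq_len(dim(mask)[3]) - 0.5) * spacing[3]
    keep <- zc >= min(z_slab) & zc <= max(z_slab)
    if (!any(keep))
      stop("z_slab [", min(z_slab), ", ", max(z_slab),
           "] lies outside the grid (z range ",
           sprintf("%.2f..%.2f", min(zc), max(zc)), " mm)", call. = FALSE)
    mask <- mask[, , keep, drop = FALSE]
  }
  vol_mm3 <- sum(mask) * voxel_volume_mm3(spacing)
  vol_mL <- vol_mm3 / 1000
  bsa <- NA_real_
  idx <- NA_real_
  if (!is.null(height_cm) && !is.null(weight_kg)) {
    if (height_cm <= 0 || weight_kg <= 0)
      stop("height_cm and weight_kg must be > 0", call. = FALSE)
    bsa <- switch(bsa_method,
                  mosteller = sqrt(height_cm * weight_kg / 3600),
                  dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
    idx <- vol_mL / bsa
  }
  list(volume_mL = vol_mL, bsa_m2 = bsa, indexed_mL_per_m2 = idx)
}

#' Aggregate stratified colocalization samples across a cohort
#'
#' Pools vertex-level fibrotic and non-fibrotic samples across cases
#' (`mode = "pooled"`, mirroring aggregation of local proximity values over
#' all models) or reduces each case to its per-group medians first
#' (`mode = "per_case"`, a sensitivity analysis that treats cases, not
#' vertices, as observations). Each metric gets a [mann_whitney_u()]
#' comparison; coverage is reported per group as the pooled percentage plus
#' quartiles of the per-case percentages.
#'
#' @param strata_list list of [stratify_by_fibrosis()] results (one per
#'   case). Cases with an empty group contribute their non-empty group to
#'   the pool but are excluded from per-case summaries; at least one case
#'   must have both groups non-empty.
#' @param mode `"pooled"` or `"per_case"`.
#' @param metrics which per-vertex metrics to compare.
#' @return object of class `cohort_summary`: `n_cases`, `mode`,
#'   `comparisons` (one `group_comparison` per metric), `coverage`
#'   (pooled percent and per-case quartiles per group), and pooled sample
#'   sizes.
#' @export
aggregate_cohort <- function(strata_list, mode = c("pooled", "per_case"),
                             metrics = c("d_eat", "v_eat")) {
  mode <- match.arg(mode)
  stopifnot(length(strata_list) >= 1L,
            all(vapply(strata_list, inherits, logical(1), "coloc_strata")))
  complete <- vapply(strata_list, function(s) is.null(s$empty_group),
                     logical(1))
  if (!any(complete))
    stop("no case has both fibrotic and non-fibrotic vertices",
         call. = FALSE)

  pool <- function(group, metric)
    unlist(lapply(strata_list, function(s) s[[group]][[metric]]),
           use.names = FALSE)
  per_case_median <- function(group, metric)
    vapply(strata_list[complete],
           function(s) median(s[[group]][[metric]]), numeric(1))

  comparisons <- lapply(metrics, function(m) {
    if (mode == "pooled")
      mann_whitney_u(pool("fibrotic", m), pool("non_fibrotic", m))
    else
      mann_whitney_u(per_case_median("fibrotic", m),
                     per_case_median("non_fibrotic", m))
  })
  names(comparisons) <- metrics

  cov_pool <- c(fibrotic = 100 * mean(pool("fibrotic", "coverage")),
                non_fibrotic = 100 * mean(pool("non_fibrotic", "coverage")))
  cov_case <- lapply(c(fibrotic = "fibrotic", non_fibrotic = "non_fibrotic"),
                     function(g) {
                       pc <- vapply(strata_list[complete], function(s)
                         100 * mean(s[[g]]$coverage), numeric(1))
                       median_iqr(pc)
                     })

  structure(list(n_cases = length(strata_list),
                 n_cases_complete = sum(complete),
                 mode = mode,
                 comparisons = comparisons,
                 coverage = list(pooled_percent = cov_pool,
                                 per_case = cov_case),
                 pooled_n = c(
                   fibrotic = length(pool("fibrotic", metrics[1])),
                   non_fibrotic = length(pool("non_fibrotic", metrics[1])))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases (%s aggregation)\n", x$n_cases,
              x$mode))
  for (m in names(x$comparisons)) {
    cat(sprintf("  %s: ", m))
    print(x$comparisons[[m]])
  }
  cat(sprintf("  coverage: fibrotic %.1f%%, non-fibrotic %.1f%%\n",
              x$coverage$pooled_percent[["fibrotic"]],
              x$coverage$pooled_percent[["non_fibrotic"]]))
  invisible(x)
}
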