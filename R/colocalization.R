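#' Per-vertex EAT proximity map (d_EAT)
#'
#' For every mesh vertex, the minimal Euclidean distance (mm) to the
#' nearest fat sample point. The default `"grid"` method uses a uniform
#' spatial index and returns values elementwise identical to the
#' exhaustive `"brute"` scan (same arithmetic, accelerated search).
#'
#' @param surface [surface_mesh()] in the registered frame.
#' @param fat [fat_model()] with at least one sample.
#' @param method `"grid"` (spatial index) or `"brute"` (exhaustive
#'   O(N x K) scan; reference implementation).
#' @return numeric vector of length `nrow(surface$vertices)`, mm.
#' @export
compute_deat_map <- function(surface, fat, method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(surface, "surface_mesh"), inherits(fat, "fat_model"))
  if (nrow(fat$points) == 0L)
    stop("no EAT present: the distance map is undefined for an empty fat ",
         "model", call. = FALSE)
  if (nrow(surface$vertices) == 0L)
    stop("surface has no vertices", call. = FALSE)
  V <- surface$vertices
  P <- fat$points
  if (method == "grid") {
    sqrt(cpp_grid_nn(P, V)$d2)
  } else {
    d <- numeric(nrow(V))
    for (i in seq_len(nrow(V))) {
      d2 <- (V[i, 1] - P[, 1])^2 + (V[i, 2] - P[, 2])^2 +
        (V[i, 3] - P[, 3])^2
      d[i] <- sqrt(min(d2))
    }
    d
  }
}

#' Per-vertex local EAT volume map (V_EAT)
#'
#' For every mesh vertex, the summed volume (mm^3) of fat samples within
#' the closed ball of radius `radius_mm` (boundary inclusive). An empty
#' fat model gives an all-zero map.
#'
#' @inheritParams compute_deat_map
#' @param radius_mm ball radius in mm (default 5).
#' @return numeric vector of per-vertex fat volumes (mm^3).
#' @export
compute_veat_map <- function(surface, fat, radius_mm = 5,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(surface, "surface_mesh"), inherits(fat, "fat_model"))
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  V <- surface$vertices
  P <- fat$points
  if (nrow(P) == 0L) return(numeric(nrow(V)))
  if (method == "grid") {
    cpp_grid_ball(P, fat$volumes, V, radius_mm)$sum
  } else {
    r2 <- radius_mm^2
    out <- numeric(nrow(V))
    for (i in seq_len(nrow(V))) {
      d2 <- (V[i, 1] - P[, 1])^2 + (V[i, 2] - P[, 2])^2 +
        (V[i, 3] - P[, 3])^2
      out[i] <- sum(fat$volumes[which(d2 <= r2)])
    }
    out
  }
}

#' Compute both colocalization maps
#'
#' Convenience wrapper returning d_EAT, V_EAT and the per-vertex coverage
#' indicator (fat present within `radius_mm`). By construction
#' `coverage == 1` exactly when `d_eat <= radius_mm` and exactly when
#' `v_eat > 0`.
#'
#' @inheritParams compute_veat_map
#' @return object of class `coloc_maps` with fields `d_eat`, `v_eat`,
#'   `coverage` (0/1 integer), `radius_mm`.
#' @export
compute_coloc_maps <- function(surface, fat, radius_mm = 5) {
  d_eat <- compute_deat_map(surface, fat)
  if (nrow(fat$points) > 0L) {
    ball <- cpp_grid_ball(fat$points, fat$volumes, surface$vertices,
                          radius_mm)
    v_eat <- ball$sum
    coverage <- as.integer(ball$count > 0L)
  } else {
    v_eat <- numeric(nrow(surface$vertices))
    coverage <- integer(nrow(surface$vertices))
  }
  structure(list(d_eat = d_eat, v_eat = v_eat, coverage = coverage,
                 radius_mm = radius_mm),
            class = "coloc_maps")
}

#' @export
print.coloc_maps <- function(x, ...) {
  cat(sprintf(paste0("<coloc_maps> %d vertices | d_EAT median %.2f mm | ",
                     "V_EAT median %.1f mm3 | coverage %.1f%% (r = %g mm)\n"),
              length(x$d_eat), median(x$d_eat), median(x$v_eat),
              100 * mean(x$coverage), x$radius_mm))
  invisible(x)
}

#' Stratify colocalization maps by fibrosis status
#'
#' Partitions the per-vertex values into fibrotic and non-fibrotic samples
#' using the mesh's `fibrotic` attribute. If one group is empty the result
#' carries the non-empty group and an explicit `empty_group` flag;
#' downstream tests must refuse such strata.
#'
#' @param maps a [compute_coloc_maps()] result.
#' @param surface the [surface_mesh()] carrying the `fibrotic` attribute.
#' @return object of class `coloc_strata`: lists `fibrotic` and
#'   `non_fibrotic` (each with `d_eat`, `v_eat`, `coverage`), `radius_mm`
#'   and `empty_group` (`NULL` or the name of the empty group).
#' @export
stratify_by_fibrosis <- function(maps, surface) {
  stopifnot(inherits(maps, "coloc_maps"), inherits(surface, "surface_mesh"))
  fib <- surface$attrs$fibrotic
  if (is.null(fib))
    stop("surface has no 'fibrotic' attribute; run ",
         "map_fibrosis_to_surface() first", call. = FALSE)
  if (length(fib) != length(maps$d_eat))
    stop("maps and surface have different vertex counts", call. = FALSE)
  is_f <- fib > 0
  take <- function(sel) list(d_eat = maps$d_eat[sel],
                             v_eat = maps$v_eat[sel],
                             coverage = maps$coverage[sel])
  empty <- if (all(is_f)) "non_fibrotic" else if (!any(is_f)) "fibrotic"
    else NULL
  structure(list(fibrotic = take(is_f), non_fibrotic = take(!is_f),
                 radius_mm = maps$radius_mm, empty_group = empty),
            class = "coloc_strata")
}

#' Fat coverage fraction per fibrosis group
#'
#' Percentage of vertices in each group with fat present within the map
#' radius. Empty groups give `NA` and are flagged.
#'
#' @param strata a [stratify_by_fibrosis()] result.
#' @return named numeric vector (percent) with entries `fibrotic` and
#'   `non_fibrotic`; attribute `empty_group` mirrors the strata flag.
#' @export
coverage_fraction <- function(strata) {
  stopifnot(inherits(strata, "coloc_strata"))
  pct <- function(g) if (length(g$coverage)) 100 * mean(g$coverage)
    else NA_real_
  structure(c(fibrotic = pct(strata$fibrotic),
              non_fibrotic = pct(strata$non_fibrotic)),
            empty_group = strata$empty_group)
}
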