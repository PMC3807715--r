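#' Cortical thickness dataset on a triangulated surface
#'
#' @param surface list with `vertex_area` (mm^2 per vertex) and `adjacency`
#'   (list of integer neighbor vectors, symmetric), as from
#'   [make_grid_surface()].
#' @param thickness subjects x vertices matrix in mm.
#' @param covariates data.frame with one row per subject: `age`, `sex`
#'   (0/1), `education`, `mmse`, `wmh`.
#' @param group factor of group labels per subject.
#' @param memory optional data.frame of memory scores per subject.
#' @return An object of class `thickness_dataset`.
#' @export
thickness_dataset <- function(surface, thickness, covariates, group,
                              memory = NULL) {
  nv <- length(surface$vertex_area)
  if (ncol(thickness) != nv) {
    stop("thickness must have one column per surface vertex")
  }
  if (length(surface$adjacency) != nv) {
    stop("adjacency must have one entry per vertex")
  }
  if (any(surface$vertex_area <= 0)) stop("vertex areas must be positive")
  n <- nrow(thickness)
  if (nrow(covariates) != n) stop("covariates must have one row per subject")
  if (length(group) != n) stop("group must have one label per subject")
  for (v in seq_len(nv)) {
    for (w in surface$adjacency[[v]]) {
      if (!(v %in% surface$adjacency[[w]])) stop("adjacency must be symmetric")
    }
  }
  structure(list(surface = surface, thickness = thickness,
                 covariates = covariates, group = factor(group),
                 memory = memory),
            class = "thickness_dataset")
}

#' @export
print.thickness_dataset <- function(x, ...) {
  cat(sprintf("<thickness_dataset> %d subjects x %d vertices; groups: %s\n",
              nrow(x$thickness), ncol(x$thickness),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Vertex-wise general linear model for a two-group contrast
#'
#' Per vertex, ordinary least squares of thickness on a group indicator plus
#' the five covariates (age, sex, education, MMSE, WMH load); two-sided
#' t-test on the group coefficient.  The same design matrix serves every
#' vertex, so a single QR decomposition is reused.
#'
#' @param dataset a [thickness_dataset()].
#' @param contrast character pair: the two group levels to compare; the
#'   indicator is 1 for the first level, so a negative coefficient means the
#'   first group is thinner.
#' @param covariate_names covariate columns to adjust for (default the five
#'   available ones).
#' @return list with `t`, `p`, `coef` (per vertex), `df`, `subjects_used`.
#' @export
vertexwise_glm <- function(dataset, contrast,
                           covariate_names = intersect(
                             c("age", "sex", "education", "mmse", "wmh"),
                             names(dataset$covariates))) {
  stopifnot(inherits(dataset, "thickness_dataset"), length(contrast) == 2L)
  sel <- dataset$group %in% contrast
  if (sum(dataset$group == contrast[1L]) == 0L ||
      sum(dataset$group == contrast[2L]) == 0L) {
    stop("both contrast groups must be non-empty")
  }
  Y <- dataset$thickness[sel, , drop = FALSE]
  ind <- as.numeric(dataset$group[sel] == contrast[1L])
  X <- cbind(intercept = 1, group = ind,
             as.matrix(dataset$covariates[sel, covariate_names, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtxi[2L, 2L])
  tval <- coefs[2L, ] / se
  # zero-residual vertices (e.g. noise-free synthetic data): the t ratio is
  # numerically unstable, so decide it from the coefficient directly
  scale <- sqrt(pmax(colMeans(Y^2), .Machine$double.eps))
  deg <- sigma2 <= .Machine$double.eps * scale^2 * 1e4
  if (any(deg)) {
    big <- abs(coefs[2L, ]) > 1e-8 * scale
    tval[deg & big] <- sign(coefs[2L, deg & big]) * Inf
    tval[deg & !big] <- 0
  }
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(t = tval, p = pval, coef = coefs[2L, ], df = df,
       subjects_used = which(sel), contrast = contrast)
}

#' Extract supra-threshold clusters on the surface
#'
#' Connected components (under the surface adjacency) of vertices with
#' `p < p_thresh` and a consistent effect sign; components whose summed
#' vertex area falls below `min_area` are discarded.  Defaults follow the
#' published thresholds: p < 0.001 uncorrected with 30 mm^2 minimum extent
#' for group contrasts (15 mm^2 for correlation maps).
#'
#' @param p_map per-vertex p-values.
#' @param stat_map per-vertex signed statistics (t or r).
#' @param vertex_area mm^2 per vertex.
#' @param adjacency neighbor list.
#' @param p_thresh significance threshold (default 0.001).
#' @param min_area minimum cluster extent in mm^2 (default 30).
#' @return list of clusters; each has `id`, `vertices`, `area`,
#'   `peak_vertex`, `peak_p`, `direction` (+1/-1 sign of the statistic).
#' @export
extract_clusters <- function(p_map, stat_map, vertex_area, adjacency,
                             p_thresh = 0.001, min_area = 30) {
  nv <- length(p_map)
  stopifnot(length(stat_map) == nv, length(vertex_area) == nv,
            length(adjacency) == nv)
  supra <- which(p_map < p_thresh & stat_map != 0)
  visited <- logical(nv)
  clusters <- list()
  for (seed in supra) {
    if (visited[seed]) next
    sgn <- sign(stat_map[seed])
    comp <- integer(0L)
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, v)
      for (w in adjacency[[v]]) {
        if (!visited[w] && p_map[w] < p_thresh && sign(stat_map[w]) == sgn) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    area <- sum(vertex_area[comp])
    if (area >= min_area) {
      comp <- sort(comp)
      pk <- comp[order(p_map[comp], -abs(stat_map[comp]), comp)][1L]
      clusters[[length(clusters) + 1L]] <-
        list(id = length(clusters) + 1L, vertices = comp, area = area,
             peak_vertex = pk, peak_p = p_map[pk], direction = sgn)
    }
  }
  clusters
}

#' Total atrophy extent
#'
#' Sum of the areas of a contrast's significant clusters, the "total
#' cortical gray matter reduction" figure.
#'
#' @param clusters list from [extract_clusters()], or a numeric vector of
#'   cluster areas in mm^2.
#' @return total area in mm^2.
#' @export
total_atrophy_extent <- function(clusters) {
  if (is.numeric(clusters)) return(sum(clusters))
  if (length(clusters) == 0L) return(0)
  sum(vapply(clusters, `[[`, numeric(1L), "area"))
}

#' Group contrast with cluster report
#'
#' Runs [vertexwise_glm()] and [extract_clusters()] and summarises the
#' result per cluster, including mean thickness per contrast group.
#'
#' @inheritParams vertexwise_glm
#' @param p_thresh,min_area thresholds passed to [extract_clusters()].
#' @return list with `glm`, `clusters`, `table` (data.frame: id, area,
#'   peak_vertex, peak_p, direction, mean thickness per group),
#'   `total_extent`.
#' @export
group_contrast <- function(dataset, contrast, p_thresh = 0.001,
                           min_area = 30, ...) {
  fit <- vertexwise_glm(dataset, contrast, ...)
  cl <- extract_clusters(fit$p, fit$t, dataset$surface$vertex_area,
                         dataset$surface$adjacency, p_thresh, min_area)
  tab <- cluster_table(dataset, cl, contrast)
  list(glm = fit, clusters = cl, table = tab,
       total_extent = total_atrophy_extent(cl))
}

cluster_table <- function(dataset, clusters, groups) {
  if (length(clusters) == 0L) {
    tab <- data.frame(id = integer(0L), area_mm2 = numeric(0L),
                      peak_vertex = integer(0L), peak_p = numeric(0L),
                      direction = integer(0L))
    for (g in groups) tab[[paste0("mean_", g)]] <- numeric(0L)
    return(tab)
  }
  tab <- data.frame(
    id = vapply(clusters, `[[`, integer(1L), "id"),
    area_mm2 = vapply(clusters, `[[`, numeric(1L), "area"),
    peak_vertex = vapply(clusters, `[[`, integer(1L), "peak_vertex"),
    peak_p = vapply(clusters, `[[`, numeric(1L), "peak_p"),
    direction = vapply(clusters, function(cl) as.integer(cl$direction), integer(1L))
  )
  for (g in groups) {
    rows <- dataset$group == g
    tab[[paste0("mean_", g)]] <- vapply(clusters, function(cl) {
      mean(dataset$thickness[rows, cl$vertices, drop = FALSE])
    }, numeric(1L))
  }
  tab
}

#' Thickness-memory correlation map within a group
#'
#' Per vertex, Pearson correlation between thickness and a memory score
#' within one group, with a two-sided t-based p-value, followed by
#' cluster-extent thresholding at 15 mm^2.
#'
#' @param dataset a [thickness_dataset()].
#' @param score name of a memory score column, or a numeric vector for the
#'   group's subjects.
#' @param group group level to analyse.
#' @param p_thresh,min_area cluster thresholds (defaults 0.001 and 15).
#' @return list with `r`, `p` (per vertex), `clusters`, `n`.
#' @export
correlation_map <- function(dataset, score, group, p_thresh = 0.001,
                            min_area = 15) {
  stopifnot(inherits(dataset, "thickness_dataset"))
  rows <- which(dataset$group == group)
  n <- length(rows)
  if (n < 4L) stop("group size must be at least 4 for a correlation map")
  if (is.character(score)) {
    if (is.null(dataset$memory) || !score %in% names(dataset$memory)) {
      stop(sprintf("memory score '%s' not found", score))
    }
    s <- dataset$memory[[score]][rows]
  } else {
    s <- score
    if (length(s) != n) stop("score vector length must equal group size")
  }
  if (any(!is.finite(s))) stop("memory score contains missing values")
  if (stats::var(s) == 0) stop("zero-variance memory score")
  Y <- dataset$thickness[rows, , drop = FALSE]
  sc <- s - mean(s)
  Yc <- sweep(Y, 2L, colMeans(Y), `-`)
  denom <- sqrt(sum(sc^2) * colSums(Yc^2))
  r <- as.numeric(crossprod(sc, Yc)) / denom
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  cl <- extract_clusters(p, r, dataset$surface$vertex_area,
                         dataset$surface$adjacency, p_thresh, min_area)
  list(r = r, p = p, clusters = cl, n = n)
}

#' Iterative neighbor-averaging surface smoothing
#'
#' Approximates Gaussian surface smoothing by repeatedly replacing each
#' vertex value with the mean of itself and its neighbors.  On a regular
#' mesh with spacing h, k iterations approximate a Gaussian kernel whose
#' variance is k times the single-step displacement variance; the iteration
#' count for a requested FWHM is derived from that relation.
#'
#' @param dataset a [thickness_dataset()].
#' @param fwhm_mm requested kernel full width at half maximum in mm
#'   (ignored when `iterations` is given).
#' @param spacing_mm mesh edge length in mm (default 1).
#' @param iterations explicit iteration count (overrides `fwhm_mm`).
#' @return the dataset with smoothed thickness.
#' @export
smooth_thickness <- function(dataset, fwhm_mm = 20, spacing_mm = 1,
                             iterations = NULL) {
  stopifnot(inherits(dataset, "thickness_dataset"))
  if (is.null(iterations)) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
    # one step of self+neighbor averaging on a 6-neighbor mesh has
    # displacement variance ~ (6/7) h^2 per tangential dimension / 2
    step_var <- spacing_mm^2 * 6 / 7 / 2
    iterations <- max(1L, as.integer(round(sigma^2 / step_var)))
  }
  Y <- dataset$thickness
  adj <- dataset$surface$adjacency
  for (k in seq_len(iterations)) {
    Ynew <- Y
    for (v in seq_along(adj)) {
      nb <- adj[[v]]
      Ynew[, v] <- (Y[, v] + rowSums(Y[, nb, drop = FALSE])) / (1 + length(nb))
    }
    Y <- Ynew
  }
  dataset$thickness <- Y
  dataset
}
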