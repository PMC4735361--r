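#' Squared Mahalanobis distances
#'
#' `MD_i = (x_i - mu)' S^{-1} (x_i - mu)` -- the squared form, which is
#' the one compared directly against chi-square quantiles.
#'
#' @param X n x p data matrix (rows = observations).
#' @param mu location p-vector.
#' @param S symmetric positive-definite p x p scatter matrix.
#' @return numeric vector of n squared distances.
#' @export
mahalanobis_sq <- function(X, mu, S) {
  X <- as.matrix(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) <= 1e-12 * max(ev))
    stop("scatter matrix is singular or indefinite")
  as.numeric(stats::mahalanobis(X, mu, S))
}

# location/scatter of a subset; returns NULL when scatter is (near-)singular
subset_fit <- function(X, idx) {
  mu <- colMeans(X[idx, , drop = FALSE])
  S <- stats::cov(X[idx, , drop = FALSE])
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) <= 1e-10 * max(ev)) return(NULL)
  list(mu = mu, S = S, det = det(S))
}

#' Minimum covariance determinant fit (FAST-MCD)
#'
#' Robust location and scatter from the h-observation subset whose sample
#' covariance has minimal determinant, located by the FAST-MCD strategy:
#' many random (p+1)-point starts, each refined by concentration steps
#' (recompute distances, keep the h smallest, refit) until the support
#' repeats; the subset with the smallest determinant wins. The raw
#' scatter is rescaled toward consistency at the normal model by
#' `median(d^2 over all observations) / qchisq(0.5, p)`, the standard
#' median-based consistency factor. Deterministic for a given `seed`.
#'
#' @param X n x p data matrix, n > p.
#' @param h subset size; default `ceiling((n + p + 1)/2)` (maximal
#'   breakdown point).
#' @param n_starts number of random starts.
#' @param seed integer seed for the subset draws (recorded in the fit).
#' @param consistency apply the normal-model consistency rescaling
#'   (disable to compare against raw-determinant enumeration).
#' @return object of class `robust_fit`: `mu`, `S`, `support` (row
#'   indices), `h`, `det_raw`, `consistency_applied`, `seed`.
#' @export
mcd_fit <- function(X, h = NULL, n_starts = 500L, seed = 1L, consistency = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than variables")
  hmin <- ceiling((n + p + 1) / 2)
  if (is.null(h)) h <- hmin
  if (h < hmin || h > n) stop(sprintf("h must lie in [%d, %d]", hmin, n))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    idx <- sample.int(n, p + 1L)
    fit <- subset_fit(X, idx)
    while (is.null(fit) && length(idx) < n) {   # grow singular starts
      idx <- union(idx, sample.int(n, 1L))
      fit <- subset_fit(X, idx)
    }
    if (is.null(fit)) next
    support <- integer(0)
    for (iter in 1:100) {                        # concentration steps
      d2 <- tryCatch(mahalanobis_sq(X, fit$mu, fit$S), error = function(e) NULL)
      if (is.null(d2)) { support <- integer(0); break }
      new_support <- sort(order(d2)[seq_len(h)])
      if (identical(new_support, support)) break
      support <- new_support
      nf <- subset_fit(X, support)
      if (is.null(nf)) break
      fit <- nf
    }
    if (length(support) == h && !is.null(fit) &&
        (is.null(best) || fit$det < best$det)) {
      best <- c(fit, list(support = support))
    }
  }
  if (is.null(best))
    stop("degenerate data: every candidate subset has singular scatter")
  S <- best$S
  if (consistency) {
    d2all <- mahalanobis_sq(X, best$mu, S)
    S <- S * stats::median(d2all) / stats::qchisq(0.5, p)
  }
  structure(list(mu = best$mu, S = S, support = best$support, h = h,
                 det_raw = best$det, consistency_applied = consistency,
                 seed = seed),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("robust_fit (MCD): h = %d, raw det = %.4g, consistency %s\n",
              x$h, x$det_raw, if (x$consistency_applied) "applied" else "off"))
  invisible(x)
}

#' Robust squared distances
#'
#' Squared Mahalanobis distances computed with the MCD location and
#' scatter instead of the classical estimates.
#'
#' @param X n x p data matrix.
#' @param fit a [mcd_fit()] result.
#' @return numeric vector of squared robust distances.
#' @export
robust_distances <- function(X, fit) mahalanobis_sq(X, fit$mu, fit$S)

#' Chi-square outlier flagging
#'
#' Flags observations whose squared distance exceeds the `level` quantile
#' of the chi-square distribution with p degrees of freedom (default the
#' 97.5% quantile).
#'
#' @param distances squared (robust or classical) distances.
#' @param p data dimension.
#' @param level quantile level in (0, 1).
#' @return list with `flags` (logical) and `threshold`.
#' @export
flag_outliers <- function(distances, p, level = 0.975) {
  if (p < 1) stop("p must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  thr <- stats::qchisq(level, df = p)
  list(flags = distances > thr, threshold = thr)
}

#' Tolerance-ellipse parameters of a bivariate fit
#'
#' The contour `(x - mu)' S^{-1} (x - mu) = qchisq(level, 2)`: centre,
#' semi-axes and rotation from the eigendecomposition of the scatter.
#'
#' @param mu centre (length-2).
#' @param S 2 x 2 scatter matrix.
#' @param level chi-square quantile level.
#' @return list with `center`, `axes` (semi-axis lengths, major first),
#'   `angle` (radians of the major axis), `level`.
#' @export
tolerance_ellipse <- function(mu, S, level = 0.975) {
  if (length(mu) != 2L || !all(dim(S) == 2L))
    stop("tolerance ellipse is defined for bivariate data")
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, 2)
  list(center = mu,
       axes = sqrt(pmax(e$values, 0) * q),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       level = level)
}

#' Outlier analysis of regions in the (area, retention) plane
#'
#' Builds the two-column dataset of region surface areas and retention
#' indices, computes classical squared Mahalanobis distances (sample mean
#' and covariance) and robust distances (MCD), flags both against the
#' chi-square quantile, and returns the tolerance ellipse of the robust
#' fit plus the distance-distance data. Regions flagged by both methods
#' are reported separately.
#'
#' @param areas region surface areas (mm^2), aligned with `retention`.
#' @param retention retention indices (s) from
#'   [residence_and_retention()].
#' @param names optional region names (defaults to `names(retention)`).
#' @param level chi-square quantile level.
#' @param h,n_starts,seed passed to [mcd_fit()].
#' @return object of class `outlier_report`: data.frame `table` (region,
#'   area_mm2, retention_s, md, rd, flag_md, flag_rd), `threshold`,
#'   `ellipse`, `fit`, `flagged_both`, `level`.
#' @export
retention_outlier_analysis <- function(areas, retention, names = NULL,
                                       level = 0.975, h = NULL,
                                       n_starts = 500L, seed = 1L) {
  if (length(areas) != length(retention)) stop("areas/retention length mismatch")
  n <- length(areas)
  if (n < 6L) stop("robust outlier analysis needs at least 6 regions")
  if (is.null(names)) names <- names(retention)
  if (is.null(names)) names <- as.character(seq_len(n))
  X <- cbind(area = as.numeric(areas), retention = as.numeric(retention))
  md <- mahalanobis_sq(X, colMeans(X), stats::cov(X))
  fit <- mcd_fit(X, h = h, n_starts = n_starts, seed = seed)
  rd <- robust_distances(X, fit)
  fm <- flag_outliers(md, p = 2L, level = level)
  fr <- flag_outliers(rd, p = 2L, level = level)
  tab <- data.frame(region = names, area_mm2 = X[, 1], retention_s = X[, 2],
                    md = md, rd = rd,
                    flag_md = fm$flags, flag_rd = fr$flags,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, threshold = fm$threshold,
                 ellipse = tolerance_ellipse(fit$mu, fit$S, level),
                 fit = fit,
                 flagged_both = names[fm$flags & fr$flags],
                 level = level),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d regions, chi2 threshold %.3f (level %.3f)\n",
              nrow(x$table), x$threshold, x$level))
  cat(sprintf("  flagged by MD: %s\n",
              paste(x$table$region[x$table$flag_md], collapse = ", ")))
  cat(sprintf("  flagged by RD: %s\n",
              paste(x$table$region[x$table$flag_rd], collapse = ", ")))
  cat(sprintf("  flagged by both: %s\n", paste(x$flagged_both, collapse = ", ")))
  invisible(x)
}

#' Write an outlier report to CSV (+ JSON metadata)
#'
#' @param report an `outlier_report`.
#' @param path output CSV path (region, area_mm2, retention_s, md, rd,
#'   flag_md, flag_rd).
#' @param meta_path optional JSON side-car (h, seed, level, threshold).
#' @return invisibly `path`.
#' @export
write_outlier_report <- function(report, path, meta_path = NULL) {
  t <- report$table
  write_lines_lf(c("region,area_mm2,retention_s,md,rd,flag_md,flag_rd",
                   sprintf("%s,%.17g,%.17g,%.17g,%.17g,%d,%d",
                           t$region, t$area_mm2, t$retention_s, t$md, t$rd,
                           as.integer(t$flag_md), as.integer(t$flag_rd))),
                 path)
  if (!is.null(meta_path))
    jsonlite::write_json(list(h = report$fit$h, seed = report$fit$seed,
                              level = report$level,
                              threshold = report$threshold),
                         meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
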