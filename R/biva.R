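# Specific bioelectrical impedance vector analysis (specific BIVA).
#
# Whole-body resistance R and reactance Xc (ohm) are standardised by a
# body-geometry factor A/L, where A estimates the transverse conductor
# area from limb/trunk circumferences (circle model, weighted
# 0.45 arm + 0.10 waist + 0.45 calf) and L = height * 1.1 approximates
# the hand-to-foot electrode distance. The standardised vector
# (Rsp, Xcsp) in ohm*cm is compared across groups with tolerance and
# confidence ellipses, the two-sample Hotelling T2 test, and the
# Mahalanobis distance.

#' Derive body geometry from anthropometrics
#'
#' Each limb/trunk area is modelled as a circle, `C^2 / (4 pi)`; the
#' weighted transverse area is `A = 0.45 arm + 0.10 waist + 0.45 calf`
#' (cm^2) and the conductor length `L = height * 1.1` (cm). BMI is
#' `weight / (height_m)^2`.
#'
#' @param height_cm,weight_kg,arm_circ_cm,waist_circ_cm,calf_circ_cm
#'   Positive scalars or equal-length vectors (cm, kg).
#' @return List of class `body_geometry` with vectors `bmi`, `arm_area`,
#'   `waist_area`, `calf_area` (cm^2), `a_factor` (cm^2), `l_factor` (cm).
#' @export
derive_geometry <- function(height_cm, weight_kg, arm_circ_cm,
                            waist_circ_cm, calf_circ_cm) {
  args <- list(height_cm = height_cm, weight_kg = weight_kg,
               arm_circ_cm = arm_circ_cm, waist_circ_cm = waist_circ_cm,
               calf_circ_cm = calf_circ_cm)
  for (nm in names(args)) {
    if (any(!is.na(args[[nm]]) & args[[nm]] <= 0))
      stop("nonpositive value in ", nm)
  }
  area <- function(circ) circ^2 / (4 * pi)
  arm_area <- area(arm_circ_cm)
  waist_area <- area(waist_circ_cm)
  calf_area <- area(calf_circ_cm)
  structure(list(
    bmi = weight_kg / (height_cm / 100)^2,
    arm_area = arm_area, waist_area = waist_area, calf_area = calf_area,
    a_factor = 0.45 * arm_area + 0.10 * waist_area + 0.45 * calf_area,
    l_factor = height_cm * 1.1), class = "body_geometry")
}

#' Raw and specific bioelectrical vector quantities
#'
#' Populates the full vector: impedivity `Z = sqrt(R^2 + Xc^2)`, phase
#' angle `PhA = atan(Xc/R) * 180/pi` (degrees), and the specific
#' quantities `Rsp = R * A/L`, `Xcsp = Xc * A/L`, `Zsp = sqrt(Rsp^2 +
#' Xcsp^2)`. The phase angle is identical for raw and specific values
#' because A/L cancels in the ratio.
#'
#' @param r,xc Resistance and reactance (ohm), positive.
#' @param geometry A [derive_geometry()] result (or any list with
#'   `a_factor` and `l_factor`).
#' @return Data frame of class `bio_vector`: `r`, `xc`, `z`, `pha`,
#'   `rsp`, `xcsp`, `zsp`.
#' @export
specific_vector <- function(r, xc, geometry) {
  if (any(!is.na(r) & r <= 0)) stop("resistance must be positive")
  if (any(!is.na(xc) & xc <= 0)) stop("reactance must be positive")
  k <- geometry$a_factor / geometry$l_factor
  out <- data.frame(
    r = r, xc = xc,
    z = sqrt(r^2 + xc^2),
    pha = atan(xc / r) * 180 / pi,
    rsp = r * k, xcsp = xc * k)
  out$zsp <- sqrt(out$rsp^2 + out$xcsp^2)
  class(out) <- c("bio_vector", "data.frame")
  out
}

#' Describe a bioelectrical reference population
#'
#' @param name Population label.
#' @param n Sample size (>= 3).
#' @param mean_rsp,mean_xcsp Means of the specific vector (ohm*cm).
#' @param sd_rsp,sd_xcsp Standard deviations (positive, ohm*cm).
#' @param corr Pearson correlation between Rsp and Xcsp, in (-1, 1).
#' @return Object of class `reference_population`.
#' @export
reference_population <- function(name, n, mean_rsp, mean_xcsp, sd_rsp,
                                 sd_xcsp, corr) {
  if (n < 3) stop("reference population needs n >= 3")
  if (sd_rsp <= 0 || sd_xcsp <= 0) stop("sds must be positive")
  if (abs(corr) >= 1) stop("|corr| must be < 1")
  structure(list(name = name, n = n, mean_rsp = mean_rsp,
                 mean_xcsp = mean_xcsp, sd_rsp = sd_rsp,
                 sd_xcsp = sd_xcsp, corr = corr),
            class = "reference_population")
}

#' Read reference-population parameters from CSV
#'
#' Expected columns: `name, n, mean_rsp, mean_xcsp, sd_rsp, sd_xcsp,
#' corr`.
#'
#' @param path CSV path.
#' @return Named list of [reference_population()] objects.
#' @export
read_reference_populations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "n", "mean_rsp", "mean_xcsp", "sd_rsp", "sd_xcsp",
            "corr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reference CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  refs <- lapply(seq_len(nrow(df)), function(i)
    reference_population(df$name[i], df$n[i], df$mean_rsp[i],
                         df$mean_xcsp[i], df$sd_rsp[i], df$sd_xcsp[i],
                         df$corr[i]))
  names(refs) <- df$name
  refs
}

ellipse_spec <- function(center, covariance, radius2, kind) {
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      any(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("covariance must be symmetric positive-definite")
  if (radius2 <= 0) stop("radius2 must be positive")
  structure(list(center = as.numeric(center), covariance = covariance,
                 radius2 = radius2, kind = kind),
            class = "ellipse_spec")
}

#' Tolerance ellipse of a reference population
#'
#' Region of the (Rsp, Xcsp) plane containing the stated fraction of the
#' reference population under a bivariate-normal model: centred at the
#' reference means with the covariance built from sds and correlation, and
#' squared Mahalanobis radius equal to the chi-square(2 df) quantile at
#' the coverage level. The menu of coverages is fixed at 50/75/95%,
#' matching BIVA practice.
#'
#' @param ref A [reference_population()].
#' @param coverage One of 0.50, 0.75, 0.95.
#' @return An `ellipse_spec`.
#' @export
tolerance_ellipse <- function(ref, coverage = 0.95) {
  stopifnot(inherits(ref, "reference_population"))
  if (!coverage %in% c(0.50, 0.75, 0.95))
    stop("coverage must be one of 0.50, 0.75, 0.95")
  cv <- ref$corr * ref$sd_rsp * ref$sd_xcsp
  ellipse_spec(c(ref$mean_rsp, ref$mean_xcsp),
               matrix(c(ref$sd_rsp^2, cv, cv, ref$sd_xcsp^2), 2, 2),
               stats::qchisq(coverage, df = 2),
               sprintf("tolerance_%d", round(100 * coverage)))
}

#' 95% confidence ellipse for a sample's bivariate mean
#'
#' Centred at the sample mean with covariance `S / n` and the exact
#' small-sample boundary `radius2 = 2 (n - 1) / (n - 2) * F(2, n - 2;
#' level)`.
#'
#' @param xy Two-column matrix or data frame of (Rsp, Xcsp) pairs, n >= 4.
#' @param level Confidence level (default 0.95).
#' @return An `ellipse_spec`.
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 4) stop("sample too small for a confidence ellipse (n < 4)")
  s <- stats::cov(xy)
  if (any(diag(s) == 0) || det(s) <= 0)
    stop("singular sample covariance")
  ellipse_spec(colMeans(xy), s / n,
               (2 * (n - 1) / (n - 2)) * stats::qf(level, 2, n - 2),
               "confidence_95")
}

#' Is a point inside (or on) an ellipse?
#'
#' The boundary is closed: a point exactly on the perimeter is contained.
#'
#' @param spec An `ellipse_spec`.
#' @param point Length-2 numeric vector, or two-column matrix of points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(spec, point) {
  stopifnot(inherits(spec, "ellipse_spec"))
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2) else
    as.matrix(point)
  d2 <- stats::mahalanobis(pts, spec$center, spec$covariance)
  d2 <= spec$radius2 + 1e-12
}

#' Boundary points of an ellipse (for plotting)
#'
#' @param spec An `ellipse_spec`.
#' @param n Number of boundary points.
#' @return Two-column matrix tracing the perimeter.
#' @export
ellipse_points <- function(spec, n = 361) {
  stopifnot(inherits(spec, "ellipse_spec"))
  eg <- eigen(spec$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(spec$radius2)
  pts <- t(eg$vectors %*% (sqrt(eg$values) * circ)) +
    rep(spec$center, each = n)
  colnames(pts) <- c("rsp", "xcsp")
  pts
}

#' Two-sample Hotelling T2 comparison of bivariate mean vectors
#'
#' `T2 = (n1 n2 / (n1 + n2)) d' S_pooled^-1 d` with `d` the difference of
#' the sample mean vectors and `S_pooled` the pooled covariance. The F
#' conversion, degrees of freedom, p-value and Mahalanobis distance follow
#' [hotelling_from_t2()]. `significant` reports whether the two 95%
#' confidence regions separate at alpha.
#'
#' @param sample_a,sample_b Two-column matrices of (Rsp, Xcsp) pairs,
#'   each with n >= 3.
#' @param alpha Significance threshold (default 0.05).
#' @return List of class `hotelling_result`: `t2`, `f_stat`, `df`,
#'   `p_value`, `mahalanobis_d`, `n1`, `n2`, `significant`.
#' @export
hotelling_two_sample <- function(sample_a, sample_b, alpha = 0.05) {
  a <- as.matrix(sample_a); b <- as.matrix(sample_b)
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 3 || n2 < 3) stop("each sample needs n >= 3")
  d <- colMeans(a) - colMeans(b)
  sp <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) /
    (n1 + n2 - 2)
  if (det(sp) <= 0) stop("singular pooled covariance")
  t2 <- as.numeric((n1 * n2 / (n1 + n2)) *
                     t(d) %*% solve(sp) %*% d)
  out <- hotelling_from_t2(t2, n1, n2)
  out$significant <- out$p_value < alpha
  out
}

#' Convert a Hotelling T2 statistic to F, p, and Mahalanobis D
#'
#' For bivariate samples of sizes n1 and n2:
#' `F = T2 (n1 + n2 - 3) / (2 (n1 + n2 - 2))` on (2, n1 + n2 - 3) degrees
#' of freedom, and `D = sqrt(T2 (n1 + n2) / (n1 n2))` (the
#' pooled-covariance bivariate distance between the mean vectors).
#'
#' @param t2 Hotelling T2 value (>= 0).
#' @param n1,n2 Group sample sizes.
#' @return List of class `hotelling_result`.
#' @export
hotelling_from_t2 <- function(t2, n1, n2) {
  if (t2 < 0) stop("T2 must be nonnegative")
  n <- n1 + n2
  f_stat <- t2 * (n - 3) / (2 * (n - 2))
  structure(list(t2 = t2, f_stat = f_stat, df = c(2, n - 3),
                 p_value = stats::pf(f_stat, 2, n - 3,
                                     lower.tail = FALSE),
                 mahalanobis_d = sqrt(t2 * n / (n1 * n2)),
                 n1 = n1, n2 = n2), class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("<hotelling_result> T2 = %.3f, F(%d, %d) = %.3f, p = %.4g, D = %.3f (n1 = %d, n2 = %d)\n",
              x$t2, x$df[1], x$df[2], x$f_stat, x$p_value,
              x$mahalanobis_d, x$n1, x$n2))
  invisible(x)
}

#' Plot tolerance or confidence ellipses on the RXc-specific plane
#'
#' Rsp on the x axis, Xcsp on the y axis (ohm*cm), equal aspect ratio.
#'
#' @param ellipses Named list of `ellipse_spec` objects.
#' @param points Optional data frame with columns `rsp`, `xcsp` and
#'   optionally `group` for individual or mean vectors.
#' @return A ggplot object.
#' @export
plot_ellipses <- function(ellipses, points = NULL) {
  if (inherits(ellipses, "ellipse_spec")) ellipses <- list(ellipses)
  if (is.null(names(ellipses)))
    names(ellipses) <- paste0("ellipse_", seq_along(ellipses))
  paths <- do.call(rbind, lapply(names(ellipses), function(nm) {
    p <- as.data.frame(ellipse_points(ellipses[[nm]]))
    p$group <- nm
    p
  }))
  gg <- ggplot2::ggplot(paths, ggplot2::aes(x = .data$rsp,
                                            y = .data$xcsp,
                                            colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Rsp (ohm·cm)", y = "Xcsp (ohm·cm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    points <- as.data.frame(points)
    if (!"group" %in% names(points)) points$group <- "sample"
    gg <- gg + ggplot2::geom_point(data = points)
  }
  gg
}
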