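#' Landmark sets for 2D morphometry
#'
#' Named 2D points and polylines (pixels or model units).  The line-ratio
#' task requires points `X` and `Y` (endpoints of line A) and a polyline
#' `optic_margin`; the angle task requires a polyline `ZLI` and points
#' `base`, `starA`, `starP`.
#'
#' @param points named list of length-2 numeric vectors.
#' @param polylines named list of k x 2 matrices (k >= 2).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points = list(), polylines = list()) {
  for (p in points) stopifnot(length(p) == 2L, is.numeric(p))
  for (pl in polylines)
    if (!is.matrix(pl) || ncol(pl) != 2L || nrow(pl) < 2L)
      stop("polylines must be k x 2 matrices with k >= 2")
  structure(list(points = points, polylines = polylines),
            class = "landmark_set")
}

require_landmarks <- function(lm, points = character(0),
                              polylines = character(0)) {
  miss_p <- setdiff(points, names(lm$points))
  miss_l <- setdiff(polylines, names(lm$polylines))
  if (length(miss_p) || length(miss_l))
    stop("missing required landmarks: ",
         paste(c(miss_p, miss_l), collapse = ", "))
}

#' Line-ratio morphometry (B:A)
#'
#' Line A runs from landmark `X` to `Y` (`Y` is the posterior limit).  A
#' perpendicular to A is positioned to intersect both A and the
#' `optic_margin` polyline; geometrically, the foot of that perpendicular
#' on A is the A-axis projection of the margin's posterior-most point
#' (largest projection toward `Y`).  Line B runs from `Y` to that foot,
#' and the result is the dimensionless ratio B:A.  The construction uses
#' only projections, so it is invariant under rigid motion and reflection
#' of all landmarks.
#'
#' @param landmarks a [landmark_set] with points `X`, `Y` and polyline
#'   `optic_margin`.
#' @return list with `A`, `B` (lengths) and `ratio` (= B/A).
#' @export
ba_ratio <- function(landmarks) {
  require_landmarks(landmarks, points = c("X", "Y"),
                    polylines = "optic_margin")
  X <- landmarks$points$X
  Y <- landmarks$points$Y
  A <- sqrt(sum((Y - X)^2))
  if (A == 0) stop("X and Y coincide: line A has zero length")
  u <- (Y - X) / A
  margin <- landmarks$polylines$optic_margin
  proj <- as.numeric((sweep(margin, 2, X)) %*% u)
  t_star <- max(proj)
  tol <- 1e-9 * A
  if (t_star < -tol || min(proj) > A + tol)
    stop("no perpendicular to line A through the optic margin intersects ",
         "the A segment: margin projections [",
         format(min(proj)), ", ", format(max(proj)),
         "] lie outside [0, ", format(A), "]")
  t_star <- min(max(t_star, 0), A)
  list(A = A, B = A - t_star, ratio = (A - t_star) / A)
}

#' Logarithmic trend of ratios over stages
#'
#' Ordinary least squares fit of `ratio = a * ln(stage) + b`.  Stage
#' values are the given ordinals (e.g. HH stage numbers, HH10 entered as
#' 10) and must be positive.
#'
#' @param stages positive numeric stage values (>= 2 distinct).
#' @param ratios numeric ratios, same length.
#' @return list with `a` (slope), `b` (intercept), `fitted` and
#'   `residuals`.
#' @export
fit_log_trend <- function(stages, ratios) {
  stopifnot(length(stages) == length(ratios))
  if (any(stages <= 0)) stop("stage values must be positive")
  if (length(unique(stages)) < 2L)
    stop("at least two distinct stage values required")
  fit <- stats::lm(ratios ~ log(stages))
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::resid(fit)))
}

#' Angles between the ZLI and base-to-landmark lines
#'
#' Measures the angle between the ZLI direction and the segment from
#' `base` to each starred landmark, in degrees within `[0, 180]`.  By
#' default the ZLI direction is the straight line through the polyline's
#' first and last points; `fit = "tls"` instead uses a total-least-squares
#' line fit over all polyline vertices (for curved annotations).
#'
#' @param landmarks a [landmark_set] with polyline `ZLI` and points
#'   `base`, `starA`, `starP`.
#' @param fit `"endpoints"` (default) or `"tls"`.
#' @return named numeric vector with angles `starA` and `starP`
#'   (degrees).
#' @export
zli_angles <- function(landmarks, fit = c("endpoints", "tls")) {
  fit <- match.arg(fit)
  require_landmarks(landmarks, points = c("base", "starA", "starP"),
                    polylines = "ZLI")
  zli <- landmarks$polylines$ZLI
  if (fit == "endpoints") {
    dirv <- zli[nrow(zli), ] - zli[1, ]
  } else {
    X <- sweep(zli, 2, colMeans(zli))
    dirv <- svd(X, nu = 0)$v[, 1]
  }
  if (sum(dirv^2) == 0) stop("zero-length ZLI direction")
  one <- function(star) {
    seg <- landmarks$points[[star]] - landmarks$points$base
    if (sum(seg^2) == 0)
      stop("zero-length segment from base to ", star)
    angle_deg(dirv, seg)
  }
  c(starA = one("starA"), starP = one("starP"))
}

#' Thresholded expression-area quantification
#'
#' Reproduces the despeckle-threshold-ROI measurement pipeline, in this
#' fixed order: (1) bright-outlier removal -- any pixel exceeding the
#' median of its radius-`despeckle_radius` neighbourhood (Euclidean disk,
#' centre included, clipped at borders) by more than `outlier_threshold`
#' is replaced by that median (dark pixels are never touched); (2)
#' binarisation at `threshold` (a pixel is positive when its value is >=
#' the threshold); (3) count of positive pixels inside the ROI polygon.
#' With `despeckle_radius = 0` step (1) is skipped and the result equals a
#' plain threshold count.
#'
#' The outlier removal emulates the documented semantics of median-based
#' "remove outliers" despeckling tools; it is an emulation, not a
#' bit-compatible port.  Threshold values are required explicitly: there
#' are no defaults masquerading as calibrated settings.
#'
#' @param image an `annotated_image` (see [generate_image()]) or a plain
#'   numeric matrix.
#' @param despeckle_radius neighbourhood radius in pixels (0 disables).
#' @param outlier_threshold intensity deviation above which a bright pixel
#'   is replaced.
#' @param threshold binarisation intensity.
#' @param roi optional k x 2 polygon (x = column, y = row, pixel units);
#'   defaults to the image's `roi`, or the whole frame if none.
#' @param pixel_size optional physical pixel edge (units/pixel) to also
#'   report area in units squared.
#' @return list with `pixels` (positive-pixel count), `area_units`
#'   (or `NA`), and `processed` (the despeckled image matrix).
#' @export
area_positive <- function(image, despeckle_radius, outlier_threshold,
                          threshold, roi = NULL, pixel_size = NULL) {
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  stopifnot(is.matrix(px))
  rng <- range(px)
  if (threshold < rng[1] || threshold > rng[2])
    warning("threshold lies outside the image intensity range")
  if (is.null(roi) && inherits(image, "annotated_image")) roi <- image$roi
  roi_mask <- if (is.null(roi)) matrix(TRUE, nrow(px), ncol(px))
              else rasterise_polygon(as.matrix(roi), dim(px))
  if (!any(roi_mask)) stop("empty ROI")
  proc <- px
  if (despeckle_radius > 0) {
    med <- neighbourhood_median(px, despeckle_radius)
    bright <- (px - med) > outlier_threshold
    proc[bright] <- med[bright]
  }
  pos <- proc >= threshold
  n <- sum(pos & roi_mask)
  list(pixels = n,
       area_units = if (is.null(pixel_size)) NA_real_
                    else n * pixel_size^2,
       processed = proc)
}

# Median over the Euclidean disk of given radius around each pixel,
# border-clipped.  Offsets stack into an array; stats::median per pixel.
neighbourhood_median <- function(px, radius) {
  r <- ceiling(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(px); nc <- ncol(px)
  stack <- matrix(NA_real_, nr * nc, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    shifted <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs - dr, cs - dc] <- px[rs, cs]
    stack[, k] <- as.vector(shifted)
  }
  matrix(apply(stack, 1, stats::median, na.rm = TRUE), nr, nc)
}

#' Two-sample t tests from closed-form formulas
#'
#' Student's pooled-variance and Welch's unequal-variance two-sided t
#' tests, implemented directly from the textbook formulas (Welch degrees
#' of freedom by Welch-Satterthwaite); the p value comes from the t
#' distribution.  Identical groups give `t = 0, p = 1`; zero variance in
#' both groups with unequal means is an error because the statistic is
#' undefined (zero standard error with a non-zero mean difference).
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param variant `"welch"` (default) or `"student"`.
#' @return list with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`,
#'   `variant`.
#' @export
two_sample_t <- function(group_a, group_b,
                         variant = c("welch", "student")) {
  variant <- match.arg(variant)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb) return(list(t = 0, df = if (variant == "student") df
                              else na + nb - 2,
                              p = 1, mean_a = ma, mean_b = mb,
                              variant = variant))
    stop("both groups have zero variance with unequal means: ",
         "the t statistic is undefined (zero standard error)")
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, variant = variant)
}

#' Read / write landmark sets as CSV
#'
#' Format: columns `name`, `x`, `y`, `polyline_id`, `order`.  Rows with an
#' empty `polyline_id` are points; rows sharing a `polyline_id` form a
#' polyline ordered by `order`.
#'
#' @param path CSV path.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$polyline_id[is.na(df$polyline_id)] <- ""
  pts <- df[df$polyline_id == "", ]
  points <- stats::setNames(lapply(seq_len(nrow(pts)), function(i)
    c(pts$x[i], pts$y[i])), pts$name)
  polylines <- list()
  for (id in unique(df$polyline_id[df$polyline_id != ""])) {
    sub <- df[df$polyline_id == id, ]
    sub <- sub[order(sub$order), ]
    polylines[[id]] <- cbind(sub$x, sub$y)
  }
  landmark_set(points, polylines)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set] to write.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- list()
  for (nm in names(landmarks$points))
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, x = landmarks$points[[nm]][1],
      y = landmarks$points[[nm]][2], polyline_id = "", order = NA_integer_)
  for (nm in names(landmarks$polylines)) {
    pl <- landmarks$polylines[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, x = pl[, 1], y = pl[, 2], polyline_id = nm,
      order = seq_len(nrow(pl)))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
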