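#' Axis frame for growth-line measurements
#'
#' Defines the anatomical reference used to orient growth-line metrics: an
#' anterior-posterior (A-P) reference polyline lying on the mesh surface
#' (the D-V direction is taken orthogonal to it in the local tangent
#' plane) and an optional named target point (the "eye") for convergence
#' measurements.
#'
#' @param ap_points m x 3 matrix of polyline vertices on the mesh
#'   (consecutive points must be distinct).
#' @param target optional length-3 coordinate of the convergence target.
#' @return An object of class `axis_frame`.
#' @export
axis_frame <- function(ap_points, target = NULL) {
  ap_points <- as.matrix(ap_points)
  if (ncol(ap_points) != 3L || nrow(ap_points) < 2L)
    stop("'ap_points' must be an m x 3 matrix with m >= 2")
  seg <- diff(ap_points)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive A-P polyline points must be distinct")
  if (!is.null(target)) stopifnot(length(target) == 3L)
  structure(list(ap_points = ap_points, target = target),
            class = "axis_frame")
}

#' Shape-classification thresholds
#'
#' The growth-line shape taxonomy (spot / line / V) is visual in origin;
#' these quantitative surrogates are package choices, stored in one config
#' object and echoed with every output.  `t_line` is the minimum
#' elongation for a non-spot, `t_v` the maximum interior angle (degrees)
#' for a V, `t_arm` the minimum arm fraction of total skeleton length,
#' `grey_band` the elongation interval scored "indeterminate" by
#' [shape_conformity()], and `eps_elong` the tolerance above 1 below which
#' orientation is undefined.
#'
#' @param t_line,t_v,t_arm,grey_band,eps_elong see description.
#' @param skeleton_bins number of bins used to trace the patch skeleton.
#' @return a named list of thresholds.
#' @export
shape_thresholds <- function(t_line = 2.5, t_v = 150, t_arm = 0.25,
                             grey_band = c(2.25, 2.75), eps_elong = 1e-3,
                             skeleton_bins = 15L) {
  list(t_line = t_line, t_v = t_v, t_arm = t_arm, grey_band = grey_band,
       eps_elong = eps_elong, skeleton_bins = as.integer(skeleton_bins))
}

#' Measure growth-line metrics for a patch at two stages
#'
#' Quantifies how an initially compact dye patch has grown between two
#' stages: area ratio, elongation and orientation from a
#' principal-component analysis of the later-stage sample points projected
#' onto their best-fit (total-least-squares) tangent plane, centroid
#' displacement, shape class, and convergence distance to the frame's
#' target when defined.  Orientation is reported in `[0, 180)` degrees
#' relative to the A-P tangent nearest the patch centroid (growth lines
#' are undirected).
#'
#' @param patch_t0,patch_t1 the same [dye_patch] propagated to two stages
#'   (identical face sets; see [propagate_dye()]).
#' @param frame an [axis_frame].
#' @param thresholds a [shape_thresholds()] list.
#' @return A list of class `growth_metrics`: `area_ratio`, `elongation`,
#'   `orientation`, `centroid_displacement`, `shape_class`, `v_angle`,
#'   `convergence_distance`, plus the thresholds echo.
#' @export
measure_growth <- function(patch_t0, patch_t1, frame,
                           thresholds = shape_thresholds()) {
  stopifnot(inherits(patch_t0, "dye_patch"), inherits(patch_t1, "dye_patch"),
            inherits(frame, "axis_frame"))
  if (!identical(patch_t0$faces, patch_t1$faces))
    stop("patches must be the same patch at two stages (same face set)")
  a0 <- patch_area(patch_t0)
  a1 <- patch_area(patch_t1)
  if (a0 <= 0) stop("zero patch area at t0")
  pts0 <- patch_coords(patch_t0)
  pts1 <- patch_coords(patch_t1)
  pl <- tangent_plane_projection(pts1, patch_normal(patch_t1, patch_t1$mesh))
  ev <- eigen(stats::cov(pl$xy), symmetric = TRUE)
  l <- pmax(ev$values, 0)
  elong <- if (l[2] <= .Machine$double.eps * l[1]) Inf else sqrt(l[1] / l[2])
  major2d <- ev$vectors[, 1]
  # A-P tangent nearest the patch centroid, projected into the plane
  tangent <- nearest_polyline_tangent(frame$ap_points, pl$centroid)
  t2d <- as.numeric(tangent %*% pl$basis)
  orientation <- NA_real_
  if (is.finite(elong) && elong > 1 + thresholds$eps_elong &&
        sqrt(sum(t2d^2)) > 0) {
    ang <- (atan2(major2d[2], major2d[1]) - atan2(t2d[2], t2d[1])) * 180 / pi
    orientation <- ang %% 180
  }
  shp <- classify_shape(patch_t1, frame, thresholds, projection = pl,
                        elongation = elong)
  conv <- NA_real_
  if (!is.null(frame$target) && is.finite(elong) &&
        elong > 1 + thresholds$eps_elong)
    conv <- convergence_distance(patch_t1, frame, thresholds,
                                 projection = pl)
  structure(list(area_ratio = a1 / a0, elongation = elong,
                 orientation = orientation,
                 centroid_displacement =
                   sqrt(sum((colMeans(pts1) - colMeans(pts0))^2)),
                 shape_class = shp$shape_class, v_angle = shp$v_angle,
                 convergence_distance = conv, thresholds = thresholds),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf(paste0("<growth_metrics: area_ratio %.3g, elongation %.3g, ",
                     "orientation %s deg, class %s%s>\n"),
              x$area_ratio, x$elongation,
              if (is.na(x$orientation)) "NA" else sprintf("%.1f", x$orientation),
              x$shape_class,
              if (!is.na(x$v_angle)) sprintf(" (v_angle %.1f)", x$v_angle)
              else ""))
  invisible(x)
}

# Best-fit plane by total least squares (PCA): returns centroid, 3x2
# in-plane basis, and the projected 2D coordinates.  When a reference
# normal is supplied the basis is made right-handed with respect to it,
# so in-plane angles have a well-defined sign (orientation in [0, 180)
# is otherwise ambiguous up to reflection).
tangent_plane_projection <- function(pts, ref_normal = NULL) {
  centroid <- colMeans(pts)
  X <- sweep(pts, 2, centroid)
  sv <- svd(X, nu = 0, nv = 3)
  basis <- sv$v[, 1:2, drop = FALSE]
  if (!is.null(ref_normal)) {
    n <- c(basis[2, 1] * basis[3, 2] - basis[3, 1] * basis[2, 2],
           basis[3, 1] * basis[1, 2] - basis[1, 1] * basis[3, 2],
           basis[1, 1] * basis[2, 2] - basis[2, 1] * basis[1, 2])
    if (sum(n * ref_normal) < 0) basis[, 2] <- -basis[, 2]
  }
  list(centroid = centroid, basis = basis, xy = X %*% basis)
}

# Area-weighted mean outward normal of a patch's triangles (uses the
# mesh winding order, which is constant across stages).
patch_normal <- function(patch, mesh) {
  tris <- which(mesh$tri_face %in% patch$faces)
  V <- mesh$vertices
  a <- V[mesh$tri[tris, 1], , drop = FALSE]
  u <- V[mesh$tri[tris, 2], , drop = FALSE] - a
  w <- V[mesh$tri[tris, 3], , drop = FALSE] - a
  n <- colSums(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                     u[, 3] * w[, 1] - u[, 1] * w[, 3],
                     u[, 1] * w[, 2] - u[, 2] * w[, 1]))
  len <- sqrt(sum(n^2))
  if (len == 0) c(0, 0, 1) else n / len
}

nearest_polyline_tangent <- function(poly, p) {
  n <- nrow(poly) - 1L
  best <- Inf
  tangent <- poly[2, ] - poly[1, ]
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    u <- b - a
    t <- sum((p - a) * u) / sum(u * u)
    t <- min(max(t, 0), 1)
    d <- sum((p - (a + t * u))^2)
    if (d < best) {
      best <- d
      tangent <- u
    }
  }
  tangent / sqrt(sum(tangent^2))
}

#' Classify the shape of a grown patch
#'
#' Categorical surrogate for the visual growth-line taxonomy.  A skeleton
#' is traced by binning the tangent-plane sample points along the major
#' principal axis and taking per-bin centroids; the vertex of maximal
#' turning splits the skeleton into two arms.  The patch is a `"V"` when
#' the interior angle between the arms is below `t_v` degrees, both arms
#' carry at least `t_arm` of the total skeleton length, and both arms are
#' themselves line-like (per-arm elongation at least `t_line` -- a folded
#' thin shape has low global elongation, so the arm-wise test is what
#' distinguishes a chevron from a blob).  Otherwise it is a `"line"` when
#' the global elongation reaches `t_line`, else a `"spot"`.
#'
#' @param patch a [dye_patch] with attached geometry (from
#'   [propagate_dye()]).
#' @param frame an [axis_frame] (unused by the classification itself but
#'   kept for interface symmetry with [measure_growth()]).
#' @param thresholds a [shape_thresholds()] list.
#' @param projection,elongation optional precomputed tangent-plane
#'   projection and elongation (internal reuse).
#' @return list with `shape_class` (`"spot"`, `"line"` or `"V"`) and
#'   `v_angle` (degrees, `NA` unless a V).
#' @export
classify_shape <- function(patch, frame = NULL,
                           thresholds = shape_thresholds(),
                           projection = NULL, elongation = NULL) {
  if (is.null(projection)) projection <- tangent_plane_projection(
    patch_coords(patch))
  xy <- projection$xy
  if (is.null(elongation)) {
    ev <- eigen(stats::cov(xy), symmetric = TRUE)
    l <- pmax(ev$values, 0)
    elongation <- if (l[2] <= .Machine$double.eps * l[1]) Inf
                  else sqrt(l[1] / l[2])
  }
  fallback <- if (elongation >= thresholds$t_line) "line" else "spot"
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  u <- ev$vectors[, 1]
  q <- xy %*% u
  brk <- seq(min(q), max(q), length.out = thresholds$skeleton_bins + 1L)
  bin <- pmin(pmax(findInterval(q, brk, rightmost.closed = TRUE), 1L),
              thresholds$skeleton_bins)
  keep <- sort(unique(bin))
  skel <- t(vapply(keep, function(b) colMeans(xy[bin == b, , drop = FALSE]),
                   numeric(2)))
  if (nrow(skel) < 3L)
    return(list(shape_class = fallback, v_angle = NA_real_))
  turn <- vapply(2:(nrow(skel) - 1L), function(i) {
    v1 <- skel[i, ] - skel[i - 1L, ]
    v2 <- skel[i + 1L, ] - skel[i, ]
    angle_deg(v1, v2)
  }, numeric(1))
  i_max <- which.max(turn) + 1L
  seglen <- sqrt(rowSums(diff(skel)^2))
  total <- sum(seglen)
  arm1 <- sum(seglen[seq_len(i_max - 1L)])
  arm2 <- total - arm1
  v1 <- skel[1, ] - skel[i_max, ]
  v2 <- skel[nrow(skel), ] - skel[i_max, ]
  interior <- angle_deg(v1, v2)
  arm_elong <- function(sel) {
    if (sum(sel) < 5L) return(1)
    e <- eigen(stats::cov(xy[sel, , drop = FALSE]), symmetric = TRUE)
    l <- pmax(e$values, 0)
    if (l[2] <= .Machine$double.eps * l[1]) Inf else sqrt(l[1] / l[2])
  }
  split_q <- (brk[keep[i_max]] + brk[keep[i_max] + 1L]) / 2
  e1 <- arm_elong(q <= split_q)
  e2 <- arm_elong(q > split_q)
  if (interior < thresholds$t_v &&
        arm1 >= thresholds$t_arm * total &&
        arm2 >= thresholds$t_arm * total &&
        min(e1, e2) >= thresholds$t_line)
    return(list(shape_class = "V", v_angle = interior))
  list(shape_class = fallback, v_angle = NA_real_)
}

angle_deg <- function(v1, v2) {
  c1 <- sqrt(sum(v1^2)); c2 <- sqrt(sum(v2^2))
  if (c1 == 0 || c2 == 0) return(NA_real_)
  acos(min(max(sum(v1 * v2) / (c1 * c2), -1), 1)) * 180 / pi
}

#' Convergence distance of a growth line to a target point
#'
#' Perpendicular distance from the frame's target point to the patch's
#' major-axis line, measured in the patch's tangent-plane projection.
#' Requires a defined orientation (elongation above `1 + eps_elong`).
#'
#' @inheritParams classify_shape
#' @param frame an [axis_frame] with a non-null `target`.
#' @return distance in model units.
#' @export
convergence_distance <- function(patch, frame,
                                 thresholds = shape_thresholds(),
                                 projection = NULL) {
  if (is.null(frame$target))
    stop("frame has no target point")
  if (is.null(projection))
    projection <- tangent_plane_projection(patch_coords(patch))
  xy <- projection$xy
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  l <- pmax(ev$values, 0)
  elong <- if (l[2] <= .Machine$double.eps * l[1]) Inf else sqrt(l[1] / l[2])
  if (is.finite(elong) && elong <= 1 + thresholds$eps_elong)
    stop("orientation undefined: patch elongation is ", format(elong),
         " (must exceed 1 + eps_elong); check that the patch is elongated")
  u <- ev$vectors[, 1]
  t2d <- as.numeric((frame$target - projection$centroid) %*% projection$basis)
  # distance from target to the line through the origin (patch centroid)
  # with direction u, in the plane
  abs(t2d[1] * u[2] - t2d[2] * u[1])
}

#' Write growth metrics as CSV rows
#'
#' One row per (sample, stage pair) with a hash of the thresholds config,
#' so outputs are traceable to the exact shape-calling parameters.
#'
#' @param metrics_list named list of `growth_metrics` (names = sample ids).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_growth_metrics <- function(metrics_list, path) {
  cfg_hash <- function(th) {
    s <- paste(names(th), vapply(th, function(x)
      paste(format(x, digits = 15), collapse = ","), character(1)),
      collapse = ";")
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
              .Machine$integer.max)
  }
  df <- do.call(rbind, lapply(names(metrics_list), function(id) {
    m <- metrics_list[[id]]
    data.frame(sample_id = id, area_ratio = m$area_ratio,
               elongation = m$elongation, orientation = m$orientation,
               centroid_displacement = m$centroid_displacement,
               shape_class = m$shape_class, v_angle = m$v_angle,
               convergence_distance = m$convergence_distance,
               config_hash = cfg_hash(m$thresholds))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
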