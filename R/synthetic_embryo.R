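#' Specify a synthetic deformation field
#'
#' Describes how a base mesh is deformed across stages to emulate the
#' growth modes seen in the embryonic forebrain: directional growth toward
#' an attractor point (the "eye"), region-wise isotropic expansion, and
#' anterior translation of a midline band.  Displacements are linear in
#' the normalised stage parameter and combine additively, so a zero
#' specification yields an identity series.
#'
#' The directional component displaces vertex `v` by
#' `g * w(v) * (a - v) / |a - v|`, where `g` is `attractor_strength`, `a`
#' the attractor point, and the weight `w(v)` decays linearly with
#' geodesic distance from the marked `optic_vertices` set:
#' `w(v) = max(0, 1 - d(v) / decay_range)`.
#'
#' @param base_mesh a [stage_mesh]; must be manifold (every edge shared by
#'   at most two faces).
#' @param n_stages number of stages (>= 2; default 4).
#' @param attractor_point length-3 coordinate, required when
#'   `attractor_strength > 0`.
#' @param attractor_strength displacement magnitude at `w = 1`
#'   (model units, >= 0).
#' @param optic_vertices integer vertex indices anchoring the directional
#'   weight field.
#' @param decay_range geodesic distance at which the directional weight
#'   reaches zero (model units).
#' @param isotropic_zones list of `list(vertices =, scale =)` entries;
#'   `scale` is either a single final-stage factor (ramped linearly from 1)
#'   or a vector of per-stage factors of length `n_stages`, all >= 0.
#' @param midline_band `list(vertices =, translation =, direction =)`;
#'   `translation` a final-stage distance or per-stage vector,
#'   `direction` a 3-vector (default `c(1, 0, 0)`, the anterior axis).
#' @param rng_seed integer seed recorded in output metadata (the field
#'   itself is deterministic).
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(base_mesh, n_stages = 4L,
                             attractor_point = NULL, attractor_strength = 0,
                             optic_vertices = integer(0), decay_range = Inf,
                             isotropic_zones = list(), midline_band = NULL,
                             rng_seed = 1L) {
  stopifnot(inherits(base_mesh, "stage_mesh"))
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("n_stages must be >= 2")
  if (attractor_strength < 0) stop("attractor_strength must be >= 0")
  if (!is_manifold(base_mesh))
    stop("base mesh is non-manifold (an edge is shared by > 2 faces)")
  nv <- nrow(base_mesh$vertices)
  check_mask <- function(m, what) {
    m <- as.integer(m)
    if (any(m < 1L | m > nv))
      stop(sprintf("%s mask references invalid vertices", what))
    m
  }
  optic_vertices <- check_mask(optic_vertices, "optic_vertices")
  if (attractor_strength > 0) {
    if (is.null(attractor_point) || length(attractor_point) != 3L)
      stop("attractor_point (length-3) required when attractor_strength > 0")
    if (length(optic_vertices) == 0L || !is.finite(decay_range))
      stop("optic_vertices and a finite decay_range are required when ",
           "attractor_strength > 0")
  }
  for (z in isotropic_zones) {
    check_mask(z$vertices, "isotropic zone")
    if (any(z$scale < 0)) stop("isotropic zone scale factors must be >= 0")
    if (!length(z$scale) %in% c(1L, n_stages))
      stop("zone scale must be a scalar or one value per stage")
  }
  if (!is.null(midline_band)) {
    check_mask(midline_band$vertices, "midline band")
    if (is.null(midline_band$direction)) midline_band$direction <- c(1, 0, 0)
    if (!length(midline_band$translation) %in% c(1L, n_stages))
      stop("band translation must be a scalar or one value per stage")
  }
  structure(list(base_mesh = base_mesh, n_stages = n_stages,
                 attractor_point = attractor_point,
                 attractor_strength = attractor_strength,
                 optic_vertices = optic_vertices, decay_range = decay_range,
                 isotropic_zones = isotropic_zones,
                 midline_band = midline_band,
                 rng_seed = as.integer(rng_seed)),
            class = "deformation_spec")
}

#' Generate a corresponding stage series from a deformation spec
#'
#' Builds `n_stages` meshes sharing the base topology, with stage `k`
#' (0-based) displaced by `tau_k = k / (n_stages - 1)` times the final
#' deformation field (per-stage scale/translation vectors override the
#' linear ramp).  Stage 0 always equals the base mesh, and a
#' zero-parameter spec yields an identity series.
#'
#' @param spec a [deformation_spec].
#' @param stage_labels optional character labels (default
#'   `"S0" ... "S{n-1}"`).
#' @return A list with `series` (a [stage_series]) and `truth`:
#'   per-stage per-vertex displacement matrices, the directional weight
#'   field, and the spec echo (including `rng_seed`).
#' @export
generate_stage_series <- function(spec, stage_labels = NULL) {
  stopifnot(inherits(spec, "deformation_spec"))
  base <- spec$base_mesh
  V0 <- base$vertices
  nv <- nrow(V0)
  n <- spec$n_stages
  if (is.null(stage_labels))
    stage_labels <- sprintf("S%d", seq_len(n) - 1L)
  w <- numeric(nv)
  if (spec$attractor_strength > 0) {
    d <- geodesic_distance(base, spec$optic_vertices)
    w <- pmax(0, 1 - d / spec$decay_range)
  }
  dir_final <- matrix(0, nv, 3)
  if (spec$attractor_strength > 0) {
    U <- matrix(spec$attractor_point, nv, 3, byrow = TRUE) - V0
    nrm <- sqrt(rowSums(U^2))
    nrm[nrm == 0] <- 1
    dir_final <- spec$attractor_strength * w * U / nrm
  }
  zone_centroids <- lapply(spec$isotropic_zones, function(z)
    colMeans(V0[z$vertices, , drop = FALSE]))
  meshes <- vector("list", n)
  disps <- vector("list", n)
  for (k in seq_len(n)) {
    tau <- (k - 1) / (n - 1)
    D <- tau * dir_final
    for (zi in seq_along(spec$isotropic_zones)) {
      z <- spec$isotropic_zones[[zi]]
      s_k <- if (length(z$scale) == 1L) 1 + tau * (z$scale - 1) else z$scale[k]
      cc <- zone_centroids[[zi]]
      rows <- z$vertices
      D[rows, ] <- D[rows, , drop = FALSE] +
        (s_k - 1) * (V0[rows, , drop = FALSE] -
                       matrix(cc, length(rows), 3, byrow = TRUE))
    }
    if (!is.null(spec$midline_band)) {
      b <- spec$midline_band
      t_k <- if (length(b$translation) == 1L) tau * b$translation
             else b$translation[k]
      u <- b$direction / sqrt(sum(b$direction^2))
      D[b$vertices, ] <- D[b$vertices, , drop = FALSE] +
        matrix(t_k * u, length(b$vertices), 3, byrow = TRUE)
    }
    m <- base
    m$vertices <- V0 + D
    m$stage_label <- stage_labels[k]
    meshes[[k]] <- m
    disps[[k]] <- D
  }
  list(series = stage_series(meshes),
       truth = list(displacements = disps, directional_weight = w,
                    spec = spec))
}

#' Partition a tube surface into named injection zones
#'
#' Splits the faces of an axis-aligned tube mesh (see [mesh_tube()]) into
#' `n_axial * n_around` zones by binning face centroids along the tube
#' axis and around its circumference.  The default 4 x 3 layout gives the
#' twelve-zone vocabulary used for injections.
#'
#' @param mesh a [stage_mesh] produced by [mesh_tube()] (axis along x).
#' @param n_axial,n_around number of bins along and around the tube.
#' @return Named list of integer face-index vectors (labels `"1"`,
#'   `"2"`, ...), a partition of all faces.
#' @export
tube_zones <- function(mesh, n_axial = 4L, n_around = 3L) {
  cent <- face_centroids(mesh)
  xr <- range(mesh$vertices[, 1])
  ax <- pmin(1L + floor((cent[, 1] - xr[1]) / diff(xr) * n_axial),
             n_axial)
  th <- atan2(cent[, 3], cent[, 2]) %% (2 * pi)
  ar <- pmin(1L + floor(th / (2 * pi) * n_around), n_around)
  zone <- (ax - 1L) * n_around + ar
  out <- split(seq_along(mesh$faces), zone)
  names(out) <- as.character(seq_along(out))
  out
}

face_centroids <- function(mesh) {
  t(vapply(mesh$faces, function(f)
    colMeans(mesh$vertices[f, , drop = FALSE]), numeric(3)))
}

#' Generate a synthetic injection set over zones
#'
#' Emulates dye injections targeting each named zone of the stage-0 mesh:
#' one seed point per record, at the zone's centroid projection when
#' `jitter = 0`, otherwise drawn uniformly (by area) from zone faces whose
#' centroid lies within geodesic distance `jitter` of the zone centroid.
#' Each record carries its injected patch and, when `regions` is given,
#' ground-truth outcome areas computed by exact forward mapping of the
#' patch (face labels are invariant under propagation) through an
#' independent brute-force overlap tally.
#'
#' @param series a [stage_series].
#' @param zones named list of face sets partitioning the stage-0 surface
#'   (e.g. [tube_zones()]).
#' @param n_per_zone records per zone.
#' @param jitter geodesic seed scatter (model units); values exceeding the
#'   zone diameter are clamped with a warning.
#' @param rng_seed integer seed.
#' @param radius geodesic dye radius passed to [inject_dye()].
#' @param regions optional [outcome_regions()] on the final stage, used to
#'   attach ground-truth areas.
#' @param min_overlap overlap fraction for the ground-truth region rule.
#' @param graph optional prebuilt [mesh_geodesic_graph()] of stage 0.
#' @return A list with `records` (list of injection records: `sample_id`,
#'   `zone`, `seed`, `patch`) and `truth` (per-record ground-truth region
#'   labels and patch face sets).
#' @export
generate_injection_set <- function(series, zones, n_per_zone = 1L,
                                   jitter = 0, rng_seed = 1L, radius = 0.5,
                                   regions = NULL, min_overlap = 0.05,
                                   graph = NULL) {
  stopifnot(inherits(series, "stage_series"))
  mesh0 <- series$meshes[[1]]
  final <- series$meshes[[n_stages(series)]]
  if (any(lengths(zones) == 0L)) stop("empty zone in 'zones'")
  if (is.null(graph)) graph <- mesh_geodesic_graph(mesh0)
  areas <- face_area(mesh0)
  records <- list()
  truth <- list()
  withr::with_seed(as.integer(rng_seed), {
    for (zname in names(zones)) {
      zfaces <- zones[[zname]]
      zcent <- colSums(face_centroids(mesh0)[zfaces, , drop = FALSE] *
                         areas[zfaces]) / sum(areas[zfaces])
      seed0 <- locate_point(mesh0, zcent)
      cand <- zfaces
      if (jitter > 0) {
        dv <- geodesic_distance(mesh0, seed0, graph = graph)
        dcent <- vapply(zfaces, function(f)
          min(dv[mesh0$faces[[f]]]), numeric(1))
        zdiam <- max(dcent)
        if (jitter > zdiam) {
          warning(sprintf("zone %s: jitter %.3g exceeds zone diameter %.3g; clamped",
                          zname, jitter, zdiam))
          jit <- zdiam
        } else jit <- jitter
        cand <- zfaces[dcent <= jit]
        if (length(cand) == 0L) cand <- seed0$face
      }
      for (i in seq_len(n_per_zone)) {
        if (jitter > 0) {
          f <- cand[sample.int(length(cand), 1L,
                               prob = areas[cand] / sum(areas[cand]))]
          tris <- which(mesh0$tri_face == f)
          tri <- tris[sample.int(length(tris), 1L)]
          r12 <- stats::runif(2)
          r1s <- sqrt(r12[1])
          bary <- c(1 - r1s, r1s * (1 - r12[2]), r1s * r12[2])
          seed <- surface_point(tri, bary, face = f)
        } else seed <- seed0
        patch <- inject_dye(mesh0, seed, radius, graph = graph,
                            zone = zname,
                            sample_id = sprintf("z%s_r%02d", zname, i))
        rec <- list(sample_id = patch$sample_id, zone = zname,
                    seed = seed, patch = patch)
        tr <- list(sample_id = patch$sample_id, faces = patch$faces)
        if (!is.null(regions))
          tr$regions <- overlap_regions_bruteforce(patch$faces, regions,
                                                   final, min_overlap)
        records[[length(records) + 1L]] <- rec
        truth[[length(truth) + 1L]] <- tr
      }
    }
  })
  list(records = records, truth = truth)
}

# Independent, deliberately simple overlap rule used for ground truth:
# plain loop over regions, comparing summed face areas.  Applies the same
# contract as the scoring path: if no area reaches min_overlap, the single
# best-overlap area is the outcome.
overlap_regions_bruteforce <- function(patch_faces, regions, mesh,
                                       min_overlap) {
  areas <- face_area(mesh)
  patch_area <- sum(areas[patch_faces])
  hit <- character(0)
  best <- ""
  best_ov <- -1
  for (rn in names(regions)) {
    ov <- 0
    for (f in patch_faces) if (f %in% regions[[rn]]) ov <- ov + areas[f]
    if (ov / patch_area >= min_overlap) hit <- c(hit, rn)
    if (ov > best_ov) {
      best_ov <- ov
      best <- rn
    }
  }
  if (length(hit) == 0L) hit <- best
  hit
}

#' Generate a synthetic annotated intensity image
#'
#' A two-level image: `background_level` everywhere, `signal_level` inside
#' the rasterised `signal_polygon`, plus isolated single-pixel "salt"
#' outliers at `salt_level` (no two salt pixels are adjacent, so a median
#' despeckle can remove them without touching the signal).  The truth mask
#' is the rasterised polygon.
#'
#' @param shape `c(rows, cols)` pixel dimensions.
#' @param signal_polygon k x 2 matrix of (x, y) vertices in pixel
#'   coordinates (x = column, y = row), inside the image bounds.
#' @param signal_level,background_level,salt_level intensities
#'   (arbitrary units; 16-bit range when written to TIFF).
#' @param salt_density fraction of pixels to corrupt (attempted; isolation
#'   may cap the achievable number).
#' @param rng_seed integer seed.
#' @return An object of class `annotated_image`: `pixels` (rows x cols
#'   matrix), `roi` (the polygon), and `truth` (`mask`, `area_px`,
#'   `salt_pixels`).
#' @export
generate_image <- function(shape, signal_polygon, signal_level = 200,
                           background_level = 100, salt_density = 0.01,
                           salt_level = 4095, rng_seed = 1L) {
  stopifnot(length(shape) == 2L)
  poly <- as.matrix(signal_polygon)
  if (nrow(unique(poly)) < 3L || polygon_area(poly) == 0)
    stop("degenerate signal polygon")
  if (any(poly[, 1] < 0 | poly[, 1] > shape[2] |
            poly[, 2] < 0 | poly[, 2] > shape[1]))
    stop("signal polygon outside image bounds")
  mask <- rasterise_polygon(poly, shape)
  img <- matrix(background_level, shape[1], shape[2])
  img[mask] <- signal_level
  salt <- matrix(FALSE, shape[1], shape[2])
  n_salt <- round(salt_density * prod(shape))
  if (n_salt > 0) {
    withr::with_seed(as.integer(rng_seed), {
      cand <- sample.int(prod(shape))
      taken <- matrix(FALSE, shape[1], shape[2])
      placed <- 0L
      for (ci in cand) {
        if (placed >= n_salt) break
        r <- ((ci - 1L) %% shape[1]) + 1L
        cc <- ((ci - 1L) %/% shape[1]) + 1L
        rr <- max(1L, r - 1L):min(shape[1], r + 1L)
        cr <- max(1L, cc - 1L):min(shape[2], cc + 1L)
        if (!any(taken[rr, cr])) {
          taken[r, cc] <- TRUE
          salt[r, cc] <- TRUE
          placed <- placed + 1L
        }
      }
    })
    img[salt] <- salt_level
  }
  structure(list(pixels = img, roi = poly,
                 truth = list(mask = mask, area_px = sum(mask),
                              salt_pixels = which(salt))),
            class = "annotated_image")
}

# Even-odd rule point-in-polygon for all pixel centers; pixel (r, c) has
# center (x = c - 0.5, y = r - 0.5).
rasterise_polygon <- function(poly, shape) {
  nr <- shape[1]; nc <- shape[2]
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, nc)
  inside <- logical(nr * nc)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Write / read an annotated image as 16-bit TIFF plus ROI CSV
#'
#' @param image an `annotated_image` (see [generate_image()]).
#' @param path_tiff output TIFF path; the ROI polygon is written next to
#'   it as `<path>.roi.csv` and the truth mask as `<path>.truth.csv`.
#' @param max_value full-scale intensity for the 16-bit encoding.
#' @return the TIFF path, invisibly.
#' @export
write_annotated_image <- function(image, path_tiff, max_value = 65535) {
  tiff::writeTIFF(pmin(image$pixels / max_value, 1), path_tiff,
                  bits.per.sample = 16L)
  utils::write.csv(data.frame(x = image$roi[, 1], y = image$roi[, 2]),
                   paste0(path_tiff, ".roi.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pixel = which(image$truth$mask)),
                   paste0(path_tiff, ".truth.csv"), row.names = FALSE)
  invisible(path_tiff)
}

#' @rdname write_annotated_image
#' @export
read_annotated_image <- function(path_tiff, max_value = 65535) {
  px <- tiff::readTIFF(path_tiff) * max_value
  roi_path <- paste0(path_tiff, ".roi.csv")
  roi <- NULL
  if (file.exists(roi_path)) {
    df <- utils::read.csv(roi_path)
    roi <- as.matrix(df[, c("x", "y")])
  }
  structure(list(pixels = round(px), roi = roi, truth = NULL),
            class = "annotated_image")
}
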