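#' Apply digital dye to a mesh
#'
#' Creates a labeled patch emulating a dye injection: all faces whose
#' vertices lie within geodesic `radius` of the seed point, plus the seed
#' face, restricted to the edge-connected component containing the seed
#' face (so a patch is always connected and never empty).  Patch
#' membership is face-granular: a face is in or out, and labels never
#' transfer between faces, which is what gives the model its no-cell-mixing
#' property.
#'
#' Each member face also receives a fixed number of uniformly drawn
#' barycentric sample points (seeded, reproducible) used later for metric
#' estimation, decoupling metric precision from mesh resolution.
#'
#' @param mesh a [stage_mesh] (the injection stage).
#' @param seed a [surface_point].
#' @param radius geodesic radius (model units, >= 0).
#' @param graph optional prebuilt [mesh_geodesic_graph()].
#' @param samples_per_face sample points per member triangle.
#' @param rng_seed seed for the barycentric samples.
#' @param zone,sample_id,stage injection metadata carried on the patch.
#' @return An object of class `dye_patch` with fields `faces` (sorted
#'   original face indices), `samples` (data frame: `tri`, `face`, `b1`,
#'   `b2`, `b3`, `sample_id`), `seed`, `zone`, `sample_id`, `stage`.
#' @export
inject_dye <- function(mesh, seed, radius, graph = NULL,
                       samples_per_face = 10L, rng_seed = 1L,
                       zone = NA_character_, sample_id = "patch",
                       stage = 0) {
  stopifnot(inherits(mesh, "stage_mesh"), inherits(seed, "surface_point"))
  if (radius < 0) stop("radius must be >= 0")
  faces <- integer(0)
  if (radius > 0) {
    d <- geodesic_distance(mesh, seed, graph = graph)
    ok <- vapply(mesh$faces, function(f) all(d[f] <= radius), logical(1))
    faces <- which(ok)
  }
  faces <- sort(unique(c(faces, seed$face)))
  if (length(faces) > 1L) {
    fg <- face_adjacency_graph(mesh)
    sub <- igraph::induced_subgraph(fg, faces)
    comp <- igraph::components(sub)
    keep <- comp$membership == comp$membership[match(seed$face, faces)]
    faces <- faces[keep]
  }
  tris <- which(mesh$tri_face %in% faces)
  withr::with_seed(as.integer(rng_seed), {
    n <- length(tris) * samples_per_face
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    B <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  })
  samples <- data.frame(tri = rep(tris, each = samples_per_face),
                        face = rep(mesh$tri_face[tris],
                                   each = samples_per_face),
                        b1 = B[, 1], b2 = B[, 2], b3 = B[, 3],
                        sample_id = seq_len(length(tris) * samples_per_face))
  structure(list(faces = faces, samples = samples, seed = seed,
                 zone = zone, sample_id = sample_id, stage = stage),
            class = "dye_patch")
}

#' @export
print.dye_patch <- function(x, ...) {
  cat(sprintf("<dye_patch '%s' zone %s: %d faces, %d samples, stage %s>\n",
              x$sample_id, x$zone, length(x$faces), nrow(x$samples),
              format(x$stage)))
  invisible(x)
}

#' Propagate a dye patch through the stage series
#'
#' Transport is correspondence-preserving: the patch keeps its face set
#' and barycentric samples exactly, and only its geometry is re-evaluated
#' on the interpolated mesh at stage parameter `s`.  Propagation is
#' therefore a bijection on face labels: disjoint patches stay disjoint at
#' every `s`, connected patches stay connected, and propagating to `s1`
#' then `s2` equals propagating directly to `s2`.
#'
#' @param patch a [dye_patch].
#' @param series a [stage_series] with the same topology as the patch's
#'   mesh.
#' @param s stage parameter in `[0, n_stages - 1]`.
#' @return A [dye_patch] at stage `s`, with `coords` (evaluated sample
#'   coordinates) and `mesh` (the interpolated stage mesh) attached.
#' @export
propagate_dye <- function(patch, series, s) {
  stopifnot(inherits(patch, "dye_patch"), inherits(series, "stage_series"))
  mesh <- interpolate_series(series, s)
  if (max(patch$samples$tri) > nrow(mesh$tri) ||
        max(patch$faces) > length(mesh$faces))
    stop("series/patch topology mismatch")
  out <- patch
  out$stage <- s
  out$coords <- embed_bary(mesh, patch$samples$tri,
                           as.matrix(patch$samples[, c("b1", "b2", "b3")]))
  out$mesh <- mesh
  out
}

#' Area of a dye patch on a mesh
#'
#' @param patch a [dye_patch].
#' @param mesh a [stage_mesh]; defaults to the mesh attached by
#'   [propagate_dye()].
#' @return total face area of the patch (model units squared).
#' @export
patch_area <- function(patch, mesh = patch$mesh) {
  if (is.null(mesh)) stop("patch has no attached mesh; pass one explicitly")
  sum(face_area(mesh, patch$faces))
}

# Evaluated sample coordinates of a patch on a given mesh.
patch_coords <- function(patch, mesh = patch$mesh) {
  if (!is.null(patch$coords) && identical(mesh, patch$mesh))
    return(patch$coords)
  if (is.null(mesh)) stop("patch has no attached mesh; pass one explicitly")
  embed_bary(mesh, patch$samples$tri,
             as.matrix(patch$samples[, c("b1", "b2", "b3")]))
}

#' Write / read a dye patch as CSV plus JSON metadata
#'
#' The CSV holds one row per sample point (`face_index`, `bary_a`,
#' `bary_b`, `bary_c`, `sample_id`, plus the triangle index); the JSON
#' sidecar records the face set, seed and injection metadata.
#'
#' @param patch a [dye_patch].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return the CSV path, invisibly.
#' @export
write_dye_patch <- function(patch, path) {
  df <- data.frame(face_index = patch$samples$face,
                   bary_a = patch$samples$b1, bary_b = patch$samples$b2,
                   bary_c = patch$samples$b3,
                   sample_id = patch$samples$sample_id,
                   tri = patch$samples$tri)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(faces = patch$faces,
               seed = list(tri = patch$seed$tri, bary = patch$seed$bary,
                           face = patch$seed$face),
               zone = patch$zone, sample_id = patch$sample_id,
               stage = patch$stage)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dye_patch
#' @export
read_dye_patch <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- data.frame(tri = df$tri, face = df$face_index, b1 = df$bary_a,
                        b2 = df$bary_b, b3 = df$bary_c,
                        sample_id = df$sample_id)
  structure(list(faces = as.integer(meta$faces),
                 samples = samples,
                 seed = surface_point(meta$seed$tri, meta$seed$bary,
                                      meta$seed$face),
                 zone = meta$zone, sample_id = meta$sample_id,
                 stage = meta$stage),
            class = "dye_patch")
}
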