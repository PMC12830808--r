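#' Construct a stage mesh
#'
#' A `stage_mesh` is one developmental snapshot of the 4D model: a surface
#' mesh whose vertices correspond one-to-one with the other stages of its
#' series.  Faces may be triangles or quads; quads are triangulated
#' internally by the (1,2,3)/(1,3,4) split, applied identically at every
#' stage so that correspondence survives triangulation.
#'
#' @param vertices numeric matrix, one row per vertex, three columns
#'   (model units).
#' @param faces integer matrix with 3 or 4 columns, or a list of integer
#'   vectors of length 3 or 4 (1-based vertex indices).
#' @param stage_label single character label, e.g. `"HH10"`.
#' @return An object of class `stage_mesh` with fields `vertices`, `faces`
#'   (list of integer vectors), `tri` (triangulated face matrix), `tri_face`
#'   (original face index of each triangle) and `stage_label`.
#' @export
stage_mesh <- function(vertices, faces, stage_label = "stage") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !is.numeric(vertices))
    stop("'vertices' must be a numeric matrix with 3 columns")
  storage.mode(vertices) <- "double"
  if (is.matrix(faces)) {
    faces <- lapply(seq_len(nrow(faces)), function(i) {
      f <- faces[i, ]
      as.integer(f[!is.na(f)])
    })
  }
  if (!is.list(faces) || length(faces) == 0L)
    stop("'faces' must be a non-empty matrix or list of vertex index tuples")
  faces <- lapply(faces, as.integer)
  sizes <- lengths(faces)
  if (any(sizes < 3L | sizes > 4L))
    stop("faces must have 3 or 4 vertices")
  idx <- unlist(faces, use.names = FALSE)
  if (any(idx < 1L) || any(idx > nrow(vertices)))
    stop("face vertex index out of range")
  if (any(vapply(faces, function(f) anyDuplicated(f) > 0L, logical(1))))
    stop("degenerate face (repeated vertex)")
  tri <- triangulate_faces(faces)
  m <- structure(
    list(vertices = vertices, faces = faces, tri = tri$tri,
         tri_face = tri$face, stage_label = as.character(stage_label)[1]),
    class = "stage_mesh")
  if (total_area(m) <= 0) stop("mesh has zero total surface area")
  m
}

# deterministic quad split: (1,2,3) and (1,3,4)
triangulate_faces <- function(faces) {
  n_tri <- sum(lengths(faces) - 2L)
  tri <- matrix(0L, n_tri, 3)
  face_of <- integer(n_tri)
  k <- 0L
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    tri[k + 1L, ] <- f[c(1L, 2L, 3L)]
    face_of[k + 1L] <- i
    k <- k + 1L
    if (length(f) == 4L) {
      tri[k + 1L, ] <- f[c(1L, 3L, 4L)]
      face_of[k + 1L] <- i
      k <- k + 1L
    }
  }
  list(tri = tri, face = face_of)
}

#' @export
print.stage_mesh <- function(x, ...) {
  cat(sprintf("<stage_mesh '%s': %d vertices, %d faces (%d triangles)>\n",
              x$stage_label, nrow(x$vertices), length(x$faces), nrow(x$tri)))
  invisible(x)
}

#' Construct a stage series
#'
#' An ordered set of corresponding stage meshes (the model's shape keys).
#' All stages must share an identical face list and vertex count; vertex
#' `i` corresponds across stages.  The stage parameter `s` used by
#' [interpolate_series()] spans `[0, n_stages - 1]`, one unit per stage
#' interval; it is ordinal, not developmental time.
#'
#' @param meshes list of [stage_mesh] objects with identical topology.
#' @return An object of class `stage_series`.
#' @export
stage_series <- function(meshes) {
  if (!is.list(meshes) || length(meshes) < 1L)
    stop("'meshes' must be a non-empty list of stage_mesh objects")
  if (!all(vapply(meshes, inherits, logical(1), "stage_mesh")))
    stop("all elements must be stage_mesh objects")
  ser <- structure(list(meshes = meshes), class = "stage_series")
  rep <- validate_series(ser)
  if (nrow(rep) > 0L)
    stop("invalid stage series:\n", paste(rep$message, collapse = "\n"))
  ser
}

#' Number of stages in a series
#' @param series a [stage_series].
#' @return integer count.
#' @export
n_stages <- function(series) length(series$meshes)

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("<stage_series: %d stages [%s], %d vertices, %d faces>\n",
              n_stages(x),
              paste(vapply(x$meshes, `[[`, character(1), "stage_label"),
                    collapse = ", "),
              nrow(x$meshes[[1]]$vertices), length(x$meshes[[1]]$faces)))
  invisible(x)
}

#' Validate a stage series
#'
#' Checks the series invariants (shared topology, in-range face indices,
#' non-degenerate faces, unique labels, positive area) and reports every
#' violation found.  Validation never throws.
#'
#' @param series a [stage_series] or bare list of [stage_mesh] objects.
#' @return A data frame with columns `stage`, `check`, `message`; zero rows
#'   if and only if all invariants hold.
#' @export
validate_series <- function(series) {
  meshes <- if (inherits(series, "stage_series")) series$meshes else series
  bad <- list()
  note <- function(stage, check, message)
    bad[[length(bad) + 1L]] <<- data.frame(stage = stage, check = check,
                                           message = message)
  ref <- meshes[[1]]
  labels <- vapply(meshes, `[[`, character(1), "stage_label")
  if (anyDuplicated(labels))
    note(NA_integer_, "labels", "stage labels are not unique")
  for (k in seq_along(meshes)) {
    m <- meshes[[k]]
    if (nrow(m$vertices) != nrow(ref$vertices))
      note(k - 1L, "topology",
           sprintf("stage %d: vertex count %d differs from stage 0 (%d)",
                   k - 1L, nrow(m$vertices), nrow(ref$vertices)))
    if (!identical(m$faces, ref$faces))
      note(k - 1L, "topology",
           sprintf("stage %d: face list differs from stage 0", k - 1L))
    idx <- unlist(m$faces, use.names = FALSE)
    if (any(idx < 1L | idx > nrow(m$vertices)))
      note(k - 1L, "face-index",
           sprintf("stage %d: face vertex index out of range", k - 1L))
    if (any(vapply(m$faces, function(f) anyDuplicated(f) > 0L, logical(1))))
      note(k - 1L, "degenerate-face",
           sprintf("stage %d: face with repeated vertex", k - 1L))
    if (total_area(m) <= 0)
      note(k - 1L, "area", sprintf("stage %d: zero total area", k - 1L))
  }
  if (length(bad) == 0L)
    return(data.frame(stage = integer(0), check = character(0),
                      message = character(0)))
  do.call(rbind, bad)
}

#' Interpolate a stage series at a stage parameter
#'
#' Piecewise-linear shape-key blend: for `s` between integer stages `k` and
#' `k + 1`, the vertex array is `(1 - t) * V_k + t * V_{k+1}` with
#' `t = s - k`; faces are unchanged.  Integer `s` returns that stage's
#' vertex array bit-exactly.
#'
#' @param series a [stage_series].
#' @param s stage parameter in `[0, n_stages - 1]`.
#' @return A [stage_mesh] at parameter `s`.
#' @export
interpolate_series <- function(series, s) {
  stopifnot(inherits(series, "stage_series"), is.numeric(s), length(s) == 1L)
  n <- n_stages(series)
  if (is.na(s) || s < 0 || s > n - 1)
    stop(sprintf("stage parameter s = %g out of range [0, %d]", s, n - 1L))
  k <- floor(s)
  t <- s - k
  if (t == 0) return(series$meshes[[k + 1L]])
  a <- series$meshes[[k + 1L]]
  b <- series$meshes[[k + 2L]]
  out <- a
  out$vertices <- (1 - t) * a$vertices + t * b$vertices
  out$stage_label <- sprintf("s=%g", s)
  out
}

#' Face and total surface areas
#'
#' Triangle areas are half the cross-product magnitude; quad faces are the
#' sum of their two triangles under the fixed (1,2,3)/(1,3,4) split.
#'
#' @param mesh a [stage_mesh].
#' @param face optional integer vector of face indices (default: all faces).
#' @return `face_area`: numeric vector of areas (model units squared);
#'   `total_area`: their sum.
#' @export
face_area <- function(mesh, face = seq_along(mesh$faces)) {
  face <- as.integer(face)
  if (any(face < 1L | face > length(mesh$faces)))
    stop("face index out of range")
  ta <- triangle_areas(mesh)
  as.numeric(rowsum(ta, mesh$tri_face)[as.character(face), ])
}

triangle_areas <- function(mesh) {
  V <- mesh$vertices
  a <- V[mesh$tri[, 1], , drop = FALSE]
  u <- V[mesh$tri[, 2], , drop = FALSE] - a
  w <- V[mesh$tri[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_area
#' @export
total_area <- function(mesh) sum(triangle_areas(mesh))

#' Construct a surface point
#'
#' A point on the mesh expressed as barycentric coordinates on one triangle
#' of the internal triangulation.  This is the carrier used to transport
#' sample points exactly through shape-key interpolation.
#'
#' @param tri triangle index (into `mesh$tri`).
#' @param bary length-3 barycentric coordinates, each in `[0, 1]`, summing
#'   to 1 (tolerance 1e-9).
#' @param face original face index (defaults to `tri` for pure-triangle
#'   meshes; filled in by [locate_point()]).
#' @return An object of class `surface_point`.
#' @export
surface_point <- function(tri, bary, face = tri) {
  bary <- as.numeric(bary)
  if (length(bary) != 3L || any(bary < -1e-9) || abs(sum(bary) - 1) > 1e-9)
    stop("barycentric coordinates must be in [0,1] and sum to 1")
  structure(list(tri = as.integer(tri), bary = pmax(bary, 0),
                 face = as.integer(face)),
            class = "surface_point")
}

#' Embed a surface point into 3D coordinates
#'
#' @param mesh a [stage_mesh].
#' @param point a [surface_point] (or list of them).
#' @return numeric length-3 coordinate, or a matrix for a list of points.
#' @export
embed_point <- function(mesh, point) {
  if (inherits(point, "surface_point")) {
    v <- mesh$tri[point$tri, ]
    return(as.numeric(point$bary %*% mesh$vertices[v, , drop = FALSE]))
  }
  t(vapply(point, function(p) embed_point(mesh, p), numeric(3)))
}

# Barycentric evaluation for many samples at once: tri (int vector),
# B (n x 3 barycentric rows) -> n x 3 coordinates.
embed_bary <- function(mesh, tri, B) {
  V <- mesh$vertices
  B[, 1] * V[mesh$tri[tri, 1], , drop = FALSE] +
    B[, 2] * V[mesh$tri[tri, 2], , drop = FALSE] +
    B[, 3] * V[mesh$tri[tri, 3], , drop = FALSE]
}

#' Closest-point projection onto a mesh
#'
#' Exhaustive per-triangle closest-point search (no spatial acceleration):
#' every triangle's closest point to the query is computed and the minimum
#' taken.  Ties (a point equidistant to two faces) are broken by the lowest
#' triangle index, so results are deterministic.
#'
#' @param mesh a [stage_mesh].
#' @param point numeric length-3 query coordinate.
#' @return A [surface_point]; its `face` field holds the original face
#'   index of the winning triangle.
#' @export
locate_point <- function(mesh, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L)
  if (length(mesh$faces) == 0L) stop("empty mesh")
  cp <- closest_point_all_tris(mesh, point)
  d2 <- rowSums((cp$P - rep(point, each = nrow(cp$P)))^2)
  i <- which.min(d2)   # first minimum = lowest triangle index
  b1 <- 1 - cp$s[i] - cp$t[i]
  bary <- c(b1, cp$s[i], cp$t[i])
  bary <- pmin(pmax(bary, 0), 1)
  bary <- bary / sum(bary)
  surface_point(i, bary, face = mesh$tri_face[i])
}

# Vectorised closest point on every triangle (Ericson's region method).
# Returns list(P = m x 3 closest points, s, t = edge parameters such that
# closest = A + s*(B-A) + t*(C-A)).
closest_point_all_tris <- function(mesh, p) {
  V <- mesh$vertices
  A <- V[mesh$tri[, 1], , drop = FALSE]
  B <- V[mesh$tri[, 2], , drop = FALSE]
  C <- V[mesh$tri[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  m <- nrow(A)
  P <- matrix(p, m, 3, byrow = TRUE)
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  s <- numeric(m); t <- numeric(m)
  done <- logical(m)
  # vertex A region
  sel <- !done & d1 <= 0 & d2 <= 0
  done <- done | sel
  # vertex B region
  sel <- !done & d3 >= 0 & d4 <= d3
  s[sel] <- 1
  done <- done | sel
  # edge AB region
  sel <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  s[sel] <- d1[sel] / (d1[sel] - d3[sel])
  done <- done | sel
  # vertex C region
  sel <- !done & d6 >= 0 & d5 <= d6
  t[sel] <- 1
  done <- done | sel
  # edge AC region
  sel <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  t[sel] <- d2[sel] / (d2[sel] - d6[sel])
  done <- done | sel
  # edge BC region
  sel <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  w <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
  s[sel] <- 1 - w
  t[sel] <- w
  done <- done | sel
  # interior
  sel <- !done
  denom <- va[sel] + vb[sel] + vc[sel]
  s[sel] <- vb[sel] / denom
  t[sel] <- vc[sel] / denom
  list(P = A + s * ab + t * ac, s = s, t = t)
}

#' Build the geodesic graph of a mesh
#'
#' Geodesic distances are graph shortest paths.  With `n_steiner = 0` the
#' graph is the plain vertex/edge graph (edge weights = Euclidean edge
#' lengths), which overestimates surface distance by up to ~15% depending
#' on direction.  With `n_steiner > 0`, each edge gains that many evenly
#' spaced auxiliary nodes and every pair of boundary nodes of each triangle
#' is connected by a straight in-face segment (a Steiner-point graph); this
#' converges to the true polyhedral geodesic as density grows and is within
#' ~1% on a refined sphere at the default of 3 points per edge.
#'
#' Building the graph is the expensive step; callers that query many
#' sources on the same mesh should build once and pass the result to
#' [geodesic_distance()] or [inject_dye()].
#'
#' @param mesh a [stage_mesh].
#' @param n_steiner auxiliary nodes per edge (non-negative integer).
#' @return An object of class `geodesic_graph` wrapping an igraph graph,
#'   the node coordinates and the number of original mesh vertices.
#' @export
mesh_geodesic_graph <- function(mesh, n_steiner = 3L) {
  n_steiner <- as.integer(n_steiner)
  stopifnot(n_steiner >= 0L)
  V <- mesh$vertices
  F3 <- mesh$tri
  nv <- nrow(V)
  E3 <- rbind(F3[, c(1, 2)], F3[, c(2, 3)], F3[, c(3, 1)])
  key <- paste(pmin(E3[, 1], E3[, 2]), pmax(E3[, 1], E3[, 2]))
  uk <- !duplicated(key)
  ea <- pmin(E3[uk, 1], E3[uk, 2])
  eb <- pmax(E3[uk, 1], E3[uk, 2])
  ne <- length(ea)
  edge_id <- seq_len(ne)
  names(edge_id) <- key[uk]
  if (n_steiner == 0L) {
    w <- sqrt(rowSums((V[ea, , drop = FALSE] - V[eb, , drop = FALSE])^2))
    g <- igraph::make_graph(rbind(ea, eb), n = nv, directed = FALSE)
    igraph::E(g)$weight <- w
    return(structure(list(graph = g, coords = V, n_vertices = nv,
                          n_steiner = 0L), class = "geodesic_graph"))
  }
  s <- n_steiner
  tpar <- seq_len(s) / (s + 1)
  SP <- matrix(0, ne * s, 3)
  for (k in seq_len(s))
    SP[(edge_id - 1L) * s + k, ] <-
      V[ea, , drop = FALSE] * (1 - tpar[k]) + V[eb, , drop = FALSE] * tpar[k]
  coords <- rbind(V, SP)
  eid_of <- function(a, b) edge_id[paste(pmin(a, b), pmax(a, b))]
  fe <- cbind(eid_of(F3[, 1], F3[, 2]), eid_of(F3[, 2], F3[, 3]),
              eid_of(F3[, 3], F3[, 1]))
  sids <- function(j) {
    base <- nv + (j - 1L) * s
    matrix(base, length(j), s) + matrix(seq_len(s), length(j), s, byrow = TRUE)
  }
  bnd <- cbind(F3, sids(fe[, 1]), sids(fe[, 2]), sids(fe[, 3]))
  nb <- ncol(bnd)
  cmb <- utils::combn(nb, 2)
  from <- as.vector(bnd[, cmb[1, ]])
  to <- as.vector(bnd[, cmb[2, ]])
  pk <- paste(pmin(from, to), pmax(from, to))
  keep <- !duplicated(pk)
  from <- from[keep]; to <- to[keep]
  w <- sqrt(rowSums((coords[from, , drop = FALSE] -
                       coords[to, , drop = FALSE])^2))
  g <- igraph::make_graph(rbind(from, to), n = nrow(coords), directed = FALSE)
  igraph::E(g)$weight <- w
  structure(list(graph = g, coords = coords, n_vertices = nv,
                 n_steiner = s), class = "geodesic_graph")
}

#' Geodesic distances on a mesh
#'
#' Shortest-path distance on the (Steiner-augmented) mesh graph from a
#' source to a set of target vertices.  A [surface_point] source is
#' embedded by connecting it to the boundary nodes of its triangle; a set
#' of source vertices yields the distance to the nearest source.
#' Disconnected targets receive `Inf`.
#'
#' @param mesh a [stage_mesh].
#' @param source a [surface_point], or an integer vector of source vertex
#'   indices.
#' @param targets integer vector of target vertex indices (default: all).
#' @param graph optional prebuilt [mesh_geodesic_graph()]; built on the fly
#'   when `NULL`.
#' @param n_steiner passed to [mesh_geodesic_graph()] when building.
#' @return numeric vector of distances, one per target.
#' @export
geodesic_distance <- function(mesh, source,
                              targets = seq_len(nrow(mesh$vertices)),
                              graph = NULL, n_steiner = 3L) {
  if (is.null(graph)) graph <- mesh_geodesic_graph(mesh, n_steiner)
  targets <- as.integer(targets)
  if (any(targets < 1L | targets > graph$n_vertices))
    stop("target vertex index out of range")
  if (inherits(source, "surface_point")) {
    # distances from the three corner vertices of the source triangle,
    # plus in-face straight segments from the embedded point.
    p <- embed_point(mesh, source)
    vs <- mesh$tri[source$tri, ]
    D <- igraph::distances(graph$graph, v = vs, to = targets,
                           algorithm = "dijkstra")
    off <- sqrt(rowSums((graph$coords[vs, , drop = FALSE] -
                           rep(p, each = 3))^2))
    # also route through Steiner nodes of the source triangle's edges
    if (graph$n_steiner > 0L) {
      sn <- source_triangle_steiner_nodes(mesh, graph, source$tri)
      if (length(sn) > 0L) {
        D2 <- igraph::distances(graph$graph, v = sn, to = targets,
                                algorithm = "dijkstra")
        off2 <- sqrt(rowSums((graph$coords[sn, , drop = FALSE] -
                                rep(p, each = length(sn)))^2))
        D <- rbind(D, D2)
        off <- c(off, off2)
      }
    }
    return(apply(D + off, 2, min))
  }
  source <- as.integer(source)
  if (any(source < 1L | source > graph$n_vertices))
    stop("source vertex index out of range")
  D <- igraph::distances(graph$graph, v = source, to = targets,
                         algorithm = "dijkstra")
  if (length(source) == 1L) as.numeric(D[1, ]) else apply(D, 2, min)
}

# Steiner node ids lying on the three edges of a given triangle.
source_triangle_steiner_nodes <- function(mesh, graph, tri) {
  s <- graph$n_steiner
  if (s == 0L) return(integer(0))
  F3 <- mesh$tri
  E3 <- rbind(F3[, c(1, 2)], F3[, c(2, 3)], F3[, c(3, 1)])
  key <- paste(pmin(E3[, 1], E3[, 2]), pmax(E3[, 1], E3[, 2]))
  uk <- !duplicated(key)
  edge_id <- seq_len(sum(uk))
  names(edge_id) <- key[uk]
  v <- F3[tri, ]
  ks <- paste(pmin(v, v[c(2, 3, 1)]), pmax(v, v[c(2, 3, 1)]))
  ids <- edge_id[ks]
  nv <- graph$n_vertices
  as.integer(outer((ids - 1L) * s + nv, seq_len(s), `+`))
}

# Face adjacency (original faces sharing an edge) as an igraph graph.
face_adjacency_graph <- function(mesh) {
  edges <- list()
  F3 <- mesh$tri
  E3 <- rbind(F3[, c(1, 2)], F3[, c(2, 3)], F3[, c(3, 1)])
  fid <- rep(mesh$tri_face, 3)
  key <- paste(pmin(E3[, 1], E3[, 2]), pmax(E3[, 1], E3[, 2]))
  sp <- split(fid, key)
  pairs <- lapply(sp, function(fs) {
    fs <- unique(fs)
    if (length(fs) < 2L) return(NULL)
    t(utils::combn(fs, 2))
  })
  pairs <- do.call(rbind, pairs)
  g <- igraph::make_empty_graph(n = length(mesh$faces), directed = FALSE)
  if (!is.null(pairs) && nrow(pairs) > 0L)
    g <- igraph::add_edges(g, t(pairs))
  g
}

# Edges appearing in more than two faces => non-manifold.
is_manifold <- function(mesh) {
  F3 <- mesh$tri
  E3 <- rbind(F3[, c(1, 2)], F3[, c(2, 3)], F3[, c(3, 1)])
  fid <- rep(mesh$tri_face, 3)
  key <- paste(pmin(E3[, 1], E3[, 2]), pmax(E3[, 1], E3[, 2]))
  counts <- vapply(split(fid, key), function(fs) length(unique(fs)),
                   integer(1))
  all(counts <= 2L)
}
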