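#' Built-in mesh primitives
#'
#' Simple parametric surfaces used as synthetic base meshes: an open-ended
#' tube (neural-tube analogue, axis along x), a hemisphere, an icosphere
#' and a flat rectangular grid.  All are triangle meshes with deterministic
#' vertex ordering.
#'
#' @param length tube length along x (model units).
#' @param radius tube / sphere radius.
#' @param n_axial number of vertex rings along the tube axis.
#' @param n_around number of vertices per ring.
#' @param stage_label label for the returned [stage_mesh].
#' @return A [stage_mesh].
#' @name primitives
NULL

#' @rdname primitives
#' @export
mesh_tube <- function(length = 10, radius = 1, n_axial = 24, n_around = 16,
                      stage_label = "tube") {
  stopifnot(n_axial >= 2, n_around >= 3)
  x <- seq(0, length, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  V <- cbind(rep(x, each = n_around),
             radius * cos(rep(th, n_axial)),
             radius * sin(rep(th, n_axial)))
  idx <- function(i, j) (i - 1L) * n_around + ((j - 1L) %% n_around) + 1L
  faces <- vector("list", 2L * (n_axial - 1L) * n_around)
  k <- 0L
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_around)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      faces[[k + 1L]] <- c(a, b, c2)
      faces[[k + 2L]] <- c(a, c2, d)
      k <- k + 2L
    }
  }
  stage_mesh(V, faces, stage_label)
}

#' @rdname primitives
#' @export
mesh_hemisphere <- function(radius = 1, n_axial = 8, n_around = 16,
                            stage_label = "hemisphere") {
  stopifnot(n_axial >= 2, n_around >= 3)
  phi <- seq(0, pi / 2, length.out = n_axial + 1L)  # 0 = pole
  th <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  V <- matrix(c(0, 0, radius), 1, 3)
  for (i in 2:(n_axial + 1L))
    V <- rbind(V, cbind(radius * sin(phi[i]) * cos(th),
                        radius * sin(phi[i]) * sin(th),
                        radius * cos(phi[i])))
  ring <- function(i, j) 1L + (i - 2L) * n_around + ((j - 1L) %% n_around) + 1L
  faces <- list()
  for (j in seq_len(n_around))
    faces[[length(faces) + 1L]] <- c(1L, ring(2L, j), ring(2L, j + 1L))
  for (i in 2:n_axial) {
    for (j in seq_len(n_around)) {
      a <- ring(i, j); b <- ring(i, j + 1L)
      c2 <- ring(i + 1L, j + 1L); d <- ring(i + 1L, j)
      faces[[length(faces) + 1L]] <- c(a, b, c2)
      faces[[length(faces) + 1L]] <- c(a, c2, d)
    }
  }
  stage_mesh(V, faces, stage_label)
}

#' @rdname primitives
#' @param subdiv icosphere subdivision level (0 = icosahedron; each level
#'   quadruples the face count).
#' @export
mesh_icosphere <- function(subdiv = 3, radius = 1, stage_label = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F3 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    nv <- nrow(V)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ks <- c(key(F3[, 1], F3[, 2]), key(F3[, 2], F3[, 3]), key(F3[, 3], F3[, 1]))
    uk <- unique(ks)
    mid_id <- stats::setNames(nv + seq_along(uk), uk)
    pr <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
    a <- as.integer(pr[, 1]); b <- as.integer(pr[, 2])
    M <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
    M <- M / sqrt(rowSums(M^2))
    V <- rbind(V, M)
    m1 <- mid_id[key(F3[, 1], F3[, 2])]
    m2 <- mid_id[key(F3[, 2], F3[, 3])]
    m3 <- mid_id[key(F3[, 3], F3[, 1])]
    F3 <- rbind(cbind(F3[, 1], m1, m3), cbind(F3[, 2], m2, m1),
                cbind(F3[, 3], m3, m2), cbind(m1, m2, m3))
  }
  stage_mesh(V * radius, F3, stage_label)
}

#' @rdname primitives
#' @param width,height extents of the flat grid in x and y.
#' @param nx,ny vertex counts along x and y.
#' @export
mesh_grid <- function(width = 10, height = 10, nx = 21, ny = 21,
                      stage_label = "grid") {
  stopifnot(nx >= 2, ny >= 2)
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  V <- cbind(rep(xs, each = ny), rep(ys, nx), 0)
  idx <- function(i, j) (i - 1L) * ny + j
  faces <- vector("list", 2L * (nx - 1L) * (ny - 1L))
  k <- 0L
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(ny - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[[k + 1L]] <- c(a, b, c2)
      faces[[k + 2L]] <- c(a, c2, d)
      k <- k + 2L
    }
  }
  stage_mesh(V, faces, stage_label)
}
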