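# Geometry kernel: construction, interpolation, areas, projection,
# geodesics, file IO.

test_that("mesh construction rejects malformed input", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(stage_mesh(V, list(c(1, 2, 4))), "out of range")
  expect_error(stage_mesh(V, list(c(1, 2, 2))), "degenerate")
  expect_error(stage_mesh(V, list(c(1, 2))), "3 or 4 vertices")
  expect_silent(m <- stage_mesh(V, list(c(1, 2, 3))))
})

test_that("series validation reports violations without throwing", {
  m <- small_tube()
  ok <- stage_series(list(m))
  expect_identical(nrow(validate_series(ok)), 0L)

  m2 <- m
  m2$faces <- m$faces[-1]
  m2$stage_label <- "other"
  rep <- validate_series(list(m, m2))
  expect_true(any(rep$check == "topology"))

  m3 <- m
  m3$faces[[1]] <- c(1L, 2L, nrow(m$vertices) + 1L)
  m3$stage_label <- "bad"
  rep <- validate_series(list(m, m3))
  expect_true(any(rep$check %in% c("face-index", "topology")))

  rep <- validate_series(list(m, m))  # duplicate labels
  expect_true(any(rep$check == "labels"))
})

test_that("interpolation is exact at integer stages and linear between", {
  for (seed in 1:5) {
    ser <- random_series(seed)
    for (k in seq_len(n_stages(ser)) - 1L) {
      expect_identical(interpolate_series(ser, k)$vertices,
                       ser$meshes[[k + 1]]$vertices)
    }
    withr::with_seed(seed, s <- runif(3, 0, n_stages(ser) - 1))
    for (si in s) {
      k <- floor(si)
      t <- si - k
      expected <- (1 - t) * ser$meshes[[k + 1]]$vertices +
        t * ser$meshes[[min(k + 2, n_stages(ser))]]$vertices
      expect_equal(interpolate_series(ser, si)$vertices, expected,
                   tolerance = 1e-12)
    }
  }
  ser <- random_series(1)
  expect_error(interpolate_series(ser, -0.1), "out of range")
  expect_error(interpolate_series(ser, n_stages(ser)), "out of range")
})

test_that("interpolating a constant series returns the base mesh", {
  m <- small_tube()
  m2 <- m
  m2$stage_label <- "same"
  ser <- stage_series(list(m, m2))
  expect_equal(interpolate_series(ser, 0.37)$vertices, m$vertices)
})

test_that("face areas match independent oracles", {
  tri <- stage_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    list(c(1, 2, 3)))
  expect_equal(face_area(tri, 1), 0.5)
  tri3 <- stage_mesh(3 * tri$vertices, list(c(1, 2, 3)))
  expect_equal(face_area(tri3, 1), 4.5)

  withr::with_seed(7, {
    for (i in 1:25) {
      V <- matrix(rnorm(9), 3, 3)
      m <- stage_mesh(V, list(c(1, 2, 3)))
      expect_equal(face_area(m, 1), heron_area(V[1, ], V[2, ], V[3, ]),
                   tolerance = 1e-9)
    }
  })

  # quad area equals the sum of its two split triangles
  V <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(0, 1, 0))
  q <- stage_mesh(V, list(c(1, 2, 3, 4)))
  expect_equal(face_area(q, 1), 2)
  expect_equal(total_area(q), 2)
})

test_that("total area scales as the square of a uniform scale", {
  m <- small_tube()
  for (k in c(0.5, 2, 3.7)) {
    mk <- m
    mk$vertices <- k * m$vertices
    expect_equal(total_area(mk), k^2 * total_area(m),
                 tolerance = 1e-9)
  }
})

test_that("closest-point projection matches vertices, centroids and an
           independent per-face search", {
  m <- small_tube()
  v10 <- m$vertices[10, ]
  sp <- locate_point(m, v10)
  expect_equal(sort(sp$bary)[3], 1, tolerance = 1e-12)
  expect_equal(embed_point(m, sp), v10, tolerance = 1e-12)

  f <- 17L
  tri_i <- which(m$tri_face == f)[1]
  centroid <- colMeans(m$vertices[m$tri[tri_i, ], ])
  sp <- locate_point(m, centroid)
  expect_equal(sp$bary, rep(1 / 3, 3), tolerance = 1e-9)

  withr::with_seed(11, {
    for (i in 1:60) {
      p <- rnorm(3, sd = 2)
      sp <- locate_point(m, p)
      d_pkg <- sqrt(sum((embed_point(m, sp) - p)^2))
      expect_equal(d_pkg, closest_point_oracle(m, p), tolerance = 1e-9)
    }
  })
})

test_that("geodesic distances obey metric axioms and basic identities", {
  m <- small_tube()
  g <- mesh_geodesic_graph(m, 2)
  d_self <- geodesic_distance(m, 5L, targets = 5L, graph = g)
  expect_equal(d_self, 0)

  # adjacent vertices: distance equals the straight edge length
  e <- m$tri[1, 1:2]
  d <- geodesic_distance(m, e[1], targets = e[2], graph = g)
  expect_equal(d, sqrt(sum((m$vertices[e[1], ] - m$vertices[e[2], ])^2)),
               tolerance = 1e-9)

  withr::with_seed(3, vs <- sample.int(nrow(m$vertices), 5))
  D <- sapply(vs, function(v)
    geodesic_distance(m, v, targets = vs, graph = g))
  expect_equal(D, t(D), tolerance = 1e-9)          # symmetry
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-9)  # triangle inequality
})

test_that("sphere antipodal geodesic approaches the great-circle limit", {
  sph <- mesh_icosphere(3)
  g <- mesh_geodesic_graph(sph, 3)
  src <- locate_point(sph, c(0, 0, 1.5))
  d <- geodesic_distance(sph, src, graph = g)
  expect_equal(max(d), pi, tolerance = 0.02)
})

test_that("disconnected targets are flagged with infinite distance", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 5, 0), c(6, 5, 0), c(5, 6, 0))
  m <- stage_mesh(V, list(c(1, 2, 3), c(4, 5, 6)))
  d <- geodesic_distance(m, 1L, graph = mesh_geodesic_graph(m, 1))
  expect_true(all(is.infinite(d[4:6])))
  expect_true(all(is.finite(d[1:3])))
})

test_that("OBJ and PLY round-trips preserve geometry and topology", {
  m <- small_tube()
  tmp <- withr::local_tempdir()
  obj <- file.path(tmp, "m.obj")
  write_mesh_obj(m, obj)
  m2 <- read_mesh_obj(obj)
  expect_equal(m2$vertices, m$vertices)
  expect_identical(m2$faces, m$faces)

  ply <- file.path(tmp, "m.ply")
  write_mesh_ply(m, ply)
  m3 <- read_mesh_ply(ply)
  expect_equal(m3$vertices, m$vertices)
  expect_identical(m3$faces, m$faces)
})

test_that("series manifests round-trip and strict mode rejects mismatches", {
  ser <- random_series(2)
  tmp <- withr::local_tempdir()
  man <- write_stage_series(ser, file.path(tmp, "ser"))
  back <- read_stage_series(man)
  for (k in seq_len(n_stages(ser)))
    expect_equal(back$meshes[[k]]$vertices, ser$meshes[[k]]$vertices)

  # corrupt one stage's face block
  files <- list.files(file.path(tmp, "ser"), pattern = "obj$",
                      full.names = TRUE)
  lines <- readLines(files[2])
  fl <- grep("^f ", lines)
  lines <- lines[-fl[1]]
  writeLines(lines, files[2])
  expect_error(read_stage_series(man), "strict")
})
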