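# Synthetic-embryo generators: deformation fields, injections, images.

test_that("a zero-parameter deformation spec yields an identity series", {
  base <- small_tube()
  spec <- deformation_spec(base, n_stages = 4)
  gen <- generate_stage_series(spec)
  for (k in seq_len(4))
    expect_identical(gen$series$meshes[[k]]$vertices, base$vertices)
  expect_identical(nrow(validate_series(gen$series)), 0L)
})

test_that("series generation is bit-identical under the same seed", {
  a <- random_series(42, with_attractor = TRUE)
  b <- random_series(42, with_attractor = TRUE)
  for (k in seq_len(n_stages(a)))
    expect_identical(a$meshes[[k]]$vertices, b$meshes[[k]]$vertices)
})

test_that("an isotropic zone scales a vertex about the zone centroid", {
  base <- small_tube()
  zone <- 1:20
  spec <- deformation_spec(base, n_stages = 3,
                           isotropic_zones = list(list(vertices = zone,
                                                       scale = 2)))
  gen <- generate_stage_series(spec)
  cc <- colMeans(base$vertices[zone, ])
  v <- base$vertices[7, ]
  # final stage: c + 2 (v - c), evaluated by hand
  expect_equal(gen$series$meshes[[3]]$vertices[7, ],
               cc + 2 * (v - cc), tolerance = 1e-12)
  # intermediate stage ramps the factor linearly: scale 1.5 at tau = 0.5
  expect_equal(gen$series$meshes[[2]]$vertices[7, ],
               cc + 1.5 * (v - cc), tolerance = 1e-12)
})

test_that("deformation specs reject bad meshes and bad masks", {
  base <- small_tube()
  expect_error(deformation_spec(base,
                                isotropic_zones = list(list(
                                  vertices = nrow(base$vertices) + 1L,
                                  scale = 2))),
               "invalid vertices")
  # non-manifold: three faces sharing one edge
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  bad <- stage_mesh(V, list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(deformation_spec(bad), "non-manifold")
  expect_error(deformation_spec(base, attractor_strength = 1),
               "attractor_point")
})

test_that("injection sets hit every zone with the requested count and
           deterministic centroid seeds at zero jitter", {
  ser <- random_series(5)
  mesh0 <- ser$meshes[[1]]
  zones <- tube_zones(mesh0)
  expect_length(zones, 12L)
  expect_setequal(unlist(zones), seq_along(mesh0$faces))

  g <- mesh_geodesic_graph(mesh0)
  inj <- generate_injection_set(ser, zones, n_per_zone = 3, jitter = 0,
                                rng_seed = 9, radius = 0.4, graph = g)
  expect_length(inj$records, 36L)

  # zero jitter: seed is the zone-centroid projection
  areas <- face_area(mesh0)
  z1 <- zones[["1"]]
  cents <- t(sapply(z1, function(f)
    colMeans(mesh0$vertices[mesh0$faces[[f]], ])))
  zcent <- colSums(cents * areas[z1]) / sum(areas[z1])
  expected_seed <- locate_point(mesh0, zcent)
  rec1 <- inj$records[[which(vapply(inj$records, `[[`, character(1),
                                    "zone") == "1")[1]]]
  expect_identical(rec1$seed$tri, expected_seed$tri)
  expect_equal(rec1$seed$bary, expected_seed$bary, tolerance = 1e-12)

  # same seed twice: identical records
  inj2 <- generate_injection_set(ser, zones, n_per_zone = 3, jitter = 0,
                                 rng_seed = 9, radius = 0.4, graph = g)
  expect_identical(lapply(inj$records, `[[`, "patch"),
                   lapply(inj2$records, `[[`, "patch"))

  expect_error(generate_injection_set(ser, c(zones, list(z0 = integer(0))),
                                      graph = g),
               "empty zone")
  expect_warning(generate_injection_set(ser, zones["1"], n_per_zone = 1,
                                        jitter = 100, rng_seed = 1,
                                        radius = 0.4, graph = g),
                 "clamped")
})

test_that("a zone wholly inside one region's preimage yields that region
           as ground truth for all its records", {
  base <- small_tube()
  spec <- deformation_spec(base, n_stages = 2)
  ser <- generate_stage_series(spec)$series
  zones <- tube_zones(base)
  # one big region covering everything plus a decoy covering nothing near
  # zone 1 (anterior-ventral faces only)
  all_faces <- seq_along(base$faces)
  cent <- t(sapply(base$faces, function(f)
    colMeans(base$vertices[f, , drop = FALSE])))
  post <- which(cent[, 1] > 5.2)
  regions <- outcome_regions(list(T1 = all_faces, D1 = post), base)
  g <- mesh_geodesic_graph(base)
  inj <- generate_injection_set(ser, zones["1"], n_per_zone = 4,
                                jitter = 0.3, rng_seed = 3, radius = 0.3,
                                regions = regions, graph = g)
  for (tr in inj$truth) expect_identical(tr$regions, "T1")
})

test_that("synthetic images carry exact truth masks and isolated salt", {
  poly <- rbind(c(10, 10), c(40, 10), c(40, 30), c(10, 30))
  img <- generate_image(c(48, 64), poly, signal_level = 200,
                        background_level = 50, salt_density = 0,
                        rng_seed = 1)
  expect_setequal(unique(as.vector(img$pixels)), c(50, 200))
  expect_equal(img$truth$area_px, 30 * 20)

  # truth mask equals an independent point-in-polygon oracle
  skip_if_not_installed("mgcv")
  centers <- expand.grid(y = seq_len(48) - 0.5, x = seq_len(64) - 0.5)
  oracle <- mgcv::in.out(rbind(poly, poly[1, ]),
                         as.matrix(centers[, c("x", "y")]))
  expect_equal(as.vector(img$truth$mask), oracle)

  # salt pixels are isolated: no two within a king-move of each other
  img2 <- generate_image(c(48, 64), poly, salt_density = 0.02,
                         rng_seed = 7)
  sp <- img2$truth$salt_pixels
  rc <- cbind(((sp - 1) %% 48) + 1, ((sp - 1) %/% 48) + 1)
  if (nrow(rc) > 1) {
    dmin <- min(as.matrix(stats::dist(rc, method = "maximum"))[
      upper.tri(diag(nrow(rc)))])
    expect_gte(dmin, 2)
  }
  # full-frame polygon: all-true mask
  full <- rbind(c(0, 0), c(64, 0), c(64, 48), c(0, 48))
  img3 <- generate_image(c(48, 64), full, salt_density = 0)
  expect_true(all(img3$truth$mask))

  expect_error(generate_image(c(48, 64), rbind(c(1, 1), c(2, 2), c(3, 3))),
               "degenerate")
  expect_error(generate_image(c(48, 64), rbind(c(-5, 1), c(70, 1),
                                               c(10, 40))),
               "bounds")
  # determinism
  a <- generate_image(c(32, 32), poly * 0.4, salt_density = 0.03,
                      rng_seed = 5)
  b <- generate_image(c(32, 32), poly * 0.4, salt_density = 0.03,
                      rng_seed = 5)
  expect_identical(a$pixels, b$pixels)
})

test_that("annotated images round-trip through 16-bit TIFF", {
  poly <- rbind(c(5, 5), c(20, 5), c(20, 18), c(5, 18))
  img <- generate_image(c(32, 32), poly, signal_level = 900,
                        background_level = 100, salt_density = 0.01,
                        salt_level = 4000, rng_seed = 2)
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "img.tif")
  write_annotated_image(img, path)
  back <- read_annotated_image(path)
  expect_equal(back$pixels, img$pixels, tolerance = 1)
  expect_equal(back$roi, img$roi, ignore_attr = TRUE)
})
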