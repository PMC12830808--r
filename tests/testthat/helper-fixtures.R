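# Shared fixtures and independent oracles.  Oracles deliberately use
# different algorithms from the package implementation.

small_tube <- function(...) mesh_tube(length = 6, radius = 1, n_axial = 8,
                                      n_around = 8, ...)

# two-stage series: stage 1 is an affine map of stage 0
affine_series <- function(base, A = diag(3), b = c(0, 0, 0)) {
  m1 <- base
  m1$vertices <- base$vertices %*% t(A) +
    matrix(b, nrow(base$vertices), 3, byrow = TRUE)
  m1$stage_label <- paste0(base$stage_label, "_t1")
  stage_series(list(base, m1))
}

# random deformed series on a small tube (seeded)
random_series <- function(seed, n_stages = 3L, with_attractor = FALSE) {
  withr::with_seed(seed, {
    base <- small_tube()
    nv <- nrow(base$vertices)
    zones <- list(list(vertices = sample.int(nv, nv %/% 3),
                       scale = runif(1, 0.7, 1.8)))
    band <- list(vertices = sample.int(nv, nv %/% 4),
                 translation = runif(1, -1.5, 1.5),
                 direction = c(1, 0, 0))
    args <- list(base_mesh = base, n_stages = n_stages,
                 isotropic_zones = zones, midline_band = band,
                 rng_seed = seed)
    if (with_attractor) {
      args$attractor_point <- c(-2, 0, -3)
      args$attractor_strength <- runif(1, 0.3, 1.5)
      args$optic_vertices <- which(base$vertices[, 1] <= 1)
      args$decay_range <- 5
    }
    generate_stage_series(do.call(deformation_spec, args))$series
  })
}

# Heron's formula triangle area (independent of the cross-product path)
heron_area <- function(a, b, c) {
  la <- sqrt(sum((b - c)^2))
  lb <- sqrt(sum((a - c)^2))
  lc <- sqrt(sum((a - b)^2))
  s <- (la + lb + lc) / 2
  sqrt(max(s * (s - la) * (s - lb) * (s - lc), 0))
}

# Independent closest-point search: per face, project onto the face
# plane; if the projection's barycentric coordinates are all
# non-negative use it, otherwise clamp to the nearest point on each of
# the three edges (a different algorithm from the region method used in
# the package).
closest_point_oracle <- function(mesh, p) {
  best <- Inf
  V <- mesh$vertices
  for (i in seq_len(nrow(mesh$tri))) {
    a <- V[mesh$tri[i, 1], ]; b <- V[mesh$tri[i, 2], ]
    cc <- V[mesh$tri[i, 3], ]
    n <- pracma_cross(b - a, cc - a)
    n2 <- sum(n^2)
    proj <- p - n * sum((p - a) * n) / n2
    # barycentric of proj
    v0 <- b - a; v1 <- cc - a; v2 <- proj - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    w1 <- (d11 * d20 - d01 * d21) / den
    w2 <- (d00 * d21 - d01 * d20) / den
    if (w1 >= 0 && w2 >= 0 && w1 + w2 <= 1) {
      cand <- sum((p - proj)^2)
    } else {
      cand <- min(point_segment_d2(p, a, b), point_segment_d2(p, b, cc),
                  point_segment_d2(p, a, cc))
    }
    if (cand < best) best <- cand
  }
  sqrt(best)
}

point_segment_d2 <- function(p, a, b) {
  u <- b - a
  t <- sum((p - a) * u) / sum(u * u)
  t <- min(max(t, 0), 1)
  sum((p - (a + t * u))^2)
}

pracma_cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# Brute-force frequency tally: nested loops over records and labels
freq_tally_oracle <- function(records) {
  zones <- unique(vapply(records, `[[`, character(1), "zone"))
  areas <- outcome_labels()
  pct <- matrix(NA_real_, length(zones), length(areas),
                dimnames = list(sort(zones), areas))
  for (z in rownames(pct)) {
    recs <- Filter(function(r) r$zone == z, records)
    for (a in areas) {
      hits <- sum(vapply(recs, function(r) a %in% r$areas, logical(1)))
      pct[z, a] <- 100 * hits / length(recs)
    }
  }
  pct
}

# Exhaustive per-cell filter rule (retention OR npc) AND NOT any exclusion
filter_oracle <- function(em, npc) {
  counts <- as.matrix(em$counts)
  keep <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ret <- counts["Otp", j] > 0 || counts["Sim1", j] > 0 || npc[j]
    ex <- FALSE
    for (g in c("Foxa1", "Foxa2", "Pitx2", "Shh",
                "Nr5a1", "Foxb1", "Tbr1", "Agrp", "Pomc"))
      if (counts[g, j] > 0) ex <- TRUE
    keep[j] <- ret && !ex
  }
  keep
}

# random tiny expression matrix containing all filter genes
random_filter_matrix <- function(seed, n_cells = 50, n_extra = 8) {
  withr::with_seed(seed, {
    genes <- c("Otp", "Sim1", "Foxa1", "Foxa2", "Pitx2", "Shh",
               "Nr5a1", "Foxb1", "Tbr1", "Agrp", "Pomc",
               sprintf("x%02d", seq_len(n_extra)))
    counts <- matrix(rpois(length(genes) * n_cells, 0.35),
                     length(genes), n_cells)
    npc <- runif(n_cells) < 0.3
    em <- expression_matrix(counts, genes, sprintf("c%03d", seq_len(n_cells)),
                            data.frame(barcode = sprintf("c%03d",
                                                         seq_len(n_cells)),
                                       npc = npc))
    list(em = em, npc = npc)
  })
}

# uniform random rotation matrix (seeded via current RNG)
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
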