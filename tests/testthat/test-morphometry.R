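# Landmark morphometry, image quantification and closed-form t tests.

test_that("the B:A construction handles axis-aligned, degenerate and
           rotated landmark layouts", {
  lm <- landmark_set(points = list(X = c(0, 0), Y = c(10, 0)),
                     polylines = list(optic_margin = rbind(c(4, -3),
                                                           c(4, 5))))
  res <- ba_ratio(lm)
  expect_equal(res$A, 10)
  expect_equal(res$B, 6)
  expect_equal(res$ratio, 0.6)

  # margin through Y: B = 0
  lm0 <- landmark_set(points = list(X = c(0, 0), Y = c(10, 0)),
                      polylines = list(optic_margin = rbind(c(10, -2),
                                                            c(10, 2))))
  expect_equal(ba_ratio(lm0)$ratio, 0)

  # rigid invariance: rotate everything by 30 degrees and translate
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  tr <- function(p) as.numeric(R %*% p + c(2, -7))
  lm_rot <- landmark_set(
    points = list(X = tr(c(0, 0)), Y = tr(c(10, 0))),
    polylines = list(optic_margin = rbind(tr(c(4, -3)), tr(c(4, 5)))))
  expect_equal(ba_ratio(lm_rot)$ratio, 0.6, tolerance = 1e-12)

  # margin entirely posterior to Y: geometry failure is named
  lm_bad <- landmark_set(points = list(X = c(0, 0), Y = c(10, 0)),
                         polylines = list(optic_margin = rbind(c(-3, 0),
                                                               c(-2, 1))))
  expect_error(ba_ratio(lm_bad), "perpendicular")
  expect_error(ba_ratio(landmark_set(points = list(X = c(1, 1),
                                                   Y = c(1, 1)),
                                     polylines = list(
                                       optic_margin = rbind(c(0, 0),
                                                            c(1, 0))))),
               "zero length")
})

test_that("the logarithmic trend fit recovers exact and noisy data", {
  stages <- c(10, 11, 14, 17, 19)
  exact <- 2 * log(stages) + 1
  fit <- fit_log_trend(stages, exact)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 1, tolerance = 1e-9)

  const <- fit_log_trend(stages, rep(0.4, 5))
  expect_equal(const$a, 0, tolerance = 1e-12)
  expect_equal(const$b, 0.4, tolerance = 1e-12)

  withr::with_seed(8, noisy <- 0.7 * log(stages) - 0.2 + rnorm(5, sd = 0.05))
  fit2 <- fit_log_trend(stages, noisy)
  # normal-equation oracle on the log-transformed predictor
  Xd <- cbind(1, log(stages))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% noisy)
  expect_equal(fit2$b, beta[1], tolerance = 1e-9)
  expect_equal(fit2$a, beta[2], tolerance = 1e-9)
  # residual orthogonality to the design
  expect_equal(as.numeric(t(Xd) %*% fit2$residuals), c(0, 0),
               tolerance = 1e-9)

  expect_error(fit_log_trend(c(0, 10), c(1, 2)), "positive")
  expect_error(fit_log_trend(c(10, 10), c(1, 2)), "distinct")
})

test_that("ZLI angles match the arc-cosine oracle and survive reflection", {
  lm <- landmark_set(points = list(base = c(0, 0), starA = c(3, 0),
                                   starP = c(0, 4)),
                     polylines = list(ZLI = rbind(c(0, -5), c(0, 5))))
  ang <- zli_angles(lm)
  expect_equal(unname(ang["starA"]), 90)
  expect_equal(unname(ang["starP"]), 0)

  withr::with_seed(12, {
    for (i in 1:10) {
      pts <- matrix(rnorm(8, sd = 3), 4, 2)
      lm_i <- landmark_set(points = list(base = pts[1, ], starA = pts[2, ],
                                         starP = pts[3, ]),
                           polylines = list(ZLI = rbind(pts[4, ],
                                                        pts[4, ] + rnorm(2))))
      a <- zli_angles(lm_i)
      zdir <- lm_i$polylines$ZLI[2, ] - lm_i$polylines$ZLI[1, ]
      oracle <- function(star) {
        v <- lm_i$points[[star]] - lm_i$points$base
        acos(sum(zdir * v) / sqrt(sum(zdir^2) * sum(v^2))) * 180 / pi
      }
      expect_equal(unname(a["starA"]), oracle("starA"), tolerance = 1e-9)
      expect_equal(unname(a["starP"]), oracle("starP"), tolerance = 1e-9)
      # reflection across the x axis preserves angles in [0, 180]
      fl <- function(p) c(p[1], -p[2])
      lm_f <- landmark_set(points = lapply(lm_i$points, fl),
                           polylines = list(ZLI = rbind(
                             fl(lm_i$polylines$ZLI[1, ]),
                             fl(lm_i$polylines$ZLI[2, ]))))
      expect_equal(zli_angles(lm_f), a, tolerance = 1e-9)
    }
  })
  expect_error(zli_angles(landmark_set(
    points = list(base = c(0, 0), starA = c(0, 0), starP = c(1, 1)),
    polylines = list(ZLI = rbind(c(0, 0), c(0, 1))))), "zero-length")
})

test_that("positive-area quantification despeckles salt but not signal", {
  # clean rectangle of 200 px inside the ROI
  img <- matrix(50, 40, 40)
  img[11:20, 11:30] <- 200   # 10 x 20 = 200 pixels
  roi <- rbind(c(5, 5), c(35, 5), c(35, 35), c(5, 35))
  expect_equal(area_positive(img, 0, 0, threshold = 125, roi = roi)$pixels,
               200)
  expect_warning(
    expect_equal(area_positive(matrix(0, 20, 20), 0, 0,
                               threshold = 1)$pixels, 0),
    "outside")

  # salt-corrupted copy: exact recovery at the stated settings
  poly <- rbind(c(10, 10), c(30, 10), c(30, 20), c(10, 20))
  syn <- generate_image(c(40, 40), poly, signal_level = 200,
                        background_level = 50, salt_density = 0.02,
                        salt_level = 4000, rng_seed = 4)
  res <- area_positive(syn, despeckle_radius = 1, outlier_threshold = 300,
                       threshold = 125)
  expect_identical(res$pixels, syn$truth$area_px)

  # despeckle disabled equals a plain threshold count
  plain <- sum(syn$pixels >= 125 &
                 growthlines:::rasterise_polygon(syn$roi, dim(syn$pixels)))
  expect_identical(area_positive(syn, 0, 0, threshold = 125)$pixels, plain)

  # physical units
  res_u <- area_positive(img, 0, 0, threshold = 125, roi = roi,
                         pixel_size = 2)
  expect_equal(res_u$area_units, 200 * 4)
  expect_error(area_positive(img, 0, 0, threshold = 125,
                             roi = rbind(c(-10, -10), c(-5, -10),
                                         c(-5, -5))),
               "empty ROI")
})

test_that("closed-form t tests match the textbook formulas and the
           reference implementation", {
  # hand-evaluated pooled-variance example
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  st <- two_sample_t(a, b, "student")
  expect_equal(st$t, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(st$df, 6)

  # identical groups
  same <- two_sample_t(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # swapping groups negates t, keeps p
  w1 <- two_sample_t(a, b, "welch")
  w2 <- two_sample_t(b, a, "welch")
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)

  withr::with_seed(14, {
    for (i in 1:100) {
      ga <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
      gb <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1),
                  sd = runif(1, 0.5, 3))
      for (variant in c("student", "welch")) {
        ours <- two_sample_t(ga, gb, variant)
        ref <- stats::t.test(ga, gb, var.equal = variant == "student")
        expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
        expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
      }
      # Welch-Satterthwaite df never exceeds the pooled df
      expect_lte(two_sample_t(ga, gb, "welch")$df,
                 length(ga) + length(gb) - 2 + 1e-9)
    }
  })

  expect_error(two_sample_t(c(1, 1), c(2, 2)), "undefined")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("landmark sets round-trip through CSV", {
  lm <- landmark_set(points = list(X = c(0, 0), Y = c(10, 0),
                                   base = c(1, 2)),
                     polylines = list(optic_margin = rbind(c(4, -3),
                                                           c(4, 5)),
                                      ZLI = rbind(c(0, -5), c(0, 5))))
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "lm.csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$points[c("X", "Y", "base")],
               lm$points[c("X", "Y", "base")])
  expect_equal(back$polylines$optic_margin, lm$polylines$optic_margin,
               ignore_attr = TRUE)
  expect_equal(ba_ratio(back)$ratio, 0.6)
})
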