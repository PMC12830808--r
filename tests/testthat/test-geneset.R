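# Gene-set stage: filtering, module scores, cluster summaries.

test_that("single-cell filter rules match their definitions", {
  genes <- c("Otp", "Sim1", "Foxa1", "Foxa2", "Pitx2", "Shh", "Nr5a1",
             "Foxb1", "Tbr1", "Agrp", "Pomc", "Aaa", "Bbb")
  counts <- matrix(0L, length(genes), 4,
                   dimnames = list(genes, paste0("c", 1:4)))
  counts["Otp", 1] <- 5L                      # retained
  counts["Otp", 2] <- 5L; counts["Foxa1", 2] <- 1L  # excluded by 1 UMI
  counts["Sim1", 3] <- 1L; counts["Pomc", 3] <- 2L  # excluded by marker
  # cell 4: no retention markers, not an NPC
  em <- expression_matrix(counts, genes, paste0("c", 1:4),
                          data.frame(barcode = paste0("c", 1:4),
                                     npc = c(FALSE, FALSE, FALSE, FALSE)))
  res <- filter_cells(em)
  expect_identical(res$matrix$barcodes, "c1")
  expect_identical(res$report$n_excluded_umi, 1L)
  expect_identical(res$report$n_excluded_marker, 1L)
  expect_identical(res$report$n_failed_retention, 1L)

  # the NPC flag rescues marker-negative cells
  em_npc <- expression_matrix(counts, genes, paste0("c", 1:4),
                              data.frame(barcode = paste0("c", 1:4),
                                         npc = c(FALSE, FALSE, FALSE, TRUE)))
  res2 <- filter_cells(em_npc)
  expect_setequal(res2$matrix$barcodes, c("c1", "c4"))

  # missing filter genes are a hard error naming the genes
  em_miss <- expression_matrix(counts[-3, ], genes[-3], paste0("c", 1:4))
  expect_error(filter_cells(em_miss), "Foxa1")

  counts0 <- counts
  counts0["Otp", ] <- 0L
  counts0["Sim1", ] <- 0L
  em0 <- expression_matrix(counts0, genes, paste0("c", 1:4))
  expect_error(filter_cells(em0), "all cells filtered")
})

test_that("the filter equals exhaustive per-cell rule evaluation on
           random matrices", {
  for (seed in 1:60) {
    fx <- random_filter_matrix(seed)
    keep_oracle <- filter_oracle(fx$em, fx$npc)
    if (!any(keep_oracle)) {
      expect_error(filter_cells(fx$em), "all cells filtered")
    } else {
      res <- filter_cells(fx$em)
      expect_identical(res$matrix$barcodes, fx$em$barcodes[keep_oracle])
    }
  }
})

test_that("planted exclusion-positive cells fail the filter exactly", {
  pl <- planted_spec(forced_positive = list(list(gene = "Foxa1",
                                                 n_cells = 17L)))
  gen <- generate_expression_matrix(200, 120, pl, rng_seed = 33)
  em <- gen$matrix
  expect_length(gen$truth$forced_positive$Foxa1, 17L)
  foxa1_pos <- which(as.vector(em$counts["Foxa1", ] > 0))
  expect_identical(foxa1_pos, gen$truth$forced_positive$Foxa1)
  # no other exclusion gene fires, so exclusion hits = the planted cells
  keep <- filter_oracle(em, em$meta$npc)
  retained_rule <- as.vector(em$counts["Otp", ] > 0 |
                               em$counts["Sim1", ] > 0) | em$meta$npc
  expect_identical(which(retained_rule & !keep), foxa1_pos[
    retained_rule[foxa1_pos]])

  # determinism
  gen2 <- generate_expression_matrix(200, 120, pl, rng_seed = 33)
  expect_identical(as.matrix(gen2$matrix$counts), as.matrix(em$counts))
})

test_that("module scores are zero on uniform data, equal the planted
           shift, and ignore global offsets", {
  genes <- sprintf("g%03d", 1:120)
  cells <- sprintf("c%03d", 1:40)
  X <- matrix(1, 120, 40, dimnames = list(genes, cells))
  set <- c("g001", "g050", "g100")
  expect_equal(unname(module_score(X, set, n_bins = 8, n_ctrl = 10,
                                   rng_seed = 1)),
               rep(0, 40))

  # uniform +c shift of the set on otherwise-identical genes: controls
  # sit at the unshifted level by construction, so score = c exactly
  cshift <- 0.8
  X2 <- X
  X2[set, ] <- X2[set, ] + cshift
  expect_equal(unname(module_score(X2, set, n_bins = 8, n_ctrl = 10,
                                   rng_seed = 1)),
               rep(cshift, 40), tolerance = 1e-12)

  # and approximately under realistic noise
  withr::with_seed(19, {
    Xn <- matrix(rnorm(120 * 40, mean = 2, sd = 0.05), 120, 40,
                 dimnames = list(genes, cells))
    Xn[set, ] <- Xn[set, ] + cshift
  })
  sc <- module_score(Xn, set, n_bins = 8, n_ctrl = 10, rng_seed = 2)
  expect_equal(mean(sc), cshift, tolerance = 0.05)

  # location invariance: adding a constant everywhere changes nothing
  expect_equal(module_score(Xn, set, n_bins = 8, n_ctrl = 10, rng_seed = 2),
               module_score(Xn + 5, set, n_bins = 8, n_ctrl = 10,
                            rng_seed = 2),
               tolerance = 1e-12)

  # reproducibility and control-pool exhaustion warning
  expect_identical(module_score(Xn, set, n_bins = 8, n_ctrl = 10,
                                rng_seed = 7),
                   module_score(Xn, set, n_bins = 8, n_ctrl = 10,
                                rng_seed = 7))
  w <- testthat::capture_warnings(module_score(Xn, set, n_bins = 8,
                                               n_ctrl = 500, rng_seed = 1))
  expect_gte(length(w), 1L)
  expect_true(all(grepl("controls", w)))
  expect_error(module_score(Xn, c(set, "nope"), rng_seed = 1), "absent")
})

test_that("cluster summaries rank planted signal first and report ties", {
  # single cluster: argmax for every score
  sc <- matrix(rnorm(30), 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  s1 <- cluster_summary(sc, rep(0, 10))
  expect_true(all(vapply(s1$top, identical, logical(1), "0")))

  # permuting labels permutes means identically
  withr::with_seed(23, cl <- sample(0:3, 10, replace = TRUE))
  s2 <- cluster_summary(sc, cl)
  perm <- c("0" = "3", "1" = "2", "2" = "0", "3" = "1")
  s3 <- cluster_summary(sc, unname(perm[as.character(cl)]))
  expect_equal(s3$means[perm[rownames(s2$means)], ], s2$means,
               ignore_attr = TRUE)

  # exact tie is reported, not broken
  sc_tie <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "s"))
  s4 <- cluster_summary(sc_tie, c(0, 1, 2, 2))
  expect_setequal(s4$top$s, c("0", "1"))

  expect_error(cluster_summary(sc, c(cl[-1], NA)), "unlabeled")

  # end-to-end planted progenitor cluster recovery over several seeds
  sets <- pvn_gene_sets()
  hits <- 0L
  for (seed in 1:10) {
    pl <- planted_spec(effects = list(list(genes = sets$progenitor$genes,
                                           cluster = 4L, shift = 1)))
    gen <- generate_expression_matrix(250, 250, pl, rng_seed = seed)
    filt <- filter_cells(gen$matrix, sets)
    X <- normalize_cp10k(filt$matrix)
    sc <- module_score(X, sets$progenitor$genes, n_bins = 10, n_ctrl = 10,
                       rng_seed = seed)
    top <- cluster_summary(cbind(progenitor = sc),
                           filt$matrix$meta$cluster)$top$progenitor
    if (identical(top, "4")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("expression matrices round-trip through MTX with sidecars and
           gene sets through YAML", {
  pl <- planted_spec()
  gen <- generate_expression_matrix(60, 80, pl, rng_seed = 2)
  tmp <- withr::local_tempdir()
  d <- file.path(tmp, "mtx")
  write_expression_matrix(gen$matrix, d)
  back <- read_expression_matrix(d)
  expect_equal(as.matrix(back$counts), as.matrix(gen$matrix$counts),
               ignore_attr = TRUE)
  expect_identical(back$genes, gen$matrix$genes)
  expect_identical(back$meta$cluster, gen$matrix$meta$cluster)

  y <- file.path(tmp, "sets.yaml")
  write_gene_sets(pvn_gene_sets(), y)
  sets2 <- read_gene_sets(y)
  expect_identical(lapply(sets2, `[[`, "genes"),
                   lapply(pvn_gene_sets(), `[[`, "genes"))
  expect_identical(sets2$exclude_umi$role, "exclude_any_umi")
})

test_that("normalisation is counts-per-10k on the log1p scale", {
  counts <- matrix(c(10, 0, 30, 5, 5, 0), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("x", "y")))
  X <- normalize_cp10k(counts)
  expect_equal(X["a", "x"], log1p(10 / 40 * 1e4))
  expect_equal(X["b", "y"], log1p(5 / 10 * 1e4))
  expect_equal(X["b", "x"], 0)
})
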