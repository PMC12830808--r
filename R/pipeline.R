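#' Demo pipeline configuration
#'
#' A single nested list holding every numeric decision of the demo
#' pipeline; unknown keys are rejected, and the effective configuration is
#' serialised next to the outputs of every run, so no hidden defaults can
#' influence a result.  Supplied values override the defaults block-wise.
#'
#' @param ... named blocks overriding parts of the default configuration
#'   (`seed`, `meshes`, `injections`, `metrics`, `scoring`, `geneset`).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_demo_config()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(over)) {
    if (is.list(cfg[[blk]])) {
      badk <- setdiff(names(over[[blk]]), names(cfg[[blk]]))
      if (length(badk))
        stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                     paste(badk, collapse = ", ")))
      cfg[[blk]][names(over[[blk]])] <- over[[blk]]
    } else cfg[[blk]] <- over[[blk]]
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

default_demo_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    meshes = list(n_stages = 4L, tube_length = 10, tube_radius = 1,
                  n_axial = 18L, n_around = 12L,
                  attractor_strength = 1.2, decay_range = 6,
                  isotropic_scale = 1.6, band_translation = 2.5),
    injections = list(n_per_zone = 3L, jitter = 0, radius = 0.45),
    metrics = list(t_line = 2.5, t_v = 150, t_arm = 0.25,
                   grey_lo = 2.25, grey_hi = 2.75, samples_per_face = 10L),
    scoring = list(min_overlap = 0.05),
    geneset = list(n_cells = 400L, n_genes = 300L, n_clusters = 8L,
                   planted_cluster = 6L, planted_shift = 1,
                   n_foxa1_cells = 25L, n_bins = 10L, n_ctrl = 10L))
}

validate_config <- function(cfg) {
  ref <- default_demo_config()
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(ref)) {
    if (!blk %in% names(cfg))
      stop("missing required config block: ", blk)
    if (is.list(ref[[blk]])) {
      badk <- setdiff(names(cfg[[blk]]), names(ref[[blk]]))
      if (length(badk))
        stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                     paste(badk, collapse = ", ")))
      missk <- setdiff(names(ref[[blk]]), names(cfg[[blk]]))
      if (length(missk))
        stop(sprintf("missing required key(s) in config block '%s': %s",
                     blk, paste(missk, collapse = ", ")))
      nums <- names(ref[[blk]])
      for (k in nums)
        if (is.null(cfg[[blk]][[k]]) || !is.numeric(cfg[[blk]][[k]]))
          stop(sprintf("config key '%s$%s' must be numeric", blk, k))
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults; unknown keys are rejected
#' with the offending name.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end demo pipeline on synthetic data
#'
#' Exercises the whole workflow on generated inputs: build a deformed
#' stage series from a tube base mesh, inject dye into each of the twelve
#' zones, propagate to the final stage, measure growth-line metrics,
#' assign outcome areas and compare against the generator's ground truth,
#' tabulate the per-zone frequency matrix with thumbnail colour maps, and
#' run the gene-set stage (filter, module scores, cluster summary) on a
#' planted expression matrix.  Every stage logs its parameters; any
#' failure aborts with the stage name.  All artefacts, plus the effective
#' configuration, are written under `out_dir`; byte-identical outputs are
#' produced for identical config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory results: `series`,
#'   `regions`, `records`, `metrics`, `freq`, `truth_agreement` (fraction
#'   of injections whose assigned areas equal ground truth), `geneset`
#'   (filter report, cluster summary), `files`.
#' @export
run_demo <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("demo stage '%s' failed: %s\nconfig echo: %s", name,
                   conditionMessage(e),
                   jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
           call. = FALSE))
  }
  cfg <- config
  seed <- as.integer(cfg$seed)

  say("[meshes] tube %dx%d, %d stages, attractor %.2f",
      cfg$meshes$n_axial, cfg$meshes$n_around, cfg$meshes$n_stages,
      cfg$meshes$attractor_strength)
  gen <- stage("meshes", {
    base <- mesh_tube(length = cfg$meshes$tube_length,
                      radius = cfg$meshes$tube_radius,
                      n_axial = cfg$meshes$n_axial,
                      n_around = cfg$meshes$n_around)
    optic <- which(base$vertices[, 1] <= cfg$meshes$tube_length * 0.1 &
                     base$vertices[, 3] < 0)
    zone_iso <- which(base$vertices[, 1] >
                        cfg$meshes$tube_length * 0.6)
    band <- which(abs(base$vertices[, 3]) < 0.35 * cfg$meshes$tube_radius &
                    base$vertices[, 2] < 0)
    spec <- deformation_spec(
      base, n_stages = cfg$meshes$n_stages,
      attractor_point = c(-0.2 * cfg$meshes$tube_length, 0,
                          -3 * cfg$meshes$tube_radius),
      attractor_strength = cfg$meshes$attractor_strength,
      optic_vertices = optic, decay_range = cfg$meshes$decay_range,
      isotropic_zones = list(list(vertices = zone_iso,
                                  scale = cfg$meshes$isotropic_scale)),
      midline_band = list(vertices = band,
                          translation = cfg$meshes$band_translation,
                          direction = c(-1, 0, 0)),
      rng_seed = seed)
    generate_stage_series(spec)
  })
  series <- gen$series
  write_stage_series(series, file.path(out_dir, "meshes"))

  say("[regions] synthetic 17-area layout on final stage")
  final <- series$meshes[[n_stages(series)]]
  regions <- stage("regions", synthetic_outcome_regions(final))
  write_outcome_regions(regions, file.path(out_dir, "regions.csv"))

  say("[injections] %d per zone, jitter %.3g, radius %.3g",
      cfg$injections$n_per_zone, cfg$injections$jitter,
      cfg$injections$radius)
  mesh0 <- series$meshes[[1]]
  graph0 <- stage("injections", mesh_geodesic_graph(mesh0))
  inj <- stage("injections", {
    zones <- tube_zones(mesh0)
    generate_injection_set(series, zones,
                           n_per_zone = cfg$injections$n_per_zone,
                           jitter = cfg$injections$jitter,
                           rng_seed = seed + 1L,
                           radius = cfg$injections$radius,
                           regions = regions,
                           min_overlap = cfg$scoring$min_overlap,
                           graph = graph0)
  })

  say("[metrics+scoring] %d records", length(inj$records))
  th <- shape_thresholds(t_line = cfg$metrics$t_line, t_v = cfg$metrics$t_v,
                         t_arm = cfg$metrics$t_arm,
                         grey_band = c(cfg$metrics$grey_lo,
                                       cfg$metrics$grey_hi))
  frame <- axis_frame(
    ap_points = cbind(seq(0, cfg$meshes$tube_length, length.out = 12),
                      -cfg$meshes$tube_radius, 0),
    target = c(-0.2 * cfg$meshes$tube_length, 0,
               -3 * cfg$meshes$tube_radius))
  s_final <- n_stages(series) - 1
  res <- stage("metrics", {
    metrics <- list()
    records <- list()
    agree <- logical(length(inj$records))
    for (i in seq_along(inj$records)) {
      rec <- inj$records[[i]]
      p0 <- propagate_dye(rec$patch, series, 0)
      p1 <- propagate_dye(rec$patch, series, s_final)
      m <- measure_growth(p0, p1, frame, th)
      metrics[[rec$sample_id]] <- m
      hit <- assign_outcomes(p1, regions,
                             min_overlap = cfg$scoring$min_overlap)
      records[[i]] <- outcome_record(rec$sample_id, rec$zone,
                                     as.character(hit))
      agree[i] <- setequal(as.character(hit), inj$truth[[i]]$regions)
    }
    list(metrics = metrics, records = records, agree = agree)
  })
  write_growth_metrics(res$metrics, file.path(out_dir, "metrics.csv"))
  write_outcome_records(res$records, file.path(out_dir, "records.tsv"))

  say("[frequency] truth agreement %.1f%%", 100 * mean(res$agree))
  freq <- stage("frequency", frequency_matrix(res$records))
  utils::write.csv(freq$percent, file.path(out_dir, "frequency.csv"))
  utils::write.csv(freq$n_hit, file.path(out_dir, "frequency_n.csv"))
  thumbs <- render_thumbnails(freq, regions, final)
  thumb_df <- do.call(rbind, lapply(names(thumbs), function(z)
    cbind(zone = z, thumbs[[z]])))
  utils::write.csv(thumb_df, file.path(out_dir, "thumbnails.csv"),
                   row.names = FALSE)

  say("[geneset] %d cells x %d genes, planted cluster %d",
      cfg$geneset$n_cells, cfg$geneset$n_genes,
      cfg$geneset$planted_cluster)
  gs <- stage("geneset", {
    sets <- pvn_gene_sets()
    pl <- planted_spec(
      n_clusters = cfg$geneset$n_clusters,
      effects = list(list(genes = sets$progenitor$genes,
                          cluster = cfg$geneset$planted_cluster,
                          shift = cfg$geneset$planted_shift)),
      forced_positive = list(list(gene = "Foxa1",
                                  n_cells = cfg$geneset$n_foxa1_cells)))
    gen <- generate_expression_matrix(cfg$geneset$n_cells,
                                      cfg$geneset$n_genes, pl,
                                      rng_seed = seed + 2L)
    write_expression_matrix(gen$matrix, file.path(out_dir, "expression"))
    filt <- filter_cells(gen$matrix, sets)
    X <- normalize_cp10k(filt$matrix)
    score_sets <- Filter(function(s) s$role == "score", sets)
    scores <- vapply(score_sets, function(s)
      module_score(X, s$genes, n_bins = cfg$geneset$n_bins,
                   n_ctrl = cfg$geneset$n_ctrl, rng_seed = seed + 3L),
      numeric(ncol(X)))
    summ <- cluster_summary(scores, filt$matrix$meta$cluster)
    utils::write.csv(data.frame(barcode = filt$matrix$barcodes,
                                cluster = filt$matrix$meta$cluster, scores),
                     file.path(out_dir, "module_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$means, file.path(out_dir, "cluster_means.csv"))
    list(report = filt$report, summary = summ, truth = gen$truth)
  })

  echo <- unclass(cfg)
  jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] outputs in %s", out_dir)
  invisible(list(series = series, regions = regions,
                 records = res$records, metrics = res$metrics,
                 freq = freq, truth_agreement = mean(res$agree),
                 geneset = gs,
                 files = list.files(out_dir, recursive = TRUE)))
}

#' Validate input files by format
#'
#' Light-weight per-file verdicts for the formats the package consumes
#' (OBJ, PLY, CSV, TSV, MTX, TIFF) without loading full data where
#' possible.  For an MTX file, sibling `genes.tsv`/`barcodes.tsv` files
#' are checked against the header dimensions, reporting the counts on
#' mismatch.  Validation reports; it never throws.
#'
#' @param paths character vector of file paths.
#' @return data frame with columns `file`, `format`, `ok`, `message`.
#' @export
validate_inputs <- function(paths) {
  one <- function(path) {
    fmt <- tolower(sub(".*\\.", "", path))
    if (!file.exists(path))
      return(data.frame(file = path, format = fmt, ok = FALSE,
                        message = "file not found"))
    res <- tryCatch({
      switch(fmt,
        obj = {
          m <- read_mesh_obj(path)
          sprintf("OBJ: %d vertices, %d faces", nrow(m$vertices),
                  length(m$faces))
        },
        ply = {
          m <- read_mesh_ply(path)
          sprintf("PLY: %d vertices, %d faces", nrow(m$vertices),
                  length(m$faces))
        },
        csv = {
          df <- utils::read.csv(path, nrows = 5)
          sprintf("CSV: %d columns", ncol(df))
        },
        tsv = {
          df <- utils::read.delim(path, nrows = 5)
          sprintf("TSV: %d columns", ncol(df))
        },
        mtx = {
          hdr <- readLines(path, n = 50)
          if (!grepl("^%%MatrixMarket", hdr[1]))
            stop("missing MatrixMarket header")
          dims <- hdr[!grepl("^%", hdr)][1]
          d <- as.integer(strsplit(trimws(dims), "\\s+")[[1]])
          msg <- sprintf("MTX: %d x %d, %d entries", d[1], d[2], d[3])
          gpath <- file.path(dirname(path), "genes.tsv")
          bpath <- file.path(dirname(path), "barcodes.tsv")
          if (file.exists(gpath)) {
            ng <- length(readLines(gpath))
            if (ng != d[1])
              stop(sprintf("genes.tsv has %d entries but MTX has %d rows",
                           ng, d[1]))
          }
          if (file.exists(bpath)) {
            nb <- length(readLines(bpath))
            if (nb != d[2])
              stop(sprintf("barcodes.tsv has %d entries but MTX has %d columns",
                           nb, d[2]))
          }
          msg
        },
        tif = ,
        tiff = {
          img <- tiff::readTIFF(path, info = TRUE)
          sprintf("TIFF: %d x %d", nrow(img), ncol(img))
        },
        stop("unrecognised format"))
    }, error = function(e) structure(conditionMessage(e), failed = TRUE))
    ok <- is.null(attr(res, "failed"))
    data.frame(file = path, format = fmt, ok = ok,
               message = as.character(res))
  }
  do.call(rbind, lapply(paths, one))
}
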