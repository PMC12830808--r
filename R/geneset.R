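#' Expression matrix container
#'
#' Gene x cell non-negative integer counts (sparse), with gene names,
#' cell barcodes, and per-cell metadata (cluster label, NPC flag).
#'
#' @param counts genes x cells matrix (coerced to `dgCMatrix`);
#'   non-negative.
#' @param genes character gene names (unique), length `nrow(counts)`.
#' @param barcodes character cell barcodes (unique), length
#'   `ncol(counts)`.
#' @param meta optional data frame with one row per cell; columns
#'   `barcode`, `cluster` (integer labels `0..k-1`) and `npc` (logical)
#'   are recognised by downstream steps.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, genes, barcodes, meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (length(genes) != nrow(counts) || anyDuplicated(genes))
    stop("'genes' must be unique and match nrow(counts)")
  if (length(barcodes) != ncol(counts) || anyDuplicated(barcodes))
    stop("'barcodes' must be unique and match ncol(counts)")
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  if (is.null(meta)) meta <- data.frame(barcode = barcodes)
  if (!identical(meta$barcode, barcodes))
    stop("meta$barcode must match 'barcodes' in order")
  structure(list(counts = counts, genes = as.character(genes),
                 barcodes = as.character(barcodes), meta = meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d cells, %d metadata columns>\n",
              length(x$genes), length(x$barcodes), ncol(x$meta)))
  invisible(x)
}

#' Gene-set definitions for the paraventricular-lineage analysis
#'
#' The named marker lists used by the cell-filtering and module-scoring
#' stage, with their roles: cells expressing Otp and/or Sim1 are retained
#' (NPCs lacking them may be added via a flag column); any cell with > 0
#' UMIs of Foxa1/Foxa2/Pitx2/Shh is excluded, as is any cell expressing
#' Nr5a1/Foxb1/Tbr1/Agrp/Pomc; the score sets are the anterior/terminal,
#' posterior/peduncular, cycling-progenitor and early-neuronal modules.
#'
#' @return named list of `list(name, genes, role)` entries; roles are
#'   `retain`, `exclude_any_umi`, `exclude_expressing`, `score`.
#' @export
pvn_gene_sets <- function() {
  gs <- function(name, genes, role) list(name = name, genes = genes,
                                         role = role)
  list(
    retain = gs("retain", c("Otp", "Sim1"), "retain"),
    exclude_umi = gs("exclude_umi", c("Foxa1", "Foxa2", "Pitx2", "Shh"),
                     "exclude_any_umi"),
    exclude_marker = gs("exclude_marker",
                        c("Nr5a1", "Foxb1", "Tbr1", "Agrp", "Pomc"),
                        "exclude_expressing"),
    terminal = gs("terminal", c("Fgf15", "Six3", "Zic1", "Zic5"), "score"),
    peduncular = gs("peduncular", c("Mfap4", "Lmo4", "Rgs4"), "score"),
    progenitor = gs("progenitor", c("Mki67", "Top2a", "Pcna"), "score"),
    neuronal = gs("neuronal", c("Neurod1", "Dcx", "Tubb3"), "score"))
}

#' Marker-based cell retention and exclusion
#'
#' Applies the lineage filter: a cell is retained when it expresses a
#' retention marker (count > 0 for Otp or Sim1) or carries the NPC flag,
#' AND has zero counts for every exclusion gene (both exclusion lists use
#' the same count > 0 criterion, so retention and exclusion commute and
#' the conjunction is order-independent).  Gene matching is
#' case-sensitive; missing filter genes are a hard error listing the
#' misses.
#'
#' @param em an [expression_matrix].
#' @param sets gene-set definitions (default [pvn_gene_sets()]).
#' @param npc_mask logical per-cell flag for neural progenitor cells to
#'   include regardless of retention markers; defaults to `em$meta$npc`
#'   or all-`FALSE`.
#' @return list with `matrix` (the retained [expression_matrix]) and
#'   `report`: per-rule counts in application order (retention,
#'   UMI-exclusion, marker-exclusion) and the retained-cell count.
#' @export
filter_cells <- function(em, sets = pvn_gene_sets(), npc_mask = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(npc_mask))
    npc_mask <- if ("npc" %in% names(em$meta)) as.logical(em$meta$npc)
                else rep(FALSE, length(em$barcodes))
  stopifnot(length(npc_mask) == length(em$barcodes))
  role_genes <- function(role) unlist(lapply(sets, function(s)
    if (s$role == role) s$genes), use.names = FALSE)
  retain_genes <- role_genes("retain")
  excl_umi <- role_genes("exclude_any_umi")
  excl_marker <- role_genes("exclude_expressing")
  need <- c(retain_genes, excl_umi, excl_marker)
  miss <- setdiff(need, em$genes)
  if (length(miss))
    stop("filter genes absent from the matrix: ",
         paste(miss, collapse = ", "))
  any_pos <- function(genes) {
    if (length(genes) == 0L) return(rep(FALSE, length(em$barcodes)))
    Matrix::colSums(em$counts[genes, , drop = FALSE] > 0) > 0
  }
  marker_retained <- any_pos(retain_genes)
  retained_rule <- marker_retained | npc_mask
  excl1 <- any_pos(excl_umi)
  excl2 <- any_pos(excl_marker)
  keep <- retained_rule & !excl1 & !excl2
  report <- list(
    n_input = length(em$barcodes),
    n_failed_retention = sum(!retained_rule),
    n_excluded_umi = sum(retained_rule & excl1),
    n_excluded_marker = sum(retained_rule & !excl1 & excl2),
    n_retained = sum(keep))
  if (!any(keep)) stop("all cells filtered: no cell passes retention and exclusion")
  out <- expression_matrix(em$counts[, keep, drop = FALSE], em$genes,
                           em$barcodes[keep],
                           em$meta[keep, , drop = FALSE])
  list(matrix = out, report = report)
}

#' Log-normalise counts (counts-per-10k, log1p)
#'
#' The normalisation applied before module scoring:
#' `log1p(counts / colsum * 1e4)` per cell.
#'
#' @param em an [expression_matrix], or a genes x cells counts matrix.
#' @return a `dgCMatrix` of normalised expression with dimnames.
#' @export
normalize_cp10k <- function(em) {
  counts <- if (inherits(em, "expression_matrix")) em$counts else em
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  X <- counts %*% Matrix::Diagonal(x = 1e4 / cs)
  X@x <- log1p(X@x)
  dimnames(X) <- dimnames(counts)
  X
}

#' Binned-control gene-set module score
#'
#' Per-cell score for a gene set on normalised expression: the mean over
#' the set's genes minus the mean over expression-matched control genes.
#' All genes are ranked by their dataset-mean expression and cut into
#' `n_bins` equal-size bins; for each set gene, `n_ctrl` control genes
#' are drawn (seeded, without replacement, excluding the set's own genes)
#' from that gene's bin, and the pooled unique controls form the control
#' mean.  When a bin cannot supply `n_ctrl` controls the draw is reduced
#' to the bin population with a warning.
#'
#' Adding a constant to every gene's expression leaves scores unchanged
#' (set and control means shift equally), and a matrix in which all genes
#' are identical scores exactly zero.
#'
#' @param X normalised genes x cells matrix (see [normalize_cp10k()]);
#'   rownames are gene names.
#' @param gene_set character vector of set genes (all must be present).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl controls drawn per set gene (default 100).
#' @param rng_seed integer seed for the control draw.
#' @return numeric per-cell score vector (named by cell).
#' @export
module_score <- function(X, gene_set, n_bins = 24L, n_ctrl = 100L,
                         rng_seed = 1L) {
  genes <- rownames(X)
  if (is.null(genes)) stop("'X' must have gene rownames")
  miss <- setdiff(gene_set, genes)
  if (length(miss))
    stop("score genes absent from the matrix: ", paste(miss, collapse = ", "))
  if (length(genes) < n_bins)
    stop("fewer genes than bins: reduce n_bins")
  avg <- Matrix::rowMeans(X)
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r / (length(genes) / n_bins))
  names(bin) <- genes
  controls <- character(0)
  withr::with_seed(as.integer(rng_seed), {
    for (g in gene_set) {
      pool <- setdiff(genes[bin == bin[g]], gene_set)
      k <- min(n_ctrl, length(pool))
      if (k < n_ctrl)
        warning(sprintf(
          "bin of gene %s holds only %d eligible controls (requested %d)",
          g, length(pool), n_ctrl))
      if (k > 0L)
        controls <- c(controls, pool[sample.int(length(pool), k)])
    }
  })
  controls <- unique(controls)
  if (length(controls) == 0L)
    stop("no control genes available for the score")
  set_mean <- Matrix::colMeans(X[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(X[controls, , drop = FALSE])
  out <- set_mean - ctrl_mean
  names(out) <- colnames(X)
  out
}

#' Per-cluster score summaries and top clusters
#'
#' Means of each module score within each cluster, the clusters ranked
#' per score, and the top-scoring cluster; ties on the top mean are
#' reported, never silently broken.
#'
#' @param scores cells x sets numeric matrix or data frame of module
#'   scores.
#' @param clusters per-cell cluster labels (no `NA`).
#' @return list with `means` (clusters x sets matrix), `ranking` (named
#'   list: clusters in decreasing score order per set), `top` (named list:
#'   top cluster(s) per set; length > 1 marks a tie).
#' @export
cluster_summary <- function(scores, clusters) {
  scores <- as.matrix(scores)
  if (length(clusters) != nrow(scores))
    stop("one cluster label per score row required")
  if (any(is.na(clusters))) stop("unlabeled cells (NA cluster)")
  cl <- as.character(clusters)
  levs <- sort(unique(cl))
  means <- do.call(rbind, lapply(levs, function(l)
    colMeans(scores[cl == l, , drop = FALSE])))
  rownames(means) <- levs
  ranking <- lapply(colnames(means), function(s)
    rownames(means)[order(means[, s], decreasing = TRUE)])
  names(ranking) <- colnames(means)
  top <- lapply(colnames(means), function(s) {
    mx <- max(means[, s])
    rownames(means)[means[, s] == mx]
  })
  names(top) <- colnames(means)
  list(means = means, ranking = ranking, top = top)
}

#' Read / write an expression matrix as MTX plus sidecars
#'
#' Standard sparse trio: `matrix.mtx` (genes x cells), `genes.tsv`,
#' `barcodes.tsv`, plus `metadata.csv` with per-cell columns (`barcode`,
#' `cluster`, `npc`).
#'
#' @param em an [expression_matrix].
#' @param dir directory (created if missing).
#' @return the directory, invisibly / an [expression_matrix].
#' @export
write_expression_matrix <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(em$counts, file.path(dir, "matrix.mtx"))
  writeLines(em$genes, file.path(dir, "genes.tsv"))
  writeLines(em$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.csv(em$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) utils::read.csv(meta_path)
          else NULL
  expression_matrix(counts, genes, barcodes, meta)
}

#' Read / write gene-set definitions as YAML
#'
#' @param path YAML file: a mapping of set name to `genes` and `role`.
#' @return named list of gene-set definitions (see [pvn_gene_sets()]).
#' @export
read_gene_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm)
    list(name = nm, genes = as.character(raw[[nm]]$genes),
         role = raw[[nm]]$role))
  stats::setNames(out, names(raw))
}

#' @rdname read_gene_sets
#' @param sets gene-set definitions to write.
#' @export
write_gene_sets <- function(sets, path) {
  yaml::write_yaml(lapply(sets, function(s)
    list(genes = s$genes, role = s$role)), path)
  invisible(path)
}
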