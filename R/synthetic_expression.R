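#' Describe planted structure for a synthetic expression matrix
#'
#' @param n_clusters number of cell clusters (labels `0..k-1`).
#' @param named_genes gene names guaranteed to exist in the matrix
#'   (defaults to every gene used by [pvn_gene_sets()]); remaining rows
#'   are filler genes `g0001, g0002, ...`.
#' @param effects list of `list(genes =, cluster =, shift =)` entries: the
#'   named genes receive an additive `shift` on the log scale (their
#'   Poisson mean is multiplied by `exp(shift)`) in cells of that cluster.
#' @param forced_positive list of `list(gene =, n_cells =, umi = 1)`
#'   entries: exactly `n_cells` cells (chosen seeded) are forced to carry
#'   `umi` counts of the gene, and all other cells zero -- used to plant
#'   known exclusion-filter hits.
#' @param npc_fraction fraction of cells flagged as neural progenitors.
#' @param high_genes genes given a broad baseline (expected ~1.2 counts
#'   per cell, so most cells express them); defaults to the retention
#'   markers, emulating a lineage-enriched capture.
#' @param silent_genes genes with zero baseline expression (only
#'   `forced_positive` can switch them on); defaults to the exclusion
#'   markers, so planted exclusion hits are exact by construction.
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(n_clusters = 8L, named_genes = NULL,
                         effects = list(), forced_positive = list(),
                         npc_fraction = 0.2, high_genes = NULL,
                         silent_genes = NULL) {
  sets <- pvn_gene_sets()
  if (is.null(named_genes))
    named_genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  if (is.null(high_genes)) high_genes <- intersect(sets$retain$genes,
                                                   named_genes)
  if (is.null(silent_genes))
    silent_genes <- intersect(c(sets$exclude_umi$genes,
                                sets$exclude_marker$genes), named_genes)
  structure(list(n_clusters = as.integer(n_clusters),
                 named_genes = named_genes, effects = effects,
                 forced_positive = forced_positive,
                 npc_fraction = npc_fraction,
                 high_genes = high_genes, silent_genes = silent_genes),
            class = "planted_spec")
}

#' Generate a synthetic gene x cell count matrix with known structure
#'
#' Counts are Poisson draws around lognormal gene means scaled by
#' per-cell library sizes; planted effects multiply the mean by
#' `exp(shift)` for the stated gene set in the stated cluster, and forced
#' positives overwrite chosen cells afterwards.  With all effect sizes
#' zero the cells are exchangeable.  Regeneration with the same seed is
#' bit-identical.
#'
#' @param n_cells,n_genes matrix dimensions (`n_genes` must cover the
#'   planted named genes).
#' @param planted a [planted_spec()].
#' @param rng_seed integer seed.
#' @param mean_counts target mean total counts per cell.
#' @return list with `matrix` (an [expression_matrix] whose metadata has
#'   `cluster` and `npc` columns) and `truth` (cluster labels, effect
#'   echo, forced-positive cell indices per gene, and the seed).
#' @export
generate_expression_matrix <- function(n_cells, n_genes,
                                       planted = planted_spec(),
                                       rng_seed = 1L, mean_counts = 2000) {
  stopifnot(inherits(planted, "planted_spec"))
  if (length(planted$named_genes) > n_genes)
    stop("planted genes exceed n_genes")
  for (e in planted$effects)
    if (!all(e$genes %in% planted$named_genes))
      stop("effect genes must be among the planted named genes")
  genes <- planted$named_genes
  n_fill <- n_genes - length(genes)
  if (n_fill > 0) genes <- c(genes, sprintf("g%04d", seq_len(n_fill)))
  forced <- list()
  withr::with_seed(as.integer(rng_seed), {
    clusters <- sample.int(planted$n_clusters, n_cells, replace = TRUE) - 1L
    npc <- stats::runif(n_cells) < planted$npc_fraction
    mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(mu) <- genes
    p <- mu / sum(mu)
    # role-aware baselines: broad retention-like genes at ~1.2 expected
    # counts/cell, silent exclusion-like genes at zero
    hi <- intersect(planted$high_genes, genes)
    sil <- intersect(planted$silent_genes, genes)
    special <- c(hi, sil)
    if (length(special)) {
      p[special] <- 0
      mass_hi <- length(hi) * 1.2 / mean_counts
      p[setdiff(genes, special)] <-
        p[setdiff(genes, special)] / sum(p[setdiff(genes, special)]) *
        (1 - mass_hi)
      p[hi] <- 1.2 / mean_counts
    }
    lib <- stats::rlnorm(n_cells, meanlog = log(mean_counts), sdlog = 0.2)
    M <- matrix(p, n_genes, n_cells) * matrix(lib, n_genes, n_cells,
                                              byrow = TRUE)
    rownames(M) <- genes
    for (e in planted$effects) {
      cells <- which(clusters == e$cluster)
      M[e$genes, cells] <- M[e$genes, cells, drop = FALSE] * exp(e$shift)
    }
    counts <- matrix(stats::rpois(n_genes * n_cells, as.vector(M)),
                     n_genes, n_cells)
    rownames(counts) <- genes
    for (fp in planted$forced_positive) {
      umi <- if (is.null(fp$umi)) 1L else fp$umi
      cells <- sample.int(n_cells, fp$n_cells)
      counts[fp$gene, ] <- 0L
      counts[fp$gene, cells] <- umi
      forced[[fp$gene]] <- sort(cells)
    }
  })
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  meta <- data.frame(barcode = barcodes, cluster = clusters, npc = npc)
  em <- expression_matrix(counts, genes, barcodes, meta)
  list(matrix = em,
       truth = list(clusters = clusters, npc = npc,
                    effects = planted$effects, forced_positive = forced,
                    rng_seed = as.integer(rng_seed)))
}
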