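#' Outcome region sets
#'
#' Named face sets on the final-stage mesh used to classify where a
#' propagated patch ended up.  The default vocabulary has seventeen areas
#' grouped as T1-T2 (telencephalon), D1-D7 (diencephalon excluding
#' hypothalamus), H1-H5 (hypothalamus) and Hm1-Hm3 (hypothalamic
#' midline).  Regions may overlap (an area can span more than one major
#' region); every set must be non-empty and labels unique.
#'
#' @param face_sets named list of integer face-index vectors.
#' @param mesh optional [stage_mesh] used to range-check indices.
#' @return An object of class `outcome_regions` (a named list).
#' @export
outcome_regions <- function(face_sets, mesh = NULL) {
  if (is.null(names(face_sets)) || anyDuplicated(names(face_sets)))
    stop("region labels must be present and unique")
  if (any(lengths(face_sets) == 0L)) stop("every region face set must be non-empty")
  face_sets <- lapply(face_sets, function(f) sort(unique(as.integer(f))))
  if (!is.null(mesh)) {
    nf <- length(mesh$faces)
    if (any(unlist(face_sets) > nf | unlist(face_sets) < 1L))
      stop("region face index out of range for the given mesh")
  }
  structure(face_sets, class = "outcome_regions")
}

#' @export
`[.outcome_regions` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "outcome_regions"
  out
}

#' The seventeen outcome-area labels
#'
#' @return character vector of the default label vocabulary.
#' @export
outcome_labels <- function() {
  c("T1", "T2", paste0("D", 1:7), paste0("H", 1:5), paste0("Hm", 1:3))
}

#' Synthetic default layout of the seventeen outcome areas
#'
#' The real areas exist only as annotated anatomy; this layout is an
#' explicitly synthetic stand-in that carries the same seventeen-label
#' vocabulary on a tube mesh: faces are binned into overlapping axial
#' bands by centroid position (T anterior, then D, H, Hm posterior, with
#' a small overlap between neighbouring areas, since areas may overlap
#' more than one region).  Every face belongs to at least one area.  It
#' exists so the scoring machinery is fully exercisable without
#' annotation files; it is not a claim about real region geometry.  For
#' real data, supply a face-set annotation (see
#' [read_outcome_regions()]).
#'
#' @param mesh the final-stage [stage_mesh] (tube-like, axis along x).
#' @return an [outcome_regions] object with 17 areas covering all faces.
#' @export
synthetic_outcome_regions <- function(mesh) {
  cent <- face_centroids(mesh)
  xr <- range(cent[, 1])
  u <- (cent[, 1] - xr[1]) / max(diff(xr), .Machine$double.eps)
  # axial bands: T (anterior) 0-0.25, D 0.25-0.6, H 0.6-0.85, Hm 0.85-1
  bands <- list(T = c(0, 0.25), D = c(0.25, 0.6), H = c(0.6, 0.85),
                Hm = c(0.85, 1))
  counts <- c(T = 2L, D = 7L, H = 5L, Hm = 3L)
  sets <- list()
  overlap <- 0.02  # axial overlap fraction between adjacent areas
  for (g in names(bands)) {
    lo <- bands[[g]][1]; hi <- bands[[g]][2]
    k <- counts[[g]]
    edges <- seq(lo, hi, length.out = k + 1L)
    for (i in seq_len(k)) {
      lab <- paste0(g, i)
      in_ax <- u >= max(edges[i] - overlap, 0) &
        u <= min(edges[i + 1L] + overlap, 1)
      sets[[lab]] <- which(in_ax)
    }
  }
  outcome_regions(sets, mesh)
}

#' Assign a propagated patch to outcome areas
#'
#' An area is included when the patch's face-area overlap with the area,
#' divided by the patch area (both measured on the final-stage mesh), is
#' at least `min_overlap`.  When no area passes, the single best-overlap
#' area is returned flagged (attribute `below_threshold = TRUE`).
#'
#' @param patch a [dye_patch] at the final stage (attached mesh required,
#'   or pass `mesh`).
#' @param regions an [outcome_regions] on the same mesh topology.
#' @param min_overlap overlap fraction threshold (default 0.05).
#' @param mesh final-stage [stage_mesh] (defaults to `patch$mesh`).
#' @return character vector of area labels (possibly with attribute
#'   `below_threshold`), plus attribute `overlap` giving each returned
#'   area's overlap fraction.
#' @export
assign_outcomes <- function(patch, regions, min_overlap = 0.05,
                            mesh = patch$mesh) {
  stopifnot(inherits(patch, "dye_patch"), inherits(regions, "outcome_regions"))
  if (is.null(mesh)) stop("patch has no attached mesh; pass one explicitly")
  if (length(patch$faces) == 0L) stop("empty patch")
  if (max(patch$faces) > length(mesh$faces))
    stop("patch and regions must live on the same mesh topology")
  areas <- face_area(mesh)
  pa <- sum(areas[patch$faces])
  ov <- vapply(regions, function(rf)
    sum(areas[intersect(patch$faces, rf)]) / pa, numeric(1))
  hit <- names(ov)[ov >= min_overlap]
  if (length(hit) == 0L) {
    hit <- names(ov)[which.max(ov)]
    attr(hit, "below_threshold") <- TRUE
  }
  attr(hit, "overlap") <- ov[hit]
  hit
}

#' Judge shape conformity of a patch against an area's expected shape
#'
#' Compares the patch's measured shape class with the expectation recorded
#' for the area.  Returns `"true"` when they match, `"indeterminate"` when
#' the patch's elongation falls in the configured grey band (the location
#' is clear but the shape call is not) or the area has no recorded
#' expectation, and `"false"` otherwise.  Summaries pool non-conforming
#' with indeterminate calls, mirroring how ambiguous shapes are scored.
#'
#' @param patch a [dye_patch] with attached geometry.
#' @param area area label.
#' @param expected_shapes named character vector mapping area labels to
#'   `"spot"`, `"line"` or `"V"`.
#' @param thresholds a [shape_thresholds()] list (supplies the grey band).
#' @return `"true"`, `"false"` or `"indeterminate"`.
#' @export
shape_conformity <- function(patch, area, expected_shapes,
                             thresholds = shape_thresholds()) {
  if (!area %in% names(expected_shapes)) {
    warning(sprintf("area '%s' missing from expected-shape table; indeterminate",
                    area))
    return("indeterminate")
  }
  pl <- tangent_plane_projection(patch_coords(patch))
  ev <- eigen(stats::cov(pl$xy), symmetric = TRUE)
  l <- pmax(ev$values, 0)
  elong <- if (l[2] <= .Machine$double.eps * l[1]) Inf else sqrt(l[1] / l[2])
  if (is.finite(elong) && elong >= thresholds$grey_band[1] &&
        elong <= thresholds$grey_band[2])
    return("indeterminate")
  cls <- classify_shape(patch, thresholds = thresholds, projection = pl,
                        elongation = elong)$shape_class
  if (identical(cls, unname(expected_shapes[area]))) "true" else "false"
}

#' Build outcome records
#'
#' One record per sample, carrying all its injection zones (zone
#' intersections are encoded as sorted label pairs like `"4+5"`), the set
#' of outcome areas hit and optional per-area conformity flags.
#'
#' @param sample_id sample identifier.
#' @param zones character vector of zone labels (length >= 1); multiple
#'   zones are collapsed into a sorted `"a+b"` intersection label.
#' @param areas character vector of outcome areas hit.
#' @param conformity optional named character vector (per area:
#'   `"true"`/`"false"`/`"indeterminate"`).
#' @return A list of class `outcome_record`.
#' @export
outcome_record <- function(sample_id, zones, areas, conformity = NULL) {
  if (length(zones) < 1L) stop("at least one zone required")
  vocab <- outcome_labels()
  if (!all(areas %in% vocab))
    stop("unknown outcome area label(s): ",
         paste(setdiff(areas, vocab), collapse = ", "))
  zone_label <- paste(sort(as.character(zones)), collapse = "+")
  structure(list(sample_id = sample_id, zone = zone_label,
                 areas = unique(areas), conformity = conformity),
            class = "outcome_record")
}

#' Per-zone outcome frequency matrix
#'
#' For each injection zone (and zone-intersection label) observed in the
#' records, the percentage of that zone's samples labelling each outcome
#' area, with the per-cell sample count.  Rows appear only for zones
#' observed; the result is independent of record order.
#'
#' @param records list of [outcome_record] objects.
#' @return A list of class `frequency_matrix` with `percent` (zones x
#'   areas matrix, values in `[0, 100]`), `n_hit` (count matrix) and
#'   `n_row` (samples per zone).
#' @export
frequency_matrix <- function(records) {
  if (length(records) == 0L) stop("non-empty record list required")
  stopifnot(all(vapply(records, inherits, logical(1), "outcome_record")))
  zones <- sort(unique(vapply(records, `[[`, character(1), "zone")))
  areas <- outcome_labels()
  n_hit <- matrix(0L, length(zones), length(areas),
                  dimnames = list(zones, areas))
  n_row <- stats::setNames(integer(length(zones)), zones)
  for (rec in records) {
    n_row[rec$zone] <- n_row[rec$zone] + 1L
    n_hit[rec$zone, rec$areas] <- n_hit[rec$zone, rec$areas] + 1L
  }
  percent <- 100 * sweep(n_hit, 1, n_row, "/")
  structure(list(percent = percent, n_hit = n_hit, n_row = n_row),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix: %d zones x %d areas, %d samples>\n",
              nrow(x$percent), ncol(x$percent), sum(x$n_row)))
  shown <- x$percent[, colSums(x$n_hit) > 0, drop = FALSE]
  print(round(shown, 1))
  invisible(x)
}

#' Frequency-coloured zone thumbnails
#'
#' For each zone row of a frequency matrix, colours every outcome area by
#' its labelling frequency: exactly white at zero frequency ("no examples
#' recorded") and a monotone white-to-crimson ramp up to 100%.  Returns
#' the per-zone colour tables; optionally renders one PNG per zone with
#' mesh faces drawn in a 2D projection.
#'
#' @param fm a [frequency_matrix].
#' @param regions the [outcome_regions] used for scoring.
#' @param mesh the final-stage [stage_mesh].
#' @param out_dir optional directory for PNG thumbnails (requires the
#'   `png` package; one file per zone).
#' @return named list (per zone) of data frames with columns `area`,
#'   `frequency`, `n`, `color`.
#' @export
render_thumbnails <- function(fm, regions, mesh, out_dir = NULL) {
  stopifnot(inherits(fm, "frequency_matrix"))
  ramp <- function(f) grDevices::rgb(1, 1 - 0.85 * f / 100,
                                     1 - 0.78 * f / 100)
  out <- lapply(rownames(fm$percent), function(z) {
    data.frame(area = colnames(fm$percent),
               frequency = fm$percent[z, ],
               n = fm$n_hit[z, ],
               color = ramp(fm$percent[z, ]),
               row.names = NULL)
  })
  names(out) <- rownames(fm$percent)
  if (!is.null(out_dir)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write thumbnail files")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cent <- face_centroids(mesh)
    xy <- cbind(cent[, 1], atan2(cent[, 3], cent[, 2]))
    for (z in names(out)) {
      tab <- out[[z]]
      face_col <- rep("#FFFFFF", length(mesh$faces))
      for (i in order(tab$frequency)) {
        if (tab$frequency[i] > 0)
          face_col[regions[[tab$area[i]]]] <- tab$color[i]
      }
      f <- file.path(out_dir, sprintf("zone_%s.png", z))
      grDevices::png(f, width = 400, height = 300)
      graphics::par(mar = c(1, 1, 2, 1))
      graphics::plot(xy, col = face_col, pch = 15, cex = 0.8, axes = FALSE,
                     xlab = "", ylab = "", main = sprintf("zone %s", z))
      grDevices::dev.off()
    }
  }
  out
}

#' Write / read outcome records as TSV
#'
#' @param records list of [outcome_record] objects.
#' @param path TSV path.
#' @return the path / the record list.
#' @export
write_outcome_records <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(sample_id = r$sample_id, zone = r$zone,
               areas = paste(r$areas, collapse = ","),
               conformity = if (is.null(r$conformity)) NA_character_
                            else paste(names(r$conformity), r$conformity,
                                       sep = "=", collapse = ","))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcome_records
#' @export
read_outcome_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    conf <- NULL
    if (!is.na(df$conformity[i]) && nzchar(df$conformity[i])) {
      kv <- strsplit(strsplit(df$conformity[i], ",")[[1]], "=")
      conf <- stats::setNames(vapply(kv, `[`, character(1), 2),
                              vapply(kv, `[`, character(1), 1))
    }
    outcome_record(df$sample_id[i], strsplit(df$zone[i], "\\+")[[1]],
                   strsplit(df$areas[i], ",")[[1]], conf)
  })
}

#' Read / write outcome-region annotations as CSV
#'
#' The annotation format is a two-column CSV (`region`, `face_index`)
#' mapping each area label to its member faces, editable by hand or from
#' any annotation tool.
#'
#' @param path CSV path.
#' @param mesh optional mesh for index range-checking.
#' @return an [outcome_regions] object.
#' @export
read_outcome_regions <- function(path, mesh = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  outcome_regions(split(as.integer(df$face_index), df$region), mesh)
}

#' @rdname read_outcome_regions
#' @param regions an [outcome_regions] object to write.
#' @export
write_outcome_regions <- function(regions, path) {
  df <- data.frame(
    region = rep(names(regions), lengths(regions)),
    face_index = unlist(regions, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
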