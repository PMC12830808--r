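#' Read and write meshes as OBJ or ascii PLY
#'
#' Minimal wavefront OBJ and ascii PLY support sufficient for
#' corresponding stage-mesh series: vertex positions and tri/quad faces.
#' OBJ face entries of the form `v/vt/vn` keep only the vertex index.
#' Normals, texture coordinates, materials and binary PLY are not handled.
#'
#' @param path file path.
#' @param stage_label label for the returned mesh (defaults to the file
#'   name without extension).
#' @return `read_mesh_obj` / `read_mesh_ply`: a [stage_mesh].
#' @export
read_mesh_obj <- function(path, stage_label = NULL) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("not a usable OBJ file (no vertices or faces): ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v ", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f ", "", fl)), "\\s+"), function(x)
    as.integer(sub("/.*$", "", x)))
  if (is.null(stage_label))
    stage_label <- sub("\\.[^.]*$", "", basename(path))
  stage_mesh(V, faces, stage_label)
}

#' @rdname read_mesh_obj
#' @param mesh a [stage_mesh] to write.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# growthlines stage mesh '%s'", mesh$stage_label), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(vapply(mesh$faces, function(f)
    paste("f", paste(f, collapse = " ")), character(1)), con)
  invisible(path)
}

#' @rdname read_mesh_obj
#' @export
read_mesh_ply <- function(path, stage_label = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  fmt <- grep("^format", lines, value = TRUE)
  if (!any(grepl("ascii", fmt)))
    stop("only ascii PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header missing element counts")
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                  function(x) {
                    n <- as.integer(x[1])
                    as.integer(x[2:(1 + n)]) + 1L  # PLY is 0-based
                  })
  if (is.null(stage_label))
    stage_label <- sub("\\.[^.]*$", "", basename(path))
  stage_mesh(V, faces, stage_label)
}

#' @rdname read_mesh_obj
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", length(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(vapply(mesh$faces, function(f)
    paste(length(f), paste(f - 1L, collapse = " ")), character(1)), con)
  invisible(path)
}

#' Read and write a stage-series manifest
#'
#' A series is stored as one mesh file per stage plus a JSON manifest
#' naming the files and stage labels.  In strict mode (default), reading
#' rejects series whose per-stage face blocks differ, which would break
#' vertex correspondence.
#'
#' @param series a [stage_series].
#' @param dir output directory (created if missing).
#' @param format `"obj"` or `"ply"`.
#' @return `write_stage_series`: the manifest path, invisibly.
#' @export
write_stage_series <- function(series, dir, format = c("obj", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_stages(series))
  for (k in seq_len(n_stages(series))) {
    m <- series$meshes[[k]]
    files[k] <- sprintf("stage_%02d.%s", k - 1L, format)
    writer <- if (format == "obj") write_mesh_obj else write_mesh_ply
    writer(m, file.path(dir, files[k]))
  }
  manifest <- list(
    format = format,
    stages = lapply(seq_len(n_stages(series)), function(k)
      list(file = files[k], label = series$meshes[[k]]$stage_label)))
  jsonlite::write_json(manifest, file.path(dir, "series.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "series.json"))
}

#' @rdname write_stage_series
#' @param manifest path to a `series.json` manifest.
#' @param strict reject series whose stage face lists differ.
#' @return `read_stage_series`: a [stage_series].
#' @export
read_stage_series <- function(manifest, strict = TRUE) {
  man <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  reader <- if (identical(man$format, "ply")) read_mesh_ply else read_mesh_obj
  meshes <- lapply(man$stages, function(st)
    reader(file.path(dir, st$file), stage_label = st$label))
  if (strict) {
    ref <- meshes[[1]]$faces
    for (k in seq_along(meshes))
      if (!identical(meshes[[k]]$faces, ref))
        stop(sprintf("strict mode: face block of stage %d differs from stage 0",
                     k - 1L))
  }
  stage_series(meshes)
}
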