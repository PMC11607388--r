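# Tab-separated dialect: header-free numeric matrices, with an optional
# JSON sidecar (<path>.json) carrying vertex ids, hemisphere labels, TR,
# run boundaries, and map names. Keeps toy fixtures diffable.

read_delim_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "character",
                                   stringsAsFactors = FALSE))
  bad <- matrix(!grepl("^[-+]?([0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)$", m) &
                  m != "NA", nrow(m), ncol(m))
  vals <- suppressWarnings(as.numeric(m))
  if (any(bad)) {
    rows <- sort(unique(which(bad, arr.ind = TRUE)[, 1L]))
    stop("non-numeric value(s) in ", path, " at row(s): ",
         paste(utils::head(rows, 10L), collapse = ", "), call. = FALSE)
  }
  matrix(vals, nrow = nrow(m), ncol = ncol(m))
}

write_delim_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

read_dense_delimited <- function(path) {
  m <- read_delim_matrix(path)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0L)
    stop("non-finite samples in ", path, " at vertex row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  meta <- read_sidecar(path)
  surface_dataset(m,
                  vertex_ids = meta$vertex_ids,
                  hemisphere = if (is.null(meta$hemisphere)) "left"
                               else meta$hemisphere,
                  tr_seconds = if (is.null(meta$tr_seconds)) NA_real_
                               else meta$tr_seconds,
                  run_boundaries = meta$run_boundaries)
}

write_dense_delimited <- function(dataset, path) {
  write_delim_matrix(dataset$data, path)
  write_sidecar(path, list(vertex_ids = dataset$vertex_ids,
                           hemisphere = dataset$hemisphere,
                           tr_seconds = dataset$tr_seconds,
                           run_boundaries = dataset$run_boundaries))
  invisible(path)
}

read_scalar_delimited <- function(path) {
  m <- read_delim_matrix(path)
  meta <- read_sidecar(path)
  values <- as.numeric(m[, 1L])
  attr(values, "map_name") <- if (is.null(meta$map_name)) "scalar"
                              else meta$map_name
  values
}

write_scalar_delimited <- function(values, path, name) {
  write_delim_matrix(matrix(as.numeric(values), ncol = 1L), path)
  write_sidecar(path, list(map_name = name))
  invisible(path)
}

read_mesh_delimited <- function(path) {
  coords <- read_delim_matrix(path)
  tri <- read_delim_matrix(paste0(path, ".tri"))
  surface_mesh(coords, tri)
}

write_mesh_delimited <- function(mesh, path) {
  write_delim_matrix(mesh$coordinates, path)
  write_delim_matrix(mesh$triangles, paste0(path, ".tri"))
  invisible(path)
}

read_parcellation_delimited <- function(path) {
  labels <- as.integer(read_delim_matrix(path)[, 1L])
  meta <- read_sidecar(path)
  if (is.null(meta$name_map))
    stop("parcellation sidecar with name_map required: ", sidecar_path(path),
         call. = FALSE)
  name_map <- unlist(meta$name_map)
  groups <- if (is.null(meta$sensory_groups)) {
    list(V1 = "V1", S1 = c("1", "2", "3a", "3b"), A1 = "A1")
  } else {
    lapply(meta$sensory_groups, unlist)
  }
  parcellation(labels, name_map, groups)
}

write_parcellation_delimited <- function(parc, path) {
  write_delim_matrix(matrix(parc$labels, ncol = 1L), path)
  write_sidecar(path, list(name_map = as.list(parc$name_map),
                           sensory_groups = parc$sensory_groups))
  invisible(path)
}
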