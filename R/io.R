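guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("delimited", "gifti",
                                                   "cifti")))
  if (grepl("\\.(dtseries|dscalar)\\.nii$", path)) "cifti"
  else if (grepl("\\.gii$", path)) "gifti"
  else "delimited"
}

#' Read a dense surface time series
#'
#' Reads a vertices-by-timepoints matrix from a CIFTI-2 dense series, a
#' GIFTI functional file, or a tab-separated matrix (optionally with a JSON
#' sidecar for vertex ids, hemisphere labels, TR, and run boundaries).
#' CIFTI files list cortical vertices explicitly, so medial-wall and
#' non-cortical rows are excluded on read; row order is preserved.
#'
#' @param path input file.
#' @param format `"cifti"`, `"gifti"`, or `"delimited"`; guessed from the
#'   file name when `NULL`.
#' @return A [surface_dataset()].
#' @export
read_dense_timeseries <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(guess_format(path, format),
         delimited = read_dense_delimited(path),
         gifti = read_dense_gifti(path),
         cifti = read_dense_cifti(path))
}

#' Write a dense surface time series
#'
#' @param dataset a [surface_dataset()].
#' @param path output file.
#' @inheritParams read_dense_timeseries
#' @return The path, invisibly.
#' @export
write_dense_timeseries <- function(dataset, path, format = NULL) {
  switch(guess_format(path, format),
         delimited = write_dense_delimited(dataset, path),
         gifti = write_dense_gifti(dataset, path),
         cifti = write_dense_cifti(dataset, path))
}

#' Write a per-vertex scalar result map
#'
#' One value per vertex of `dataset`. The map name is recorded in the
#' format's metadata; a map named `"angle"` is validated against the
#' angular domain \[0, 360).
#'
#' @param values numeric vector, one value per vertex (`NA` allowed for
#'   flagged vertices).
#' @param dataset the [surface_dataset()] the values belong to.
#' @param path output file.
#' @param format `"cifti"`, `"gifti"`, or `"delimited"` (guessed when
#'   `NULL`).
#' @param name map name (e.g. `"angle"`, `"magnitude"`, `"difference"`).
#' @return The path, invisibly.
#' @export
write_scalar_map <- function(values, dataset, path, format = NULL,
                             name = "scalar") {
  values <- as.numeric(values)
  if (length(values) != n_vertices(dataset))
    stop("one value per vertex required: got ", length(values), " for ",
         n_vertices(dataset), " vertices", call. = FALSE)
  if (identical(name, "angle")) {
    ok <- is.na(values) | (values >= 0 & values < 360)
    if (!all(ok))
      stop("angle values must lie in [0, 360): offending vertex row(s) ",
           paste(utils::head(which(!ok), 10L), collapse = ", "),
           call. = FALSE)
  }
  switch(guess_format(path, format),
         delimited = write_scalar_delimited(values, path, name),
         gifti = write_scalar_gifti(values, path, name,
                                    hemisphere = dataset$hemisphere[1L]),
         cifti = write_scalar_cifti(values, dataset, path, name))
}

#' Read a per-vertex scalar map
#'
#' @inheritParams read_dense_timeseries
#' @return Numeric vector with a `map_name` attribute.
#' @export
read_scalar_map <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(guess_format(path, format),
         delimited = read_scalar_delimited(path),
         gifti = read_scalar_gifti(path),
         cifti = read_scalar_cifti(path))
}

#' Read a triangulated surface mesh
#'
#' Delimited meshes are a coordinate TSV (`path`) plus a triangle TSV
#' (`path.tri`, 1-based indices); GIFTI surf files carry POINTSET and
#' TRIANGLE arrays (0-based on disk, shifted on read).
#'
#' @inheritParams read_dense_timeseries
#' @return A [surface_mesh()].
#' @export
read_surface_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(guess_format(path, format),
         delimited = read_mesh_delimited(path),
         gifti = read_mesh_gifti(path),
         cifti = stop("meshes are not stored in CIFTI files", call. = FALSE))
}

#' Write a triangulated surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @inheritParams write_dense_timeseries
#' @return The path, invisibly.
#' @export
write_surface_mesh <- function(mesh, path, format = NULL) {
  switch(guess_format(path, format),
         delimited = write_mesh_delimited(mesh, path),
         gifti = write_mesh_gifti(mesh, path),
         cifti = stop("meshes are not stored in CIFTI files", call. = FALSE))
}

#' Read a vertex parcellation
#'
#' @inheritParams read_dense_timeseries
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(guess_format(path, format),
         delimited = read_parcellation_delimited(path),
         gifti = read_parcellation_gifti(path),
         cifti = stop("use label GIFTI or delimited parcellations",
                      call. = FALSE))
}

#' Write a vertex parcellation
#'
#' @param parc a [parcellation()].
#' @inheritParams write_dense_timeseries
#' @return The path, invisibly.
#' @export
write_parcellation <- function(parc, path, format = NULL) {
  switch(guess_format(path, format),
         delimited = write_parcellation_delimited(parc, path),
         gifti = write_parcellation_gifti(parc, path),
         cifti = stop("use label GIFTI or delimited parcellations",
                      call. = FALSE))
}
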