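# CIFTI-2 dense files (.dtseries.nii, .dscalar.nii): a NIfTI-2 container
# whose header extension (code 32) is an XML matrix map. Only surface
# brain models are read; voxel models and the medial wall are excluded by
# construction since CIFTI lists cortical vertices explicitly.

cifti_xml <- function(img) {
  exts <- RNifti::extensions(img)
  for (e in exts) {
    if (identical(attr(e, "code"), 32L))
      return(xml2::read_xml(rawToChar(e)))
  }
  stop("no CIFTI extension (code 32) found in NIfTI header", call. = FALSE)
}

cifti_parse_brain_models <- function(doc) {
  maps <- xml2::xml_find_all(doc, "//MatrixIndicesMap")
  bm_map <- NULL
  for (m in maps) {
    if (identical(xml2::xml_attr(m, "IndicesMapToDataType"),
                  "CIFTI_INDEX_TYPE_BRAIN_MODELS")) bm_map <- m
  }
  if (is.null(bm_map))
    stop("CIFTI file has no BRAIN_MODELS matrix map", call. = FALSE)
  models <- xml2::xml_find_all(bm_map, "./BrainModel")
  out <- list()
  for (bm in models) {
    if (!identical(xml2::xml_attr(bm, "ModelType"),
                   "CIFTI_MODEL_TYPE_SURFACE")) next
    structure_name <- xml2::xml_attr(bm, "BrainStructure")
    offset <- as.integer(xml2::xml_attr(bm, "IndexOffset"))
    count <- as.integer(xml2::xml_attr(bm, "IndexCount"))
    vi_node <- xml2::xml_find_first(bm, "./VertexIndices")
    vertices <- as.integer(strsplit(trimws(xml2::xml_text(vi_node)),
                                    "[[:space:]]+")[[1L]])
    if (length(vertices) != count)
      stop("CIFTI BrainModel VertexIndices length mismatch", call. = FALSE)
    hemi <- if (grepl("RIGHT", structure_name)) "right" else "left"
    out[[length(out) + 1L]] <- list(hemisphere = hemi, offset = offset,
                                    vertices = vertices)
  }
  if (length(out) == 0L)
    stop("CIFTI file holds no surface brain models", call. = FALSE)
  out
}

cifti_series_step <- function(doc) {
  maps <- xml2::xml_find_all(doc, "//MatrixIndicesMap")
  for (m in maps) {
    if (identical(xml2::xml_attr(m, "IndicesMapToDataType"),
                  "CIFTI_INDEX_TYPE_SERIES")) {
      step <- as.numeric(xml2::xml_attr(m, "SeriesStep"))
      unit <- xml2::xml_attr(m, "SeriesUnit")
      if (identical(unit, "SECOND")) return(step)
      return(NA_real_)
    }
  }
  NA_real_
}

read_dense_cifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("cannot read NIfTI container ", path, ": ", conditionMessage(e),
         call. = FALSE))
  doc <- cifti_xml(img)
  models <- cifti_parse_brain_models(doc)
  d <- dim(img)
  n_rows <- d[length(d)]       # CIFTI dim 7: columns of the matrix (vertices)
  n_maps <- d[length(d) - 1L]  # CIFTI dim 6: rows (timepoints / maps)
  m <- t(matrix(as.vector(img), nrow = n_maps, ncol = n_rows))
  hemi <- character(n_rows)
  ids <- integer(n_rows)
  for (bm in models) {
    rows <- bm$offset + seq_along(bm$vertices)  # offset is 0-based
    hemi[rows] <- bm$hemisphere
    ids[rows] <- bm$vertices + 1L               # to 1-based
  }
  keep <- hemi != ""                            # drop voxel-model rows
  m <- m[keep, , drop = FALSE]
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0L)
    stop("non-finite samples in ", path, " at vertex row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  surface_dataset(m, vertex_ids = ids[keep], hemisphere = hemi[keep],
                  tr_seconds = cifti_series_step(doc))
}

cifti_brain_models_xml <- function(dataset, applies_to = 1L) {
  parts <- character(0)
  offset <- 0L
  for (h in c("left", "right")) {
    rows <- which(dataset$hemisphere == h)
    if (length(rows) == 0L) next
    verts <- dataset$vertex_ids[rows] - 1L      # to 0-based
    surf_n <- max(verts) + 1L
    parts <- c(parts, paste0(
      '<BrainModel IndexOffset="', offset, '" IndexCount="', length(rows),
      '" ModelType="CIFTI_MODEL_TYPE_SURFACE" BrainStructure="',
      if (h == "left") "CIFTI_STRUCTURE_CORTEX_LEFT"
      else "CIFTI_STRUCTURE_CORTEX_RIGHT",
      '" SurfaceNumberOfVertices="', surf_n, '">',
      "<VertexIndices>", paste(verts, collapse = " "), "</VertexIndices>",
      "</BrainModel>"))
    offset <- offset + length(rows)
  }
  paste0('<MatrixIndicesMap AppliesToMatrixDimension="', applies_to,
         '" IndicesMapToDataType="CIFTI_INDEX_TYPE_BRAIN_MODELS">',
         paste(parts, collapse = ""), "</MatrixIndicesMap>")
}

# CIFTI orders left-hemisphere rows before right; reorder a copy if needed.
cifti_hemi_order <- function(dataset) {
  ord <- order(match(dataset$hemisphere, c("left", "right")),
               seq_along(dataset$hemisphere))
  if (identical(ord, seq_along(ord))) return(list(dataset = dataset,
                                                  order = ord))
  list(dataset = surface_dataset(dataset$data[ord, , drop = FALSE],
                                 vertex_ids = dataset$vertex_ids[ord],
                                 hemisphere = dataset$hemisphere[ord],
                                 tr_seconds = dataset$tr_seconds,
                                 run_boundaries = dataset$run_boundaries),
       order = ord)
}

cifti_write_container <- function(matrix_rows_by_maps, xml, path) {
  n_maps <- ncol(matrix_rows_by_maps)
  n_rows <- nrow(matrix_rows_by_maps)
  arr <- array(as.numeric(t(matrix_rows_by_maps)),
               dim = c(1L, 1L, 1L, 1L, n_maps, n_rows))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`extension<-`(img, 32L, charToRaw(xml))
  ok <- tryCatch({ RNifti::writeNifti(img, path, version = 2);
                   file.exists(path) },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write CIFTI file: ", path, call. = FALSE)
  invisible(path)
}

write_dense_cifti <- function(dataset, path) {
  reord <- cifti_hemi_order(dataset)
  ds <- reord$dataset
  step <- if (is.na(ds$tr_seconds)) 1 else ds$tr_seconds
  xml <- paste0('<CIFTI Version="2.0"><Matrix>',
                '<MatrixIndicesMap AppliesToMatrixDimension="0" ',
                'IndicesMapToDataType="CIFTI_INDEX_TYPE_SERIES" ',
                'NumberOfSeriesPoints="', ncol(ds$data),
                '" SeriesExponent="0" SeriesStart="0" SeriesStep="',
                format(step, digits = 17), '" SeriesUnit="SECOND"/>',
                cifti_brain_models_xml(ds), "</Matrix></CIFTI>")
  cifti_write_container(ds$data, xml, path)
}

write_scalar_cifti <- function(values, dataset, path, name) {
  reord <- cifti_hemi_order(dataset)
  xml <- paste0('<CIFTI Version="2.0"><Matrix>',
                '<MatrixIndicesMap AppliesToMatrixDimension="0" ',
                'IndicesMapToDataType="CIFTI_INDEX_TYPE_SCALARS">',
                "<NamedMap><MapName><![CDATA[", name,
                "]]></MapName></NamedMap></MatrixIndicesMap>",
                cifti_brain_models_xml(reord$dataset), "</Matrix></CIFTI>")
  cifti_write_container(matrix(as.numeric(values)[reord$order], ncol = 1L),
                        xml, path)
}

read_scalar_cifti <- function(path) {
  img <- RNifti::readNifti(path)
  doc <- cifti_xml(img)
  d <- dim(img)
  n_rows <- d[length(d)]
  n_maps <- d[length(d) - 1L]
  m <- t(matrix(as.vector(img), nrow = n_maps, ncol = n_rows))
  values <- as.numeric(m[, 1L])
  nm <- xml2::xml_text(xml2::xml_find_first(doc, "//NamedMap/MapName"))
  attr(values, "map_name") <- if (is.na(nm) || nm == "") "scalar" else nm
  values
}
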