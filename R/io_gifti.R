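# Minimal GIFTI-1 XML support for dense func/surf/label/shape arrays.
# Writing uses ASCII encoding (diffable); reading additionally handles
# Base64Binary and GZipBase64Binary little-endian payloads.

gii_type_info <- function(datatype) {
  switch(datatype,
         "NIFTI_TYPE_FLOAT32" = list(what = "double", size = 4L),
         "NIFTI_TYPE_FLOAT64" = list(what = "double", size = 8L),
         "NIFTI_TYPE_INT32"   = list(what = "integer", size = 4L),
         "NIFTI_TYPE_UINT8"   = list(what = "integer", size = 1L),
         stop("unsupported GIFTI datatype: ", datatype, call. = FALSE))
}

gii_decode_data <- function(node) {
  encoding <- xml2::xml_attr(node, "Encoding")
  datatype <- xml2::xml_attr(node, "DataType")
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dims <- vapply(paste0("Dim", 0:(ndim - 1L)),
                 function(a) as.integer(xml2::xml_attr(node, a)), 0L,
                 USE.NAMES = FALSE)
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  data_node <- xml2::xml_find_first(node, ".//*[local-name()='Data']")
  txt <- xml2::xml_text(data_node)
  values <- switch(encoding,
    "ASCII" = as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1L]]),
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (encoding == "GZipBase64Binary")
        raw <- memDecompress(raw, type = "gzip")
      info <- gii_type_info(datatype)
      readBin(raw, what = info$what, n = prod(dims), size = info$size,
              endian = "little")
    },
    stop("unsupported GIFTI encoding: ", encoding, call. = FALSE))
  if (length(values) != prod(dims))
    stop("GIFTI data length does not match declared dims", call. = FALSE)
  if (length(dims) == 2L) {
    if (identical(order, "ColumnMajorOrder"))
      matrix(values, nrow = dims[1L], ncol = dims[2L])
    else
      matrix(values, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  } else {
    values
  }
}

gii_metadata <- function(node) {
  md <- xml2::xml_find_all(node, "./*[local-name()='MetaData']/*[local-name()='MD']")
  vals <- vapply(md, function(m)
    xml2::xml_text(xml2::xml_find_first(m, "./*[local-name()='Value']")), "")
  names(vals) <- vapply(md, function(m)
    xml2::xml_text(xml2::xml_find_first(m, "./*[local-name()='Name']")), "")
  vals
}

gii_read <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse GIFTI file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  root <- xml2::xml_find_first(doc, "/*[local-name()='GIFTI']")
  if (inherits(root, "xml_missing"))
    stop("not a GIFTI document (missing GIFTI root): ", path, call. = FALSE)
  arrays <- xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
  list(
    arrays = lapply(arrays, gii_decode_data),
    intents = vapply(arrays, function(a) xml2::xml_attr(a, "Intent"), ""),
    metadata = lapply(arrays, gii_metadata),
    file_metadata = gii_metadata(root),
    labels = gii_read_label_table(doc)
  )
}

gii_read_label_table <- function(doc) {
  nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='LabelTable']/*[local-name()='Label']")
  if (length(nodes) == 0L) return(NULL)
  keys <- vapply(nodes, function(n) xml2::xml_attr(n, "Key"), "")
  vals <- vapply(nodes, xml2::xml_text, "")
  stats::setNames(vals, keys)
}

gii_format_values <- function(x, datatype) {
  if (datatype == "NIFTI_TYPE_INT32") format(as.integer(x), trim = TRUE)
  else format(as.numeric(x), digits = 17, trim = TRUE)
}

gii_array_xml <- function(values, intent, datatype, metadata = NULL,
                          label_table = NULL) {
  if (is.matrix(values)) {
    dims <- sprintf(' Dimensionality="2" Dim0="%d" Dim1="%d"',
                    nrow(values), ncol(values))
    payload <- paste(apply(values, 1L, function(r)
      paste(gii_format_values(r, datatype), collapse = " ")),
      collapse = "\n")
  } else {
    dims <- sprintf(' Dimensionality="1" Dim0="%d"', length(values))
    payload <- paste(gii_format_values(values, datatype), collapse = "\n")
  }
  md <- ""
  if (!is.null(metadata) && length(metadata) > 0L) {
    md <- paste0("<MetaData>",
                 paste0("<MD><Name><![CDATA[", names(metadata),
                        "]]></Name><Value><![CDATA[", metadata,
                        "]]></Value></MD>", collapse = ""),
                 "</MetaData>")
  }
  paste0('<DataArray Intent="', intent, '" DataType="', datatype,
         '" ArrayIndexingOrder="RowMajorOrder" Encoding="ASCII" ',
         'Endian="LittleEndian" ExternalFileName="" ExternalFileOffset=""',
         dims, ">", md, "<Data>", payload, "</Data></DataArray>")
}

gii_write <- function(path, arrays_xml, file_metadata = NULL) {
  md <- ""
  if (!is.null(file_metadata) && length(file_metadata) > 0L) {
    md <- paste0("<MetaData>",
                 paste0("<MD><Name><![CDATA[", names(file_metadata),
                        "]]></Name><Value><![CDATA[", file_metadata,
                        "]]></Value></MD>", collapse = ""),
                 "</MetaData>")
  }
  txt <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="',
                length(arrays_xml), '">', md,
                paste(arrays_xml, collapse = "\n"), "</GIFTI>")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write GIFTI file: ", path, call. = FALSE)
  invisible(path)
}

gii_structure <- function(hemisphere) {
  if (hemisphere == "left") "CortexLeft" else "CortexRight"
}

gii_hemisphere <- function(metadata_list, file_metadata) {
  pick <- function(md) {
    s <- unname(md["AnatomicalStructurePrimary"])
    if (length(s) != 1L || is.na(s)) NA_character_
    else if (grepl("Right", s, ignore.case = TRUE)) "right" else "left"
  }
  for (md in metadata_list) {
    h <- pick(md)
    if (!is.na(h)) return(h)
  }
  h <- pick(file_metadata)
  if (is.na(h)) "left" else h
}

read_dense_gifti <- function(path) {
  g <- gii_read(path)
  cols <- g$arrays[g$intents != "NIFTI_INTENT_POINTSET" &
                   g$intents != "NIFTI_INTENT_TRIANGLE"]
  if (length(cols) == 0L)
    stop("GIFTI file holds no functional data arrays: ", path, call. = FALSE)
  m <- do.call(cbind, lapply(cols, as.numeric))
  hemi <- gii_hemisphere(g$metadata, g$file_metadata)
  tr <- suppressWarnings(as.numeric(unname(g$file_metadata["TimeStep"])))
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0L)
    stop("non-finite samples in ", path, " at vertex row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  surface_dataset(m, hemisphere = hemi,
                  tr_seconds = if (length(tr) == 1L && !is.na(tr)) tr
                               else NA_real_)
}

write_dense_gifti <- function(dataset, path) {
  hemi <- unique(dataset$hemisphere)
  if (length(hemi) != 1L)
    stop("GIFTI func files hold one hemisphere; split the dataset first",
         call. = FALSE)
  arrays <- lapply(seq_len(ncol(dataset$data)), function(j)
    gii_array_xml(dataset$data[, j], "NIFTI_INTENT_TIME_SERIES",
                  "NIFTI_TYPE_FLOAT32",
                  metadata = c(AnatomicalStructurePrimary =
                                 gii_structure(hemi))))
  fm <- c(AnatomicalStructurePrimary = gii_structure(hemi))
  if (!is.na(dataset$tr_seconds))
    fm <- c(fm, TimeStep = format(dataset$tr_seconds, digits = 17))
  gii_write(path, arrays, fm)
}

read_scalar_gifti <- function(path) {
  g <- gii_read(path)
  values <- as.numeric(g$arrays[[1L]])
  nm <- unname(g$metadata[[1L]]["Name"])
  attr(values, "map_name") <- if (length(nm) != 1L || is.na(nm)) "scalar"
                              else nm
  values
}

write_scalar_gifti <- function(values, path, name, hemisphere = "left") {
  arr <- gii_array_xml(as.numeric(values), "NIFTI_INTENT_NONE",
                       "NIFTI_TYPE_FLOAT32",
                       metadata = c(Name = name,
                                    AnatomicalStructurePrimary =
                                      gii_structure(hemisphere)))
  gii_write(path, list(arr))
}

read_mesh_gifti <- function(path) {
  g <- gii_read(path)
  pts <- g$arrays[[match("NIFTI_INTENT_POINTSET", g$intents)]]
  tri <- g$arrays[[match("NIFTI_INTENT_TRIANGLE", g$intents)]]
  if (is.null(pts) || is.null(tri))
    stop("surf GIFTI needs POINTSET and TRIANGLE arrays: ", path,
         call. = FALSE)
  surface_mesh(pts, tri + 1L)  # triangles are 0-based on disk
}

write_mesh_gifti <- function(mesh, path, hemisphere = "left") {
  arrays <- list(
    gii_array_xml(mesh$coordinates, "NIFTI_INTENT_POINTSET",
                  "NIFTI_TYPE_FLOAT32",
                  metadata = c(AnatomicalStructurePrimary =
                                 gii_structure(hemisphere))),
    gii_array_xml(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32"))
  gii_write(path, arrays)
}

read_parcellation_gifti <- function(path) {
  g <- gii_read(path)
  labels <- as.integer(g$arrays[[1L]])
  if (is.null(g$labels))
    stop("label GIFTI without LabelTable: ", path, call. = FALSE)
  name_map <- g$labels[g$labels != "???"]
  parcellation(labels, name_map)
}

write_parcellation_gifti <- function(parc, path, hemisphere = "left") {
  lt <- paste0("<LabelTable>",
               '<Label Key="0" Red="1" Green="1" Blue="1" Alpha="0">',
               "<![CDATA[???]]></Label>",
               paste0('<Label Key="', names(parc$name_map),
                      '" Red="0.5" Green="0.5" Blue="0.5" Alpha="1">',
                      "<![CDATA[", parc$name_map, "]]></Label>",
                      collapse = ""),
               "</LabelTable>")
  arr <- gii_array_xml(as.integer(parc$labels), "NIFTI_INTENT_LABEL",
                       "NIFTI_TYPE_INT32",
                       metadata = c(AnatomicalStructurePrimary =
                                      gii_structure(hemisphere)))
  md <- ""
  txt <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="1">', md, lt,
                arr, "</GIFTI>")
  writeLines(txt, path)
  invisible(path)
}
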