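#' Triangulated surface mesh
#'
#' @param coordinates numeric matrix, one xyz row (mm) per vertex.
#' @param triangles integer matrix with three 1-based vertex indices per row.
#' @return An object of class `surface_mesh` with an `adjacency` element
#'   (list of sorted neighbor index vectors) built via [build_adjacency()].
#' @export
surface_mesh <- function(coordinates, triangles) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(coordinates) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  if (ncol(triangles) != 3L) stop("triangles must be m x 3", call. = FALSE)
  nv <- nrow(coordinates)
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of vertex range", call. = FALSE)
  mesh <- structure(list(coordinates = coordinates, triangles = triangles,
                         adjacency = NULL),
                    class = "surface_mesh")
  mesh$adjacency <- build_adjacency(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$coordinates), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Vertex neighbor relation from shared triangle edges
#'
#' Two vertices are neighbors iff they share an edge of at least one
#' triangle. The relation is symmetric and irreflexive.
#'
#' @param mesh a [surface_mesh()] (or a bare list with `coordinates` and
#'   `triangles`).
#' @return A list with one sorted integer vector of neighbor indices per
#'   vertex.
#' @export
build_adjacency <- function(mesh) {
  tri <- mesh$triangles
  storage.mode(tri) <- "integer"
  if (any(tri[, 1L] == tri[, 2L] | tri[, 1L] == tri[, 3L] |
          tri[, 2L] == tri[, 3L]))
    stop("degenerate triangle with repeated vertex", call. = FALSE)
  nv <- nrow(mesh$coordinates)
  from <- c(tri[, 1L], tri[, 2L], tri[, 3L], tri[, 2L], tri[, 3L], tri[, 1L])
  to   <- c(tri[, 2L], tri[, 3L], tri[, 1L], tri[, 1L], tri[, 2L], tri[, 3L])
  adj <- split(to, factor(from, levels = seq_len(nv)))
  unname(lapply(adj, function(v) sort(unique(v))))
}

#' Parcellation labels for a surface dataset
#'
#' Associates every vertex with an integer parcel code and groups parcels
#' into the three primary sensory systems: V1 (primary visual), A1 (primary
#' auditory), and the four-area primary somatosensory strip (areas 1, 2,
#' 3a, 3b), following the multimodal-parcellation naming convention.
#'
#' @param labels integer code per vertex (0 = unlabeled association cortex).
#' @param name_map named character vector mapping code (as name) to parcel
#'   name, e.g. `c("1" = "V1", "2" = "A1", ...)`.
#' @param sensory_groups named list mapping group name (`V1`, `S1`, `A1`) to
#'   the parcel names it comprises. Defaults to the standard grouping.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, name_map,
                         sensory_groups = list(V1 = "V1",
                                               S1 = c("1", "2", "3a", "3b"),
                                               A1 = "A1")) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integer codes", call. = FALSE)
  if (is.null(names(name_map))) stop("name_map must be named", call. = FALSE)
  structure(list(labels = labels, name_map = name_map,
                 sensory_groups = sensory_groups),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", length(x$labels), " vertices, ",
      length(x$name_map), " named parcels\n", sep = "")
  invisible(x)
}

#' Vertices belonging to a sensory group
#'
#' @param parc a [parcellation()].
#' @param group one of the names of `parc$sensory_groups` (typically
#'   `"V1"`, `"S1"`, `"A1"`).
#' @return Integer vector of vertex indices (1-based).
#' @export
group_vertices <- function(parc, group) {
  if (!group %in% names(parc$sensory_groups))
    stop("unknown sensory group: ", group, call. = FALSE)
  parcel_names <- parc$sensory_groups[[group]]
  codes <- as.integer(names(parc$name_map)[parc$name_map %in% parcel_names])
  idx <- which(parc$labels %in% codes)
  if (length(idx) == 0L)
    stop("sensory group '", group, "' is empty on this parcellation",
         call. = FALSE)
  idx
}
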