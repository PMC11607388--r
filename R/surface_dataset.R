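#' Dense cortical surface time series
#'
#' Container for BOLD samples on a triangulated cortical surface: a
#' vertices-by-timepoints matrix plus per-vertex bookkeeping. This is the
#' dependent variable of the sensory-integration regression.
#'
#' @param data numeric matrix, vertices in rows, timepoints in columns.
#' @param vertex_ids integer vector, one id per row. Defaults to
#'   `seq_len(nrow(data))`. Ids are 1-based; ids read from 0-based file
#'   formats (GIFTI, CIFTI) are shifted on read.
#' @param hemisphere character vector (`"left"`/`"right"`), either length 1
#'   (recycled) or one entry per vertex.
#' @param tr_seconds repetition time in seconds, or `NA` when unknown.
#' @param run_boundaries integer vector of cumulative run end columns, one
#'   per concatenated run; the last element must equal `ncol(data)`. A
#'   single-run dataset has `run_boundaries = ncol(data)`.
#'
#' @return An object of class `surface_dataset`.
#' @export
surface_dataset <- function(data, vertex_ids = NULL,
                            hemisphere = "left",
                            tr_seconds = NA_real_,
                            run_boundaries = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(rowSums(!is.finite(data)) > 0L)
    stop("non-finite samples at vertex row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  nv <- nrow(data)
  if (is.null(vertex_ids)) vertex_ids <- seq_len(nv)
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) != nv)
    stop("vertex_ids length must equal number of rows", call. = FALSE)
  if (length(hemisphere) == 1L) hemisphere <- rep(hemisphere, nv)
  if (length(hemisphere) != nv)
    stop("hemisphere labels must match number of rows", call. = FALSE)
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere labels must be 'left' or 'right'", call. = FALSE)
  if (!is.na(tr_seconds) && tr_seconds <= 0)
    stop("tr_seconds must be positive or NA", call. = FALSE)
  if (is.null(run_boundaries)) run_boundaries <- ncol(data)
  run_boundaries <- as.integer(run_boundaries)
  if (length(run_boundaries) == 0L || any(diff(run_boundaries) <= 0L) ||
      run_boundaries[1L] < 1L ||
      run_boundaries[length(run_boundaries)] != ncol(data))
    stop("run_boundaries must be strictly increasing and end at ncol(data)",
         call. = FALSE)
  structure(list(data = data, vertex_ids = vertex_ids,
                 hemisphere = hemisphere, tr_seconds = tr_seconds,
                 run_boundaries = run_boundaries),
            class = "surface_dataset")
}

#' @export
print.surface_dataset <- function(x, ...) {
  cat("<surface_dataset> ", nrow(x$data), " vertices x ", ncol(x$data),
      " timepoints, ", length(x$run_boundaries), " run(s)\n", sep = "")
  hem <- table(x$hemisphere)
  cat("  hemisphere:", paste(names(hem), hem, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.surface_dataset <- function(x) dim(x$data)

n_vertices <- function(x) nrow(x$data)
n_timepoints <- function(x) ncol(x$data)

#' Number of runs and their column ranges
#'
#' @param dataset a [surface_dataset()].
#' @return A two-column integer matrix (`start`, `end`), one row per run.
#' @export
run_ranges <- function(dataset) {
  ends <- dataset$run_boundaries
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Extract one run as a single-run dataset
#'
#' @param dataset a [surface_dataset()].
#' @param run run index (1-based).
#' @return A single-run [surface_dataset()].
#' @export
extract_run <- function(dataset, run) {
  rr <- run_ranges(dataset)
  if (run < 1L || run > nrow(rr)) stop("run index out of range", call. = FALSE)
  cols <- rr[run, "start"]:rr[run, "end"]
  surface_dataset(dataset$data[, cols, drop = FALSE],
                  vertex_ids = dataset$vertex_ids,
                  hemisphere = dataset$hemisphere,
                  tr_seconds = dataset$tr_seconds)
}

stop_vertex_mismatch <- function(a, b) {
  if (nrow(a$data) != nrow(b$data) ||
      !identical(a$vertex_ids, b$vertex_ids) ||
      !identical(a$hemisphere, b$hemisphere))
    stop("datasets have mismatching vertex sets or order", call. = FALSE)
  invisible(NULL)
}
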