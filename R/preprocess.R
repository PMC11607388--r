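#' Drop rest intervals (plus a hemodynamic lag) from a movie run
#'
#' Movie-watching runs interleave stimulus clips with rest intervals. The
#' rest volumes are discarded, and to account for the hemodynamic delay the
#' `lag_volumes` volumes immediately following each rest interval are
#' discarded as well. Applies to a single run.
#'
#' @param dataset a single-run [surface_dataset()].
#' @param rest_mask logical (or 0/1) vector, one entry per timepoint;
#'   `TRUE` marks a rest volume.
#' @param lag_volumes non-negative count of post-rest volumes to drop
#'   (default 10).
#' @return A [surface_dataset()] with the retained timepoints.
#' @export
trim_rest_volumes <- function(dataset, rest_mask, lag_volumes = 10L) {
  if (length(dataset$run_boundaries) != 1L)
    stop("trim_rest_volumes applies to a single run; use extract_run()",
         call. = FALSE)
  n <- n_timepoints(dataset)
  rest_mask <- as.logical(rest_mask)
  if (length(rest_mask) != n)
    stop("rest_mask length (", length(rest_mask),
         ") must equal timepoint count (", n, ")", call. = FALSE)
  if (anyNA(rest_mask)) stop("rest_mask must be 0/1 or logical",
                             call. = FALSE)
  lag_volumes <- as.integer(lag_volumes)
  if (lag_volumes < 0L) stop("lag_volumes must be >= 0", call. = FALSE)
  drop <- rest_mask
  if (lag_volumes > 0L) {
    # a volume is lag-dropped when any of the preceding lag_volumes volumes
    # is a rest volume
    rest_end <- which(rest_mask & !c(rest_mask[-1L], FALSE))
    for (e in rest_end) {
      lag <- e + seq_len(lag_volumes)
      drop[lag[lag <= n]] <- TRUE
    }
  }
  keep <- which(!drop)
  if (length(keep) == 0L) stop("no timepoints retained", call. = FALSE)
  surface_dataset(dataset$data[, keep, drop = FALSE],
                  vertex_ids = dataset$vertex_ids,
                  hemisphere = dataset$hemisphere,
                  tr_seconds = dataset$tr_seconds)
}

#' Temporally standardize every vertex series
#'
#' Subtracts the temporal mean and divides by the standard deviation of
#' each vertex series. The SD convention defaults to the population SD
#' (divide by N); the classical sample SD (N - 1) is available via
#' `sd_method`. Constant series cannot be standardized: they are set to
#' all zeros and reported in a warning, and their indices are attached as
#' the `constant_vertices` attribute.
#'
#' @param dataset a [surface_dataset()].
#' @param sd_method `"population"` (default) or `"sample"`.
#' @return A standardized [surface_dataset()].
#' @export
standardize <- function(dataset, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  m <- dataset$data
  n <- ncol(m)
  if (n < 2L) stop("standardize needs at least 2 timepoints", call. = FALSE)
  mu <- rowMeans(m)
  centered <- m - mu
  ss <- rowSums(centered^2)
  s <- sqrt(ss / if (sd_method == "population") n else n - 1L)
  flat <- s < .Machine$double.eps * n * pmax(abs(mu), 1)
  if (any(flat)) {
    warning("zero-variance series set to zeros at vertex row(s): ",
            paste(utils::head(which(flat), 10L), collapse = ", "),
            call. = FALSE)
    s[flat] <- 1
    centered[flat, ] <- 0
  }
  out <- surface_dataset(centered / s,
                         vertex_ids = dataset$vertex_ids,
                         hemisphere = dataset$hemisphere,
                         tr_seconds = dataset$tr_seconds,
                         run_boundaries = dataset$run_boundaries)
  attr(out, "sd_method") <- sd_method
  attr(out, "constant_vertices") <- which(flat)
  out
}

#' Concatenate runs along the time axis
#'
#' All runs must share the same vertex set, order, and hemisphere labels,
#' and should each already be standardized (standardization is per run,
#' before concatenation).
#'
#' @param runs list of [surface_dataset()] objects.
#' @return A [surface_dataset()] whose `run_boundaries` record the joins.
#' @export
concatenate_runs <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L)
    stop("runs must be a non-empty list", call. = FALSE)
  if (length(runs) == 1L) return(runs[[1L]])
  first <- runs[[1L]]
  for (r in runs[-1L]) stop_vertex_mismatch(first, r)
  lens <- vapply(runs, n_timepoints, 0L)
  surface_dataset(do.call(cbind, lapply(runs, `[[`, "data")),
                  vertex_ids = first$vertex_ids,
                  hemisphere = first$hemisphere,
                  tr_seconds = first$tr_seconds,
                  run_boundaries = cumsum(lens))
}

#' Split runs into two concatenated test/retest sessions
#'
#' @param runs named or unnamed list of single-run [surface_dataset()]
#'   objects.
#' @param session_a,session_b run identifiers (names or indices); they
#'   must be disjoint and together cover all runs.
#' @return A list with elements `a` and `b`, each a concatenated
#'   [surface_dataset()].
#' @export
split_sessions <- function(runs, session_a, session_b) {
  ids <- if (is.null(names(runs))) seq_along(runs) else names(runs)
  resolve <- function(s) {
    pos <- match(s, ids)
    if (anyNA(pos)) stop("unknown run identifier(s): ",
                         paste(s[is.na(pos)], collapse = ", "),
                         call. = FALSE)
    pos
  }
  pa <- resolve(session_a)
  pb <- resolve(session_b)
  if (length(intersect(pa, pb)) > 0L)
    stop("sessions overlap: ", paste(ids[intersect(pa, pb)], collapse = ", "),
         call. = FALSE)
  if (!setequal(c(pa, pb), seq_along(runs)))
    stop("sessions must together cover all runs", call. = FALSE)
  list(a = concatenate_runs(runs[pa]), b = concatenate_runs(runs[pb]))
}

#' Preprocess a list of runs into one analysis-ready dataset
#'
#' Fixed order: per-run rest trimming (movie runs only), per-run
#' standardization on the retained volumes, then concatenation.
#'
#' @param runs list of single-run [surface_dataset()] objects.
#' @param rest_masks optional list of per-run rest masks (`NULL` entries
#'   skip trimming for that run).
#' @param lag_volumes post-rest volumes to drop (default 10).
#' @param sd_method SD convention passed to [standardize()].
#' @return A concatenated, standardized [surface_dataset()].
#' @export
preprocess_runs <- function(runs, rest_masks = NULL, lag_volumes = 10L,
                            sd_method = "population") {
  out <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!is.null(rest_masks) && !is.null(rest_masks[[i]]))
      r <- trim_rest_volumes(r, rest_masks[[i]], lag_volumes)
    out[[i]] <- standardize(r, sd_method)
  }
  concatenate_runs(out)
}
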