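#' Threshold a map at a percentile of its finite values
#'
#' Keeps vertices whose value strictly exceeds the stated percentile,
#' computed with linear interpolation (quantile type 7).
#'
#' @param values per-vertex scalars (`NA` ignored, never suprathreshold).
#' @param percentile percentile in \[0, 100).
#' @return Logical mask, plus the cutoff as attribute `cutoff`.
#' @export
threshold_map <- function(values, percentile = 95) {
  finite <- is.finite(values)
  if (!any(finite)) stop("threshold_map needs at least 1 finite value",
                         call. = FALSE)
  cutoff <- as.numeric(stats::quantile(values[finite], percentile / 100,
                                       type = 7, names = FALSE))
  mask <- !is.na(values) & finite & values > cutoff
  attr(mask, "cutoff") <- cutoff
  mask
}

#' Connected components of a suprathreshold vertex set
#'
#' Breadth-first search over the mesh neighbor relation restricted to
#' masked vertices. Cluster ids are assigned in order of descending size
#' (ties by first vertex index).
#'
#' @param mask logical per-vertex mask.
#' @param adjacency neighbor list from [build_adjacency()].
#' @return List with `labels` (integer per vertex, 0 = subthreshold) and
#'   `sizes` (vertex counts, descending).
#' @export
connected_clusters <- function(mask, adjacency) {
  mask <- as.logical(mask)
  if (length(mask) != length(adjacency))
    stop("mask length must match adjacency", call. = FALSE)
  labels <- integer(length(mask))
  sizes <- integer(0)
  next_id <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    next_id <- next_id + 1L
    queue <- seed
    labels[seed] <- next_id
    count <- 1L
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adjacency[[v]]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb) > 0L) {
        labels[nb] <- next_id
        count <- count + length(nb)
        queue <- c(queue, nb)
      }
    }
    sizes <- c(sizes, count)
  }
  if (next_id > 1L) {                  # relabel by descending size
    ord <- order(-sizes, seq_along(sizes))
    relabel <- integer(next_id)
    relabel[ord] <- seq_len(next_id)
    labels[labels > 0L] <- relabel[labels[labels > 0L]]
    sizes <- sizes[ord]
  }
  list(labels = labels, sizes = sizes)
}

max_cluster_size <- function(values, cutoff, adjacency) {
  mask <- !is.na(values) & values > cutoff
  if (!any(mask)) return(0L)
  cl <- connected_clusters(mask, adjacency)
  if (length(cl$sizes) == 0L) 0L else cl$sizes[1L]
}

#' Sign-flip cluster-based permutation test
#'
#' Family-wise inference on subject-level difference maps. The observed
#' group mean map is thresholded at `percentile` and its connected
#' clusters located. In each permutation every subject's whole map is
#' multiplied by an independent fair-coin sign, the permuted group mean is
#' re-thresholded at the same percentile (the cutoff value recomputed
#' within the permuted map), and the maximum cluster size recorded.
#' Each observed cluster's p-value follows the add-one rule
#' `p = (1 + #permutations with max size >= observed) / (1 + n)`; clusters
#' with `p < alpha` are marked significant. The cluster-size threshold at
#' the 95th percentile of the null maximum-size distribution is reported
#' alongside.
#'
#' @param subject_maps subjects-by-vertices matrix of difference values
#'   (angular variances, or signed magnitude differences).
#' @param adjacency neighbor list from [build_adjacency()].
#' @param n_permutations number of sign-flip permutations (default 5000).
#' @param percentile vertex-level threshold percentile (default 95).
#' @param alpha cluster-level significance threshold (default 0.05).
#' @param seed integer seed for the permutation RNG.
#' @return An object of class `cluster_result`: list with `labels`,
#'   `sizes`, `cluster_p`, `significant` (logical per cluster),
#'   `null_max_sizes`, `size_threshold` (95th percentile of the null),
#'   `cutoff`, `group_map`, `n_permutations`, `seed`.
#' @export
sign_flip_cluster_test <- function(subject_maps, adjacency,
                                   n_permutations = 5000L, percentile = 95,
                                   alpha = 0.05, seed = 1L) {
  subject_maps <- as.matrix(subject_maps)
  ns <- nrow(subject_maps)
  if (ns < 2L) stop("sign-flip test needs at least 2 subjects",
                    call. = FALSE)
  if (ncol(subject_maps) != length(adjacency))
    stop("subject maps must align with the mesh adjacency", call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1",
                                call. = FALSE)
  group <- colMeans(subject_maps)
  mask <- threshold_map(group, percentile)
  observed <- connected_clusters(mask, adjacency)

  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_permutations * ns, replace = TRUE),
                  nrow = n_permutations, ncol = ns)
  perm_means <- (signs %*% subject_maps) / ns
  prob <- percentile / 100
  null_max <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    row <- perm_means[p, ]
    cutoff <- as.numeric(stats::quantile(row, prob, type = 7,
                                         names = FALSE))
    null_max[p] <- max_cluster_size(row, cutoff, adjacency)
  }
  sizes <- observed$sizes
  cluster_p <- vapply(sizes, function(s)
    (1 + sum(null_max >= s)) / (1 + n_permutations), 0)
  structure(list(labels = observed$labels, sizes = sizes,
                 cluster_p = cluster_p,
                 significant = cluster_p < alpha,
                 null_max_sizes = null_max,
                 size_threshold = as.numeric(
                   stats::quantile(null_max, 0.95, type = 7, names = FALSE)),
                 cutoff = attr(mask, "cutoff"),
                 group_map = group,
                 n_permutations = n_permutations, percentile = percentile,
                 alpha = alpha, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$sizes), " cluster(s), ",
      x$n_permutations, " permutations (seed ", x$seed, ")\n", sep = "")
  if (length(x$sizes) > 0L) {
    df <- data.frame(id = seq_along(x$sizes), size = x$sizes,
                     p = signif(x$cluster_p, 3),
                     significant = x$significant)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Cluster table of a `cluster_result`
#'
#' @param result a [sign_flip_cluster_test()] result.
#' @return Data frame with columns `id`, `size`, `p`, `significant`.
#' @export
cluster_table <- function(result) {
  data.frame(id = seq_along(result$sizes), size = result$sizes,
             p = result$cluster_p, significant = result$significant)
}

#' Per-subject angular difference between corresponding hemisphere vertices
#'
#' Uses the index-correspondence convention of the symmetric standard
#' mesh: vertex i of the left hemisphere corresponds to vertex i of the
#' right. The resulting per-subject angular-variance maps feed
#' [sign_flip_cluster_test()] with one hemisphere's adjacency.
#'
#' @param angles_left,angles_right subjects-by-vertices matrices of
#'   degrees with equal dimensions.
#' @return Subjects-by-vertices matrix of angular variances, with the
#'   signed wrapped left-minus-right difference as attribute
#'   `signed_delta`.
#' @export
hemisphere_difference <- function(angles_left, angles_right) {
  angles_left <- as.matrix(angles_left)
  angles_right <- as.matrix(angles_right)
  if (!all(dim(angles_left) == dim(angles_right)))
    stop("hemisphere maps must have equal vertex counts", call. = FALSE)
  av <- angular_variance(angles_right, angles_left)  # delta = left - right
  out <- matrix(av$variance_v, nrow(angles_left))
  attr(out, "signed_delta") <- matrix(av$signed_delta, nrow(angles_left))
  out
}
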