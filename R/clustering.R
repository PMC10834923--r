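#' Build z-normalized abundance trajectories
#'
#' For each requested protein, the mean over POS (enzyme-active) replicates
#' at each time point, z-normalized across the time course (mean 0,
#' population SD 1). Zero-variance trajectories cannot be z-scored; they are
#' zero-filled and flagged degenerate.
#'
#' @param matrix fully imputed LOG2 [lfq_matrix()].
#' @param proteins character vector of protein ids (subset of the matrix).
#' @return Object of class `trajectory_set`: list with `trajectories`
#'   (proteins x time points matrix), `time_min`, `degenerate` (named
#'   logical).
#' @export
build_trajectories <- function(matrix, proteins) {
  if (matrix$scale != "LOG2") stop_data("trajectories require LOG2 scale")
  if (anyNA(matrix$values)) stop_data("matrix must be fully imputed")
  missing <- setdiff(proteins, protein_ids(matrix))
  if (length(missing))
    stop_data("protein(s) not in matrix: %s",
              paste(utils::head(missing, 5), collapse = ", "))
  tps <- time_points(matrix)
  raw <- vapply(tps, function(tt)
    rowMeans(matrix$values[proteins, sample_cols(matrix, "POS", tt),
                           drop = FALSE]),
    numeric(length(proteins)))
  raw <- matrix(raw, nrow = length(proteins),
                dimnames = list(proteins, tps))
  mu <- rowMeans(raw)
  sd_pop <- sqrt(rowMeans((raw - mu)^2))
  degenerate <- sd_pop < 1e-9
  z <- (raw - mu) / ifelse(degenerate, 1, sd_pop)
  z[degenerate, ] <- 0
  structure(list(trajectories = z, time_min = tps,
                 degenerate = setNames(degenerate, proteins)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d proteins x %d time points (%d degenerate)\n",
              nrow(x$trajectories), length(x$time_min), sum(x$degenerate)))
  invisible(x)
}

# kmeans++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance from the nearest chosen
# center. Far superior to uniform restarts when clusters are tight and
# well separated.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- if (all(d2 == 0)) sample.int(n, 1) else
      sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# One k-means fit from given centers; empty clusters (possible with Lloyd
# iterations on duplicated points) are re-seeded from the point farthest
# from its assigned centroid.
kmeans_once <- function(x, k, centers) {
  for (attempt in 1:5) {
    fit <- suppressWarnings(kmeans(x, centers = centers, iter.max = 100,
                                   algorithm = "Lloyd"))
    if (all(fit$size > 0)) return(fit)
    d <- rowSums((x - fit$centers[fit$cluster, , drop = FALSE])^2)
    centers <- fit$centers
    for (empty in which(fit$size == 0)) {
      far <- which.max(d)
      centers[empty, ] <- x[far, ]
      d[far] <- -Inf
    }
  }
  fit
}

#' Cluster abundance trajectories
#'
#' Unsupervised grouping of z-normalized trajectories, by default k-means on
#' Euclidean distance with `k = 10` (the fixed cluster count of the target
#' analysis) and the best of `n_init` seeded restarts by within-cluster sum
#' of squares. Each restart starts from `k` distinct trajectory vectors.
#' Degenerate (flat) trajectories are held out of the fit and assigned to
#' the nearest centroid afterwards. A hierarchical alternative (Euclidean,
#' average linkage, cut at k) is available via `method`.
#'
#' @param trajset a [build_trajectories()] result, or a plain numeric matrix
#'   of trajectories.
#' @param k number of clusters.
#' @param seed integer seed (restarts are deterministic given it).
#' @param n_init number of k-means restarts (default 50).
#' @param method `"kmeans"` (default) or `"hierarchical"`.
#' @return Object of class `cluster_assignment`: list with `assignment`
#'   (data.frame protein_id, cluster_id), `centroids` (k x time matrix),
#'   `inertia`, `k`, `seed`, `method`.
#' @export
cluster_trajectories <- function(trajset, k = 10, seed = 1L, n_init = 50,
                                 method = c("kmeans", "hierarchical")) {
  method <- match.arg(method)
  if (inherits(trajset, "trajectory_set")) {
    x <- trajset$trajectories
    degenerate <- trajset$degenerate
  } else {
    x <- as.matrix(trajset)
    if (is.null(rownames(x)))
      rownames(x) <- sprintf("T%05d", seq_len(nrow(x)))
    degenerate <- setNames(rep(FALSE, nrow(x)), rownames(x))
  }
  if (k < 1) stop_config("k must be >= 1")
  fit_x <- x[!degenerate, , drop = FALSE]
  if (nrow(fit_x) < k)
    stop_data("fewer non-degenerate trajectories (%d) than clusters (%d)",
              nrow(fit_x), k)
  if (method == "kmeans") {
    uniq <- unique(fit_x)
    if (nrow(uniq) < k)
      stop_data("fewer distinct trajectories (%d) than clusters (%d)",
                nrow(uniq), k)
    best <- NULL
    withr::with_seed(seed, {
      for (i in seq_len(n_init)) {
        fit <- kmeans_once(fit_x, k, kmeanspp_centers(uniq, k))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
    })
    centroids <- best$centers
    cl <- best$cluster
    inertia <- best$tot.withinss
  } else {
    hc <- hclust(dist(fit_x), method = "average")
    cl <- cutree(hc, k = k)
    centroids <- do.call(rbind, lapply(seq_len(k), function(g)
      colMeans(fit_x[cl == g, , drop = FALSE])))
    inertia <- sum((fit_x - centroids[cl, , drop = FALSE])^2)
  }
  # assign degenerate trajectories to the nearest centroid
  assignment <- setNames(integer(nrow(x)), rownames(x))
  assignment[rownames(fit_x)] <- cl
  for (id in names(degenerate)[degenerate]) {
    d <- rowSums((centroids - matrix(x[id, ], nrow(centroids),
                                     ncol(x), byrow = TRUE))^2)
    assignment[id] <- which.min(d)
  }
  rownames(centroids) <- seq_len(k)
  structure(list(assignment = data.frame(protein_id = names(assignment),
                                         cluster_id = unname(assignment)),
                 centroids = centroids, inertia = inertia, k = k,
                 seed = seed, method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d proteins in %d clusters (%s, inertia %.3f)\n",
              nrow(x$assignment), x$k, x$method, x$inertia))
  invisible(x)
}

#' Organelle composition of trajectory clusters
#'
#' For each cluster, the percentage of member-label pairs per organelle:
#' a protein carrying several labels contributes one pair per label, so
#' percentages within a cluster sum to 100. The enzyme share of cluster
#' members is reported separately (a flag, not a location label).
#'
#' @param assignment a [cluster_trajectories()] result.
#' @param annotations an [annotation_table()] covering all assigned proteins.
#' @return data.frame with columns `cluster_id`, `n_members`, one percentage
#'   column per organelle present, and `enzyme_pct`.
#' @export
cluster_organelle_composition <- function(assignment, annotations) {
  ids <- assignment$assignment$protein_id
  labs <- annotation_labels(annotations, ids, "assigned protein")
  enz <- annotations$enzyme[match(ids, annotations$protein_id)]
  orgs <- sort(unique(unlist(labs)))
  out <- lapply(sort(unique(assignment$assignment$cluster_id)), function(g) {
    in_g <- assignment$assignment$cluster_id == g
    pairs <- unlist(labs[in_g])
    pct <- 100 * table(factor(pairs, levels = orgs)) / length(pairs)
    cbind(data.frame(cluster_id = g, n_members = sum(in_g)),
          as.data.frame.matrix(t(as.matrix(pct))),
          data.frame(enzyme_pct = 100 * mean(enz[in_g])))
  })
  do.call(rbind, out)
}
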