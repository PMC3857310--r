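# Hierarchical cluster analysis of hydropathy profiles: four pairwise
# distances, average linkage, cophenetic correlation, and MATLAB-style
# inconsistency coefficients used to cut the dendrogram into clusters.

PROFILE_METRICS <- c("cityblock", "correlation", "cosine", "euclidean")

#' Pairwise distances between profile rows
#'
#' Computes one of the four supported pairwise distances between the rows of
#' a profile matrix:
#' \describe{
#'   \item{cityblock}{\eqn{\sum_i |p_i - q_i|}}
#'   \item{euclidean}{\eqn{\sqrt{\sum_i (p_i - q_i)^2}}}
#'   \item{cosine}{\eqn{1 - p \cdot q / (\|p\| \|q\|)}}
#'   \item{correlation}{\eqn{1 - \mathrm{Pearson}(p, q)}}
#' }
#' Degenerate rows (zero norm under cosine, zero variance under correlation)
#' get distance 1 to every other row, with a warning, rather than aborting
#' the run: an all-gap fragment is uninformative, not fatal.
#'
#' @param X Numeric matrix, rows = profiles.
#' @param metric One of `"cityblock"`, `"correlation"`, `"cosine"`,
#'   `"euclidean"`.
#' @return A [stats::dist] object with `method` set to the metric name.
#' @export
profile_distance <- function(X, metric = PROFILE_METRICS) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 profiles", call. = FALSE)
  d <- switch(metric,
    cityblock = stats::dist(X, method = "manhattan"),
    euclidean = stats::dist(X, method = "euclidean"),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      bad <- nrm == 0
      if (any(bad)) {
        warning("zero-norm profile(s) under cosine distance; distance set to 1: ",
                paste(rownames(X)[bad], collapse = ", "))
        nrm[bad] <- 1
      }
      S <- tcrossprod(X / nrm)
      D <- 1 - S
      if (any(bad)) {
        D[bad, ] <- 1; D[, bad] <- 1
      }
      diag(D) <- 0
      stats::as.dist(pmax(D, 0))
    },
    correlation = {
      v <- apply(X, 1L, stats::var)
      bad <- v == 0
      if (any(bad)) {
        warning("zero-variance profile(s) under correlation distance; ",
                "distance set to 1: ", paste(rownames(X)[bad], collapse = ", "))
      }
      C <- suppressWarnings(stats::cor(t(X)))
      D <- 1 - C
      if (any(bad)) {
        D[bad, ] <- 1; D[, bad] <- 1
      }
      diag(D) <- 0
      stats::as.dist(pmax(D, 0))
    })
  attr(d, "method") <- metric
  d
}

#' Average-linkage hierarchical clustering
#'
#' Unweighted average linkage (UPGMA-style inter-cluster mean distance) on a
#' distance matrix, via [stats::hclust]. Ties in agglomeration are broken by
#' the lowest member index, so runs are reproducible.
#'
#' @param d A [stats::dist] object (e.g. from [profile_distance()]), n >= 2.
#' @return An `hclust` object.
#' @export
linkage_average <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("need at least 2 observations", call. = FALSE)
  stats::hclust(d, method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the heights at which pairs first merge in the
#' dendrogram); values near 1 mean the tree faithfully represents the input
#' distances.
#'
#' @param hc An `hclust` object built from `d`.
#' @param d The [stats::dist] the tree was built from.
#' @return Scalar in \[-1, 1\], or `NA` with a warning when fewer than two
#'   distinct pairs (n < 3) or zero variance make the correlation undefined.
#' @export
cophenetic_correlation <- function(hc, d) {
  stopifnot(inherits(hc, "hclust"))
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  coph <- stats::cophenetic(hc)
  x <- as.vector(d)
  y <- as.vector(coph)
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("cophenetic correlation undefined (too few pairs or zero variance)")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# non-leaf (link) children of link k in an hclust merge table, as link indices
link_children <- function(merge, k) {
  ch <- merge[k, ]
  ch[ch > 0]
}

# comparison set of link heights for link k at a given depth: link k plus all
# non-leaf links up to depth-1 levels below it
comparison_set <- function(merge, height, k, depth) {
  idx <- k
  frontier <- k
  for (lvl in seq_len(depth - 1L)) {
    frontier <- unlist(lapply(frontier, function(j) link_children(merge, j)))
    if (length(frontier) == 0L) break
    idx <- c(idx, frontier)
  }
  height[idx]
}

#' Inconsistency coefficients of dendrogram links
#'
#' For each link k, the comparison set S consists of the link itself plus the
#' non-leaf links up to `depth - 1` levels below it (so `depth = 2` compares
#' a link with its immediate child links). The coefficient is
#' \eqn{Y_k = (h_k - \mathrm{mean}(S)) / \mathrm{sd}(S)} with the sample
#' (n-1) standard deviation; `Y_k = 0` when S is a single height or its
#' standard deviation is 0. Under this convention the largest possible value
#' for a two-height comparison set is \eqn{1/\sqrt{2} \approx 0.7071}, the
#' usual baseline against which cluster-cutting thresholds are chosen.
#'
#' @param hc An `hclust` object.
#' @param depth Number of levels of the tree entering each comparison set
#'   (default 2).
#' @return Numeric vector of length n-1, one coefficient per merge, in merge
#'   order.
#' @export
inconsistency_coefficients <- function(hc, depth = 2L) {
  stopifnot(inherits(hc, "hclust"), depth >= 1L)
  n_links <- nrow(hc$merge)
  vapply(seq_len(n_links), function(k) {
    s <- comparison_set(hc$merge, hc$height, k, depth)
    if (length(s) < 2L) return(0)
    sdv <- stats::sd(s)
    if (sdv == 0) return(0)
    (hc$height[k] - mean(s)) / sdv
  }, numeric(1L))
}

#' Cut a dendrogram by inconsistency coefficient
#'
#' A cluster is a maximal subtree all of whose links are consistent
#' (inconsistency coefficient <= `cutoff`); leaves hanging below inconsistent
#' links only become singletons. Cluster labels are numbered 1..K in order of
#' first leaf appearance.
#'
#' @param hc An `hclust` object.
#' @param cutoff Inconsistency threshold (> 0); links above it are split.
#' @param depth Depth for [inconsistency_coefficients()] (default 2).
#' @return Integer vector of cluster labels named by leaf label.
#' @export
cut_by_inconsistency <- function(hc, cutoff = 0.8, depth = 2L) {
  stopifnot(inherits(hc, "hclust"), cutoff > 0)
  Y <- inconsistency_coefficients(hc, depth)
  n_links <- nrow(hc$merge)
  # consistent[k]: Y[k] <= cutoff and all descendant links consistent
  consistent <- logical(n_links)
  for (k in seq_len(n_links)) {   # merge order guarantees children come first
    ch <- link_children(hc$merge, k)
    consistent[k] <- Y[k] <= cutoff && all(consistent[ch])
  }
  n <- n_links + 1L
  labels <- integer(n)
  next_lab <- 0L
  assign_leaves <- function(node, lab) {
    # node: negative = leaf index, positive = link index
    if (node < 0) {
      labels[-node] <<- lab
    } else {
      assign_leaves(hc$merge[node, 1L], lab)
      assign_leaves(hc$merge[node, 2L], lab)
    }
  }
  walk <- function(node) {
    if (node < 0 || consistent[node]) {
      next_lab <<- next_lab + 1L
      assign_leaves(node, next_lab)
    } else {
      walk(hc$merge[node, 1L])
      walk(hc$merge[node, 2L])
    }
  }
  walk(n_links)  # root link
  # renumber 1..K by first appearance in leaf input order
  first <- match(unique(labels), labels)
  relab <- match(labels, labels[sort(first)])
  names(relab) <- if (!is.null(hc$labels)) hc$labels else as.character(seq_len(n))
  relab
}

#' Run the full structural-divergence clustering across all four metrics
#'
#' Convenience wrapper: for each metric, computes the distance matrix, the
#' average-linkage tree, the cophenetic correlation, per-link inconsistency
#' coefficients and the inconsistency-based partition.
#'
#' @param X Profile matrix (rows = sequences).
#' @param metrics Subset of the four metric names (default all).
#' @param depth,cutoff Parameters of the inconsistency rule (defaults 2
#'   and 0.8).
#' @return Named list (one element per metric) of lists with `dist`, `hclust`,
#'   `cophenetic_correlation`, `inconsistency` and `clusters`; class
#'   `profile_clustering`.
#' @export
cluster_profiles <- function(X, metrics = PROFILE_METRICS, depth = 2L,
                             cutoff = 0.8) {
  metrics <- match.arg(metrics, PROFILE_METRICS, several.ok = TRUE)
  out <- lapply(metrics, function(m) {
    d <- profile_distance(X, m)
    hc <- linkage_average(d)
    list(dist = d,
         hclust = hc,
         cophenetic_correlation = cophenetic_correlation(hc, d),
         inconsistency = inconsistency_coefficients(hc, depth),
         clusters = cut_by_inconsistency(hc, cutoff, depth))
  })
  names(out) <- metrics
  structure(out, class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("%-11s cophenetic r = %.4f, %d cluster(s)\n", m,
                x[[m]]$cophenetic_correlation,
                max(x[[m]]$clusters)))
  }
  invisible(x)
}
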