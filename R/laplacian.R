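# Class-aware Laplacian-score feature ranking. Within each survival
# profile a k-nearest-neighbour subject similarity graph is built and
# every voxel is scored by how smoothly it varies over that graph;
# low scores indicate features that preserve local connectivity among
# subjects and are retained.

#' Build a heat-kernel k-nearest-neighbour similarity graph
#'
#' Edges are the union of directed k-nearest-neighbour relations; edge
#' weights are `exp(-||x_i - x_j||^2 / t)`. With
#' `kernel_width = "auto"`, `t` is the median squared distance over the
#' directed kNN edges (1 if all distances vanish, making identical
#' subjects a complete graph of unit weights).
#'
#' @param X Numeric matrix, one row per subject of a single class
#'   (>= 3 rows).
#' @param n_neighbors Neighbours per node (< number of rows).
#' @param kernel_width `"auto"` or a positive heat-kernel width.
#' @return A `similarity_graph`: `n_nodes`, `weights` (symmetric, zero
#'   diagonal), `degree`, `laplacian` (D - W), `kernel_width` (resolved
#'   value), `n_neighbors`, `n_components`. A disconnected graph is
#'   flagged with a warning.
#' @export
build_similarity_graph <- function(X, n_neighbors = 5, kernel_width = "auto") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects to build a graph", call. = FALSE)
  if (n_neighbors >= n)
    stop(sprintf("n_neighbors (%d) must be below the class size (%d)",
                 n_neighbors, n), call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  diag(D2) <- Inf
  A <- matrix(FALSE, n, n)
  knn_d2 <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[seq_len(n_neighbors)]
    A[i, nb] <- TRUE
    knn_d2 <- c(knn_d2, D2[i, nb])
  }
  U <- A | t(A)
  if (identical(kernel_width, "auto")) {
    t_heat <- stats::median(knn_d2)
    if (!is.finite(t_heat) || t_heat <= 0) t_heat <- 1
  } else {
    stopifnot_scalar_pos(kernel_width, "kernel_width")
    t_heat <- kernel_width
  }
  D2[!is.finite(D2)] <- 0
  W <- ifelse(U, exp(-D2 / t_heat), 0)
  diag(W) <- 0
  W <- (W + t(W)) / 2  # exact symmetry
  deg <- rowSums(W)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1)
    warning(sprintf("similarity graph has %d disconnected components", comp$no),
            call. = FALSE)
  if (any(deg == 0))
    warning("similarity graph has isolated nodes (all weights underflowed)",
            call. = FALSE)
  structure(list(n_nodes = n, weights = W, degree = deg,
                 laplacian = diag(deg) - W, kernel_width = t_heat,
                 n_neighbors = n_neighbors, n_components = comp$no),
            class = "similarity_graph")
}

# vectorized Laplacian scores for all columns of X on one graph;
# degree-weighted-constant features receive an Inf sentinel
laplacian_scores_matrix <- function(X, graph) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == graph$n_nodes)
  Dv <- graph$degree
  W <- graph$weights
  sDv <- sum(Dv)
  fbar <- as.numeric(crossprod(X, Dv)) / sDv
  Ft <- sweep(X, 2, fbar)
  num <- colSums(Ft * (Dv * Ft)) - colSums(Ft * (W %*% Ft))
  den <- colSums(Dv * Ft^2)
  num <- pmax(num, 0)  # clamp rounding noise; f'Lf >= 0 for valid graphs
  scale2 <- apply(X, 2, function(f) max(f^2))
  degenerate <- den == 0 | den < 1e-18 * sDv * pmax(scale2, .Machine$double.xmin)
  score <- ifelse(degenerate, Inf, num / den)
  attr(score, "flagged") <- which(degenerate)
  score
}

#' Laplacian score of a single feature
#'
#' For feature values `f` on a graph with weights `W`, degrees `D` and
#' Laplacian `L = D - W`, the degree-weighted centring
#' `f~ = f - (f'D1 / 1'D1) 1` is followed by
#' `score = (f~' L f~) / (f~' D f~)`. Lower scores indicate better
#' locality preservation. A degree-weighted-constant feature (zero
#' denominator) yields an `Inf` sentinel with a `"flagged"` attribute
#' rather than an error, so bulk scoring can proceed.
#'
#' @param f Numeric vector, one value per graph node.
#' @param graph A [build_similarity_graph()] result.
#' @return A single score (possibly `Inf`).
#' @export
laplacian_score <- function(f, graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (length(f) != graph$n_nodes)
    stop("feature length must equal the number of graph nodes", call. = FALSE)
  s <- laplacian_scores_matrix(matrix(f, ncol = 1), graph)
  out <- as.numeric(s)
  attr(out, "flagged") <- length(attr(s, "flagged")) > 0
  out
}

#' Class-aware voxel ranking by Laplacian score
#'
#' Restricts the feature matrix to one survival profile's subjects,
#' builds the similarity graph on those rows, scores every voxel and
#' retains the `m` best. Because each profile gets its own graph,
#' different profiles select different voxel sets. Zero-variance
#' features are flagged with an `Inf` sentinel and always rank last;
#' score ties break by ascending voxel index.
#'
#' @param features A `feature_matrix` (see [assemble_features()]) or a
#'   plain numeric matrix.
#' @param labels Profile label per subject (row).
#' @param class_id The profile to rank for (>= 3 members).
#' @param m Number of voxels to retain (<= feature count).
#' @param n_neighbors,kernel_width Graph parameters, see
#'   [build_similarity_graph()].
#' @param decreasing If `TRUE`, rank high scores first (sensitivity
#'   analysis; the standard convention selects low scores).
#' @return A `class_ranking`: `class_id`, `scores`, `order`
#'   (permutation of features), `selected` (first `m` of `order`), `m`,
#'   `n_class`.
#' @export
class_aware_ranking <- function(features, labels, class_id, m = 400,
                                n_neighbors = 5, kernel_width = "auto",
                                decreasing = FALSE) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (length(labels) != nrow(X))
    stop("`labels` must have one entry per subject row", call. = FALSE)
  rows <- which(labels == class_id)
  if (length(rows) < 3)
    stop(sprintf("class %s has %d members; need >= 3", class_id, length(rows)),
         call. = FALSE)
  if (m > ncol(X)) stop("`m` exceeds the number of features", call. = FALSE)
  g <- build_similarity_graph(X[rows, , drop = FALSE],
                              n_neighbors = n_neighbors,
                              kernel_width = kernel_width)
  scores <- laplacian_scores_matrix(X[rows, , drop = FALSE], g)
  key <- if (decreasing) -scores else scores
  key[!is.finite(scores)] <- Inf  # sentinels last under either convention
  ord <- order(key, seq_along(key))
  structure(list(class_id = class_id, scores = as.numeric(scores),
                 order = ord, selected = ord[seq_len(m)], m = as.integer(m),
                 n_class = length(rows), graph = g),
            class = "class_ranking")
}

#' @export
print.class_ranking <- function(x, ...) {
  cat(sprintf("class_ranking: class %s, %d subjects, %d features, m = %d retained\n",
              x$class_id, x$n_class, length(x$scores), x$m))
  invisible(x)
}

#' Retained-information profile over ranking cutoffs
#'
#' For each cutoff `m'`, reports the share of the total
#' locality-preserving signal captured by the `m'` best-ranked
#' features, quantifying how much a narrowing of the retained set (for
#' example 2000 to 400 voxels) preserves. A feature that varies
#' independently of the similarity graph has a Laplacian score close
#' to 1, so the signal of a feature is measured as its inverse score
#' in excess of that neutral value, `max(1/score - 1, 0)`; summing raw
#' inverse scores would make the profile scale with the bulk of
#' uninformative voxels instead of the informative minority.
#'
#' @param ranking A [class_aware_ranking()] result.
#' @param cutoffs Sorted vector of candidate `m` values.
#' @return A data frame with columns `m` and `share` in \[0, 1\].
#' @export
score_profile <- function(ranking, cutoffs) {
  stopifnot(inherits(ranking, "class_ranking"))
  if (length(cutoffs) == 0)
    return(data.frame(m = integer(0), share = numeric(0)))
  if (is.unsorted(cutoffs)) stop("`cutoffs` must be sorted", call. = FALSE)
  sc <- ranking$scores[ranking$order]
  inv <- ifelse(is.finite(sc), pmax(1 / sc - 1, 0), 0)  # Inf sentinel: no signal
  zero <- is.finite(sc) & sc == 0            # perfect scores: cap at max weight
  if (any(zero)) inv[zero] <- if (any(inv[!zero] > 0)) max(inv[!zero]) else 1
  tot <- sum(inv)
  cums <- cumsum(inv)
  share <- if (tot == 0) rep(0, length(cutoffs)) else cums[pmin(cutoffs, length(inv))] / tot
  data.frame(m = as.integer(cutoffs), share = share)
}
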