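# Contiguous-cluster extraction from selected-voxel masks, cluster
# localization, and hypo-/hypermetabolic direction labelling.

conn_offsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26", call. = FALSE))
  as.matrix(g[keep, ])
}

#' Extract contiguous voxel clusters from a binary mask
#'
#' Connected components under 6-, 18- or 26-neighbour adjacency.
#' Only components with extent strictly greater than `min_extent`
#' survive (the conventional "more than 100 contiguous voxels" rule
#' keeps extents of 101 and above). Clusters are sorted by descending
#' extent, ties by first voxel in grid order.
#'
#' @param selected_mask 3-D logical (or 0/1) array.
#' @param min_extent Minimum extent, exclusive (default 100).
#' @param connectivity 6, 18 or 26 (default 26, the standard for
#'   volumetric cluster-extent reporting).
#' @return A list of clusters, each a list with `extent`, `voxels`
#'   (0-based m x 3 coordinates) and `lin_index` (1-based linear grid
#'   indices).
#' @export
extract_clusters <- function(selected_mask, min_extent = 100,
                             connectivity = 26) {
  offs <- conn_offsets(connectivity)
  dims <- dim(selected_mask)
  if (length(dims) != 3L) stop("mask must be 3-D", call. = FALSE)
  mask <- array(as.logical(selected_mask), dims)
  lin <- which(mask)
  if (length(lin) == 0) return(list())
  node <- integer(prod(dims))
  node[lin] <- seq_along(lin)
  co <- arrayInd(lin, dims)
  edges <- NULL
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    ok <- co[, 1] + d[1] >= 1 & co[, 1] + d[1] <= dims[1] &
          co[, 2] + d[2] >= 1 & co[, 2] + d[2] <= dims[2] &
          co[, 3] + d[3] >= 1 & co[, 3] + d[3] <= dims[3]
    nb <- lin[ok] + sum(d * strides)
    hit <- node[nb] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(node[lin[ok]][hit], node[nb][hit]))
  }
  if (is.null(edges)) {
    membership <- seq_along(lin)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
    membership <- igraph::components(g)$membership
  }
  comp_ids <- unique(membership)
  clusters <- lapply(comp_ids, function(cid) {
    sel <- membership == cid
    list(extent = sum(sel),
         voxels = co[sel, , drop = FALSE] - 1L,
         lin_index = lin[sel])
  })
  clusters <- Filter(function(cl) cl$extent > min_extent, clusters)
  ord <- order(-vapply(clusters, `[[`, 0L, "extent"),
               vapply(clusters, function(cl) min(cl$lin_index), 0L))
  clusters[ord]
}

#' Localize a cluster in voxel and world coordinates
#'
#' The centroid is the mean of the cluster's 0-based voxel coordinates
#' mapped through the affine. When a relative-intensity map is given,
#' the peak is the cluster voxel with maximal deviation of the mean
#' relative intensity from 1 (the whole-brain mean after
#' normalization).
#'
#' @param cluster One element of [extract_clusters()] output.
#' @param affine 4 x 4 voxel-to-mm map.
#' @param rel_intensity Optional 3-D array of mean relative intensity
#'   across the relevant profile's subjects.
#' @return A list: `centroid_vox`, `centroid_mm`, and (when
#'   `rel_intensity` is given) `peak_vox`, `peak_mm`.
#' @export
localize_cluster <- function(cluster, affine, rel_intensity = NULL) {
  if (cluster$extent == 0) stop("empty cluster", call. = FALSE)
  centroid <- colMeans(matrix(cluster$voxels, ncol = 3))
  out <- list(centroid_vox = centroid,
              centroid_mm = as.numeric(voxel_to_world(centroid, affine)))
  if (!is.null(rel_intensity)) {
    v <- rel_intensity[cluster$lin_index]
    pk <- cluster$voxels[which.max(abs(v - 1)), ]
    out$peak_vox <- as.numeric(pk)
    out$peak_mm <- as.numeric(voxel_to_world(pk, affine))
  }
  out
}

#' Metabolic direction of a cluster
#'
#' Averages normalized intensity over the cluster's voxels and the
#' profile's subjects; with the whole-brain mean as reference (1 after
#' normalization), a mean below 1 is relative hypometabolism, at or
#' above 1 relative hypermetabolism.
#'
#' @param cluster One element of [extract_clusters()] output.
#' @param volumes List of normalized [brain_volume()] objects for the
#'   profile's subjects, or a numeric matrix of subjects x cluster
#'   voxel values.
#' @return A list: `direction` (`"hypo"`/`"hyper"`) and
#'   `mean_relative_intensity`.
#' @export
cluster_direction <- function(cluster, volumes) {
  if (is.matrix(volumes)) {
    vals <- volumes
  } else {
    if (length(volumes) == 0) stop("empty subject set", call. = FALSE)
    vals <- t(vapply(volumes, function(v) v$data[cluster$lin_index],
                     numeric(cluster$extent)))
  }
  m <- mean(vals)
  list(direction = if (m < 1) "hypo" else "hyper",
       mean_relative_intensity = m)
}

#' Map a class ranking to a table of discriminant clusters
#'
#' Builds the binary mask of the profile's selected voxels, extracts
#' contiguous clusters above the extent threshold, localizes each and
#' labels its metabolic direction from the profile's subjects.
#'
#' @param ranking A [class_aware_ranking()] result.
#' @param features The `feature_matrix` the ranking was computed from
#'   (normalized intensities).
#' @param labels Profile label per subject row of `features`.
#' @param min_extent,connectivity See [extract_clusters()].
#' @return A `voxel_cluster_report` data frame: one row per cluster
#'   with `class_id`, `extent`, peak and centroid coordinates (voxel
#'   and mm), `direction` and `mean_relative_intensity`.
#' @export
map_class_clusters <- function(ranking, features, labels,
                               min_extent = 100, connectivity = 26) {
  stopifnot(inherits(ranking, "class_ranking"),
            inherits(features, "feature_matrix"))
  mask <- array(FALSE, features$grid_shape)
  mask[features$lin_index[ranking$selected]] <- TRUE
  clusters <- extract_clusters(mask, min_extent, connectivity)
  rows <- which(labels == ranking$class_id)
  rel <- array(NA_real_, features$grid_shape)
  rel[features$lin_index] <- colMeans(features$values[rows, , drop = FALSE])
  out <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    loc <- localize_cluster(cl, features$affine, rel)
    idx <- match(cl$lin_index, features$lin_index)
    dir <- cluster_direction(cl, features$values[rows, idx, drop = FALSE])
    data.frame(class_id = ranking$class_id, cluster = i, extent = cl$extent,
               peak_x = loc$peak_vox[1], peak_y = loc$peak_vox[2],
               peak_z = loc$peak_vox[3],
               centroid_x_mm = loc$centroid_mm[1],
               centroid_y_mm = loc$centroid_mm[2],
               centroid_z_mm = loc$centroid_mm[3],
               direction = dir$direction,
               mean_relative_intensity = dir$mean_relative_intensity)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(class_id = ranking$class_id[0], cluster = integer(0),
               extent = integer(0), peak_x = numeric(0), peak_y = numeric(0),
               peak_z = numeric(0), centroid_x_mm = numeric(0),
               centroid_y_mm = numeric(0), centroid_z_mm = numeric(0),
               direction = character(0),
               mean_relative_intensity = numeric(0))
  class(out) <- c("voxel_cluster_report", "data.frame")
  out
}
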