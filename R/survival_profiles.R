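# Unsupervised discretization of survival times: 1-D k-means, variance
# explained, and data-driven choice of the number of profiles.

new_survival_partition <- function(k, labels, boundaries, centers, stats) {
  structure(list(k = k, labels = labels, boundaries = boundaries,
                 centers = centers, ve = stats$ve,
                 within_ss = stats$within_ss, between_ss = stats$between_ss,
                 total_ss = stats$total_ss),
            class = "survival_partition")
}

#' @export
print.survival_partition <- function(x, ...) {
  b <- paste(sprintf("%.2f", x$boundaries), collapse = ", ")
  cat(sprintf("survival_partition: k = %d, VE = %.1f%%, boundaries (years): %s\n",
              x$k, 100 * x$ve, if (nzchar(b)) b else "none"))
  invisible(x)
}

#' Variance explained by a partition of survival times
#'
#' Decomposes the total sum of squares of the times into between-group
#' and within-group components: `SST = sum_i (t_i - mean)^2`,
#' `SSB = sum_c n_c (mean_c - mean)^2`, `VE = SSB / SST`. A single-group
#' partition has VE 0; all-equal times make VE undefined and raise an
#' error.
#'
#' @param times Positive survival times (>= 2 values).
#' @param labels Group label per subject.
#' @return A `survival_partition` carrying `ve`, `within_ss`,
#'   `between_ss`, `total_ss` (boundaries unset).
#' @export
compute_ve <- function(times, labels) {
  if (length(times) < 2) stop("need at least two subjects", call. = FALSE)
  if (length(labels) != length(times))
    stop("`labels` and `times` lengths differ", call. = FALSE)
  mu <- mean(times)
  sst <- sum((times - mu)^2)
  if (sst == 0)
    stop("all survival times equal: variance explained undefined", call. = FALSE)
  gm <- tapply(times, labels, mean)
  gn <- tapply(times, labels, length)
  ssb <- sum(gn * (gm - mu)^2)
  ssw <- sum((times - gm[as.character(labels)])^2)
  stats <- list(ve = ssb / sst, within_ss = ssw, between_ss = ssb, total_ss = sst)
  new_survival_partition(length(gm), labels, numeric(0), as.numeric(gm), stats)
}

# nearest-centre assignment for sorted 1-D centres; ties go upward,
# guaranteeing labels contiguous in the sorted order of the times
assign_1d <- function(times, centers) {
  centers <- sort(centers)
  cuts <- (centers[-1] + centers[-length(centers)]) / 2
  findInterval(times, cuts) + 1L
}

# k-means++ style seeding over distinct values
seed_centers_1d <- function(vals, k) {
  centers <- numeric(k)
  centers[1] <- vals[sample.int(length(vals), 1L)]
  if (k > 1) for (c in 2:k) {
    d2 <- vapply(vals, function(v) min((v - centers[1:(c - 1)])^2), numeric(1))
    if (sum(d2) == 0) centers[c] <- vals[sample.int(length(vals), 1L)]
    else centers[c] <- vals[sample.int(length(vals), 1L, prob = d2)]
  }
  centers
}

#' One-dimensional k-means partition of survival times
#'
#' Lloyd iterations from k-means++-style seeding (plus one
#' deterministic quantile start), best of `restarts` random starts,
#' followed by an exact coordinate-descent refinement of the cut
#' positions on the sorted times; single-cut moves are optimized to
#' convergence, which removes the boundary-local optima Lloyd can stop
#' at. The returned labels are 1..k in increasing survival order and
#' contiguous on the sorted times; `boundaries` are the midpoints
#' between adjacent clusters' extreme members.
#'
#' @param times Positive survival times.
#' @param k Number of profiles (<= number of distinct values).
#' @param restarts Number of random restarts (default 20).
#' @param seed Optional integer seed.
#' @return A `survival_partition`.
#' @export
kmeans_1d <- function(times, k, restarts = 20, seed = NULL) {
  k <- as.integer(k)
  vals <- unique(times)
  if (k > length(vals))
    stop(sprintf("k = %d exceeds the %d distinct survival values",
                 k, length(vals)), call. = FALSE)
  n <- length(times)
  if (k == length(vals)) {
    labels <- match(times, sort(vals))
  } else {
    ord <- order(times)
    xs <- times[ord]
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    seg_ss <- function(i, j) {
      s <- cs[j] - if (i > 1) cs[i - 1] else 0
      s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
      max(s2 - s^2 / (j - i + 1), 0)
    }
    cuts_ssw <- function(cuts) {
      b <- c(0L, cuts, n)
      sum(vapply(seq_len(k), function(j) seg_ss(b[j] + 1L, b[j + 1L]),
                 numeric(1)))
    }
    # exact single-cut coordinate descent on the sorted order
    refine_cuts <- function(cuts) {
      b <- c(0L, cuts, n)
      for (sweep in 1:100) {
        moved <- FALSE
        for (j in seq_len(k - 1)) {
          lo <- b[j]; hi <- b[j + 2L]
          cand <- (lo + 1L):(hi - 1L)
          cost <- vapply(cand, function(cc) seg_ss(lo + 1L, cc) + seg_ss(cc + 1L, hi),
                         numeric(1))
          cbest <- cand[which.min(cost)]
          if (cbest != b[j + 1L]) { b[j + 1L] <- cbest; moved <- TRUE }
        }
        if (!moved) break
      }
      b[2:k]
    }
    lloyd_cuts <- function(centers) {
      for (it in 1:100) {
        lab <- assign_1d(xs, centers)
        newc <- tapply(xs, factor(lab, levels = 1:k), mean)
        if (anyNA(newc)) return(NULL)  # empty cluster
        newc <- sort(as.numeric(newc))
        if (max(abs(newc - centers)) < 1e-12) break
        centers <- newc
      }
      cnt <- tabulate(assign_1d(xs, centers), k)
      if (any(cnt == 0)) return(NULL)
      cumsum(cnt)[seq_len(k - 1)]
    }
    best_cuts <- NULL; best_ssw <- Inf
    with_seed(seed, {
      for (r in 0:restarts) {
        starts <- if (r == 0) {
          list(as.integer(round(n * seq_len(k - 1) / k)))  # deterministic start
        } else {
          list(lloyd_cuts(sort(seed_centers_1d(vals, k))),
               sort(sample.int(n - 1L, k - 1L)))           # random cut start
        }
        for (cuts in starts) {
          if (is.null(cuts) || any(diff(c(0L, cuts, n)) < 1L)) next
          cuts <- refine_cuts(cuts)
          ssw <- cuts_ssw(cuts)
          if (ssw < best_ssw - 1e-12) { best_ssw <- ssw; best_cuts <- cuts }
        }
      }
    })
    labels <- integer(n)
    labels[ord] <- rep(seq_len(k), diff(c(0L, best_cuts, n)))
  }
  st <- compute_ve(times, labels)
  centers <- as.numeric(tapply(times, factor(labels, levels = 1:k), mean))
  boundaries <- vapply(seq_len(k - 1), function(c) {
    (max(times[labels == c]) + min(times[labels == c + 1])) / 2
  }, numeric(1))
  new_survival_partition(k, labels, boundaries, centers,
                         list(ve = st$ve, within_ss = st$within_ss,
                              between_ss = st$between_ss, total_ss = st$total_ss))
}

#' Choose the number of survival profiles
#'
#' Runs [kmeans_1d()] for each candidate `k` and selects the value
#' maximizing the chosen criterion. The default criterion is the mean
#' silhouette width, which peaks at the number of well-separated
#' profiles; the Calinski-Harabasz variance ratio
#' `(SSB/(k-1)) / (SSW/(n-k))` is available via
#' `criterion = "ch"`. Raw variance explained is monotone in `k` and is
#' reported for the winner rather than used for selection. Ties break
#' toward smaller `k`; candidate `k` exceeding the number of distinct
#' values (or `n - 1`) are skipped.
#'
#' @param times Positive survival times.
#' @param k_range Candidate numbers of profiles (default 2:6).
#' @param restarts Restarts per `k` (default 20).
#' @param seed Optional integer seed.
#' @param criterion `"silhouette"` (default) or `"ch"`.
#' @return A list: `k` (chosen), `partition` (`survival_partition`),
#'   `criterion` (named vector of criterion values over the feasible
#'   range).
#' @export
select_k <- function(times, k_range = 2:6, restarts = 20, seed = NULL,
                     criterion = c("silhouette", "ch")) {
  criterion <- match.arg(criterion)
  n <- length(times)
  feasible <- k_range[k_range <= min(length(unique(times)), n - 1) & k_range >= 2]
  if (length(feasible) == 0) stop("no feasible k in `k_range`", call. = FALSE)
  parts <- list(); crit <- numeric(length(feasible))
  d <- if (criterion == "silhouette") stats::dist(times) else NULL
  for (i in seq_along(feasible)) {
    k <- feasible[i]
    p <- kmeans_1d(times, k, restarts = restarts,
                   seed = if (is.null(seed)) NULL else seed + k)
    parts[[i]] <- p
    crit[i] <- switch(criterion,
      silhouette = mean(cluster::silhouette(p$labels, d)[, "sil_width"]),
      ch = {
        ssw <- p$within_ss
        if (ssw == 0) Inf else (p$between_ss / (k - 1)) / (ssw / (n - k))
      })
  }
  names(crit) <- feasible
  best <- which.max(crit)  # first maximum: ties toward smaller k
  list(k = feasible[best], partition = parts[[best]], criterion = crit)
}
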