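# Independent oracles used to validate the implementation: brute-force
# or closed-form computations written against the definitions, not the
# package internals.

# sum of squares of a sorted segment x[i..j]
.segss <- function(cs, cs2, i, j) {
  s <- cs[j] - if (i > 1) cs[i - 1] else 0
  s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
  max(s2 - s^2 / (j - i + 1), 0)
}

# optimal within-cluster SS over all contiguous k-partitions (dynamic
# programming on the sorted values)
dp_contiguous_ssw <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- .segss(cs, cs2, 1, j)
  if (k > 1) for (c in 2:k) for (j in c:n) {
    D[c, j] <- min(vapply(c:j, function(i) D[c - 1, i - 1] + .segss(cs, cs2, i, j),
                          numeric(1)))
  }
  D[k, n]
}

# exhaustive enumeration of contiguous k-partitions (small n only)
exhaustive_contiguous_ssw <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  if (k == 1) return(sum((x - mean(x))^2))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c in seq_len(ncol(cuts))) {
    bnd <- c(0, cuts[, c], n)
    ssw <- 0
    for (s in seq_len(k)) {
      seg <- x[(bnd[s] + 1):bnd[s + 1]]
      ssw <- ssw + sum((seg - mean(seg))^2)
    }
    best <- min(best, ssw)
  }
  best
}

# Laplacian score from the pairwise-difference identity
# f'Lf = 1/2 sum_ij w_ij (f_i - f_j)^2
laplacian_score_oracle <- function(f, W) {
  d <- rowSums(W)
  ft <- f - sum(f * d) / sum(d)
  n <- length(f)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (ft[i] - ft[j])^2
  num <- num / 2
  den <- sum(d * ft^2)
  num / den
}

# brute-force pairwise kNN heat-kernel graph
knn_graph_oracle <- function(X, k) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D2[i, j] <- sum((X[i, ] - X[j, ])^2)
  A <- matrix(FALSE, n, n)
  d2s <- c()
  for (i in 1:n) {
    o <- setdiff(order(D2[i, ]), i)[seq_len(k)]
    A[i, o] <- TRUE
    d2s <- c(d2s, D2[i, o])
  }
  t_heat <- stats::median(d2s)
  if (!is.finite(t_heat) || t_heat <= 0) t_heat <- 1
  W <- ifelse(A | t(A), exp(-D2 / t_heat), 0)
  diag(W) <- 0
  W
}

# queue-based flood fill, independent of the graph-based implementation
flood_fill_components <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- NULL
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nab <- abs(di) + abs(dj) + abs(dk)
    keep <- (connectivity == 6 && nab == 1) ||
            (connectivity == 18 && nab <= 2) ||
            connectivity == 26
    if (keep) offs <- rbind(offs, c(di, dj, dk))
  }
  comp <- array(0L, dims)
  cur <- 0L
  for (start in which(mask)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    stack <- integer(sum(mask))
    stack[1] <- start
    top <- 1L
    comp[start] <- cur
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        nl <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask[nl] && comp[nl] == 0L) {
          comp[nl] <- cur
          top <- top + 1L
          stack[top] <- nl
        }
      }
    }
  }
  comp
}

# AUROC as the pairwise comparison probability
auroc_oracle <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# moments of the preset class distributions by numeric integration
tnorm_mean_oracle <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z, lo, hi)$value
}

texp_mean_oracle <- function(offset, m, cap) {
  z <- 1 - exp(-(cap - offset) / m)
  stats::integrate(function(x) x * stats::dexp(x - offset, 1 / m) / z,
                   offset, cap)$value
}

# dense separable-Gaussian convolution by direct summation (zero
# padding); valid comparison when the input support stays > 6 sigma
# away from the grid edge
dense_smooth_oracle <- function(a, sigma) {
  rad <- max(1L, as.integer(ceiling(6 * max(sigma))))
  g <- lapply(sigma, function(s) {
    k <- stats::dnorm(-rad:rad, 0, s)
    k / sum(k)
  })
  dims <- dim(a)
  out <- array(0, dims)
  for (v in which(a != 0)) {
    co <- arrayInd(v, dims)
    for (di in -rad:rad) for (dj in -rad:rad) for (dk in -rad:rad) {
      nb <- co + c(di, dj, dk)
      if (any(nb < 1) || any(nb > dims)) next
      out[nb[1], nb[2], nb[3]] <- out[nb[1], nb[2], nb[3]] +
        a[v] * g[[1]][di + rad + 1] * g[[2]][dj + rad + 1] * g[[3]][dk + rad + 1]
    }
  }
  out
}
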