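# Independent oracles used across the suite. These deliberately use naive
# algorithms (double loops, pair counting, graph closure, permutation search)
# so they cannot share a defect with the implementation they check.

# Exhaustive max-gradient search over all (t, w) pairs of an expansion trace.
# frames/e: aligned vectors; intervals: window widths. Ties: earliest t, then
# smallest w, matching the documented contract.
brute_force_score <- function(frames, e, intervals) {
  best <- NULL
  lookup <- setNames(e, as.character(frames))
  for (w in intervals) {
    for (t in frames) {
      key <- as.character(t + w)
      if (!key %in% names(lookup)) next
      g <- (lookup[[key]] - lookup[[as.character(t)]]) / w
      if (is.null(best) || g > best$grad ||
          (g == best$grad && (t < best$t || (t == best$t && w < best$w))))
        best <- list(grad = g, t = t, w = w)
    }
  }
  best
}

# Mann-Whitney pair statistic: fraction of (pos, neg) pairs with pos > neg,
# ties counted 1/2.
pair_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Single-linkage closure on centroids: connected components of the graph with
# an edge wherever two centroids are within `radius`.
closure_components <- function(row, col, radius) {
  n <- length(row)
  adj <- as.matrix(dist(cbind(row, col))) <= radius
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Exact minimum-total-distance one-to-one assignment by permutation search
# (tiny n only); returns the detection index matched to each track.
optimal_assignment <- function(D) {
  n <- nrow(D)
  stopifnot(n == ncol(D), n <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(seq_len(n), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}
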