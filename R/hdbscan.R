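# Hierarchical density-based clustering (HDBSCAN) of preferred axes.
#
# Written in-package: mutual-reachability distances, a single-linkage
# hierarchy (equivalent to the minimum spanning tree of the mutual-
# reachability graph), tree condensation at min_cluster_size, and
# excess-of-mass cluster extraction. The root cluster is never selectable
# (no single-cluster solutions), matching the reference behavior of the
# scikit-learn implementation, against which this code is cross-checked in
# the test suite.

hdbscan_core <- function(X, minClusterSize = 2L, minSamples = 2L) {
  n <- nrow(X)
  if (n < 2) stop("insufficient-data: need >= 2 points")
  D <- as.matrix(stats::dist(X))
  # core distance: distance to the minSamples-th nearest neighbor, counting
  # the point itself
  core <- apply(D, 1, function(r) sort(r)[minSamples])
  MR <- pmax(D, outer(core, core, pmax))

  if (max(MR) <= 0) {
    # fully degenerate input (all points identical): one cluster
    return(list(labels = rep(1L, n)))
  }

  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  # dendrogram bookkeeping: node ids 1..n leaves, n+i for merge i
  merge <- hc$merge
  height <- hc$height
  node_of <- function(m) ifelse(m < 0, -m, n + m)
  children <- cbind(node_of(merge[, 1]), node_of(merge[, 2]))
  size <- c(rep(1L, n), integer(n - 1))
  for (i in seq_len(n - 1)) {
    size[n + i] <- size[children[i, 1]] + size[children[i, 2]]
  }
  leaves_under <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v) else stack <- c(stack, children[v - n, ])
    }
    out
  }
  lambda_at <- function(node) {
    1 / max(height[node - n], .Machine$double.eps)
  }

  # condense: walk the hierarchy top-down; splits where both sides reach
  # minClusterSize create new clusters, smaller sides fall out as points
  cl_parent <- integer(0)
  cl_birth <- numeric(0)
  cl_death <- numeric(0)
  cl_nsplit <- numeric(0) # points remaining at a true split
  pt_cluster <- integer(n)
  pt_lambda <- numeric(n)
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_death[length(cl_death) + 1L] <<- NA_real_
    cl_nsplit[length(cl_nsplit) + 1L] <<- 0
    length(cl_parent)
  }
  root_id <- new_cluster(0L, 0)

  stack <- list(list(node = 2L * n - 1L, cid = root_id))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    cid <- fr$cid
    if (node <= n) { # single point left in the cluster: it falls out at
      pt_cluster[node] <- cid # the lambda already assigned by the parent
      next
    }
    lam <- lambda_at(node)
    kids <- children[node - n, ]
    big <- size[kids] >= minClusterSize
    if (all(big)) {
      cl_death[cid] <- lam
      cl_nsplit[cid] <- size[node]
      for (k in kids) {
        stack[[length(stack) + 1L]] <- list(node = k,
                                            cid = new_cluster(cid, lam))
      }
    } else {
      for (j in 1:2) {
        k <- kids[j]
        if (big[j]) {
          stack[[length(stack) + 1L]] <- list(node = k, cid = cid)
        } else {
          pts <- leaves_under(k)
          pt_cluster[pts] <- cid
          pt_lambda[pts] <- lam
        }
      }
      if (!any(big)) cl_death[cid] <- lam
    }
  }
  # leaves that fell through with no recorded lambda leave at their parent's
  # split lambda (already set); isolated top-level leaves keep lambda of the
  # merge that shed them, assigned above.

  # stability (excess of mass) per condensed cluster
  stability <- numeric(length(cl_parent))
  for (c in seq_along(cl_parent)) {
    pts <- which(pt_cluster == c)
    s <- sum(pt_lambda[pts] - cl_birth[c])
    if (!is.na(cl_death[c]) && cl_nsplit[c] > 0) {
      s <- s + cl_nsplit[c] * (cl_death[c] - cl_birth[c])
    }
    stability[c] <- s
  }

  # bottom-up EOM selection; the root is never selected
  kids_of <- split(seq_along(cl_parent), cl_parent)
  selected <- logical(length(cl_parent))
  subtree_value <- numeric(length(cl_parent))
  order_by_depth <- rev(seq_along(cl_parent)) # children created after parents
  deselect_subtree <- function(c) {
    stack <- c
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      selected[v] <<- FALSE
      stack <- c(stack, kids_of[[as.character(v)]])
    }
  }
  for (c in order_by_depth) {
    ch <- kids_of[[as.character(c)]]
    if (is.null(ch) || !length(ch)) {
      selected[c] <- TRUE
      subtree_value[c] <- stability[c]
    } else {
      child_val <- sum(subtree_value[ch])
      if (stability[c] > child_val && cl_parent[c] != 0L) {
        for (k in ch) deselect_subtree(k)
        selected[c] <- TRUE
        subtree_value[c] <- stability[c]
      } else {
        subtree_value[c] <- child_val
      }
    }
  }
  selected[root_id] <- FALSE

  # a point belongs to the selected cluster on its ancestor chain (if any)
  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  relabel <- integer(length(cl_parent))
  relabel[sel_ids] <- seq_along(sel_ids)
  for (p in seq_len(n)) {
    c <- pt_cluster[p]
    while (c != 0L) {
      if (selected[c]) {
        labels[p] <- relabel[c]
        break
      }
      c <- cl_parent[c]
    }
  }
  list(labels = labels)
}

#' Cluster preferred axes with HDBSCAN
#'
#' Density-based clustering of the units' preferred axes (their
#' cross-validated regression coefficient vectors) with hierarchical density
#' estimates, `min_cluster_size = 2` and `min_samples = 2`. Units whose
#' cross-validated R^2 does not exceed the gate are excluded before
#' clustering (label `NA`); units in no cluster are labeled `-1` ("None").
#' Each cluster is summarized by its medoid (the member minimizing the summed
#' within-cluster Euclidean distance in axis space) and by medians and
#' quartiles of R^2 and VII when supplied.
#'
#' @param betas units x K matrix of preferred axes.
#' @param minClusterSize minimum cluster size (default 2).
#' @param minSamples neighborhood size for core points (default 2).
#' @param r2 optional per-unit cross-validated R^2 used for gating and
#'   summaries.
#' @param vii optional per-unit view invariance index for summaries.
#' @param r2Gate gate applied when `r2` is supplied (default 0.25; axes of
#'   units at or below it are not clustered).
#' @return A [ClusterResult-class].
#' @export
clusterAxes <- function(betas, minClusterSize = 2, minSamples = 2,
                        r2 = NULL, vii = NULL, r2Gate = 0.25) {
  betas <- as.matrix(betas)
  nAll <- nrow(betas)
  keep <- if (is.null(r2)) rep(TRUE, nAll) else r2 > r2Gate
  if (sum(keep) < 2) stop("insufficient-data: need >= 2 units to cluster")
  res <- hdbscan_core(betas[keep, , drop = FALSE],
                      as.integer(minClusterSize), as.integer(minSamples))
  labels <- rep(NA_integer_, nAll)
  labels[keep] <- res$labels

  ids <- sort(unique(res$labels[res$labels > 0]))
  D <- as.matrix(stats::dist(betas))
  medoids <- integer(length(ids))
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    members <- which(!is.na(labels) & labels == ids[j])
    within <- D[members, members, drop = FALSE]
    medoids[j] <- members[which.min(rowSums(within))]
    q <- function(v) {
      if (is.null(v)) rep(NA_real_, 3)
      else stats::quantile(v[members], c(0.25, 0.5, 0.75), names = FALSE)
    }
    qr2 <- q(r2)
    qv <- q(vii)
    rows[[j]] <- data.frame(cluster = ids[j], n = length(members),
                            medoid = medoids[j],
                            r2_q25 = qr2[1], r2_median = qr2[2],
                            r2_q75 = qr2[3],
                            vii_q25 = qv[1], vii_median = qv[2],
                            vii_q75 = qv[3])
  }
  names(medoids) <- ids
  methods::new("ClusterResult", labels = labels, medoids = medoids,
               summary = if (length(rows)) do.call(rbind, rows)
                         else data.frame(),
               minClusterSize = as.integer(minClusterSize),
               minSamples = as.integer(minSamples))
}
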