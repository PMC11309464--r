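# Two-dimensional cluster-based permutation analysis on channel x frequency
# (20 x 40) or channel x time (20 x 256 over [-0.2, +0.8] s) grids:
# cell-wise t maps, edge-connectivity cluster formation with geometric size
# and statistical size (tsize = sum of member t statistics), a max-statistic
# permutation null, percentile-based significance at the 95th percentile, and
# cluster-based aggregated (CBA) subject measures.

# grids: [subject, channel, bin] array -> subjects x cells matrix; cell linear
# index = channel + (bin - 1) * n_channels (internal)
flatten_grids <- function(grids) {
  stopifnot(length(dim(grids)) == 3)
  d <- dim(grids)
  list(X = matrix(grids, d[1], d[2] * d[3]), n_channels = d[2], n_bins = d[3])
}

infer_space <- function(n_bins) {
  if (n_bins == 40) "channel_frequency" else
    if (n_bins == 256) "channel_time" else "custom"
}

default_min_size <- function(space) {
  switch(space, channel_frequency = 2, channel_time = 20, 2)
}

# pooled-variance two-sample t per column; rows of Z are group-1 indicators
perm_t_independent <- function(X, X2, Z, n1, n2) {
  tot1 <- colSums(X)
  tot2 <- colSums(X2)
  S1 <- Z %*% X
  Q1 <- Z %*% X2
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, tot1, `+`) / n2
  v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
  v2 <- (sweep(-Q1, 2, tot2, `+`) - (sweep(-S1, 2, tot1, `+`))^2 / n2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- 0
  tt
}

# paired t per column for sign-flip rows S (+1/-1)
perm_t_paired <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(M), ncol(M), byrow = TRUE)
  v <- (ssq - n * M^2) / (n - 1)
  tt <- M / sqrt(v / n)
  tt[!is.finite(tt)] <- 0
  tt
}

#' First-level t map over an analysis grid
#'
#' Cell-wise two-sided t statistics between two groups (pooled-variance
#' Student's t) or between two visits of the same subjects (paired t).
#' Zero-variance cells yield t = 0, p = 1 with a warning.
#'
#' @param grids `[subject, channel, bin]` array (visit 1 for the paired design).
#' @param labels two-level factor of group membership (independent design).
#' @param design `"independent"` or `"paired"`.
#' @param grids2 visit-2 array for the paired design (same subject order).
#' @return object of class `stat_grid`: `t`, `p` (channels x bins), `df`,
#'   `design`, `space`, `dims`.
#' @export
first_level <- function(grids, labels = NULL,
                        design = c("independent", "paired"), grids2 = NULL) {
  design <- match.arg(design)
  fl <- flatten_grids(grids)
  if (design == "independent") {
    labels <- as.factor(labels)
    stopifnot(nlevels(labels) == 2, length(labels) == nrow(fl$X))
    n1 <- sum(labels == levels(labels)[1])
    n2 <- sum(labels == levels(labels)[2])
    if (n1 < 2 || n2 < 2) stopf("need at least 2 subjects per group")
    Z <- matrix(0, 1, length(labels))
    Z[1, labels == levels(labels)[1]] <- 1
    tt <- perm_t_independent(fl$X, fl$X^2, Z, n1, n2)[1, ]
    df <- n1 + n2 - 2
  } else {
    stopifnot(!is.null(grids2), identical(dim(grids), dim(grids2)))
    if (dim(grids)[1] < 2) stopf("need at least 2 pairs")
    D <- fl$X - flatten_grids(grids2)$X
    tt <- perm_t_paired(D, matrix(1, 1, nrow(D)))[1, ]
    df <- nrow(D) - 1
  }
  if (any(tt == 0)) {
    zv <- sum(tt == 0)
    if (zv > 0.5 * length(tt)) {
      warning(sprintf("%d cells have zero variance (t set to 0, p to 1)", zv),
              call. = FALSE)
    }
  }
  tmat <- matrix(tt, fl$n_channels, fl$n_bins)
  pmat <- 2 * stats::pt(-abs(tmat), df)
  pmat[tmat == 0] <- 1
  structure(list(t = tmat, p = pmat, df = df, design = design,
                 space = infer_space(fl$n_bins),
                 dims = c(fl$n_channels, fl$n_bins)),
            class = "stat_grid")
}

# connected components of suprathreshold same-sign cells under 4-neighbour
# (edge) adjacency; returns list(cells, size, tsize, sign) per cluster
find_grid_clusters <- function(tmat, crit, min_size, adj) {
  nch <- nrow(tmat); nbins <- ncol(tmat)
  supra <- which(abs(tmat) > crit)
  if (length(supra) == 0) return(list())
  in_supra <- logical(nch * nbins)
  in_supra[supra] <- TRUE
  visited <- logical(nch * nbins)
  sgn <- sign(tmat)
  clusters <- list()
  for (s0 in supra) {
    if (visited[s0]) next
    stack <- s0
    visited[s0] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ch <- ((cur - 1) %% nch) + 1
      b <- ((cur - 1) %/% nch) + 1
      nbrs <- integer(0)
      if (b > 1) nbrs <- c(nbrs, cur - nch)
      if (b < nbins) nbrs <- c(nbrs, cur + nch)
      for (ac in adj[[ch]]) nbrs <- c(nbrs, ac + (b - 1) * nch)
      for (nb in nbrs) {
        if (in_supra[nb] && !visited[nb] && sgn[nb] == sgn[cur]) {
          visited[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    if (length(members) >= min_size) {
      clusters[[length(clusters) + 1]] <- list(
        cells = cbind(channel = ((members - 1) %% nch) + 1,
                      bin = ((members - 1) %/% nch) + 1),
        size = length(members),
        tsize = sum(tmat[members]),
        sign = if (sgn[members[1]] > 0) "+" else "-")
    }
  }
  if (length(clusters)) {
    clusters <- clusters[order(-abs(vapply(clusters, `[[`, 0, "tsize")))]
  }
  clusters
}

#' Form clusters from a first-level statistic grid
#'
#' Thresholds cells at `p < alpha`, groups same-sign suprathreshold cells into
#' connected components under 4-neighbour (edge) adjacency -- cells sharing a
#' channel and adjacent bins, or adjacent channels and the same bin -- and
#' discards components smaller than `min_size` (2 cells on the
#' channel-frequency grid, 20 on the channel-time grid). Channel adjacency
#' defaults to consecutive montage rows and can be overridden with a symmetric
#' logical matrix.
#'
#' @param stat a `stat_grid` from [first_level()].
#' @param alpha first-level significance threshold (default 0.01).
#' @param min_size minimum geometric cluster size (defaults by space).
#' @param adjacency optional channel adjacency matrix.
#' @return list of clusters, each with `cells`, `size`, `tsize`, `sign`,
#'   `percentile` (NA until assessed), `significant`; ordered by decreasing
#'   `|tsize|`.
#' @export
form_clusters <- function(stat, alpha = 0.01, min_size = NULL, adjacency = NULL) {
  stopifnot(inherits(stat, "stat_grid"))
  min_size <- min_size %||% default_min_size(stat$space)
  adj <- adjacency_list(adjacency %||% default_channel_adjacency(stat$dims[1]))
  crit <- stats::qt(1 - alpha / 2, stat$df)
  cl <- find_grid_clusters(stat$t, crit, min_size, adj)
  lapply(cl, function(x) {
    x$percentile <- NA_real_
    x$significant <- NA
    x
  })
}

#' Max-statistic permutation null distribution
#'
#' Re-runs the first-level test and cluster formation with identical
#' parameters under `n_perm` random relabelings -- label shuffles preserving
#' group sizes (independent design) or per-pair sign flips (paired design) --
#' and records the largest `|tsize|` per iteration (0 when an iteration forms
#' no cluster). For 10 or fewer subjects the relabelings are enumerated
#' exhaustively (with a warning) instead of sampled.
#'
#' @inheritParams first_level
#' @inheritParams form_clusters
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `null_distribution`: `max_tsizes`, `n_perm`,
#'   `seed`, `exact`.
#' @export
permutation_null <- function(grids, labels = NULL,
                             design = c("independent", "paired"),
                             grids2 = NULL, alpha = 0.01, min_size = NULL,
                             n_perm = 1000, seed = 1L, adjacency = NULL) {
  design <- match.arg(design)
  fl <- flatten_grids(grids)
  space <- infer_space(fl$n_bins)
  min_size <- min_size %||% default_min_size(space)
  adj <- adjacency_list(adjacency %||% default_channel_adjacency(fl$n_channels))
  n <- nrow(fl$X)
  exact <- n <= 10

  if (design == "independent") {
    labels <- as.factor(labels)
    n1 <- sum(labels == levels(labels)[1]); n2 <- n - n1
    df <- n - 2
    if (exact) {
      warning(sprintf(
        "small sample (n = %d): enumerating all %d label assignments exactly",
        n, choose(n, n1)), call. = FALSE)
      sets <- utils::combn(n, n1)
      Z <- matrix(0, ncol(sets), n)
      for (i in seq_len(ncol(sets))) Z[i, sets[, i]] <- 1
    } else {
      Z <- with_seed(derive_seed(seed, "perm"), {
        m <- matrix(0, n_perm, n)
        for (i in seq_len(n_perm)) m[i, sample.int(n, n1)] <- 1
        m
      })
    }
    TT <- perm_t_independent(fl$X, fl$X^2, Z, n1, n2)
  } else {
    stopifnot(!is.null(grids2))
    D <- fl$X - flatten_grids(grids2)$X
    df <- n - 1
    if (exact) {
      warning(sprintf(
        "small sample (n = %d pairs): enumerating all %d sign flips exactly",
        n, 2^n), call. = FALSE)
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      colnames(S) <- NULL
    } else {
      S <- with_seed(derive_seed(seed, "perm"),
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
    }
    TT <- perm_t_paired(D, S)
  }

  crit <- stats::qt(1 - alpha / 2, df)
  maxes <- apply(TT, 1, function(tt) {
    cl <- find_grid_clusters(matrix(tt, fl$n_channels, fl$n_bins),
                             crit, min_size, adj)
    if (length(cl)) max(abs(vapply(cl, `[[`, 0, "tsize"))) else 0
  })
  structure(list(max_tsizes = as.numeric(maxes), n_perm = length(maxes),
                 seed = seed, exact = exact, design = design),
            class = "null_distribution")
}

#' Assess cluster significance against a permutation null
#'
#' The percentile of each cluster is the percentage of null maximum `|tsize|`
#' values at or below the cluster's `|tsize|` (ties count as below); a cluster
#' is significant when its percentile reaches the 95th.
#'
#' @param clusters list from [form_clusters()].
#' @param null a `null_distribution`.
#' @param level significance percentile (default 95).
#' @return the cluster list with `percentile` and `significant` filled in.
#' @export
assess_significance <- function(clusters, null, level = 95) {
  stopifnot(inherits(null, "null_distribution"), null$n_perm > 0)
  lapply(clusters, function(cl) {
    cl$percentile <- 100 * sum(null$max_tsizes <= abs(cl$tsize)) / null$n_perm
    cl$significant <- cl$percentile >= level
    cl
  })
}

#' Cluster-based aggregated (CBA) measure for one subject
#'
#' Unweighted mean of the subject's grid values over the cluster's cells --
#' the subject-level scalar used as a biomarker predictor.
#'
#' @param grid channels x bins matrix (a subject's PSD values or ERP waveform).
#' @param cluster one cluster from [form_clusters()].
#' @return scalar CBA value.
#' @export
extract_cba <- function(grid, cluster) {
  if (is.null(cluster) || cluster$size == 0) stopf("empty cluster")
  mean(grid[cluster$cells])
}

#' CBA values for all subjects of a grid array
#'
#' @param grids `[subject, channel, bin]` array.
#' @param cluster one cluster.
#' @return numeric vector, one CBA per subject.
#' @export
cba_by_subject <- function(grids, cluster) {
  apply(grids, 1, function(g) mean(g[cluster$cells]))
}

#' Run the full cluster-based permutation analysis
#'
#' Convenience wrapper: first-level t map, cluster formation, max-statistic
#' permutation null with identical parameters, and percentile assessment.
#'
#' @inheritParams permutation_null
#' @return object of class `cluster_test`: `stat`, `clusters` (assessed),
#'   `null`, and the parameters used.
#' @export
cluster_permutation_test <- function(grids, labels = NULL,
                                     design = c("independent", "paired"),
                                     grids2 = NULL, alpha = 0.01,
                                     min_size = NULL, n_perm = 1000,
                                     seed = 1L, adjacency = NULL) {
  design <- match.arg(design)
  stat <- first_level(grids, labels, design, grids2)
  min_size <- min_size %||% default_min_size(stat$space)
  clusters <- form_clusters(stat, alpha, min_size, adjacency)
  null <- permutation_null(grids, labels, design, grids2, alpha, min_size,
                           n_perm, seed, adjacency)
  clusters <- assess_significance(clusters, null)
  structure(list(stat = stat, clusters = clusters, null = null,
                 alpha = alpha, min_size = min_size, n_perm = null$n_perm,
                 seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s grid (%d x %d), %d clusters, %d permutations\n",
              x$stat$space, x$stat$dims[1], x$stat$dims[2],
              length(x$clusters), x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  %s size %d, tsize %.1f, percentile %.1f%s\n", cl$sign,
                cl$size, cl$tsize, cl$percentile,
                if (isTRUE(cl$significant)) " *" else ""))
  }
  invisible(x)
}

#' Export a cluster report as JSON-ready list
#'
#' @param cluster a cluster; @param channels channel labels.
#' @return list with cells, size, tsize, sign, percentile, covered channels
#'   and bin window.
#' @export
cluster_report <- function(cluster, channels = NULL) {
  chs <- sort(unique(cluster$cells[, "channel"]))
  list(size = cluster$size, tsize = cluster$tsize, sign = cluster$sign,
       percentile = cluster$percentile, significant = cluster$significant,
       channels = if (is.null(channels)) chs else channels[chs],
       bin_window = range(cluster$cells[, "bin"]),
       cells = apply(cluster$cells, 1, paste, collapse = ","))
}
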