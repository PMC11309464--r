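# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation (union-find instead of BFS,
# explicit DFT sums instead of FFT, direct enumeration instead of the
# vectorized permutation engine).

# --- brute-force connected components via union-find -------------------------
# cells: suprathreshold cells of a t matrix; chain channel adjacency.
oracle_clusters <- function(tmat, crit, min_size) {
  nch <- nrow(tmat); nb <- ncol(tmat)
  supra <- which(abs(tmat) > crit, arr.ind = TRUE)
  if (nrow(supra) == 0) return(list())
  parent <- seq_len(nrow(supra))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  same_sign <- function(i, j) {
    sign(tmat[supra[i, 1], supra[i, 2]]) == sign(tmat[supra[j, 1], supra[j, 2]])
  }
  for (i in seq_len(nrow(supra))) {
    for (j in seq_len(nrow(supra))) {
      if (i >= j) next
      dch <- abs(supra[i, 1] - supra[j, 1])
      dbn <- abs(supra[i, 2] - supra[j, 2])
      if (((dch == 1 && dbn == 0) || (dch == 0 && dbn == 1)) && same_sign(i, j)) {
        union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(nrow(supra)), find, 1L)
  out <- lapply(unique(roots), function(r) {
    members <- which(roots == r)
    cells <- supra[members, , drop = FALSE]
    list(size = length(members),
         tsize = sum(tmat[cells]),
         cells = cells)
  })
  out[vapply(out, function(x) x$size >= min_size, logical(1))]
}

# --- direct DFT (explicit sum) PSD of one 1-s epoch --------------------------
oracle_psd_epoch <- function(x, fs) {
  n <- length(x)
  w <- signal::kaiser(n, 6)
  xw <- x * w
  bins <- 1:40
  vapply(bins, function(f) {
    k <- f * n / fs  # DFT index for f Hz
    re <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
    (1 / fs) * 2 * (re^2 + im^2)
  }, numeric(1))
}

# --- exhaustive max-tsize null for a tiny independent design -----------------
# computes first-level t via the textbook formula, forms clusters with the
# union-find oracle, for every assignment of n1 subjects to group 1.
oracle_exact_null <- function(grids, n1, alpha, min_size) {
  n <- dim(grids)[1]
  df <- n - 2
  crit <- qt(1 - alpha / 2, df)
  sets <- utils::combn(n, n1)
  apply(sets, 2, function(idx) {
    g1 <- grids[idx, , , drop = FALSE]
    g2 <- grids[-idx, , , drop = FALSE]
    tmat <- matrix(0, dim(grids)[2], dim(grids)[3])
    for (ch in seq_len(dim(grids)[2])) {
      for (b in seq_len(dim(grids)[3])) {
        a <- g1[, ch, b]; bb <- g2[, ch, b]
        sp <- sqrt(((length(a) - 1) * var(a) + (length(bb) - 1) * var(bb)) / df)
        tmat[ch, b] <- (mean(a) - mean(bb)) /
          (sp * sqrt(1 / length(a) + 1 / length(bb)))
      }
    }
    cl <- oracle_clusters(tmat, crit, min_size)
    if (length(cl)) max(abs(vapply(cl, `[[`, 0, "tsize"))) else 0
  })
}

# --- small fixtures ----------------------------------------------------------
# epochs with known content: trials x channels x time
make_epochs <- function(data, fs = 256, t0 = -0.8, metadata = NULL) {
  nt <- dim(data)[1]
  times <- t0 + (seq_len(dim(data)[3]) - 1) / fs
  if (is.null(metadata)) {
    metadata <- data.frame(trial_type = rep("target", nt),
                           correct = rep(TRUE, nt), rt_s = rep(0.5, nt))
  }
  new_epochs(data, fs, times, paste0("ch", seq_len(dim(data)[2])), metadata)
}

tiny_cohort <- function(n_hc = 3, n_mci = 3, duration = 20, seed = 7, ...) {
  cfg <- cohort_config(n_hc = n_hc, n_mci = n_mci,
                       resting_duration_s = duration, seed = seed, ...)
  list(config = cfg, cohort = make_cohort(cfg))
}
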