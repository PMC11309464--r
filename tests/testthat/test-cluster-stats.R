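rand_grids <- function(n, nch, nb, seed, shift_cells = NULL, shift = 0) {
  set.seed(seed)
  g <- array(rnorm(n * nch * nb), c(n, nch, nb))
  if (!is.null(shift_cells)) {
    half <- seq_len(n / 2)
    for (cell in seq_len(nrow(shift_cells))) {
      g[-half, shift_cells[cell, 1], shift_cells[cell, 2]] <-
        g[-half, shift_cells[cell, 1], shift_cells[cell, 2]] + shift
    }
  }
  g
}

test_that("first-level t maps agree with t.test cell by cell", {
  g <- rand_grids(12, 4, 5, seed = 1)
  labels <- rep(c("HC", "MCI"), each = 6)
  st <- first_level(g, labels)
  for (ch in 1:4) {
    for (b in 1:5) {
      tt <- t.test(g[1:6, ch, b], g[7:12, ch, b], var.equal = TRUE)
      expect_equal(st$t[ch, b], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(st$p[ch, b], tt$p.value, tolerance = 1e-10)
    }
  }
  expect_equal(st$df, 10)
  expect_equal(st$space, "custom")
})

test_that("paired first-level statistics match the paired t test and its degenerate case", {
  g1 <- rand_grids(8, 3, 4, seed = 2)
  g2 <- rand_grids(8, 3, 4, seed = 3)
  st <- first_level(g1, design = "paired", grids2 = g2)
  tt <- t.test(g1[, 2, 3], g2[, 2, 3], paired = TRUE)
  expect_equal(st$t[2, 3], unname(tt$statistic), tolerance = 1e-10)
  # visit2 identical to visit1: all t exactly 0
  st0 <- suppressWarnings(first_level(g1, design = "paired", grids2 = g1))
  expect_true(all(st0$t == 0))
  expect_true(all(st0$p == 1))
})

test_that("zero-variance cells yield t = 0 and p = 1", {
  g <- rand_grids(10, 2, 3, seed = 4)
  g[, 1, 1] <- 7  # constant across everyone
  st <- first_level(g, rep(c("a", "b"), each = 5))
  expect_equal(st$t[1, 1], 0)
  expect_equal(st$p[1, 1], 1)
})

test_that("null first-level p values are uniform and a strong shift is detected", {
  g <- rand_grids(40, 20, 40, seed = 5)
  st <- first_level(g, rep(c("HC", "MCI"), each = 20))
  ks <- ks.test(as.vector(st$p), "punif")
  expect_gt(ks$p.value, 0.01)
  # one cell shifted by 3 pooled SDs at n = 20/20
  g2 <- rand_grids(40, 20, 40, seed = 6,
                   shift_cells = cbind(5, 7), shift = 3)
  st2 <- first_level(g2, rep(c("HC", "MCI"), each = 20))
  expect_lt(st2$p[5, 7], 0.01)
})

test_that("cluster formation matches the worked toy example", {
  # 4x4 grid, suprathreshold cells (1,1), (1,2), (2,2), (4,4); min size 2
  tmat <- matrix(0, 4, 4)
  tmat[1, 1] <- 3; tmat[1, 2] <- 3.5; tmat[2, 2] <- 4; tmat[4, 4] <- 5
  st <- structure(list(t = tmat, p = 2 * pt(-abs(tmat), 20), df = 20,
                       design = "independent", space = "custom", dims = c(4, 4)),
                  class = "stat_grid")
  cl <- form_clusters(st, alpha = 0.01, min_size = 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 3)
  expect_equal(cl[[1]]$tsize, 3 + 3.5 + 4)
  expect_equal(cl[[1]]$sign, "+")
})

test_that("adjacent suprathreshold cells of opposite sign form separate clusters", {
  tmat <- matrix(0, 3, 3)
  tmat[1, 1] <- 4; tmat[1, 2] <- -4; tmat[2, 2] <- -4.5
  st <- structure(list(t = tmat, p = 2 * pt(-abs(tmat), 20), df = 20,
                       design = "independent", space = "custom", dims = c(3, 3)),
                  class = "stat_grid")
  cl <- form_clusters(st, alpha = 0.01, min_size = 1)
  expect_length(cl, 2)
  signs <- vapply(cl, `[[`, "", "sign")
  expect_setequal(signs, c("+", "-"))
  sizes <- vapply(cl, `[[`, 0, "size")
  expect_setequal(sizes, c(1, 2))
})

test_that("cluster formation matches the union-find oracle on all 3x3 patterns", {
  set.seed(7)
  for (pattern in 0:511) {
    bits <- as.integer(intToBits(pattern))[1:9]
    tmat <- matrix(0, 3, 3)
    tmat[bits == 1] <- 4 + runif(sum(bits), 0, 2)
    # mix in a negative cell occasionally to exercise the sign rule
    if (pattern %% 5 == 0 && any(bits == 1)) {
      flip <- which(bits == 1)[1]
      tmat[flip] <- -tmat[flip]
    }
    st <- structure(list(t = tmat, p = 2 * pt(-abs(tmat), 20), df = 20,
                         design = "independent", space = "custom",
                         dims = c(3, 3)),
                    class = "stat_grid")
    for (ms in c(1, 2)) {
      got <- form_clusters(st, alpha = 0.01, min_size = ms)
      want <- oracle_clusters(tmat, qt(0.995, 20), ms)
      expect_equal(length(got), length(want),
                   info = sprintf("pattern %d min_size %d", pattern, ms))
      expect_setequal(round(vapply(got, `[[`, 0, "tsize"), 9),
                      round(vapply(want, `[[`, 0, "tsize"), 9))
      expect_setequal(vapply(got, `[[`, 0, "size"),
                      vapply(want, `[[`, 0, "size"))
    }
  }
})

test_that("a custom channel adjacency changes connectivity", {
  tmat <- matrix(0, 4, 2)
  tmat[1, 1] <- 4; tmat[4, 1] <- 4  # channels 1 and 4, same bin
  st <- structure(list(t = tmat, p = 2 * pt(-abs(tmat), 20), df = 20,
                       design = "independent", space = "custom", dims = c(4, 2)),
                  class = "stat_grid")
  # chain adjacency: two singletons
  expect_length(form_clusters(st, min_size = 2), 0)
  # adjacency declaring channels 1 and 4 neighbours: one cluster of 2
  adj <- matrix(FALSE, 4, 4)
  adj[1, 4] <- adj[4, 1] <- TRUE
  cl <- form_clusters(st, min_size = 2, adjacency = adj)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 2)
})

test_that("the exact small-sample null matches brute-force enumeration", {
  g <- rand_grids(4, 3, 4, seed = 8)
  expect_warning(
    null <- permutation_null(g, rep(c("a", "b"), each = 2), alpha = 0.05,
                             min_size = 1),
    "enumerating")
  expect_equal(null$n_perm, choose(4, 2))
  want <- oracle_exact_null(g, 2, alpha = 0.05, min_size = 1)
  expect_equal(sort(null$max_tsizes), sort(want), tolerance = 1e-9)
})

test_that("the permutation null is deterministic and respects group sizes", {
  g <- rand_grids(24, 5, 8, seed = 9)
  labels <- rep(c("HC", "MCI"), each = 12)
  n1 <- permutation_null(g, labels, alpha = 0.2, n_perm = 50, seed = 42,
                         min_size = 1)
  n2 <- permutation_null(g, labels, alpha = 0.2, n_perm = 50, seed = 42,
                         min_size = 1)
  expect_identical(n1$max_tsizes, n2$max_tsizes)
  n3 <- permutation_null(g, labels, alpha = 0.2, n_perm = 50, seed = 43,
                         min_size = 1)
  expect_false(identical(n1$max_tsizes, n3$max_tsizes))
  expect_length(n1$max_tsizes, 50)
  expect_true(all(n1$max_tsizes >= 0))
})

test_that("label swapping leaves the cluster statistics invariant", {
  g <- rand_grids(20, 6, 10, seed = 10)
  labels <- rep(c("HC", "MCI"), each = 10)
  st1 <- first_level(g, labels)
  st2 <- first_level(g, rev(labels))
  expect_equal(st1$t, -st2$t, tolerance = 1e-12)
  cl1 <- form_clusters(st1, min_size = 1)
  cl2 <- form_clusters(st2, min_size = 1)
  expect_equal(sort(abs(vapply(cl1, `[[`, 0, "tsize"))),
               sort(abs(vapply(cl2, `[[`, 0, "tsize"))), tolerance = 1e-12)
})

test_that("percentiles follow the tie-inclusive convention and the 95th rule", {
  cl <- list(list(cells = cbind(1, 1:2), size = 2, tsize = 10, sign = "+",
                  percentile = NA, significant = NA))
  null <- structure(list(max_tsizes = c(1:89 / 10, 15, rep(20, 10)),
                         n_perm = 100, seed = 1, exact = FALSE,
                         design = "independent"),
                    class = "null_distribution")
  out <- assess_significance(cl, null)
  # 89 values below 10, the value 15 and the ten 20s above: percentile 89
  expect_equal(out[[1]]$percentile, 89)
  expect_false(out[[1]]$significant)
  # above every null value -> 100, significant
  cl[[1]]$tsize <- -100  # sign is irrelevant, |tsize| is compared
  out2 <- assess_significance(cl, null)
  expect_equal(out2[[1]]$percentile, 100)
  expect_true(out2[[1]]$significant)
  cl[[1]]$tsize <- 0.01
  expect_equal(assess_significance(cl, null)[[1]]$percentile, 0)
})

test_that("CBA extraction averages the cluster cells", {
  grid <- matrix(5, 4, 4)
  cl <- list(cells = cbind(channel = c(1, 2), bin = c(1, 1)), size = 2)
  expect_equal(extract_cba(grid, cl), 5)
  grid[1, 1] <- 1; grid[2, 1] <- 3
  expect_equal(extract_cba(grid, cl), 2)
  grids <- array(0, c(3, 4, 4)); grids[2, , ] <- 1; grids[3, , ] <- 4
  expect_equal(cba_by_subject(grids, cl), c(0, 1, 4))
})

test_that("CBA aggregation gains over single-cell measures on the grid cohort", {
  gains <- vapply(1:15, function(r) {
    gc <- simulate_stat_grids(30, 30, "channel_frequency", seed = 800 + r)
    ef <- gc$effects[[2]]  # slow-beta suppression
    cba <- cba_by_subject(gc$visits[[1]], list(cells = ef$mask, size = 1))
    cell <- gc$visits[[1]][, ef$channels[10], ef$bins[3]]
    mci <- gc$labels == "MCI"
    abs(hedges_g(cba[mci], cba[!mci])) - abs(hedges_g(cell[mci], cell[!mci]))
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("the full cluster test finds the injected spectral effects", {
  gc <- simulate_stat_grids(40, 40, "channel_frequency", seed = 77)
  ct <- cluster_permutation_test(gc$visits[[1]], gc$labels, n_perm = 200,
                                 seed = 77)
  expect_s3_class(ct, "cluster_test")
  expect_equal(prod(ct$stat$dims), 800)
  sig <- Filter(function(c) isTRUE(c$significant), ct$clusters)
  expect_gt(length(sig), 0)
  # at least one significant cluster overlaps an injected band
  hit <- any(vapply(sig, function(cl) {
    any(cl$cells[, "bin"] %in% 3:7) || any(cl$cells[, "bin"] %in% 13:20)
  }, logical(1)))
  expect_true(hit)
})
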