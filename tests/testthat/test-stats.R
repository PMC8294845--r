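test_that("group t-maps match hand-computed one-sample t-tests", {
  maps <- array(0.5, c(5, 3, 4))
  expect_true(all(group_tmap(maps) == 0))

  m2 <- array(0.5, c(3, 1, 1))
  m2[, 1, 1] <- c(0.6, 0.7, 0.8) # mean .7, sd .1 -> t = .2/(.1/sqrt(3))
  expect_equal(group_tmap(m2)[1, 1], 3.4641016, tolerance = 1e-6)

  # adding a constant shifts t monotonically
  m3 <- m2; m3[, 1, 1] <- m3[, 1, 1] + 0.05
  expect_gt(group_tmap(m3)[1, 1], group_tmap(m2)[1, 1])
  expect_error(group_tmap(array(0.5, c(2, 2, 2))), "3 participants")
})

test_that("connected-component labelling matches an igraph oracle", {
  skip_if_not_installed("igraph")
  igraph_labels <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    on <- which(mask)
    if (!length(on)) return(matrix(0L, nr, nc))
    edges <- list()
    for (cell in on) {
      r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
      if (r < nr && mask[cell + 1]) edges[[length(edges) + 1]] <- c(cell, cell + 1)
      if (c < nc && mask[cell + nr]) edges[[length(edges) + 1]] <- c(cell, cell + nr)
    }
    g <- igraph::graph_from_data_frame(
      if (length(edges)) as.data.frame(do.call(rbind, edges)) else
        data.frame(V1 = integer(), V2 = integer()),
      directed = FALSE, vertices = data.frame(name = as.character(on)))
    comp <- igraph::components(g)$membership
    lab <- matrix(0L, nr, nc)
    lab[on] <- as.integer(comp[as.character(on)])
    lab
  }
  set.seed(20)
  for (rep in 1:25) {
    mask <- matrix(runif(12 * 15) < 0.35, 12, 15)
    mine <- label_clusters(mask)
    oracle <- igraph_labels(mask)
    # same partition up to label permutation
    expect_equal(mine > 0, oracle > 0)
    tab <- table(mine[mine > 0], oracle[oracle > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("cluster permutation test scores block effects and degenerate maps", {
  # flat maps at chance: no clusters at all
  maps <- array(0.5, c(6, 5, 8))
  res <- cluster_permutation_test(maps, n_perm = 100, seed = 1)
  expect_length(res$clusters, 0)
  expect_false(any(res$mask))

  # two disjoint suprathreshold blocks on a clearly subthreshold background
  # -> exactly two clusters whose masses equal the block-wise t sums
  set.seed(21)
  maps <- array(0.45 + rnorm(12 * 10 * 12, sd = 0.002), c(12, 10, 12))
  maps[, 2:3, 2:4] <- maps[, 2:3, 2:4] + 0.25
  maps[, 7:9, 8:11] <- maps[, 7:9, 8:11] + 0.25
  res <- cluster_permutation_test(maps, n_perm = 200, seed = 2)
  expect_length(res$clusters, 2)
  tsum <- sum(res$tmap[res$tmap > res$t_crit])
  expect_equal(sum(vapply(res$clusters, `[[`, numeric(1), "mass")), tsum)
  ps <- vapply(res$clusters, `[[`, numeric(1), "p")
  expect_true(all(ps >= 1 / (200 + 1))) # the permutation-p lower bound
  expect_true(all(ps <= 0.05))
  expect_true(all(res$mask[2:3, 2:4]))
})

test_that("JZS Bayes factors reproduce worked examples and behave in limits", {
  expect_equal(bayes_factor_one_sample(-0.50, 24, "greater", r = 0.71),
               6.53, tolerance = 0.02)
  expect_equal(bayes_factor_one_sample(-1.24, 24, "two", r = 0.707),
               2.36, tolerance = 0.03)
  # BF01 * BF10 = 1 by construction; check consistency across sides
  for (t in c(-1, 0.3, 2.5)) {
    b2 <- bayes_factor_one_sample(t, 20, "two")
    expect_gt(b2, 0)
  }
  # decreasing in |t| for the two-sided test
  bfs <- vapply(c(0, 1, 2, 4, 8, 15),
                function(t) bayes_factor_one_sample(t, 24, "two"), numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_lt(bfs[length(bfs)], 1e-6)
  expect_error(bayes_factor_one_sample(NaN, 24), "finite")
})

test_that("ROI summaries average the stated window and report dz = t/sqrt(n)", {
  freqs <- seq(2, 30, 2)
  times <- seq(-6, 64) / 64
  maps <- array(0.55, c(24, length(freqs), length(times)))
  res <- roi_summary(maps, freqs, times)
  expect_equal(res$roi_auc, rep(0.55, 24))
  expect_equal(res$dz, res$t / sqrt(24))

  # printed worked examples of the dz identity
  expect_equal(-0.50 / sqrt(24), -0.10, tolerance = 0.03)
  expect_equal(2.89 / sqrt(23), 0.60, tolerance = 0.01)

  # bins outside the closed ROI do not contribute
  maps2 <- maps
  maps2[, freqs > 8, ] <- 99
  maps2[, , times < 0.1 | times > 0.7] <- 99
  res2 <- roi_summary(maps2, freqs, times)
  expect_equal(res2$roi_auc, rep(0.55, 24))
  expect_error(roi_summary(maps, freqs, times,
                           roi = list(freq = c(40, 50), time = c(0, 1))),
               "empty ROI")
})

test_that("d-prime follows the corrected normal-quantile definition", {
  # counts whose log-linear corrected rates are exactly 0.75 / 0.25
  res <- dprime(7, 2, 2, 7)
  expect_equal(res$hit_rate, 0.75)
  expect_equal(res$fa_rate, 0.25)
  expect_equal(res$dprime, 2 * qnorm(0.75))

  expect_equal(dprime(50, 50, 50, 50)$dprime, 0)
  # monotone in hits at fixed false alarms
  d1 <- dprime(60, 40, 20, 80)$dprime
  d2 <- dprime(80, 20, 20, 80)$dprime
  expect_gt(d2, d1)
  # without correction, the raw rates are used
  expect_equal(dprime(75, 25, 25, 75, correction = FALSE)$dprime,
               2 * qnorm(0.75))
  expect_error(dprime(0, 0, 5, 5), "signal")
})

test_that("behavioral conflict effects recover the generator's effect size", {
  tabs <- lapply(1:24, function(p) {
    d <- generate_design("content_discrimination_1", 400, seed = p)
    generate_behavior(d, "content_discrimination_1",
                      behavior_params(conflict_rt_ms = 30), seed = 1000 + p)
  })
  res <- behavior_conflict_effects(tabs)
  expect_equal(res$tests["rt_ms", "mean_diff"], 30, tolerance = 5 / 30)
  expect_lt(res$tests["rt_ms", "p"], 0.001)
  expect_gt(res$tests["error_rate", "mean_diff"], 0) # rates 5% vs 10%
  expect_equal(res$tests["rt_ms", "dz"],
               res$tests["rt_ms", "t"] / sqrt(24))

  expect_error(behavior_conflict_effects(tabs[1]), "2 participants")
  bad <- tabs
  bad[[1]] <- bad[[1]][bad[[1]]$congruency == "congruent", ]
  expect_error(behavior_conflict_effects(bad), "both congruency levels")
})
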