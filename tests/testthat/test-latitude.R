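# independent density oracle: explicit per-branch Normal terms
o_bm_lp <- function(tree, x, s2, mu, bounds, min_br = 1e-4) {
  ta <- tree_ages(tree)
  ed <- tree$edge
  lp <- 0
  brks <- sort(unique(c(0, bounds, Inf)))
  for (r in seq_len(nrow(ed))) {
    p <- ed[r, 1]; ch <- ed[r, 2]
    tk <- vapply(seq_len(length(brks) - 1), function(k)
      max(min(ta$ages[p], brks[k + 1]) - max(ta$ages[ch], brks[k]), 0),
      numeric(1))
    tt <- max(ta$ages[p] - ta$ages[ch], min_br)
    lp <- lp + dnorm(x[ch] - x[p], sum(mu * tk), sqrt(s2 * tt), log = TRUE)
  }
  lp + dnorm(x[ape::Ntip(tree) + 1], 0, 50, log = TRUE) +
    sum(dnorm(mu, 0, 10, log = TRUE)) - log(1 + s2^2)
}

test_that("log posterior matches closed forms and the density oracle", {
  tr <- tree2(10, 10)
  x <- c(2, -1, 0.5)                     # t1, t2, root
  lp <- bm_trend_log_posterior(tr, x, sigma2 = 0.7, mu = 0, bin_bounds = numeric(0))
  manual <- dnorm(2 - 0.5, 0, sqrt(7), log = TRUE) +
    dnorm(-1 - 0.5, 0, sqrt(7), log = TRUE) +
    dnorm(0.5, 0, 50, log = TRUE) + dnorm(0, 0, 10, log = TRUE) - log(1 + 0.49)
  expect_equal(lp, manual, tolerance = 1e-12)

  # single bin covering the branch: expected displacement mu * t
  lp_trend <- bm_trend_log_posterior(tr, x, 0.7, mu = 0.3, bin_bounds = numeric(0))
  manual_trend <- dnorm(2 - 0.5, 3, sqrt(7), log = TRUE) +
    dnorm(-1 - 0.5, 3, sqrt(7), log = TRUE) +
    dnorm(0.5, 0, 50, log = TRUE) + dnorm(0.3, 0, 10, log = TRUE) - log(1 + 0.49)
  expect_equal(lp_trend, manual_trend, tolerance = 1e-12)

  # 3-tip tree with a fossil, two bins, all states fixed: oracle equality
  tr3 <- tree3_fossil()
  x3 <- c(1, -2, 4, 0, 2.5)
  for (mu in list(c(0, 0), c(0.4, -0.2))) {
    expect_equal(bm_trend_log_posterior(tr3, x3, 1.3, mu, bin_bounds = 1.5),
                 o_bm_lp(tr3, x3, 1.3, mu, 1.5), tolerance = 1e-10)
  }
  expect_error(bm_trend_log_posterior(tr3, x3, -1, c(0, 0), 1.5), "positive")
})

test_that("the sampler recovers a two-bin trend simulated with fossils", {
  set.seed(3)
  tr <- simulate_fbd_tree(lambda = 0.1, mu = 0.03, psi = 0.04, rho = 1,
                          origin = 80, min_tips = 60)
  bb <- tree_ages(tr)$root_age / 2
  sim <- simulate_latitudes(tr, sigma2 = 1, mu = c(-0.3, 0.3), bin_bounds = bb)
  lat <- sim[!is.na(sim$label), c("label", "latitude")]
  fit <- run_latitude_mcmc(tr, lat, bin_bounds = bb, n_generations = 30000,
                           thin = 20, seed = 5)
  td <- tidy(fit)
  expect_true(td$conf.low[td$term == "mu_1"] < -0.3 &&
              td$conf.high[td$term == "mu_1"] > -0.3)
  expect_true(td$conf.low[td$term == "mu_2"] < 0.3 &&
              td$conf.high[td$term == "mu_2"] > 0.3)
  expect_lt(abs(td$estimate[td$term == "sigma2"] - 1), 0.5)
})

test_that("the trait rescaling factor does not change the reported posterior", {
  set.seed(9)
  tr <- simulate_fbd_tree(lambda = 0.12, mu = 0.02, psi = 0.05, rho = 1,
                          origin = 50, min_tips = 40)
  sim <- simulate_latitudes(tr, sigma2 = 2, mu = 0.2, bin_bounds = numeric(0))
  lat <- sim[!is.na(sim$label), c("label", "latitude")]
  f1 <- run_latitude_mcmc(tr, lat, bin_bounds = numeric(0),
                          n_generations = 20000, thin = 20, rescale = 1, seed = 7)
  f10 <- run_latitude_mcmc(tr, lat, bin_bounds = numeric(0),
                           n_generations = 20000, thin = 20, rescale = 10, seed = 7)
  t1 <- tidy(f1); t10 <- tidy(f10)
  # same degree-scale posterior up to Monte-Carlo error
  expect_lt(abs(t1$estimate[t1$term == "mu_1"] - t10$estimate[t10$term == "mu_1"]),
            0.1)
  expect_lt(abs(log(t1$estimate[t1$term == "sigma2"] /
                    t10$estimate[t10$term == "sigma2"])), 0.35)
})

test_that("a degenerate two-tip tree still yields a finite posterior sample", {
  lat <- tibble::tibble(label = c("t1", "t2"), latitude = c(10, -5))
  fit <- run_latitude_mcmc(tree2(5, 5), lat, bin_bounds = numeric(0),
                           n_generations = 2000, thin = 10, seed = 2)
  expect_true(all(is.finite(fit$samples$sigma2)))
  expect_gt(nrow(fit$samples), 10)
})

test_that("span envelope interpolates lineages and matches a per-draw oracle", {
  # hand-built posterior: one tree, one draw, states fixed
  tr <- tree2(10, 10)
  fit <- structure(list(
    samples = tibble::tibble(tree = 1L, draw = 1L, sigma2 = 1),
    node_states = list(matrix(c(30, -30, 0), nrow = 1)),
    trees = list(tr), bin_bounds = numeric(0), rescale = 10,
    acceptance = list(c(x = 0.3, sigma2 = 0.3, mu = 0.3))),
    class = "latitude_trend")
  sp <- span_through_time(fit, grid = c(10, 5, 0), type = "minmax")
  expect_equal(sp$lat_min, c(0, -15, -30))
  expect_equal(sp$lat_max, c(0, 15, 30))

  # grid point at a node age contains the node's sampled state
  expect_true(sp$lat_min[1] <= 0 && sp$lat_max[1] >= 0)

  # pooled samples: envelope equals an independent per-draw recomputation
  set.seed(13)
  tr2 <- simulate_fbd_tree(lambda = 0.15, mu = 0.02, psi = 0.03, rho = 1,
                           origin = 40, min_tips = 15)
  sim <- simulate_latitudes(tr2, 1.5, 0.1, numeric(0))
  lat <- sim[!is.na(sim$label), c("label", "latitude")]
  f <- run_latitude_mcmc(tr2, lat, bin_bounds = numeric(0),
                         n_generations = 4000, thin = 50, seed = 11)
  grid <- seq(tree_ages(f$trees[[1]])$root_age, 0, length.out = 7)
  sp2 <- span_through_time(f, grid = grid, type = "minmax")
  ta <- tree_ages(f$trees[[1]])
  ed <- f$trees[[1]]$edge
  st <- f$node_states[[1]]
  for (gi in seq_len(nrow(sp2))) {
    tt <- sp2$time[gi]
    vals <- c()
    for (dr in seq_len(nrow(st))) {
      for (r in seq_len(nrow(ed))) {
        p <- ed[r, 1]; ch <- ed[r, 2]
        if (ta$ages[ch] <= tt + 1e-12 && ta$ages[p] >= tt - 1e-12) {
          len <- ta$ages[p] - ta$ages[ch]
          w <- if (len > 0) (ta$ages[p] - tt) / len else 1
          vals <- c(vals, st[dr, p] * (1 - w) + st[dr, ch] * w)
        }
      }
    }
    expect_equal(sp2$lat_min[gi], min(vals), tolerance = 1e-9)
    expect_equal(sp2$lat_max[gi], max(vals), tolerance = 1e-9)
  }

  # pooling draws never narrows the min/max envelope
  half <- f
  half$node_states[[1]] <- st[1:ceiling(nrow(st) / 2), , drop = FALSE]
  sp_half <- span_through_time(half, grid = grid, type = "minmax")
  expect_true(all(sp2$lat_min <= sp_half$lat_min + 1e-9))
  expect_true(all(sp2$lat_max >= sp_half$lat_max - 1e-9))
})
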