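test_that("fossil-free settings produce no fossil tips", {
  set.seed(71)
  tr <- simulate_fbd_tree(lambda = 0.2, mu = 0.05, psi = 0, rho = 1, origin = 30)
  expect_false(any(tree_ages(tr)$is_fossil))
  expect_false(any(grepl("^f", tr$tip.label)))
})

test_that("pure-birth tip counts match the conditional closed-form expectation", {
  # N ~ Geometric(p) with p = exp(-lambda*T); the simulator conditions on
  # N >= 2, so the oracle is E[N | N >= 2] = (1/p - p) / (1 - p)
  set.seed(72)
  lambda <- 0.1; T0 <- 20
  counts <- vapply(1:2000, function(i)
    ape::Ntip(simulate_fbd_tree(lambda, 0, 0, 1, T0)), numeric(1))
  p <- exp(-lambda * T0)
  expected <- (1 / p - p) / (1 - p)
  # the heavy geometric tail makes the sample mean noisy; check it loosely and
  # test the distribution itself with a goodness-of-fit over {2,...,9,10+}
  expect_lt(abs(mean(counts) - expected) / expected, 0.08)
  emp <- table(factor(pmin(counts, 10), levels = 2:10))
  cond <- p * (1 - p)^(2:9 - 1) / (1 - p)
  probs <- c(cond, 1 - sum(cond))
  gof <- suppressWarnings(chisq.test(as.numeric(emp), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("fossil counts match Poisson thinning of the total lineage length", {
  # with mu = 0 and rho = 1 nothing is pruned, so total lineage length equals
  # the sum of branch lengths plus the stem up to the origin
  set.seed(73)
  lambda <- 0.08; psi <- 0.05; T0 <- 30
  nf <- Ltot <- numeric(300)
  for (i in 1:300) {
    tr <- simulate_fbd_tree(lambda, 0, psi, 1, T0)
    ta <- tree_ages(tr)
    nf[i] <- sum(ta$is_fossil)
    Ltot[i] <- sum(tr$edge.length) + (T0 - ta$root_age)
  }
  expected <- psi * mean(Ltot)
  se <- sd(nf) / sqrt(length(nf))
  expect_lt(abs(mean(nf) - expected), 3 * se + 0.05)
})

test_that("event-free DEC history passes the root range to every tip", {
  set.seed(74)
  geo <- geo_complete(3, horizon = 100)
  tr <- simulate_fbd_tree(lambda = 0.15, mu = 0, psi = 0.02, rho = 1,
                          origin = 40, min_tips = 8)
  # a singleton root range: cladogenesis is pure sympatry, so with zero rates
  # every tip inherits the root range and no anagenetic event can occur
  h <- simulate_dec_history(tr, geo, d = 0, e = 0, root_mask = 2L)
  expect_true(all(h$tip_ranges$mask == 2L))
  expect_identical(sum(!h$events$event_type %in%
                         c("sympatry", "subset_sympatry", "vicariance")), 0L)
})

test_that("replaying the event log reproduces the simulated tip ranges", {
  set.seed(75)
  geo <- geo_complete(3, horizon = 100)
  tr <- simulate_fbd_tree(lambda = 0.12, mu = 0.03, psi = 0.03, rho = 1,
                          origin = 50, min_tips = 10)
  h <- simulate_dec_history(tr, geo, d = 0.02, e = 0.02)
  ev <- h$events
  codes <- geo$areas$code
  for (tip in seq_len(ape::Ntip(tr))) {
    cur <- h$corner_masks[tip]
    if (cur == 0L) next
    sub <- ev[!is.na(ev$branch) & ev$branch == tip, ]
    sub <- sub[order(sub$time, decreasing = TRUE), ]
    for (r in seq_len(nrow(sub))) {
      bit <- bitwShiftL(1L, match(sub$area[r], codes) - 1L)
      cur <- if (sub$event_type[r] == "dispersal") bitwOr(cur, bit)
             else bitwAnd(cur, bitwNot(bit))
    }
    expect_identical(cur, h$tip_ranges$mask[tip])
  }
})

test_that("single-branch dispersal frequencies match the rate-matrix transition law", {
  set.seed(76)
  geo <- geo_complete(2, horizon = 100)
  tr <- tree2(5, 5)
  ends <- integer(0)
  ndisp <- integer(0)
  for (i in 1:1000) {
    h <- simulate_dec_history(tr, geo, d = 0.05, e = 0.03, root_mask = 1L)
    ends <- c(ends, h$tip_ranges$mask)
    ndisp <- c(ndisp, vapply(1:2, function(b)
      sum(h$events$event_type == "dispersal" & !is.na(h$events$branch) &
            h$events$branch == b), integer(1)))
  }
  # empirical mean dispersal count per branch within 3 SE of d * t for the
  # dominant single-gain pathway (small d*t)
  expect_lt(abs(mean(ndisp) - 0.05 * 5), 3 * sd(ndisp) / sqrt(length(ndisp)) + 0.02)
  # chi-square: end-state frequencies against exp(Qt) row computed densely
  Q <- as.matrix(dec_rate_matrix(geo, 1, 0.05, 0.03))
  P <- ape::matexpo(Q * 5)
  probs <- P[geo$state_lookup[2], ]
  obs_counts <- vapply(seq_along(geo$state_space), function(s)
    sum(ends == geo$state_space[s]), numeric(1))
  keep <- probs > 1e-8
  gof <- suppressWarnings(chisq.test(obs_counts[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("latitude simulation obeys the BM moments and drift direction", {
  tr <- tree2(10, 10)
  set.seed(77)
  tips <- replicate(1000, {
    s <- simulate_latitudes(tr, sigma2 = 2, mu = 0, bin_bounds = numeric(0),
                            root_value = 5)
    s$latitude[1]
  })
  expect_lt(abs(var(tips) - 20) / 20, 0.10)      # sigma2 * t
  expect_lt(abs(mean(tips) - 5), 0.5)
  # zero-rate limit collapses to the root value
  s0 <- simulate_latitudes(tr, sigma2 = 1e-12, mu = 0, bin_bounds = numeric(0),
                           root_value = -3)
  expect_equal(s0$latitude, rep(-3, 3), tolerance = 1e-4)
  # positive drift raises tips above the root on average
  set.seed(78)
  up <- replicate(200, mean(simulate_latitudes(tr, 0.5, 0.4, numeric(0),
                                               root_value = 0)$latitude[1:2]))
  expect_gt(mean(up), 2)
})

test_that("the study-sized fixture has the documented shape and is reproducible", {
  fx <- make_paper_like_fixture(seed = 99, n_extant = 80, n_fossil = 20)
  ta <- tree_ages(fx$tree)
  expect_gte(sum(ta$is_fossil), 10)
  expect_true(ta$root_age >= 296 && ta$root_age <= 358.9)
  expect_lte(mean(range_size(fx$observations$mask) > 1), 0.05)
  expect_true(all(fx$observations$mask != 0L))
  # fossil tips are coded ambiguously, extant tips exactly
  fos <- fx$observations$label %in% fx$tree$tip.label[ta$is_fossil]
  expect_true(all(fx$observations$ambiguous[fos]))
  expect_false(any(fx$observations$ambiguous[!fos]))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  fx1 <- make_paper_like_fixture(seed = 99, dir = dir1, n_extant = 80, n_fossil = 20)
  fx2 <- make_paper_like_fixture(seed = 99, dir = dir2, n_extant = 80, n_fossil = 20)
  for (f in c("tree.nwk", "ranges.data", "geo.yaml", "latitudes.tsv"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
})
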