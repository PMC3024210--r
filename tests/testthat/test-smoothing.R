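test_that("global smoothing matches exact-arithmetic evaluation on a 3-area map", {
  m <- area_map(c("a", "b", "c"), x = 1:3, y = rep(0, 3),
                population = rep(100, 3))
  cs <- case_vector(c(0, 3, 12), m)
  sm <- marshall_smooth(m, cs, mode = "global")
  # worked by hand in exact rationals:
  #   m = 15/300 = 1/20; t = (0, 3/100, 12/100)
  #   s2 = 100 * ((1/20)^2 + (1/50)^2 + (7/100)^2) / 300 = 13/5000
  #   nbar = 100; A = 13/5000 - (1/20)/100 = 21/10000
  #   w = A / (A + (1/20)/100) = 21/26
  #   theta = (25, 88, 277) / 2600
  expect_equal(sm$prior_mean, rep(1 / 20, 3))
  expect_equal(sm$prior_var, rep(21 / 10000, 3))
  expect_equal(sm$weights, rep(21 / 26, 3))
  expect_equal(sm$theta_hat, c(25, 88, 277) / 2600)
})

test_that("identical raw rates shrink completely to the common rate", {
  m <- area_map(letters[1:4], x = 1:4, y = rep(0, 4),
                population = c(100, 200, 300, 400))
  cs <- case_vector(c(2, 4, 6, 8), m)  # every t_i = 0.02
  sm <- marshall_smooth(m, cs, mode = "global")
  expect_equal(sm$theta_hat, rep(0.02, 4))
  expect_equal(sm$weights, rep(0, 4))  # zero prior variance forces w = 0
  # the same holds locally on a fully connected adjacency
  adj <- lapply(letters[1:4], function(a) setdiff(letters[1:4], a))
  names(adj) <- letters[1:4]
  m_adj <- area_map(letters[1:4], x = 1:4, y = rep(0, 4),
                    population = c(100, 200, 300, 400), adjacency = adj)
  sml <- marshall_smooth(m_adj, cs, mode = "local")
  expect_equal(sml$theta_hat, rep(0.02, 4))
})

test_that("shrinkage weight grows with population and theta stays a convex combination", {
  set.seed(8)
  pops <- c(10, 100, 1000, 10000, 100000)
  m <- area_map(paste0("p", pops), x = seq_along(pops), y = rep(0, 5),
                population = pops)
  cs <- case_vector(c(1, 3, 40, 300, 4000), m)
  sm <- marshall_smooth(m, cs, mode = "global")
  expect_true(all(diff(sm$weights) > 0))   # w_i = A/(A + m/n_i) rises with n_i
  expect_gt(sm$weights[5], 0.9)            # huge population: little shrinkage
  lo <- pmin(sm$raw_rates, sm$prior_mean)
  hi <- pmax(sm$raw_rates, sm$prior_mean)
  expect_true(all(sm$theta_hat >= lo - 1e-15 & sm$theta_hat <= hi + 1e-15))
  expect_true(all(sm$weights >= 0 & sm$weights <= 1))
})

test_that("local smoothing on a hex flower matches per-neighbourhood evaluation", {
  flower <- hex_grid(rows = 3, cols = 3, jitter_scale = 0.03, seed = 2)
  keep <- c("r2c2", hex_ring_ids(flower, "r2c2"))
  sub <- flower$areas[match(keep, flower$areas$id), ]
  adj0 <- lapply(flower$adjacency[keep], intersect, keep)
  m7 <- area_map(sub$id, sub$x, sub$y, sub$population, adjacency = adj0)
  y <- ifelse(m7$areas$id == "r2c2", 7L, 0L)
  cs <- case_vector(y, m7)
  sm <- marshall_smooth(m7, cs, mode = "local")
  want <- vapply(seq_len(7), function(i) {
    nbh <- sort(c(i, match(m7$adjacency[[m7$areas$id[i]]], m7$areas$id)))
    marshall_oracle_theta(y, m7$areas$population, nbh, i)
  }, numeric(1))
  expect_equal(sm$theta_hat, want)
  # the centre holds all cases, so its smoothed rate stays the largest
  expect_equal(which.max(sm$theta_hat), match("r2c2", m7$areas$id))
})

test_that("local estimates depend only on the first-order neighbourhood", {
  # two disconnected triangles; perturbing the far one leaves the near one fixed
  ids <- c(paste0("L", 1:3), paste0("R", 1:3))
  adj <- list(L1 = c("L2", "L3"), L2 = c("L1", "L3"), L3 = c("L1", "L2"),
              R1 = c("R2", "R3"), R2 = c("R1", "R3"), R3 = c("R1", "R2"))
  m <- area_map(ids, x = c(0, 1, 0.5, 10, 11, 10.5), y = c(0, 0, 1, 0, 0, 1),
                population = rep(100, 6), adjacency = adj)
  sm1 <- marshall_smooth(m, case_vector(c(1, 2, 3, 0, 0, 0), m), mode = "local")
  sm2 <- marshall_smooth(m, case_vector(c(1, 2, 3, 9, 9, 9), m), mode = "local")
  expect_equal(sm1$theta_hat[1:3], sm2$theta_hat[1:3])
  expect_false(isTRUE(all.equal(sm1$theta_hat[4:6], sm2$theta_hat[4:6])))
})

test_that("local equals global when every neighbourhood is the whole map", {
  ids <- letters[1:5]
  adj <- lapply(ids, function(a) setdiff(ids, a))
  names(adj) <- ids
  m <- area_map(ids, x = 1:5, y = rep(0, 5),
                population = c(120, 80, 200, 150, 90), adjacency = adj)
  cs <- case_vector(c(1, 0, 7, 2, 4), m)
  g <- marshall_smooth(m, cs, mode = "global")
  l <- marshall_smooth(m, cs, mode = "local")
  expect_equal(l$theta_hat, g$theta_hat)
  expect_equal(l$weights, g$weights)
})

test_that("an area with no neighbours falls back to its raw rate, with a warning", {
  adj <- list(a = "b", b = "a")
  m <- area_map(c("a", "b", "c"), x = 1:3, y = rep(0, 3),
                population = rep(100, 3), adjacency = adj)
  cs <- case_vector(c(1, 4, 9), m)
  expect_warning(sm <- marshall_smooth(m, cs, mode = "local"), "no neighbours")
  expect_equal(sm$theta_hat[3], 9 / 100)
  expect_equal(sm$weights[3], 0)
})

test_that("smoothing rejects zero populations and missing adjacency", {
  m0 <- area_map(c("a", "b"), 1:2, c(0, 0), population = c(0, 10))
  expect_error(marshall_smooth(m0, case_vector(c(0, 1), m0)), "zero population.*a")
  m <- area_map(c("a", "b"), 1:2, c(0, 0), population = c(10, 10))
  expect_error(marshall_smooth(m, case_vector(c(0, 1), m), mode = "local"),
               "adjacency")
})

test_that("replication probabilities normalise smoothed expected counts", {
  m <- area_map(letters[1:3], x = 1:3, y = rep(0, 3),
                population = c(100, 200, 300))
  cs <- case_vector(c(2, 3, 1), m)
  # uniform rates reduce to the null distribution n_i / N
  sm_u <- structure(list(theta_hat = rep(0.4, 3)), class = "smoothed_rates")
  expect_equal(smoothed_probabilities(sm_u, m), c(100, 200, 300) / 600)
  # raw rates reproduce the raw mean model c_i / C
  sm_t <- structure(list(theta_hat = cs$counts / m$areas$population),
                    class = "smoothed_rates")
  expect_equal(smoothed_probabilities(sm_t, m), cs$counts / cs$total)
  # positive rescaling is a no-op
  sm_t2 <- sm_t; sm_t2$theta_hat <- sm_t$theta_hat * 7.3
  expect_equal(smoothed_probabilities(sm_t2, m), smoothed_probabilities(sm_t, m))
  sm_0 <- structure(list(theta_hat = rep(0, 3)), class = "smoothed_rates")
  expect_error(smoothed_probabilities(sm_0, m), "zero")
  # end-to-end: 3-area global smooth gives p proportional to n * theta
  sm <- marshall_smooth(m, cs, mode = "global")
  ev <- m$areas$population * sm$theta_hat
  expect_equal(smoothed_probabilities(sm, m), ev / sum(ev))
})
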