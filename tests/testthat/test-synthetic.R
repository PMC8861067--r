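test_that("simulation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_species = 8, n_area_responders = 2,
                          n_dsouth_responders = 3)
  a <- simulate_ringing(cfg, seed = 99)
  b <- simulate_ringing(cfg, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- simulate_ringing(cfg, seed = 100)
  expect_false(identical(a$records$count, c$records$count))
})

test_that("generated matrix has sum(years) rows and n_species columns", {
  cfg <- synthetic_config(n_species = 12, n_area_responders = 4,
                          n_dsouth_responders = 6)
  sim <- simulate_ringing(cfg, seed = 1)
  cm <- pivot_records(sim$records)
  expect_equal(nrow(cm), sum(cfg$years_per_island))  # 74 island-years
  expect_equal(ncol(cm), 12)
  expect_equal(sort(unique(sample_meta(cm)$island)),
               sort(names(cfg$years_per_island)))
})

test_that("with no island responses or noise, species means match the analytic mean", {
  cfg <- synthetic_config(
    n_species = 6, n_area_responders = 0, n_dsouth_responders = 0,
    beta0_sd = 0, island_sd = 0, year_sd = 0, family = "poisson")
  sim <- simulate_ringing(cfg, seed = 4)
  eff <- (cfg$effort_net_m / 100) * cfg$effort_days
  mu <- sim$truth$C * cfg$scaling * eff
  cm <- pivot_records(sim$records)
  obs <- colMeans(cm)[sim$truth$species]
  se <- sqrt(mu / nrow(cm))
  expect_true(all(abs(obs - mu) <= 3 * se + 1e-9))
})

test_that("a unit area slope gives a tenfold count ratio between 1 and 10 km2", {
  desc <- data.frame(island = c("small", "big"), Area = c(1, 10),
                     MinDSouthLand = c(50, 50),
                     row.names = c("small", "big"))
  cfg <- synthetic_config(
    n_species = 1, islands = desc,
    years_per_island = c(small = 2L, big = 2L),
    n_area_responders = 1, beta_area = 1, n_dsouth_responders = 0,
    beta0_sd = 0, island_sd = 0, year_sd = 0, family = "poisson")
  mu <- expected_counts(cfg, data.frame(
    species = "sp01", C = 1e6, beta0 = 0, beta_area = 1, beta_dsouth = 0))
  expect_equal(unname(mu["big", 1] / mu["small", 1]), 10)
})

test_that("expected counts increase with distance to southern land when planted", {
  cfg <- synthetic_config(n_species = 2, n_area_responders = 0,
                          n_dsouth_responders = 1, beta_dsouth = 0.4,
                          beta0_sd = 0)
  truth <- data.frame(species = c("sp01", "sp02"), C = c(1e6, 1e6),
                      beta0 = 0, beta_area = 0, beta_dsouth = c(0.4, 0))
  mu <- expected_counts(cfg, truth)
  ord <- order(cfg$islands[rownames(mu), "MinDSouthLand"])
  expect_true(all(diff(mu[ord, "sp01"]) > 0))
  expect_true(all(abs(diff(mu[ord, "sp02"])) < 1e-9))
})

test_that("nbinom2 draws show the mu + mu^2/theta variance inflation", {
  set.seed(31)
  theta <- 2; mu <- 40
  x <- rnbinom(20000, size = theta, mu = mu)
  expect_equal(var(x), mu + mu^2 / theta, tolerance = 0.06)
  # and the generator passes theta through: simulated counts overdisperse
  cfg <- synthetic_config(n_species = 4, n_area_responders = 0,
                          n_dsouth_responders = 0, beta0_sd = 0,
                          island_sd = 0, year_sd = 0,
                          family = "nbinom2", theta = 2)
  sim <- simulate_ringing(cfg, seed = 8)
  cm <- pivot_records(sim$records)
  eff <- (cfg$effort_net_m / 100) * cfg$effort_days
  mu_sp <- sim$truth$C * cfg$scaling * eff
  vr <- apply(unclass(cm)[, sim$truth$species], 2, var)
  expected_vr <- mu_sp + mu_sp^2 / 2
  expect_true(all(vr / expected_vr > 0.5 & vr / expected_vr < 2))
})

test_that("trait linkage ties wing pointedness to planted responses", {
  cfg0 <- synthetic_config(n_species = 35, kipp_b = 0, kipp_c = 0)
  sim <- simulate_ringing(cfg0, seed = 2)
  tr0 <- simulate_traits(cfg0, sim$truth, seed = 3)
  expect_lt(abs(cor(tr0$kipp_mean, sim$truth$beta_area)), 0.35)

  cfgs <- synthetic_config(n_species = 35, kipp_b = 10, kipp_c = 0,
                           kipp_sd = 0)
  trs <- simulate_traits(cfgs, sim$truth, seed = 3)
  expect_equal(cor(trs$kipp_mean, sim$truth$beta_area,
                   method = "spearman") > 0.99, TRUE)

  trd <- simulate_traits(synthetic_config(), sim$truth, seed = 3)
  expect_gt(cor(trd$kipp_mean, trd$war), 0.8)
})

test_that("simulated trees are ultrametric with unit depth and stable under seed", {
  tr <- simulate_tree(35, seed = 6)
  expect_equal(ape::Ntip(tr), 35)
  depths <- ape::node.depth.edgelength(tr)[1:35]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(35, seed = 6)))

  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(tr2$tip.label), c("sp01", "sp02"))
  expect_equal(unname(ape::node.depth.edgelength(tr2)[1:2]), c(1, 1))
})

test_that("traits on trees follow the lambda-scaled Brownian covariance", {
  # sister tips sharing 99% of depth: correlation ~0.99 at lambda = 1
  tree <- read_newick(text = "((A:0.01,B:0.01):0.99,C:1);")
  xs <- sapply(1:300, function(s)
    simulate_trait_on_tree(tree, lambda = 1, sigma2 = 1, seed = s))
  expect_gt(cor(xs["A", ], xs["B", ]), 0.9)
  # lambda = 0: tips iid
  x0 <- sapply(1:300, function(s)
    simulate_trait_on_tree(tree, lambda = 0, sigma2 = 1, seed = s))
  expect_lt(abs(cor(x0["A", ], x0["B", ])), 0.2)
  # sigma2 = 0: constant at the root value
  expect_equal(unname(simulate_trait_on_tree(tree, 1, 0, seed = 1, root = 3)),
               rep(3, 3))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(theta = 0), "theta")
  expect_error(synthetic_config(years_per_island = c(Aire = 1L)), ">= 2 years")
  expect_error(synthetic_config(n_species = 5, n_area_responders = 4,
                                n_dsouth_responders = 4), "responders")
  desc <- data.frame(island = "x", Area = 0, MinDSouthLand = 5,
                     row.names = "x")
  cfg <- synthetic_config(islands = desc, n_species = 2,
                          years_per_island = c(x = 2L),
                          n_area_responders = 0, n_dsouth_responders = 0)
  expect_error(simulate_ringing(cfg, 1), "non-positive Area")
})
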