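test_that("orthogonal predictors all have VIF 1 and none is removed", {
  set.seed(2)
  # orthogonal to the intercept and to each other: correlations exactly 0
  X <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  vf <- vif_filter(X, 10)
  expect_equal(unname(vf$vif), rep(1, 3), tolerance = 1e-10)
  expect_equal(vf$removed, character(0))
})

test_that("a constructed near-collinear triple loses exactly one variable", {
  set.seed(6)
  x <- rnorm(30); y <- rnorm(30)
  z <- x + y + rnorm(30, 0, 0.01)
  vf <- vif_filter(data.frame(x = x, y = y, z = z), 10)
  expect_equal(length(vf$removed), 1)
  expect_true(all(vf$vif < 10))
  expect_error(vif_filter(data.frame(x = x, k = rep(1, 30))), "constant")
})

test_that("the island geographic set drops MinDistAfrica and Latitude", {
  isl <- island_descriptors()
  geo <- c("Latitude", "LongKm", "MinDistAfrica", "StrDistAfrica",
           "MinDistLand", "MinDSouthLand")
  suppressMessages(ld <- log_descriptors(isl, geo))
  vf <- vif_filter(ld, 10)
  expect_setequal(vf$removed, c("MinDistAfrica", "Latitude"))
  expect_lte(max(vf$vif), 2.1 * 1.15)
  # habitat block passes untouched
  suppressMessages(lh <- log_descriptors(isl, c("Area", "MaxAlt", "NDVI")))
  vfh <- vif_filter(lh, 10)
  expect_equal(vfh$removed, character(0))
  expect_lt(max(vfh$vif), 3)
})

test_that("rda recovers an exactly linear response with zero residual", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("p1", "p2")))
  B <- matrix(rnorm(8), 2, 4)
  Y <- X %*% B
  rd <- rda_fit(Y, X, n_perm = 99, seed = 1)
  expect_equal(length(rd$eig), 2)
  expect_equal(rd$R2, 1, tolerance = 1e-10)
  expect_equal(sum(rd$pct_total), 100, tolerance = 1e-9)
})

test_that("the Ezekiel adjustment matches its closed form", {
  expect_equal(adj_r2(0.5, 11, 2), 0.375)
  expect_lte(adj_r2(0.5, 11, 2), 0.5)
})

test_that("canonical eigenvalues match the naive least-squares oracle and vegan", {
  set.seed(15)
  rc <- random_community(n_islands = 4, years = 4:5, n_species = 7)
  X <- matrix(rnorm(nrow(rc$m) * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  rd <- rda_fit(rc$m, X, n_perm = 99, seed = 1)
  expect_equal(rd$eig, rda_oracle_eig(rc$m, X), tolerance = 1e-8)
  skip_if_not_installed("vegan")
  vg <- vegan::rda(unclass(rc$m) ~ ., data = as.data.frame(X))
  expect_equal(unname(rd$eig), unname(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(rd$R2, unname(vegan::RsquareAdj(vg)$r.squared),
               tolerance = 1e-8)
  expect_equal(rd$R2_adj, unname(vegan::RsquareAdj(vg)$adj.r.squared),
               tolerance = 1e-8)
})

test_that("orthonormal mixing of predictors leaves the fit unchanged", {
  set.seed(16)
  rc <- random_community(n_islands = 3, years = 4:5, n_species = 6)
  X <- matrix(rnorm(nrow(rc$m) * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  XQ <- X %*% Q
  colnames(XQ) <- colnames(X)
  rd1 <- rda_fit(rc$m, X, n_perm = 99, seed = 1)
  rd2 <- rda_fit(rc$m, XQ, n_perm = 99, seed = 1)
  expect_equal(rd1$eig, rd2$eig, tolerance = 1e-8)
  expect_equal(rd1$R2, rd2$R2, tolerance = 1e-8)
})

test_that("axis p-values are roughly uniform when predictors are pure noise", {
  set.seed(18)
  ps <- replicate(40, {
    Y <- matrix(rnorm(16 * 5), 16)
    X <- matrix(rnorm(16 * 2), 16, dimnames = list(NULL, c("a", "b")))
    rda_fit(Y, X, n_perm = 99, seed = sample.int(1e6, 1))$axis_p[1]
  })
  expect_gt(mean(ps < 0.05), 0)  # some rejections happen
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)       # but p is not concentrated near 0
})

test_that("rank-deficient predictors are reported with the aliased column", {
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  Y <- matrix(rnorm(30), 10)
  expect_error(rda_fit(Y, X, n_perm = 99), "aliased")
})

test_that("forward selection finds a strong informative predictor first", {
  set.seed(20)
  hits <- 0; nrep <- 20
  for (r in seq_len(nrep)) {
    n <- 25
    X <- data.frame(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
    Y <- outer(X$sig, rnorm(5)) + matrix(rnorm(n * 5, 0, 0.4), n)
    fs <- forward_select(Y, X, alpha = 0.05, n_perm = 99,
                         seed = sample.int(1e6, 1))
    if (length(fs$selected) && fs$selected[1] == "sig") hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("forward selection on pure noise stays modest and handles empty input", {
  set.seed(22)
  any_sel <- replicate(40, {
    n <- 20
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    Y <- matrix(rnorm(n * 4), n)
    length(forward_select(Y, X, alpha = 0.05, n_perm = 99,
                          seed = sample.int(1e6, 1))$selected) > 0
  })
  expect_lte(mean(any_sel), 0.35)  # greedy inflation, but not runaway
  expect_equal(forward_select(matrix(rnorm(20), 5), data.frame())$selected,
               character(0))
})

test_that("variance partitioning fractions obey their defining identity", {
  set.seed(24)
  for (r in 1:5) {
    rc <- random_community(n_islands = 4, years = 3:4, n_species = 6)
    n <- nrow(rc$m)
    Xg <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("g1", "g2")))
    Xh <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("h1", "h2")))
    vp <- varpart2(rc$m, Xg, Xh)
    expect_equal(vp$a + vp$b + vp$c, vp$R2_adj_all, tolerance = 1e-10)
    expect_equal(vp$residual, 1 - vp$R2_adj_all, tolerance = 1e-12)
  }
})

test_that("duplicated blocks put everything in the shared fraction", {
  set.seed(25)
  n <- 24
  Xg <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("g1", "g2")))
  Y <- Xg %*% matrix(rnorm(8), 2) + matrix(rnorm(n * 4, 0, 0.5), n)
  Xh <- Xg + matrix(rnorm(n * 2, 0, 1e-5), n)
  colnames(Xh) <- c("h1", "h2")
  vp <- varpart2(Y, Xg, Xh)
  expect_lt(abs(vp$a), 0.05)
  expect_lt(abs(vp$c), 0.05)
  expect_gt(vp$b, 0.3)
})

test_that("independent blocks explaining disjoint responses split cleanly", {
  set.seed(26)
  n <- 40
  Xg <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g"))
  Xh <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "h"))
  Y <- cbind(Xg %*% t(rep(1, 3)) + matrix(rnorm(n * 3, 0, 0.2), n),
             Xh %*% t(rep(1, 3)) + matrix(rnorm(n * 3, 0, 0.2), n))
  vp <- varpart2(Y, Xg, Xh)
  expect_lt(abs(vp$b), 0.08)
  expect_equal(vp$a, vp$R2_adj_all - vp$R2_adj_hab, tolerance = 1e-12)
  expect_gt(vp$a, 0.2); expect_gt(vp$c, 0.2)
})

test_that("species correlations isolate an axis-loading species and cap Bonferroni", {
  set.seed(27)
  n <- 30
  grad <- rnorm(n)
  X <- cbind(driver = grad, noise = rnorm(n))
  Y <- cbind(sp_on_axis = grad * 2 + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 3, 0, 1), n,
                    dimnames = list(NULL, paste0("bg", 1:3))))
  rd <- rda_fit(Y, X, n_perm = 99, seed = 1)
  sc <- species_axis_correlations(rd, Y, axes = 1)
  r1 <- sc$r[sc$species == "sp_on_axis"]
  expect_gt(abs(r1), 0.98)
  expect_true(all(sc$p_bonferroni <= 1))
  expect_true(all(sc$p_bonferroni >= sc$p, na.rm = TRUE))
})

test_that("island-mean regression avoids pseudo-replicated significance", {
  # predictor varies only between islands, axis scores only within:
  # per-sample tests see n = 40 replicates, the island-mean test n = 5
  set.seed(28)
  island <- rep(paste0("I", 1:5), each = 8)
  naive_rej <- 0; agg_rej <- 0; nrep <- 60
  for (r in seq_len(nrep)) {
    pred <- rep(rnorm(5), each = 8)
    score <- rnorm(40)  # pure within-island variation
    naive_p <- suppressWarnings(cor.test(pred, score))$p.value
    m_score <- tapply(score, island, mean)
    m_pred <- tapply(pred, island, mean)
    agg_p <- summary(lm(m_score ~ m_pred))$coefficients[2, 4]
    if (naive_p < 0.05) naive_rej <- naive_rej + 1
    if (agg_p < 0.05) agg_rej <- agg_rej + 1
  }
  expect_lte(agg_rej / nrep, 0.15)
  # the packaged association table uses the aggregated test
  Y <- matrix(rnorm(40 * 4), 40)
  rownames(Y) <- paste0(island, "_", 1:40)
  X <- data.frame(pred = rep(rnorm(5), each = 8))
  rd <- rda_fit(Y, cbind(X, noise = rnorm(40)), n_perm = 99, seed = 2)
  tab <- axis_variable_association(rd, X, island = island, axes = 1)
  expect_true(all(c("r", "p_island") %in% names(tab)))
  expect_false(anyNA(tab$p_island))
})
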