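make_cm <- function(counts, island, year) {
  rec <- make_records(data.frame(
    island = rep(island, ncol(counts)),
    year = rep(year, ncol(counts)),
    species = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts)))
  pivot_records(rec)
}

test_that("offsets follow their defining formulas", {
  cm <- make_cm(cbind(s1 = c(600, 400), s2 = c(400, 100)),
                island = c("A", "B"), year = c(2001L, 2001L))
  off <- build_offsets(cm, mode = "percentage")
  expect_equal(unname(off), log(c(1000, 500)))

  eff <- data.frame(island = rep(c("A", "B"), each = 30),
                    date = rep(as.Date("2001-04-16") + 0:29, 2),
                    net_length = 300)
  class(eff) <- c("effort_records", "data.frame")
  off_rate <- build_offsets(cm, eff, mode = "rate")
  expect_equal(unname(off_rate), rep(log(3 * 30), 2))

  off_excl <- build_offsets(cm, eff, mode = "rate", exclude = "B")
  expect_true(is.na(off_excl["B_2001"]))
  expect_false(is.na(off_excl["A_2001"]))
})

test_that("zero totals yield NA offsets with a warning", {
  cm <- make_cm(cbind(s1 = c(5, 3)), island = c("A", "B"),
                year = c(2001L, 2001L))
  m <- unclass(cm); m[2, 1] <- 0
  fake <- structure(m, meta = sample_meta(cm),
                    class = class(cm))
  expect_warning(off <- build_offsets(fake, mode = "percentage"),
                 "zero-total")
  expect_true(is.na(off[2]))
})

test_that("poisson GLM recovers a known slope with near-nominal coverage", {
  set.seed(33)
  isl <- island_descriptors()
  x <- log(isl$Area) - mean(log(isl$Area))
  reps <- rep(seq_len(9), times = c(16, 8, 5, 9, 7, 5, 7, 7, 10))  # 74 rows
  xv <- x[reps]
  hit <- 0; nrep <- 150
  for (r in seq_len(nrep)) {
    mu <- exp(1.5 + 0.5 * xv)
    d <- data.frame(y = rpois(74, mu), v = xv)
    fit <- fit_count_glm(y ~ v, d, family = "poisson")
    ci <- coef(fit)["v"] + c(-1.96, 1.96) * fit$se["v"]
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hit <- hit + 1
  }
  expect_gte(hit / nrep, 0.9)
})

test_that("nbinom2 estimates theta and collapses to Poisson as theta grows", {
  set.seed(34)
  n <- 200
  x <- rnorm(n)
  mu <- exp(2 + 0.4 * x)
  d <- data.frame(y = rnbinom(n, size = 2, mu = mu), v = x)
  fit <- fit_count_glm(y ~ v, d, family = "nbinom2")
  expect_gt(fit$theta, 1); expect_lt(fit$theta, 4)
  expect_equal(unname(coef(fit)["v"]), 0.4, tolerance = 0.15)

  # Poisson-generated data: nbinom2 coefficients match the Poisson fit
  d2 <- data.frame(y = rpois(n, mu), v = x)
  f_nb <- fit_count_glm(y ~ v, d2, family = "nbinom2")
  f_po <- fit_count_glm(y ~ v, d2, family = "poisson")
  expect_equal(coef(f_nb), coef(f_po), tolerance = 1e-3)
  expect_true(f_nb$theta > 100 || f_nb$poisson_like)
})

test_that("nbinom1 maximum likelihood matches moments on NB1 data", {
  set.seed(35)
  n <- 300
  x <- rnorm(n)
  mu <- exp(2.5 + 0.3 * x)
  alpha <- 1.5  # variance mu * (1 + alpha)
  d <- data.frame(y = rnbinom(n, size = mu / alpha, mu = mu), v = x)
  fit <- fit_count_glm(y ~ v, d, family = "nbinom1")
  expect_equal(unname(coef(fit)["v"]), 0.3, tolerance = 0.12)
  expect_gt(fit$alpha, 0.7); expect_lt(fit$alpha, 3)
})

test_that("an offset-only null recovers the log rate", {
  set.seed(36)
  off <- log(runif(80, 50, 150))
  d <- data.frame(y = rpois(80, exp(off) * 0.02))
  fit <- fit_count_glm(y ~ 1, d, offset = off, family = "poisson")
  expect_equal(unname(coef(fit)[1]), log(0.02), tolerance = 0.1)
})

test_that("poisson IRLS agrees with a direct Newton optimization", {
  set.seed(37)
  x <- rnorm(60); mu <- exp(1 + 0.6 * x)
  y <- rpois(60, mu)
  d <- data.frame(y = y, v = x)
  fit <- fit_count_glm(y ~ v, d, family = "poisson")
  nll <- function(b) -sum(dpois(y, exp(b[1] + b[2] * x), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
})

test_that("model selection classifies planted shapes and signs", {
  set.seed(38)
  isl <- island_descriptors()
  suppressMessages(ld <- log_descriptors(isl, c("Area", "MinDSouthLand")))
  reps <- rep(rownames(isl), times = 8)
  v <- scale(ld$Area)[match(reps, rownames(isl))]
  year <- rep(2001:2008, each = 9)
  # species 1: positive linear in area; species 2: inverted-U; species 3: noise
  mu1 <- exp(2 + 0.8 * v)
  mu2 <- exp(3 - 1.2 * v^2)
  counts <- cbind(lin = rpois(72, mu1), quad = rpois(72, mu2),
                  nil = rpois(72, exp(2)))
  cm <- make_cm(counts, island = reps, year = year)
  meta <- sample_meta(cm)
  pred <- ld[meta$island, "Area", drop = FALSE]
  sr <- suppressWarnings(
    select_models(cm, pred, families = "poisson"))
  lin_row <- sr[sr$species == "lin", ]
  expect_equal(lin_row$shape, "linear")
  expect_equal(lin_row$sign, "+")
  quad_row <- sr[sr$species == "quad", ]
  expect_equal(quad_row$shape, "quadratic")
  expect_equal(quad_row$sign, "intermediate")
  expect_equal(sr[sr$species == "nil", "shape"], "none")

  tab <- summarize_response(sr)
  expect_equal(tab$total, 2)
  expect_equal(tab$intermediate, 1)
  expect_equal(tab$lin_pos, 1)
})

test_that("a single-species input yields a 0/1 summary table", {
  set.seed(39)
  isl <- island_descriptors()
  reps <- rep(rownames(isl), times = 4)
  cm <- make_cm(cbind(only = rpois(36, 20)), island = reps,
                year = rep(2001:2004, each = 9))
  suppressMessages(pred <- log_descriptors(isl, "Area")[sample_meta(cm)$island, , drop = FALSE])
  sr <- suppressWarnings(select_models(cm, pred, families = "poisson"))
  tab <- summarize_response(sr)
  expect_equal(nrow(tab), 1)
  expect_lte(tab$total, 1)
})

test_that("count GLM rejects invalid inputs", {
  d <- data.frame(y = c(1.5, 2, 3), v = 1:3)
  expect_error(fit_count_glm(y ~ v, d, family = "poisson"),
               "non-negative integers")
  d2 <- data.frame(y = c(1L, 2L, 3L), v = 1:3, w = 2 * (1:3))
  expect_error(fit_count_glm(y ~ v + w, d2, family = "poisson"),
               "full rank")
})
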