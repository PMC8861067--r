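# Per-species count models of abundance against island descriptors, with
# ringing-effort offsets, family selection (Poisson / nbinom1 / nbinom2 by
# AICc on null fits), linear-vs-quadratic shape selection and a summary
# table of significant responses per descriptor.

#' Offsets for species response models
#'
#' Two modes mirror the two response definitions:
#' * `"percentage"`: the natural log of the total number of birds ringed
#'   (all selected species) in each island-year, so the model describes a
#'   species' share of total captures;
#' * `"rate"`: the natural log of (net length in hundreds of metres x
#'   number of ringing days), so the model describes captures per 100 m of
#'   net per day. Islands listed in `exclude` (e.g. a station whose net
#'   placement makes its capture rate non-comparable) get `NA` and are
#'   dropped from the design.
#'
#' @param cm a `community_matrix` (island-year x species counts).
#' @param effort an `effort_records` data frame (required for `"rate"`).
#' @param mode `"percentage"` or `"rate"`.
#' @param exclude islands to exclude in `"rate"` mode.
#' @return named numeric vector aligned with `rownames(cm)`; `NA` marks
#'   rows to drop.
#' @export
build_offsets <- function(cm, effort = NULL,
                          mode = c("percentage", "rate"),
                          exclude = character()) {
  mode <- match.arg(mode)
  meta <- sample_meta(cm)
  if (mode == "percentage") {
    tot <- rowSums(cm)
    off <- ifelse(tot > 0, log(tot), NA_real_)
    if (anyNA(off))
      warning("build_offsets: zero-total island-year(s) dropped")
  } else {
    if (is.null(effort)) stop("build_offsets: rate mode needs effort records")
    year <- as.integer(format(effort$date, "%Y"))
    key <- paste(effort$island, year, sep = "_")
    days <- tapply(as.character(effort$date), key,
                   function(d) length(unique(d)))
    netm <- tapply(effort$net_length, key, mean)
    e <- (netm / 100) * days
    off <- log(e)[rownames(cm)]
    if (anyNA(off))
      warning("build_offsets: island-year(s) without effort dropped")
    off[meta$island %in% exclude] <- NA_real_
  }
  setNames(as.vector(off), rownames(cm))
}

nbinom1_loglik <- function(beta, log_alpha, y, Xm, off) {
  mu <- exp(drop(Xm %*% beta) + off)
  alpha <- exp(log_alpha)
  suppressWarnings(sum(dnbinom(y, size = mu / alpha, mu = mu, log = TRUE)))
}

fit_nbinom1 <- function(y, Xm, off) {
  start_fit <- glm.fit(Xm, y, family = poisson(), offset = off)
  p <- ncol(Xm)
  par0 <- c(start_fit$coefficients, 0)  # log_alpha = 0
  nll <- function(par) {
    ll <- nbinom1_loglik(par[seq_len(p)], par[p + 1], y, Xm, off)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 500), hessian = TRUE)
  if (opt$convergence != 0)
    stop("fit_count_glm: nbinom1 did not converge")
  se <- rep(NA_real_, p)
  h <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(h, "try-error")) {
    dh <- diag(h)[seq_len(p)]
    se[dh > 0] <- sqrt(dh[dh > 0])
  }
  list(coefficients = setNames(opt$par[seq_len(p)], colnames(Xm)),
       se = setNames(se, colnames(Xm)),
       alpha = exp(opt$par[p + 1]), logLik = -opt$value)
}

#' Fit a count GLM with log link and offset
#'
#' Fixed-effect count regression for island-year capture counts: Poisson
#' via [glm()], nbinom2 (variance quadratic in the mean,
#' \eqn{\mu + \mu^2/\theta}) via [MASS::glm.nb()], and nbinom1 (variance
#' linear in the mean, \eqn{\mu(1+\alpha)}) by direct maximum likelihood.
#' AICc parameter counts: Poisson `k = p`; negative binomial `k = p + 1`.
#'
#' @param formula model formula for the counts (response on the left).
#' @param data data frame holding the variables.
#' @param offset numeric offset vector (log scale), same length as rows of
#'   `data`.
#' @param family `"poisson"`, `"nbinom1"` or `"nbinom2"`.
#' @return object of class `count_glm`: coefficients, standard errors,
#'   `theta` (nbinom2) or `alpha` (nbinom1), `logLik`, `AICc`, `family`,
#'   `poisson_like` flag (dispersion estimated at the Poisson boundary).
#' @export
fit_count_glm <- function(formula, data, offset = NULL,
                          family = c("poisson", "nbinom1", "nbinom2")) {
  family <- match.arg(family)
  if (is.null(offset)) offset <- rep(0, nrow(data))
  mf <- model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y)))
    stop("fit_count_glm: counts must be non-negative integers")
  Xm <- model.matrix(formula, data)
  if (qr(Xm)$rank < ncol(Xm)) stop("fit_count_glm: design not full rank")
  n <- length(y); p <- ncol(Xm)
  theta <- NA_real_; alpha <- NA_real_; poisson_like <- FALSE

  dat2 <- data; dat2$.off <- offset
  f2 <- update(formula, . ~ . + offset(.off))
  environment(f2) <- environment()
  if (family == "poisson") {
    fit <- glm(f2, data = dat2, family = poisson())
    cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(logLik(fit)); k <- p
  } else if (family == "nbinom2") {
    fit <- suppressWarnings(MASS::glm.nb(f2, data = dat2, maxit = 100))
    if (!fit$converged) stop("fit_count_glm: nbinom2 did not converge")
    cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
    theta <- fit$theta
    poisson_like <- theta > 1e4
    ll <- as.numeric(logLik(fit)); k <- p + 1
  } else {
    nb1 <- fit_nbinom1(y, Xm, offset)
    fit <- NULL
    cf <- nb1$coefficients; se <- nb1$se
    alpha <- nb1$alpha
    poisson_like <- alpha < 1e-4
    ll <- nb1$logLik; k <- p + 1
  }
  structure(list(
    family = family, coefficients = cf, se = se,
    theta = theta, alpha = alpha, logLik = ll,
    AICc = aicc(-2 * ll + 2 * k, k, n), k = k, n = n,
    poisson_like = poisson_like, fit = fit, formula = formula),
    class = "count_glm")
}

#' @export
print.count_glm <- function(x, digits = 4, ...) {
  cat("Count GLM (", x$family, "), n = ", x$n, "\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, digits))
  if (x$family == "nbinom2") cat("theta =", format(x$theta, digits = digits), "\n")
  if (x$family == "nbinom1") cat("alpha =", format(x$alpha, digits = digits), "\n")
  cat("logLik =", format(x$logLik, digits = digits),
      " AICc =", format(x$AICc, digits = digits), "\n")
  invisible(x)
}

#' Per-species model selection against island descriptors
#'
#' For every species: (1) fit the null model (intercept + year factor +
#' offset) under each candidate family and keep the family with the lowest
#' AICc; (2) for each descriptor fit linear and quadratic models
#' (descriptors are z-scored log values, so the quadratic term is well
#' conditioned); (3) a model is retained only if its AICc beats the null's;
#' the quadratic is kept over the linear only if the likelihood-ratio test
#' rejects at 0.05; (4) the effect is classified `+`/`-` from the linear
#' coefficient, or `"intermediate"` when a retained quadratic has an
#' interior extremum within the observed descriptor range.
#'
#' Island identity is not a fixed factor here: descriptors are constant
#' within islands, so an island factor would absorb them completely. Year
#' enters as a fixed factor.
#'
#' @param cm `community_matrix` of counts (island-year x species).
#' @param predictors data frame of descriptor values per sample (aligned
#'   with `rownames(cm)`); they are z-scored internally.
#' @param offset offset vector from [build_offsets()] (`NA` rows dropped).
#' @param families candidate families.
#' @param year optional year per sample (defaults to metadata).
#' @return object of class `species_response`: data frame with one row per
#'   species x predictor (`species`, `predictor`, `family`, `shape`,
#'   `sign`, `dAICc_null`, `plausible`).
#' @export
select_models <- function(cm, predictors, offset = NULL,
                          families = c("poisson", "nbinom1", "nbinom2"),
                          year = NULL) {
  meta <- sample_meta(cm)
  if (is.null(year)) year <- meta$year
  if (is.null(offset)) offset <- rep(0, nrow(cm))
  keep <- !is.na(offset)
  x <- unclass(cm)[keep, , drop = FALSE]
  off <- offset[keep]
  yr <- factor(year[keep])
  P <- as.data.frame(scale(as.data.frame(predictors)[keep, , drop = FALSE]))
  has_year <- nlevels(yr) > 1
  base_rhs <- if (has_year) "year" else "1"
  rows <- list()
  for (j in seq_len(ncol(x))) {
    sp <- colnames(x)[j]
    d <- data.frame(y = x[, j], year = yr)
    # family choice on the null model
    nulls <- lapply(families, function(fam) {
      tryCatch(fit_count_glm(stats::as.formula(paste("y ~", base_rhs)),
                             d, offset = off, family = fam),
               error = function(e) NULL)
    })
    ok <- !vapply(nulls, is.null, logical(1))
    if (!any(ok)) next
    fam <- families[ok][which.min(vapply(nulls[ok], `[[`, 0, "AICc"))]
    null_fit <- nulls[ok][[which.min(vapply(nulls[ok], `[[`, 0, "AICc"))]]
    for (v in names(P)) {
      d$v <- P[[v]]
      lin <- tryCatch(fit_count_glm(
        stats::as.formula(paste("y ~", base_rhs, "+ v")),
        d, offset = off, family = fam), error = function(e) NULL)
      quad <- tryCatch(fit_count_glm(
        stats::as.formula(paste("y ~", base_rhs, "+ v + I(v^2)")),
        d, offset = off, family = fam), error = function(e) NULL)
      shape <- "none"; sgn <- NA_character_; best_aicc <- null_fit$AICc
      if (!is.null(quad) && !is.null(lin) && quad$AICc < null_fit$AICc) {
        lrt <- 2 * (quad$logLik - lin$logLik)
        p_lrt <- pchisq(lrt, df = 1, lower.tail = FALSE)
        if (p_lrt < 0.05) shape <- "quadratic"
      }
      if (shape == "none" && !is.null(lin) && lin$AICc < null_fit$AICc)
        shape <- "linear"
      if (shape == "linear") {
        sgn <- if (coef(lin)["v"] > 0) "+" else "-"
        best_aicc <- lin$AICc
      } else if (shape == "quadratic") {
        b1 <- coef(quad)["v"]; b2 <- coef(quad)["I(v^2)"]
        vertex <- -b1 / (2 * b2)
        rng <- range(d$v)
        if (b2 != 0 && vertex > rng[1] && vertex < rng[2]) {
          sgn <- "intermediate"
        } else {
          # monotone over the observed range: sign of derivative at midpoint
          sgn <- if (b1 + 2 * b2 * mean(rng) > 0) "+" else "-"
        }
        best_aicc <- quad$AICc
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, predictor = v, family = fam, shape = shape,
        sign = sgn, dAICc_null = null_fit$AICc - best_aicc,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # plausible set: within 2 AICc of the species' best retained model
  tab$plausible <- FALSE
  for (sp in unique(tab$species)) {
    sel <- tab$species == sp & tab$shape != "none"
    if (any(sel)) {
      best <- max(tab$dAICc_null[sel])
      tab$plausible[sel] <- tab$dAICc_null[sel] >= best - 2
    }
  }
  structure(tab, class = c("species_response", "data.frame"))
}

#' Summary of significant species responses per descriptor
#'
#' Counts, per descriptor, the species whose retained model was linear or
#' quadratic, with the breakdown of positive / negative / intermediate
#' (interior-maximum) effects. When descriptors are correlated across
#' islands, a species' true response to one descriptor can leak into
#' another tested alone; restricting to each species' *plausible* model
#' set (within 2 AICc of its best retained model) attributes effects to
#' the descriptor that actually carries them, so the summary reports both
#' all retained models (`total`) and the plausible subset
#' (`total_plausible`, `plaus_pos`, `plaus_neg`).
#'
#' @param sr a `species_response` table from [select_models()].
#' @param plausible_only if `TRUE`, all counts are computed on the
#'   plausible subset only.
#' @return data frame with one row per predictor.
#' @export
summarize_response <- function(sr, plausible_only = FALSE) {
  preds <- unique(sr$predictor)
  out <- lapply(preds, function(v) {
    s <- sr[sr$predictor == v & sr$shape != "none", , drop = FALSE]
    pl <- s[s$plausible, , drop = FALSE]
    if (plausible_only) s <- pl
    lin <- s[s$shape == "linear", , drop = FALSE]
    quad <- s[s$shape == "quadratic", , drop = FALSE]
    data.frame(
      predictor = v,
      linear = nrow(lin),
      lin_pos = sum(lin$sign == "+"), lin_neg = sum(lin$sign == "-"),
      quadratic = nrow(quad),
      quad_pos = sum(quad$sign == "+"), quad_neg = sum(quad$sign == "-"),
      intermediate = sum(s$sign == "intermediate"),
      total = nrow(s),
      total_plausible = nrow(pl),
      plaus_pos = sum(pl$sign == "+"), plaus_neg = sum(pl$sign == "-"))
  })
  do.call(rbind, out)
}
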