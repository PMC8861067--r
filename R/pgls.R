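# Phylogenetic generalized least squares with Pagel's lambda, used to
# compare wing-shape indices between species groups defined by their
# responses to island characteristics.

#' Kipp wing-pointedness index
#'
#' `100 * primary_projection / wing_length` (both in mm): the primary
#' projection as a percentage of wing length. More pointed wings give
#' larger values.
#'
#' @param primary_projection distance from the tip of the first secondary
#'   to the tip of the longest primary (mm, > 0).
#' @param wing_length maximum wing chord (mm, > projection).
#' @return numeric value(s) in (0, 100).
#' @examples
#' kipp_index(15, 60)  # 25
#' @export
kipp_index <- function(primary_projection, wing_length) {
  if (any(primary_projection <= 0) || any(wing_length <= 0))
    stop("kipp_index: measurements must be positive")
  if (any(primary_projection >= wing_length))
    stop("kipp_index: primary projection must be smaller than wing length")
  100 * primary_projection / wing_length
}

#' Phylogenetic covariance matrix
#'
#' Brownian-motion expectation: `V[a, b]` is the depth (root-to-node path
#' length) of the most recent common ancestor of tips `a` and `b`;
#' diagonal entries are root-to-tip depths.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return symmetric matrix with tip labels as dimnames.
#' @export
phylo_cov <- function(tree) {
  if (is.null(tree$edge.length)) stop("phylo_cov: tree has no branch lengths")
  V <- ape::vcv.phylo(tree)
  if (any(diag(V) <= 0)) stop("phylo_cov: non-positive root-to-tip depth")
  V
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 0` removes all phylogenetic covariance, `1` is
#' plain Brownian motion, and (moderately) negative values are admissible
#' as long as the result stays positive definite.
#'
#' @param V phylogenetic covariance matrix.
#' @param lambda scalar multiplier of the off-diagonals.
#' @export
lambda_transform <- function(V, lambda) {
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Smallest lambda keeping V(lambda) well conditioned
#'
#' Returns the smallest (possibly negative) `lambda` for which the
#' transformed covariance stays comfortably positive definite: its
#' smallest eigenvalue must be at least `margin` times the mean tip
#' depth. The margin matters because the profiled ML likelihood develops
#' spurious spikes as `V(lambda)` approaches singularity (the model then
#' asserts a near-exact linear constraint on the tip values, and any
#' chance near-orthogonality of the data to the collapsing direction
#' inflates the likelihood without bound).
#'
#' @param V phylogenetic covariance matrix.
#' @param lower search floor (default -3).
#' @param margin required smallest eigenvalue, as a fraction of the mean
#'   tip depth (default 0.01).
#' @return numeric lower bound for the lambda search.
#' @export
lambda_min <- function(V, lower = -3, margin = 0.01) {
  target <- margin * mean(diag(V))
  ok <- function(lam) {
    ev <- min(eigen(lambda_transform(V, lam), symmetric = TRUE,
                    only.values = TRUE)$values)
    ev >= target
  }
  if (ok(lower)) return(lower)
  lo <- lower; hi <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Profile log-likelihood pieces at a fixed lambda: whitened GLS via
# Cholesky, ML sigma^2, and the Gaussian log-likelihood.
pgls_at_lambda <- function(y, Xm, V, lambda) {
  W <- lambda_transform(V, lambda)
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  L <- t(R)
  wy <- forwardsolve(L, y)
  wX <- forwardsolve(L, Xm)
  colnames(wX) <- colnames(Xm)
  fit <- lm.fit(wX, wy)
  n <- length(y); p <- ncol(Xm)
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2_ml) - sum(log(diag(L))) - n / 2
  XtX_inv <- chol2inv(qr.R(qr(wX)))
  list(coefficients = fit$coefficients, rss = rss, sigma2_ml = sigma2_ml,
       logLik = ll, XtX_inv = XtX_inv, n = n, p = p)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS fit of a species-level trait model with residual covariance
#' `sigma^2 * V(lambda)`. `lambda` is either profiled by maximum
#' likelihood (grid search plus local refinement) or fixed (e.g. 0 for no
#' phylogenetic signal). The default search interval is the standard
#' Pagel interval `[0, 1]`; `lambda_range` may extend it below zero, in
#' which case the lower end is clamped at [lambda_min()] to keep
#' `V(lambda)` well conditioned (near the positive-definiteness boundary
#' the profiled likelihood develops spurious spikes; see [lambda_min()]).
#' The fit at `lambda = 0` is always computed so a likelihood ratio test
#' of phylogenetic signal (chi-squared, 1 df) is reported. Coefficient
#' t-tests use the unbiased variance estimate with `n - p` residual
#' degrees of freedom.
#'
#' @param formula trait model formula.
#' @param data data frame of species-level variables; rownames (or a
#'   `species` column) must match the tips of `V`.
#' @param V phylogenetic covariance matrix (see [phylo_cov()]).
#' @param lambda `"ML"` (default) or a fixed numeric value.
#' @param lambda_range search interval for the ML profile.
#' @return object of class `pgls_fit`: `coefficients` table (estimate,
#'   se, t, df, p), `lambda`, `logLik`, `logLik0` (at lambda = 0),
#'   `LRT`, `LRT_p`, `sigma2`.
#' @export
fit_pgls <- function(formula, data, V, lambda = "ML",
                     lambda_range = c(0, 1)) {
  ids <- if ("species" %in% names(data)) data$species else rownames(data)
  if (!all(ids %in% rownames(V)))
    stop("fit_pgls: data species not all present in V")
  V <- V[ids, ids]
  mf <- model.frame(formula, data)
  y <- stats::model.response(mf)
  Xm <- model.matrix(formula, data)
  n <- length(y); p <- ncol(Xm)
  if (qr(Xm)$rank < p) stop("fit_pgls: design not full rank")
  if (n <= p + 1) stop("fit_pgls: too few species for the model")

  at0 <- pgls_at_lambda(y, Xm, V, 0)
  estimated <- identical(lambda, "ML")
  if (estimated) {
    lmin <- max(lambda_range[1], lambda_min(V))
    lmax <- min(lambda_range[2], 1)
    grid <- seq(lmin, lmax, length.out = 41)
    lls <- vapply(grid, function(l) {
      r <- pgls_at_lambda(y, Xm, V, l)
      if (is.null(r)) -Inf else r$logLik
    }, numeric(1))
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(function(l) {
      r <- pgls_at_lambda(y, Xm, V, l)
      if (is.null(r)) -Inf else r$logLik
    }, interval = c(lo, hi), maximum = TRUE)
    lam_hat <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  } else {
    lam_hat <- as.numeric(lambda)
  }
  best <- pgls_at_lambda(y, Xm, V, lam_hat)
  if (is.null(best)) stop("fit_pgls: V(lambda) not positive definite")

  sigma2_hat <- best$rss / (n - p)
  se <- sqrt(diag(best$XtX_inv) * sigma2_hat)
  tval <- best$coefficients / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  coefs <- data.frame(estimate = best$coefficients, se = se, t = tval,
                      df = n - p, p = pval)
  lrt <- if (estimated) 2 * (best$logLik - at0$logLik) else NA_real_
  structure(list(
    coefficients = coefs, lambda = lam_hat, lambda_estimated = estimated,
    logLik = best$logLik, logLik0 = at0$logLik,
    LRT = lrt,
    LRT_p = if (estimated) pchisq(max(lrt, 0), 1, lower.tail = FALSE)
            else NA_real_,
    sigma2 = sigma2_hat, n = n, p = p, formula = formula),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("PGLS fit (lambda =", format(x$lambda, digits = digits),
      if (x$lambda_estimated) "[ML]" else "[fixed]", ")\n")
  print(round(x$coefficients, digits))
  cat("logLik =", format(x$logLik, digits = digits),
      " logLik(lambda=0) =", format(x$logLik0, digits = digits), "\n")
  if (x$lambda_estimated)
    cat("LRT vs lambda=0:", format(x$LRT, digits = digits),
        " p =", format(x$LRT_p, digits = digits), "\n")
  invisible(x)
}

#' Wing-shape comparisons between species response groups
#'
#' For each trait (columns of `traits` other than `species`) and the pair
#' of group indicators, fits a bivariate PGLS with interaction, drops the
#' interaction if non-significant (t-test p >= 0.05), and selects between
#' the ML-lambda and lambda = 0 fits by likelihood ratio test (the simpler
#' lambda = 0 model is kept when the LRT is not significant).
#'
#' @param traits data frame with a `species` column and numeric trait
#'   columns (e.g. `kipp_mean`, `war`).
#' @param groups data frame with a `species` column and two
#'   logical/0-1 indicator columns (e.g. related to island area /
#'   related to southern-land distance).
#' @param tree an [ape::phylo] covering the species.
#' @return data frame with one row per trait x indicator: the indicator's
#'   `estimate`, `t`, `df`, `p`, the selected `lambda` and `LRT_p`.
#' @export
group_tests <- function(traits, groups, tree) {
  gcols <- setdiff(names(groups), "species")
  if (length(gcols) != 2) stop("group_tests: exactly two group indicators required")
  tcols <- setdiff(names(traits), "species")
  d <- merge(traits, groups, by = "species")
  d <- d[d$species %in% tree$tip.label, , drop = FALSE]
  for (g in gcols) {
    d[[g]] <- as.numeric(d[[g]])
    if (min(table(d[[g]][!is.na(d[[g]])])) < 2)
      stop("group_tests: group too small for '", g, "'")
  }
  V <- phylo_cov(tree)
  out <- list()
  for (tr in tcols) {
    dd <- d[!is.na(d[[tr]]), c("species", tr, gcols)]
    f_int <- stats::as.formula(paste(tr, "~", gcols[1], "*", gcols[2]))
    f_add <- stats::as.formula(paste(tr, "~", gcols[1], "+", gcols[2]))
    # interaction only if estimable (disjoint groups make it constant-zero)
    Xi <- model.matrix(f_int, dd)
    if (qr(Xi)$rank == ncol(Xi)) {
      fit <- fit_pgls(f_int, dd, V)
      int_row <- grep(":", rownames(fit$coefficients))
      if (length(int_row) && fit$coefficients$p[int_row] >= 0.05)
        fit <- fit_pgls(f_add, dd, V)
    } else {
      fit <- fit_pgls(f_add, dd, V)
    }
    if (fit$LRT_p >= 0.05) {
      # no phylogenetic signal: keep the lambda = 0 (ordinary GLS) fit
      fit <- fit_pgls(stats::formula(fit$formula), dd, V, lambda = 0)
    }
    for (g in gcols) {
      i <- match(g, rownames(fit$coefficients))
      if (is.na(i)) next
      out[[length(out) + 1]] <- data.frame(
        trait = tr, group = g,
        estimate = fit$coefficients$estimate[i],
        t = fit$coefficients$t[i],
        df = fit$coefficients$df[i],
        p = fit$coefficients$p[i],
        lambda = fit$lambda,
        lambda_estimated = fit$lambda_estimated,
        n = fit$n)
    }
  }
  do.call(rbind, out)
}
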