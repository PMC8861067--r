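# Redundancy analysis of chord-transformed composition on island
# descriptors, with collinearity screening, forward selection, variance
# partitioning and variable/species-axis association tables.

#' Log-transform island descriptor columns
#'
#' Natural log of the selected descriptor columns; values below `floor`
#' (e.g. a zero distance for the westernmost island's longitudinal
#' coordinate) are floored at `floor` km before taking logs.
#'
#' @param desc island descriptor data frame.
#' @param vars columns to transform; default all numeric columns present
#'   among the standard geographic and habitat descriptors.
#' @param floor lower floor applied before the log (default 0.1).
#' @return data frame of log-transformed descriptors (same rownames).
#' @export
log_descriptors <- function(desc, vars = NULL, floor = 0.1) {
  std <- c("Latitude", "LongKm", "MinDistAfrica", "StrDistAfrica",
           "MinDistLand", "MinDSouthLand", "Area", "MaxAlt", "NDVI")
  if (is.null(vars)) vars <- intersect(std, names(desc))
  out <- desc[, vars, drop = FALSE]
  for (v in vars) {
    x <- pmax(out[[v]], floor)
    if (any(out[[v]] < floor))
      message("log_descriptors: floored ", v, " at ", floor, " before log")
    out[[v]] <- log(x)
  }
  out
}

vif_values <- function(X) {
  X <- as.matrix(X)
  sapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  })
}

#' Iterative collinearity filtering by variance inflation factor
#'
#' Computes the VIF of every predictor (1/(1-R^2) of that predictor
#' regressed on the others) and repeatedly removes the predictor with the
#' highest VIF until all remaining VIFs are below `threshold`.
#'
#' @param X data frame or matrix of predictors (>= 2 columns, none
#'   constant).
#' @param threshold VIF threshold (default 10).
#' @return list with `retained` (column names), `removed` (in removal
#'   order), `trace` (data frame of removal steps with the VIF that
#'   triggered each) and `vif` (final VIFs of retained predictors).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("vif_filter: needs >=2 predictors")
  cst <- vapply(X, function(x) sd(x) == 0, logical(1))
  if (any(cst))
    stop("vif_filter: constant column(s): ", paste(names(X)[cst], collapse = ", "))
  removed <- character(); trace <- list()
  while (ncol(X) >= 2) {
    v <- vif_values(X)
    if (max(v) < threshold) break
    worst <- which.max(v)
    trace[[length(trace) + 1]] <- data.frame(
      removed = names(X)[worst], vif = v[worst])
    removed <- c(removed, names(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  fin <- if (ncol(X) >= 2) setNames(vif_values(X), names(X))
         else setNames(rep(1, ncol(X)), names(X))
  list(retained = names(X), removed = removed,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(removed = character(), vif = numeric()),
       vif = fin)
}

# Core RDA computation on centered response / standardized predictors.
# Returns eigenvalues, scores, R2 and the pieces needed by the tests.
rda_core <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = TRUE)
  N <- nrow(Y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rda: rank-deficient predictors; aliased: ",
         paste(aliased, collapse = ", "))
  }
  Yhat <- qr.fitted(qrX, Y)
  sv <- svd(Yhat)
  keep <- sv$d^2 / max(sv$d^2, 1) > 1e-12
  keep[sv$d == 0] <- FALSE
  d <- sv$d[keep]
  eig <- d^2 / (N - 1)
  ss_tot <- sum(Y^2)
  ss_fit <- sum(d^2)
  list(Y = Y, X = X, qrX = qrX, Yhat = Yhat,
       u = sv$u[, keep, drop = FALSE], d = d,
       v = sv$v[, keep, drop = FALSE],
       eig = eig, ss_tot = ss_tot, ss_fit = ss_fit,
       R2 = ss_fit / ss_tot, N = N, m = ncol(X))
}

#' Ezekiel-adjusted R-squared
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(N - 1)/(N - m - 1)}.
#'
#' @param R2 unadjusted R-squared.
#' @param N number of samples.
#' @param m number of predictors.
#' @export
adj_r2 <- function(R2, N, m) 1 - (1 - R2) * (N - 1) / (N - m - 1)

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of the chord-transformed community matrix on
#' island descriptors: the response columns are centered and regressed on
#' the centered/standardized predictors, and the canonical axes are the
#' principal components of the fitted values. Axis significance is
#' assessed sequentially: for axis k the response and predictors are
#' residualized on the previous canonical site scores and the rows of the
#' residualized response are permuted.
#'
#' Axis signs are fixed by orienting every axis so that the species with
#' the largest absolute score on it loads positively.
#'
#' @param tm chord-transformed community matrix (samples x species).
#' @param X data frame/matrix of predictors (samples x variables), already
#'   log-transformed where appropriate (see [log_descriptors()]).
#' @param n_perm permutations for the per-axis tests (>= 99).
#' @param seed integer seed.
#' @param max_axes maximum number of axes to test (default 5).
#' @return object of class `rda_fit` with eigenvalues, `%` of total and of
#'   constrained variance per axis, site scores, species scores, predictor
#'   biplot scores, per-axis permutation p-values, `R2` and `R2_adj`.
#' @export
rda_fit <- function(tm, X, n_perm = 999, seed = 1, max_axes = 5) {
  if (n_perm < 99) stop("rda_fit: n_perm must be >= 99")
  core <- rda_core(unclass(tm), X)
  set.seed(seed)
  naxes <- length(core$eig)
  site <- core$u %*% diag(core$d, naxes)      # lc site scores
  species <- core$v
  # sign convention: dominant species loads positively on each axis
  for (a in seq_len(naxes)) {
    s <- sign(species[which.max(abs(species[, a])), a])
    if (s < 0) { species[, a] <- -species[, a]; site[, a] <- -site[, a] }
  }
  dimnames(site) <- list(rownames(tm), paste0("RDA", seq_len(naxes)))
  dimnames(species) <- list(colnames(tm), colnames(site))
  biplot <- cor(core$X, site)

  ntest <- min(naxes, max_axes)
  axis_p <- rep(NA_real_, naxes)
  for (a in seq_len(ntest)) {
    if (a == 1) {
      Yr <- core$Y; Xr <- core$X
    } else {
      Z <- site[, seq_len(a - 1), drop = FALSE]
      qz <- qr(Z)
      Yr <- qr.resid(qz, core$Y)
      Xr <- qr.resid(qz, core$X)
    }
    lam_obs <- core$eig[a]
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yr[sample.int(core$N), , drop = FALSE]
      sv <- svd(qr.fitted(qr(Xr), Yp), nu = 0, nv = 0)
      if (sv$d[1]^2 / (core$N - 1) >= lam_obs) exceed <- exceed + 1L
    }
    axis_p[a] <- (1 + exceed) / (n_perm + 1)
  }

  structure(list(
    eig = core$eig,
    pct_total = 100 * core$eig * (core$N - 1) / core$ss_tot,
    pct_constrained = 100 * core$eig / sum(core$eig),
    site_scores = site, species_scores = species,
    biplot_scores = biplot, axis_p = axis_p,
    R2 = core$R2, R2_adj = adj_r2(core$R2, core$N, core$m),
    N = core$N, m = core$m, n_perm = n_perm, seed = seed,
    meta = attr(tm, "meta")),
    class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, digits = 3, ...) {
  cat("Redundancy analysis:", x$m, "predictors,", x$N, "samples\n")
  cat(sprintf("  R2 = %.4f, R2_adj = %.4f\n", x$R2, x$R2_adj))
  tab <- data.frame(eigenvalue = x$eig, pct_total = x$pct_total,
                    pct_constrained = x$pct_constrained, p = x$axis_p)
  rownames(tab) <- colnames(x$site_scores)
  print(round(tab, digits), ...)
  invisible(x)
}

#' Forward selection of predictors for RDA
#'
#' Greedy forward selection: at each step the candidate adding the largest
#' conditional pseudo-F is tested by permuting the residuals of the
#' reduced model; it enters if its permutation p-value is below `alpha`
#' and (optionally) the adjusted R-squared of the selected set does not
#' exceed that of the full predictor set (a guard against overselection).
#'
#' @inheritParams rda_fit
#' @param alpha entry threshold on the permutation p-value.
#' @param adjr2_stop also stop when the selected set's R2_adj exceeds the
#'   full set's. Off by default: with few informative and several noise
#'   predictors the full-set R2_adj is diluted below that of a good
#'   subset, so the guard can veto clearly significant variables; the
#'   permutation p-value is the primary stopping rule.
#' @return list with `selected` (names in entry order) and a step `trace`.
#' @export
forward_select <- function(tm, X, alpha = 0.05, n_perm = 199, seed = 1,
                           adjr2_stop = FALSE) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) return(list(selected = character(),
                                trace = data.frame()))
  set.seed(seed)
  Y <- scale(unclass(tm), center = TRUE, scale = FALSE)
  N <- nrow(Y)
  full_adj <- if (adjr2_stop && ncol(X) < N - 1)
    adj_r2(rda_core(Y, X)$R2, N, ncol(X)) else Inf
  selected <- character(); trace <- list()
  repeat {
    cand <- setdiff(names(X), selected)
    if (!length(cand)) break
    ss_tot <- sum(Y^2)
    if (length(selected)) {
      q_sel <- qr(scale(as.matrix(X[, selected, drop = FALSE])))
      Yres <- qr.resid(q_sel, Y)
    } else {
      Yres <- Y
    }
    best <- NULL
    for (v in cand) {
      Xv <- scale(as.matrix(X[, c(selected, v), drop = FALSE]))
      qv <- qr(Xv)
      ss_fit_v <- sum(qr.fitted(qv, Y)^2)
      ss_res_v <- ss_tot - ss_fit_v
      ss_prev <- ss_tot - sum(Yres^2)
      f <- (ss_fit_v - ss_prev) / (ss_res_v / (N - ncol(Xv) - 1))
      if (is.null(best) || f > best$f) best <- list(v = v, f = f, q = qv)
    }
    # permutation test of the best candidate, permuting reduced-model residuals
    Xb <- scale(as.matrix(X[, c(selected, best$v), drop = FALSE]))
    qb <- qr(Xb)
    df_res <- N - ncol(Xb) - 1
    ss_prev <- sum(Y^2) - sum(Yres^2)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yres[sample.int(N), , drop = FALSE]
      if (length(selected)) Yp <- Yp + (Y - Yres)  # reattach fitted part
      ss_fit_p <- sum(qr.fitted(qb, Yp)^2)
      fp <- (ss_fit_p - ss_prev) / ((sum(Yp^2) - ss_fit_p) / df_res)
      if (fp >= best$f) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    adj_now <- adj_r2(1 - (sum(Y^2) - sum(qr.fitted(qb, Y)^2)) / sum(Y^2),
                      N, ncol(Xb))
    trace[[length(trace) + 1]] <- data.frame(
      variable = best$v, F = best$f, p = p, R2_adj = adj_now)
    if (p >= alpha) break
    if (adjr2_stop && adj_now > full_adj) break
    selected <- c(selected, best$v)
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else data.frame())
}

#' Two-set variance partitioning
#'
#' Partitions the Ezekiel-adjusted explained variance of the composition
#' matrix between two predictor sets (geography and habitat) into the
#' unique fraction of each (`a`, `c`), the shared fraction (`b`, not
#' testable) and the residual: `a = R2adj(all) - R2adj(hab)`,
#' `c = R2adj(all) - R2adj(geo)`, `b = R2adj(geo) + R2adj(hab) -
#' R2adj(all)`, `residual = 1 - R2adj(all)`.
#'
#' @param tm chord-transformed community matrix.
#' @param X_geo,X_hab the two predictor blocks (samples x variables).
#' @return object of class `varpart2` with the fractions and the three
#'   adjusted R-squared values.
#' @export
varpart2 <- function(tm, X_geo, X_hab) {
  Y <- unclass(tm)
  N <- nrow(Y)
  r2 <- function(X) adj_r2(rda_core(Y, X)$R2, N, ncol(as.matrix(X)))
  Xall <- cbind(as.matrix(X_geo), as.matrix(X_hab))
  adj_geo <- r2(X_geo); adj_hab <- r2(X_hab); adj_all <- r2(Xall)
  structure(list(
    a = adj_all - adj_hab, c = adj_all - adj_geo,
    b = adj_geo + adj_hab - adj_all, residual = 1 - adj_all,
    R2_adj_geo = adj_geo, R2_adj_hab = adj_hab, R2_adj_all = adj_all,
    testable = c(a = TRUE, b = FALSE, c = TRUE)),
    class = "varpart2")
}

#' @export
print.varpart2 <- function(x, digits = 4, ...) {
  cat("Variance partitioning (adjusted R-squared fractions)\n")
  cat(sprintf("  [a] geography unique: %.*f\n", digits, x$a))
  cat(sprintf("  [b] shared:           %.*f (not testable)\n", digits, x$b))
  cat(sprintf("  [c] habitat unique:   %.*f\n", digits, x$c))
  cat(sprintf("  residual:             %.*f\n", digits, x$residual))
  invisible(x)
}

#' Association of island descriptors with RDA axes
#'
#' Pearson correlation of each (sample-level) predictor with each axis's
#' site scores. Because descriptors are constant within islands while axis
#' scores vary between years, per-sample p-values would treat repeated
#' yearly samples as independent; significance is instead assessed by
#' regressing the island-mean axis score on the island-level descriptor
#' value (one observation per island).
#'
#' @param rda an `rda_fit` object.
#' @param X the predictor data frame used in the fit (samples x variables).
#' @param island island id per sample; defaults to the ordination
#'   metadata.
#' @param axes which axes to report (default the significant ones at 0.05,
#'   or the first three if none tested).
#' @return data frame with one row per predictor x axis: `r` and
#'   `p_island` (island-level regression p).
#' @export
axis_variable_association <- function(rda, X, island = NULL, axes = NULL) {
  if (is.null(island)) {
    if (is.null(rda$meta)) stop("axis_variable_association: no island ids")
    island <- rda$meta$island
  }
  if (is.null(axes)) {
    axes <- which(!is.na(rda$axis_p) & rda$axis_p < 0.05)
    if (!length(axes)) axes <- seq_len(min(3, ncol(rda$site_scores)))
  }
  X <- as.data.frame(X)
  out <- list()
  for (a in axes) {
    sc <- rda$site_scores[, a]
    sc_isl <- tapply(sc, island, mean)
    for (v in names(X)) {
      x_isl <- tapply(X[[v]], island, mean)[names(sc_isl)]
      fit <- lm(sc_isl ~ x_isl)
      pv <- summary(fit)$coefficients
      p <- if (nrow(pv) > 1) pv[2, 4] else NA_real_
      out[[length(out) + 1]] <- data.frame(
        variable = v, axis = colnames(rda$site_scores)[a],
        r = cor(X[[v]], sc), p_island = p)
    }
  }
  do.call(rbind, out)
}

#' Correlation of species with RDA axes
#'
#' Pearson correlation of each (chord-transformed) species column with the
#' site scores of the selected axes, with two-sided t-test p-values and a
#' Bonferroni flag across all species x axis tests.
#'
#' @param rda an `rda_fit` object.
#' @param tm the chord-transformed matrix used in the fit.
#' @param axes axis indices (default as in [axis_variable_association()]).
#' @return data frame with `species`, `axis`, `r`, `p`, `p_bonferroni`
#'   (raw p times the number of tests, capped at 1) and `significant`.
#' @export
species_axis_correlations <- function(rda, tm, axes = NULL) {
  if (is.null(axes)) {
    axes <- which(!is.na(rda$axis_p) & rda$axis_p < 0.05)
    if (!length(axes)) axes <- seq_len(min(3, ncol(rda$site_scores)))
  }
  x <- unclass(tm)
  out <- list()
  for (a in axes) {
    sc <- rda$site_scores[, a]
    for (j in seq_len(ncol(x))) {
      xj <- x[, j]
      if (sd(xj) == 0) { r <- NA_real_; p <- NA_real_ }
      else {
        ct <- suppressWarnings(cor.test(xj, sc))
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        species = colnames(x)[j], axis = colnames(rda$site_scores)[a],
        r = r, p = p)
    }
  }
  tab <- do.call(rbind, out)
  m <- sum(!is.na(tab$p))
  tab$p_bonferroni <- pmin(tab$p * m, 1)
  tab$significant <- !is.na(tab$p_bonferroni) & tab$p_bonferroni < 0.05
  tab
}
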