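#' Total beta diversity as the variance of the community matrix
#'
#' Total beta diversity of a (chord-transformed) island-year x species
#' matrix is its total variance: with \eqn{y_{ijk}} the value for species
#' \eqn{j} on island \eqn{i} in year \eqn{k} and \eqn{\bar y_j} the grand
#' mean of species \eqn{j},
#' \deqn{SS_{Total} = \sum_{ijk} (y_{ijk} - \bar y_j)^2, \qquad
#'       BD_{I,T} = SS_{Total} / (N - 1)}
#' where \eqn{N} is the number of island-year samples. Under the chord
#' transform \eqn{BD_{I,T} \in [0, 1]}. Local contributions
#' \eqn{LCBD_r = SS_r / SS_{Total}} (row sums of squared deviations) and
#' species contributions \eqn{SCBD_j = SS_j / SS_{Total}} (column sums)
#' each sum to 1.
#'
#' @param tm a `chord_matrix` (any numeric matrix is accepted).
#' @return list with `SS_total`, `BD_IT`, `LCBD` (per sample), `SCBD`
#'   (per species) and `N`.
#' @references Legendre & De Caceres (2013) Beta diversity as the variance
#'   of community data. Ecology Letters 16:951-963.
#' @export
total_beta <- function(tm) {
  N <- nrow(tm)
  if (N < 2) stop("total_beta: at least 2 samples required")
  dev2 <- sweep(tm, 2, colMeans(tm))^2
  SS_total <- sum(dev2)
  if (SS_total == 0) {
    warning("total_beta: all samples identical; LCBD/SCBD reported uniform")
    lcbd <- setNames(rep(1 / N, N), rownames(tm))
    scbd <- setNames(rep(1 / ncol(tm), ncol(tm)), colnames(tm))
  } else {
    lcbd <- rowSums(dev2) / SS_total
    scbd <- colSums(dev2) / SS_total
  }
  list(SS_total = SS_total, BD_IT = SS_total / (N - 1),
       LCBD = lcbd, SCBD = scbd, N = N)
}

#' Partition beta diversity into spatial and temporal components
#'
#' Splits the total variance of the transformed island-year x species
#' matrix into a between-island component and within-island temporal
#' components. With \eqn{\bar y_{ij}} the mean of species \eqn{j} over the
#' years of island \eqn{i}:
#' \deqn{SS_I = \sum_{ij} (\bar y_{ij} - \bar y_j)^2, \qquad
#'       BD_I = SS_I / (n - 1)}
#' \deqn{SS_{Temp} = \sum_{ijk} (y_{ijk} - \bar y_{ij})^2, \qquad
#'       BD_T = SS_{Temp} / (Y - n)}
#' \deqn{SS_{Temp,i} = \sum_{jk} (y_{ijk} - \bar y_{ij})^2, \qquad
#'       BD_{Ti} = SS_{Temp,i} / (Y_i - 1)}
#' where \eqn{n} is the number of islands, \eqn{Y = N} the total number of
#' island-years and \eqn{Y_i} the years of island \eqn{i}. The exact
#' decomposition
#' \eqn{SS_{Total} = SS_{Temp} + \sum_i Y_i \sum_j (\bar y_{ij} - \bar y_j)^2}
#' is evaluated and returned as `identity_gap` (should be ~0; note the
#' weighted between-island term differs from the unweighted \eqn{SS_I}
#' whenever the design is unbalanced).
#'
#' @param tm a `chord_matrix` with sample metadata (see [pivot_records()]),
#'   or any matrix plus an explicit `island` grouping vector.
#' @param island optional island id per row; defaults to the matrix
#'   metadata.
#' @return an object of class `beta_partition`; see Details for fields.
#' @details Fields: `SS_total`, `BD_IT`, `LCBD`, `SCBD` (as [total_beta()]);
#'   `SS_I`, `BD_I`; `SS_temp`, `BD_T`; per-island table `islands` with
#'   `Y_i`, `SS_temp_i`, `BD_Ti`, `mean_LCBD`, `mean_log_LCBD`;
#'   `identity_gap`; `N`, `n`.
#' @export
beta_partition <- function(tm, island = NULL) {
  if (is.null(island)) {
    meta <- attr(tm, "meta")
    if (is.null(meta)) stop("beta_partition: no island grouping available")
    island <- meta$island
  }
  island <- as.character(island)
  n <- length(unique(island))
  if (n < 2) stop("beta_partition: needs >=2 islands")
  tb <- total_beta(tm)
  N <- tb$N

  Y_i <- table(island)[unique(island)]
  ybar_ij <- rowsum(unclass(tm), island) / as.vector(table(island)[sort(unique(island))])
  ybar_ij <- ybar_ij[unique(island), , drop = FALSE]
  ybar_j <- colMeans(tm)

  SS_I <- sum(sweep(ybar_ij, 2, ybar_j)^2)
  BD_I <- SS_I / (n - 1)

  within_dev2 <- (unclass(tm) - ybar_ij[island, , drop = FALSE])^2
  SS_temp_i <- rowsum(rowSums(within_dev2), island)[unique(island), 1]
  SS_temp <- sum(SS_temp_i)
  BD_T <- SS_temp / (N - n)

  Yi <- as.vector(Y_i)
  if (any(Yi < 2))
    warning("beta_partition: island(s) with a single year: BD_Ti undefined (NA): ",
            paste(names(Y_i)[Yi < 2], collapse = ", "))
  BD_Ti <- ifelse(Yi >= 2, SS_temp_i / (Yi - 1), NA_real_)

  between_weighted <- sum(Yi * rowSums(sweep(ybar_ij, 2, ybar_j)^2))
  identity_gap <- tb$SS_total - SS_temp - between_weighted

  lcbd_island_mean <- tapply(tb$LCBD, island, mean)[unique(island)]
  lcbd_island_logmean <- tapply(log(tb$LCBD), island, mean)[unique(island)]

  isl <- data.frame(
    island = unique(island), Y_i = Yi,
    SS_temp_i = as.vector(SS_temp_i), BD_Ti = BD_Ti,
    mean_LCBD = as.vector(lcbd_island_mean),
    mean_log_LCBD = as.vector(lcbd_island_logmean),
    row.names = unique(island), stringsAsFactors = FALSE)
  isl <- isl[order(isl$island), , drop = FALSE]

  structure(list(
    SS_total = tb$SS_total, BD_IT = tb$BD_IT,
    LCBD = tb$LCBD, SCBD = tb$SCBD,
    SS_I = SS_I, BD_I = BD_I,
    SS_temp = SS_temp, BD_T = BD_T,
    islands = isl, identity_gap = identity_gap,
    N = N, n = n, island = island),
    class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, digits = 4, ...) {
  cat("Beta diversity partition (", x$N, " island-year samples, ",
      x$n, " islands)\n", sep = "")
  cat(sprintf("  Total  BD_I,T = %.*f  (SS_Total = %.*f)\n",
              digits, x$BD_IT, digits, x$SS_total))
  cat(sprintf("  Island BD_I   = %.*f  (SS_I = %.*f)\n",
              digits, x$BD_I, digits, x$SS_I))
  cat(sprintf("  Temporal BD_T = %.*f  (SS_Temp = %.*f)\n",
              digits, x$BD_T, digits, x$SS_temp))
  cat("Per-island temporal beta diversity and mean LCBD:\n")
  print(round(x$islands[, c("Y_i", "BD_Ti", "mean_LCBD")], digits), ...)
  invisible(x)
}

#' @export
summary.beta_partition <- function(object, ...) {
  cat("Decomposition check (SS_Total - SS_Temp - weighted between-island SS):",
      format(object$identity_gap), "\n")
  cat("sum(LCBD) =", format(sum(object$LCBD)),
      " sum(SCBD) =", format(sum(object$SCBD)), "\n")
  print(object, ...)
}

#' Compare temporal variability between islands
#'
#' ANOVA of log-transformed yearly LCBD values by island (log because the
#' LCBD distribution is right-skewed), with a Tukey HSD post-hoc on the
#' island means.
#'
#' @param bp a `beta_partition` object.
#' @return list with `anova` (`F`, `df`, `p`), `tukey` (the [TukeyHSD()]
#'   table) and the fitted [aov()] object.
#' @export
island_temporal_tests <- function(bp) {
  if (bp$n < 2) stop("island_temporal_tests: needs >=2 islands")
  d <- data.frame(loglcbd = log(bp$LCBD), island = factor(bp$island))
  fit <- aov(loglcbd ~ island, data = d)
  a <- anova(fit)
  list(anova = list(F = a$`F value`[1], df = a$Df, p = a$`Pr(>F)`[1]),
       tukey = TukeyHSD(fit)$island, fit = fit)
}

#' Correlation with a two-sided p-value
#'
#' Pearson or Spearman correlation via [cor.test()], erroring on constant
#' input rather than returning `NA` silently.
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p`.
#' @export
cor_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (sd(x) == 0 || sd(y) == 0)
    stop("cor_with_p: correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}
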