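#' Small-sample corrected AIC
#'
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}; converges to AIC as \eqn{n}
#' grows.
#'
#' @param aic AIC value.
#' @param k number of estimated parameters (including the error variance
#'   for Gaussian models).
#' @param n number of observations.
#' @export
aicc <- function(aic, k, n) {
  if (n - k - 1 <= 0) stop("aicc: n must exceed k + 1")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

aicc_lm <- function(fit) {
  k <- length(coef(fit)) + 1  # + residual variance
  n <- length(residuals(fit))
  aicc(stats::AIC(fit), k, n)
}

#' Does continental abundance drive stopover abundance?
#'
#' Fits log-log linear models of the mean number ringed per island-year
#' (per island x species) on continental abundance, island, their
#' interaction, each main effect alone, and the intercept-only null, and
#' ranks them by AICc. Rows with zero mean (species never ringed on an
#' island) are omitted because the log is undefined.
#'
#' @param mean_ringed data frame with columns `island`, `species`,
#'   `mean_count` (mean individuals ringed per used year).
#' @param continental named numeric vector of continental abundance (pairs)
#'   per species.
#' @return object of class `model_comparison`: data frame with one row per
#'   candidate (`model`, `k`, `logLik`, `AICc`, `dAICc`), plus the fitted
#'   `lm` objects in attribute `fits`.
#' @export
fit_loglog_models <- function(mean_ringed, continental) {
  d <- mean_ringed[mean_ringed$mean_count > 0, , drop = FALSE]
  n_drop <- nrow(mean_ringed) - nrow(d)
  if (n_drop > 0)
    message("fit_loglog_models: omitted ", n_drop, " zero-mean island x species row(s)")
  d$logy <- log(d$mean_count)
  d$logC <- log(continental[d$species])
  if (anyNA(d$logC)) stop("fit_loglog_models: species missing continental abundance")
  d$island <- factor(d$island)
  forms <- list(
    "abundance x island" = logy ~ logC * island,
    "abundance + island" = logy ~ logC + island,
    "abundance"          = logy ~ logC,
    "island"             = logy ~ island,
    "null"               = logy ~ 1)
  fits <- list(); rows <- list()
  for (nm in names(forms)) {
    fit <- lm(forms[[nm]], data = d)
    k <- length(coef(fit)) + 1
    if (nrow(d) - k - 1 <= 0) {
      warning("fit_loglog_models: skipping '", nm, "' (too few observations)")
      next
    }
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, k = k,
                             logLik = as.numeric(logLik(fit)),
                             AICc = aicc_lm(fit))
  }
  tab <- do.call(rbind, rows)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits, class = c("model_comparison", "data.frame"))
}

#' Final regression of total ringed on continental abundance
#'
#' OLS of log10 total number ringed (all islands, all used years) on log10
#' continental abundance, reported with the overall F test (df 1, n-2) and
#' the Pearson correlation. Species with |DFBETA| of the slope exceeding
#' \eqn{2/\sqrt n} are flagged as influential (e.g. a single very abundant
#' species dominating the fit).
#'
#' @param totals named numeric vector: total ringed per species.
#' @param continental named numeric vector: continental abundance (pairs).
#' @return list with `slope`, `intercept`, `F`, `df`, `p`, `r`,
#'   `influential` (character vector) and the `lm` fit.
#' @export
fit_final_regression <- function(totals, continental) {
  sp <- intersect(names(totals), names(continental))
  sp <- sp[totals[sp] > 0 & continental[sp] > 0]
  if (length(sp) < 3) stop("fit_final_regression: needs >=3 species")
  d <- data.frame(y = log10(totals[sp]), x = log10(continental[sp]),
                  row.names = sp)
  fit <- lm(y ~ x, data = d)
  a <- suppressWarnings(anova(fit))
  n <- nrow(d)
  se_slope <- suppressWarnings(sqrt(diag(vcov(fit))["x"]))
  dfb <- if (se_slope > 0) dfbeta(fit)[, "x"] / se_slope else rep(0, n)
  influential <- sp[abs(dfb) > 2 / sqrt(n)]
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       F = a$`F value`[1], df = c(1, n - 2), p = a$`Pr(>F)`[1],
       r = unname(sign(coef(fit)["x"]) *
                    sqrt(suppressWarnings(summary(fit))$r.squared)),
       influential = influential, fit = fit)
}

#' Mean ringed per used year, per island and species
#'
#' @param records a `capture_records` data frame.
#' @return data frame with `island`, `species`, `mean_count`, `total`.
#' @export
mean_ringed_table <- function(records) {
  years_per_island <- tapply(records$year, records$island,
                             function(y) length(unique(y)))
  tot <- aggregate(count ~ island + species, data = records, FUN = sum)
  tot$mean_count <- tot$count / as.vector(years_per_island[tot$island])
  data.frame(island = tot$island, species = tot$species,
             mean_count = tot$mean_count, total = tot$count,
             stringsAsFactors = FALSE)
}
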