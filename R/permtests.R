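# Permutation inference on chord-transformed composition. The chord space
# is Euclidean, so sums of squares are computed directly from coordinates
# (identical to the Gower-centered distance-matrix formulation).

ss_within_between <- function(x, g) {
  # x: samples x variables; g: factor. Returns c(SS_between, SS_within).
  ss_tot <- sum(sweep(x, 2, colMeans(x))^2)
  gs <- rowsum(x, g)              # group column sums
  m <- as.vector(table(g)[rownames(gs)])
  ss_w <- sum(x^2) - sum(gs^2 / m)
  c(ss_tot - ss_w, ss_w)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA of chord-transformed composition against a grouping
#' (island by default). The pseudo-F is
#' \eqn{F = (SS_B/(g-1)) / (SS_W/(N-g))} on Euclidean distances in chord
#' space; the p-value comes from unrestricted permutation of row labels,
#' with the observed statistic included in the reference set:
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (n_{perm} + 1)}.
#'
#' @param tm a `chord_matrix` (or any numeric matrix).
#' @param grouping group label per row; defaults to the island metadata.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `perm_test`.
#' @export
permanova <- function(tm, grouping = NULL, n_perm = 999, seed = 1) {
  g <- resolve_grouping(tm, grouping)
  check_perm_args(g, n_perm)
  set.seed(seed)
  x <- unclass(tm)
  N <- nrow(x); ng <- nlevels(g)
  df <- c(ng - 1, N - ng)
  ss <- ss_within_between(x, g)
  f_obs <- (ss[1] / df[1]) / (ss[2] / df[2])
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- g[sample.int(N)]
    ssb <- ss_within_between(x, gp)
    fb <- (ssb[1] / df[1]) / (ssb[2] / df[2])
    if (fb >= f_obs) exceed <- exceed + 1L
  }
  new_perm_test("PERMANOVA (pseudo-F)", f_obs, df,
                (1 + exceed) / (n_perm + 1), n_perm, seed,
                extra = list(SS_between = ss[1], SS_within = ss[2]))
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether within-group scatter (temporal variability of composition
#' within islands) differs between groups: each sample's Euclidean distance
#' to its group centroid in chord space is computed, optionally
#' bias-adjusted for small samples by \eqn{\sqrt{m_g/(m_g-1)}}, and the
#' distances are compared between groups with a one-way F statistic. The
#' p-value permutes the raw rows across groups and recomputes centroids,
#' distances and F.
#'
#' @inheritParams permanova
#' @param bias_adjust multiply each group's distances by
#'   \eqn{\sqrt{m_g/(m_g-1)}} (small-sample bias adjustment).
#' @return object of class `perm_test`; per-sample distances in
#'   `$distances`, group means in `$group_means`, and the distance ANOVA
#'   Tukey HSD table in `$tukey`.
#' @export
dispersion_test <- function(tm, grouping = NULL, bias_adjust = TRUE,
                            n_perm = 999, seed = 1) {
  g <- resolve_grouping(tm, grouping)
  check_perm_args(g, n_perm)
  set.seed(seed)
  x <- unclass(tm)
  N <- nrow(x); ng <- nlevels(g)
  df <- c(ng - 1, N - ng)

  centroid_dist <- function(x, g) {
    cent <- rowsum(x, g) / as.vector(table(g)[levels(g)])
    d <- sqrt(rowSums((x - cent[as.character(g), , drop = FALSE])^2))
    if (bias_adjust) {
      m <- as.vector(table(g)[as.character(g)])
      d <- d * sqrt(m / (m - 1))
    }
    d
  }
  disp_f <- function(d, g) {
    ssb_ssw <- ss_within_between(matrix(d, ncol = 1), g)
    (ssb_ssw[1] / df[1]) / (ssb_ssw[2] / df[2])
  }

  d_obs <- centroid_dist(x, g)
  f_obs <- disp_f(d_obs, g)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    db <- centroid_dist(x[perm, , drop = FALSE], g)
    if (disp_f(db, g) >= f_obs) exceed <- exceed + 1L
  }
  fit <- aov(d_obs ~ g)
  out <- new_perm_test("homogeneity of multivariate dispersion", f_obs, df,
                       (1 + exceed) / (n_perm + 1), n_perm, seed,
                       extra = list(
                         distances = setNames(d_obs, rownames(x)),
                         group_means = tapply(d_obs, g, mean),
                         tukey = TukeyHSD(fit)$g))
  out
}

#' Pairwise PERMANOVA contrasts with FDR control
#'
#' Runs [permanova()] on every pair of groups and adjusts the raw p-values
#' with the Benjamini-Hochberg procedure.
#'
#' @inheritParams permanova
#' @param method p-value adjustment method (see [p.adjust()]).
#' @return list with symmetric matrices `p_raw` and `p_adjusted`, plus
#'   `F` statistics per pair.
#' @export
pairwise_permanova <- function(tm, grouping = NULL, n_perm = 999, seed = 1,
                               method = "BH") {
  g <- resolve_grouping(tm, grouping)
  lev <- levels(g)
  np <- length(lev)
  if (np < 2) stop("pairwise_permanova: needs >=2 groups")
  p_raw <- f_mat <- matrix(NA_real_, np, np, dimnames = list(lev, lev))
  pairs <- utils::combn(np, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sel <- g %in% lev[c(i, j)]
    sub <- unclass(tm)[sel, , drop = FALSE]
    pt <- permanova(sub, grouping = droplevels(g[sel]),
                    n_perm = n_perm, seed = seed + k)
    p_raw[i, j] <- p_raw[j, i] <- pt$p
    f_mat[i, j] <- f_mat[j, i] <- pt$statistic
  }
  up <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[up] <- p.adjust(p_raw[up], method = method)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(p_raw = p_raw, p_adjusted = p_adj, F = f_mat,
       method = method, n_perm = n_perm, seed = seed)
}

resolve_grouping <- function(tm, grouping) {
  if (is.null(grouping)) {
    meta <- attr(tm, "meta")
    if (is.null(meta)) stop("no grouping supplied and matrix has no metadata")
    grouping <- meta$island
  }
  droplevels(factor(grouping))
}

check_perm_args <- function(g, n_perm) {
  if (nlevels(g) < 2) stop("permutation test: needs >=2 groups")
  if (min(table(g)) < 2) stop("permutation test: every group needs >=2 samples")
  if (n_perm < 99) stop("permutation test: n_perm must be >= 99")
}

new_perm_test <- function(method, statistic, df, p, n_perm, seed, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   n_perm = n_perm, seed = seed), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  F(%d, %d) = %.4f, permutation p = %.4g (%d permutations)\n",
              x$df[1], x$df[2], x$statistic, x$p, x$n_perm))
  invisible(x)
}
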