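# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive loops / textbook formulas
# and never call the code paths they check.

# Beta-diversity sums of squares by naive triple loops.
beta_oracle <- function(x, island) {
  n_r <- nrow(x); n_c <- ncol(x)
  ybar_j <- numeric(n_c)
  for (j in seq_len(n_c)) ybar_j[j] <- mean(x[, j])
  SS_total <- 0
  for (r in seq_len(n_r)) for (j in seq_len(n_c))
    SS_total <- SS_total + (x[r, j] - ybar_j[j])^2
  isl <- unique(island)
  ybar_ij <- matrix(0, length(isl), n_c)
  for (i in seq_along(isl)) for (j in seq_len(n_c))
    ybar_ij[i, j] <- mean(x[island == isl[i], j])
  SS_I <- 0
  for (i in seq_along(isl)) for (j in seq_len(n_c))
    SS_I <- SS_I + (ybar_ij[i, j] - ybar_j[j])^2
  SS_temp_i <- numeric(length(isl))
  for (i in seq_along(isl)) {
    rows <- which(island == isl[i])
    for (r in rows) for (j in seq_len(n_c))
      SS_temp_i[i] <- SS_temp_i[i] + (x[r, j] - ybar_ij[i, j])^2
  }
  weighted_between <- 0
  for (i in seq_along(isl)) {
    Yi <- sum(island == isl[i])
    for (j in seq_len(n_c))
      weighted_between <- weighted_between + Yi * (ybar_ij[i, j] - ybar_j[j])^2
  }
  list(SS_total = SS_total, SS_I = SS_I, SS_temp = sum(SS_temp_i),
       SS_temp_i = SS_temp_i, islands = isl,
       weighted_between = weighted_between)
}

# Total variance and LCBD from the pairwise-distance (Gower) formulation:
# SS_total = sum_{r<s} d_rs^2 / N ; LCBD from the diagonal of the
# Gower-centered matrix.
gower_oracle <- function(x) {
  N <- nrow(x)
  D2 <- as.matrix(dist(x))^2
  SS_total <- sum(D2[upper.tri(D2)]) / N
  C <- diag(N) - matrix(1 / N, N, N)
  G <- -0.5 * C %*% D2 %*% C
  list(SS_total = SS_total, LCBD = diag(G) / sum(diag(G)))
}

# Classical one-way MANOVA trace pseudo-F computed column by column.
manova_trace_f <- function(x, g) {
  g <- factor(g)
  ssb <- 0; ssw <- 0
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]; gm <- mean(xj)
    for (lev in levels(g)) {
      v <- xj[g == lev]
      ssb <- ssb + length(v) * (mean(v) - gm)^2
      ssw <- ssw + sum((v - mean(v))^2)
    }
  }
  df1 <- nlevels(g) - 1; df2 <- length(g) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# OLS through explicit normal equations.
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# RDA canonical eigenvalues via naive per-column least squares plus an
# eigendecomposition of the covariance of fitted values.
rda_oracle_eig <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X))
  N <- nrow(Y)
  Yhat <- matrix(0, N, ncol(Y))
  for (j in seq_len(ncol(Y)))
    Yhat[, j] <- fitted(lm(Y[, j] ~ X))
  ev <- eigen(crossprod(Yhat) / (N - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev[ev > 1e-12 * max(ev, 1)]
}

# Phylogenetic covariance by walking root-to-tip paths.
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1
  parent <- integer(max(tree$edge)); blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- integer(0)
    while (node != root) { p <- c(p, node); node <- parent[node] }
    p
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    pa <- path_to_root(a); pb <- path_to_root(b)
    shared <- intersect(pa, pb)  # edges (as child nodes) on both paths
    V[a, b] <- sum(blen[shared])
  }
  V
}

# GLS through explicit V^-1 weighted normal equations.
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[, 1]
}

# Random unbalanced community matrix with island structure.
random_community <- function(n_islands = 4, years = 2:5, n_species = 5,
                             chord = TRUE) {
  isl <- paste0("I", seq_len(n_islands))
  yi <- sample(years, n_islands, replace = TRUE)
  rows <- list(); island <- character()
  for (i in seq_len(n_islands)) for (k in seq_len(yi[i])) {
    rows[[length(rows) + 1]] <- rpois(n_species, lambda = runif(1, 2, 20))
    island <- c(island, isl[i])
  }
  m <- do.call(rbind, rows)
  m[rowSums(m) == 0, 1] <- 1
  colnames(m) <- paste0("sp", seq_len(n_species))
  rownames(m) <- paste0(island, "_", seq_along(island))
  if (chord) m <- m / sqrt(rowSums(m^2))
  list(m = m, island = island)
}

# Tiny capture-record builder.
make_records <- function(df) as_capture_records(df)
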