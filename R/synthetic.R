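# Generative model for standardized island ringing data. Expected counts
# are log-linear in island descriptors:
#   log mu_ijk = log(C_j * s) + beta0_j + b_i
#                + beta_area_j * clog(Area_i) + beta_dsouth_j * clog(MinDSouthLand_i)
#                + u_ik + log(effort_ik)
# with C_j the species' continental abundance, s a global capture-rate
# scaling, b_i an island baseline, u_ik a year-passage effect and clog a
# centered natural log (centering keeps the scaling interpretable; count
# ratios between islands are unchanged). Counts are Poisson or nbinom2.

default_years_used <- c(
  Aire = 16L, Cabrera = 8L, Colom = 5L, Columbrets = 9L, Conillera = 7L,
  Dragonera = 5L, Formentera = 7L, Grosa = 7L, Tabarca = 10L)

#' Configuration of the synthetic ringing-data generator
#'
#' Defaults emulate the nine-island spring-ringing study design: the nine
#' real island descriptor rows, the published number of used years per
#' island (5-16, 74 island-years in total), 35 species with continental
#' abundances log-uniform over 10^4.5 to 10^7.5 pairs, 10 species with a
#' strong positive response to island area and 20 with a positive response
#' to the distance to southern land, overdispersed (nbinom2) counts, and
#' constant effort of 300 net-metres over 30 days per island-year.
#'
#' @param n_species number of species.
#' @param islands island descriptor data frame (needs `Area` and
#'   `MinDSouthLand` columns and island rownames).
#' @param years_per_island named integer vector of years per island (all
#'   >= 2); names must match `islands`.
#' @param first_year first calendar year of the simulated period.
#' @param log10C_range range of log10 continental abundance (pairs).
#' @param scaling global capture-rate scaling `s`.
#' @param n_area_responders,beta_area number of species with an area
#'   response and its log-linear slope.
#' @param n_dsouth_responders,beta_dsouth same for distance to southern
#'   land (assigned to the species after the area responders).
#' @param beta0_sd SD of the per-species baseline (log scale).
#' @param island_sd SD of the island baseline `b_i` (log scale).
#' @param year_sd SD of the island-year passage effect `u_ik` (log scale).
#' @param family `"poisson"` or `"nbinom2"`.
#' @param theta nbinom2 dispersion (variance `mu + mu^2/theta`).
#' @param effort_net_m,effort_days mist-net metres and ringing days per
#'   island-year.
#' @param kipp_a,kipp_b,kipp_c,kipp_sd trait linkage: species Kipp index
#'   `kipp_a + kipp_b * beta_area - kipp_c * beta_dsouth + noise`.
#' @param war_a,war_b,war_sd wing aspect ratio as an affine function of the
#'   Kipp index plus noise.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_species = 35,
    islands = island_descriptors(),
    years_per_island = default_years_used,
    first_year = 2003L,
    log10C_range = c(4.5, 7.5),
    scaling = 1e-7,
    n_area_responders = 10, beta_area = 0.5,
    n_dsouth_responders = 20, beta_dsouth = 0.4,
    beta0_sd = 0.5, island_sd = 0.2, year_sd = 0.3,
    family = c("nbinom2", "poisson"), theta = 2,
    effort_net_m = 300, effort_days = 30,
    kipp_a = 25, kipp_b = 10, kipp_c = 10, kipp_sd = 2,
    war_a = 1.5, war_b = 0.18, war_sd = 0.3) {
  family <- match.arg(family)
  if (any(years_per_island < 2))
    stop("synthetic_config: every island needs >= 2 years")
  if (theta <= 0) stop("synthetic_config: theta must be > 0")
  if (any(c(beta0_sd, island_sd, year_sd, kipp_sd, war_sd) < 0))
    stop("synthetic_config: SDs must be >= 0")
  if (!all(names(years_per_island) %in% rownames(islands)))
    stop("synthetic_config: years_per_island names must match islands")
  if (n_area_responders + n_dsouth_responders > n_species)
    stop("synthetic_config: more responders than species")
  structure(as.list(environment()), class = "synthetic_config")
}

species_ids <- function(n) sprintf("sp%02d", seq_len(n))

#' Expected counts under a synthetic configuration
#'
#' The deterministic part of the generative model (no year effects, no
#' island baselines, no noise): expected count per island x species for
#' one island-year at the configured effort.
#'
#' @param config a `synthetic_config`.
#' @param truth a truth table from [simulate_ringing()] (to reuse drawn
#'   species parameters), or `NULL` to use zero baselines.
#' @return matrix islands x species of expected counts.
#' @export
expected_counts <- function(config, truth) {
  isl <- config$islands[names(config$years_per_island), , drop = FALSE]
  la <- log(isl$Area); la <- la - mean(la)
  ld <- log(isl$MinDSouthLand); ld <- ld - mean(ld)
  eff <- (config$effort_net_m / 100) * config$effort_days
  lmu <- outer(rep(0, nrow(isl)), log(truth$C * config$scaling), "+") +
    outer(la, truth$beta_area) + outer(ld, truth$beta_dsouth) +
    matrix(truth$beta0, nrow(isl), config$n_species, byrow = TRUE) +
    log(eff)
  dimnames(lmu) <- list(rownames(isl), truth$species)
  exp(lmu)
}

#' Simulate standardized ringing data
#'
#' Draws species parameters (continental abundance, baselines, planted
#' area / southern-distance responses), island and island-year effects,
#' and counts for every island x year x species cell, together with daily
#' effort records spanning the standard spring window and a truth table
#' for recovery tests.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @return list with `records` (`capture_records`, including zero counts),
#'   `effort` (`effort_records`), `truth` (per-species data frame with the
#'   drawn `C`, `beta0`, `beta_area`, `beta_dsouth`) and `year_effects`.
#' @export
simulate_ringing <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  isl_names <- names(config$years_per_island)
  isl <- config$islands[isl_names, , drop = FALSE]
  if (any(isl$Area <= 0))
    stop("simulate_ringing: non-positive Area for island ",
         isl_names[which(isl$Area <= 0)[1]])
  if (any(isl$MinDSouthLand <= 0))
    stop("simulate_ringing: non-positive MinDSouthLand for island ",
         isl_names[which(isl$MinDSouthLand <= 0)[1]])
  ns <- config$n_species
  sp <- species_ids(ns)
  C <- 10^runif(ns, config$log10C_range[1], config$log10C_range[2])
  beta0 <- rnorm(ns, 0, config$beta0_sd)
  beta_area <- rep(0, ns)
  beta_dsouth <- rep(0, ns)
  if (config$n_area_responders > 0)
    beta_area[seq_len(config$n_area_responders)] <- config$beta_area
  if (config$n_dsouth_responders > 0)
    beta_dsouth[config$n_area_responders +
                  seq_len(config$n_dsouth_responders)] <- config$beta_dsouth
  b_isl <- rnorm(length(isl_names), 0, config$island_sd)

  la <- log(isl$Area); la <- la - mean(la)
  ld <- log(isl$MinDSouthLand); ld <- ld - mean(ld)
  eff <- (config$effort_net_m / 100) * config$effort_days

  rec <- list(); ye <- list()
  for (i in seq_along(isl_names)) {
    years <- config$first_year + seq_len(config$years_per_island[i]) - 1L
    for (k in seq_along(years)) {
      u <- rnorm(1, 0, config$year_sd)
      lmu <- log(C * config$scaling) + beta0 + b_isl[i] +
        beta_area * la[i] + beta_dsouth * ld[i] + u + log(eff)
      mu <- exp(lmu)
      cnt <- if (config$family == "poisson") rpois(ns, mu)
             else rnbinom(ns, size = config$theta, mu = mu)
      rec[[length(rec) + 1]] <- data.frame(
        island = isl_names[i], year = years[k], species = sp,
        count = cnt, stringsAsFactors = FALSE)
      ye[[length(ye) + 1]] <- data.frame(
        island = isl_names[i], year = years[k], u = u)
    }
  }
  records <- as_capture_records(do.call(rbind, rec))

  # daily effort: effort_days consecutive days from 16 April
  eff_rows <- lapply(seq_along(isl_names), function(i) {
    years <- config$first_year + seq_len(config$years_per_island[i]) - 1L
    do.call(rbind, lapply(years, function(y) {
      start <- as.Date(sprintf("%d-04-16", y))
      data.frame(island = isl_names[i],
                 date = start + seq_len(config$effort_days) - 1L,
                 net_length = config$effort_net_m)
    }))
  })
  effort <- do.call(rbind, eff_rows)
  class(effort) <- c("effort_records", "data.frame")

  truth <- data.frame(species = sp, C = C, beta0 = beta0,
                      beta_area = beta_area, beta_dsouth = beta_dsouth,
                      stringsAsFactors = FALSE)
  list(records = records, effort = effort, truth = truth,
       year_effects = do.call(rbind, ye),
       island_effects = setNames(b_isl, isl_names))
}

#' Simulate species wing traits linked to island responses
#'
#' Kipp wing-pointedness index generated as
#' `kipp_a + kipp_b * beta_area - kipp_c * beta_dsouth + noise` (species
#' that respond to island area get more pointed wings; species responding
#' to the southern-land distance get rounder wings), and wing aspect ratio
#' as an affine function of the Kipp index plus noise (strong positive
#' correlation between the two indices).
#'
#' @param config a `synthetic_config`.
#' @param truth truth table from [simulate_ringing()].
#' @param seed integer seed.
#' @return data frame with `species`, `kipp_mean`, `kipp_sd`, `war`.
#' @export
simulate_traits <- function(config, truth, seed = 1) {
  set.seed(seed)
  ns <- nrow(truth)
  kipp <- config$kipp_a + config$kipp_b * truth$beta_area -
    config$kipp_c * truth$beta_dsouth + rnorm(ns, 0, config$kipp_sd)
  kipp <- pmin(pmax(kipp, 1), 99)
  war <- config$war_a + config$war_b * kipp + rnorm(ns, 0, config$war_sd)
  data.frame(species = truth$species, kipp_mean = kipp,
             kipp_sd = rep(config$kipp_sd, ns), war = war,
             stringsAsFactors = FALSE)
}

#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with `n` tips, rescaled to unit root-to-tip
#' depth; tip labels are the synthetic species identifiers.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 2) stop("simulate_tree: needs >= 2 tips")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- species_ids(n_species)
  tr
}

#' Simulate a trait on a tree under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal realization with covariance
#' `sigma2 * V(lambda)` where `V` is the Brownian phylogenetic covariance
#' of the tree and `V(lambda)` scales its off-diagonals by `lambda`.
#'
#' @param tree an [ape::phylo] object.
#' @param lambda Pagel's lambda of the generating process.
#' @param sigma2 Brownian rate (>= 0); 0 returns the root value at every
#'   tip.
#' @param seed integer seed.
#' @param root root (mean) value.
#' @return named numeric vector of tip values.
#' @export
simulate_trait_on_tree <- function(tree, lambda = 1, sigma2 = 1, seed = 1,
                                   root = 0) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  if (sigma2 == 0) return(setNames(rep(root, n), tree$tip.label))
  V <- lambda_transform(phylo_cov(tree), lambda)
  x <- MASS::mvrnorm(1, mu = rep(root, n), Sigma = sigma2 * V)
  setNames(as.vector(x), tree$tip.label)
}
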