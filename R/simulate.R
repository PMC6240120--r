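# Synthetic-data generators with known generating parameters ("truth"), so
# every pipeline stage can be validated without field data. Defaults emulate
# the study conditions the pipeline is designed for: 44 plants, 43 avian
# frugivores, 3 sites, 4 seasons, brightness-nutrient couplings of marginal
# r^2 0.11-0.35, and frugivore-trait-dependent fruit choice at effect sizes
# of about |0.3|-|0.7| on the standardized scale.

#' Simulation configuration
#'
#' Bundles the generator defaults. `r2_nutrient` are the target marginal
#' r^2 of the brightness-nutrient couplings (with their signs), matching the
#' weak-cue regime the pipeline targets; protein is uncoupled by design.
#'
#' @param n_plants,n_frugivores,n_sites Counts.
#' @param seasons Season names.
#' @param r2_nutrient Named target r^2 per nutrient.
#' @param nutrient_sign Named signs of the brightness couplings.
#' @param phylo_share Share of residual trait variance that is phylogenetic.
#' @param gamma_generalism Preference coefficient: generalism x brightness.
#' @param gamma_migration Preference coefficient: migratory distance x
#'   darkness during the migration period (summer/autumn).
#' @param base_rate Baseline visitation rate (visits/h) per pair.
#' @param effort Observation effort in hours per network.
#' @param resident_frac Fraction of resident (zero-distance) frugivores.
#' @param mask_frac Fraction of per-visit consumption rates masked missing.
#' @param seed Master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_plants = 44, n_frugivores = 43, n_sites = 3,
                       seasons = SEASONS,
                       r2_nutrient = c(lipid = 0.23, sugar = 0.11,
                                       protein = 0, anthocyanin = 0.35),
                       nutrient_sign = c(lipid = 1, sugar = -1,
                                         protein = 1, anthocyanin = -1),
                       phylo_share = 0.3, gamma_generalism = 0.4,
                       gamma_migration = 0.3, base_rate = 0.01, effort = 30,
                       resident_frac = 0.5, mask_frac = 0.2, seed = 1) {
  if (n_plants < 2 || n_frugivores < 2 || n_sites < 1)
    stop("counts must be >= 2 (plants, frugivores) and >= 1 (sites)")
  if (any(r2_nutrient < 0 | r2_nutrient >= 1))
    stop("target r^2 must lie in [0, 1)")
  if (effort <= 0) stop("effort must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Unit-depth ultrametric tree with `n_tips` tips labelled `t1..tn`;
#' reproducible per seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param prefix Tip-label prefix.
#' @return An [ape::phylo] tree of depth 1.
#' @export
sim_tree <- function(n_tips, seed = 1, prefix = "t") {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0(prefix, seq_len(n_tips))
  tree
}

# Standardized trait with a phylogenetic (Brownian) and an iid component;
# L is the (pre-computed) lower Cholesky factor of the correlation matrix.
.phylo_trait <- function(L, phylo_share) {
  n <- nrow(L)
  bm <- drop(L %*% stats::rnorm(n))
  sqrt(phylo_share) * bm + sqrt(1 - phylo_share) * stats::rnorm(n)
}

.chol_corr <- function(tree) {
  C <- unclass(correlation_from_tree(tree))
  L <- t(chol(C + diag(1e-10, nrow(C))))
  rownames(L) <- rownames(C)
  L
}

#' Simulate plant traits coupled to fruit brightness
#'
#' Brightness is a standardized phylogenetic + iid latent mapped into (0, 1).
#' Each log-nutrient equals `slope * brightness_latent + residual` with
#' `slope = sign * sqrt(r2 / (1 - r2))` and unit-variance residual, so the
#' population marginal r^2 of the coupling equals the target. Chromatic
#' coordinates are drawn inside the tetrahedron independently of nutrients.
#' Fruit diameter and pulp mass follow a log-log allometry with slope 2
#' (plus phylogenetic noise) to exercise the pulp-mass imputation sub-model.
#'
#' @param tree Plant phylogeny from [sim_tree()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param mask Optionally a named vector of fractions of values to mask as
#'   missing, e.g. `c(anthocyanin = 0.2, pulp_mass = 0.2)`.
#' @return List with `plants` (data frame: species, diameter, pulp_mass,
#'   lipid, sugar, protein, anthocyanin, x, y, z, a), and `truth` (latents,
#'   slopes, masked true values).
#' @export
sim_plant_traits <- function(tree, config = sim_config(), seed = 1,
                             mask = NULL) {
  set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  L <- .chol_corr(tree)[sp, , drop = FALSE]
  z_a <- stats::setNames(.phylo_trait(L, config$phylo_share), sp)
  a <- pmin(pmax(0.5 + 0.12 * z_a, 0.02), 0.98)         # brightness in (0,1)

  r2 <- config$r2_nutrient
  slopes <- config$nutrient_sign[names(r2)] * sqrt(r2 / (1 - r2))
  base <- c(lipid = log(0.05), sugar = log(0.3), protein = log(0.05),
            anthocyanin = log(1))
  # residuals are sample-orthogonalized against the brightness latent and
  # rescaled, so the realized (not just population) coupling r^2 equals the
  # target -- the generator emulates an observed community, not an ensemble
  z_std <- as.numeric(scale(z_a))
  nut <- sapply(names(r2), function(k) {
    resid <- .phylo_trait(L, config$phylo_share)
    e <- stats::resid(stats::lm(resid ~ z_std))
    e <- as.numeric(scale(e))
    exp(base[k] + slopes[k] * z_std + e)
  })
  rownames(nut) <- sp

  # chroma: Dirichlet relative catches -> tetra coordinates, independent of
  # the nutrient couplings
  g <- matrix(stats::rgamma(4 * n, shape = 3), n, 4)
  rel <- g / rowSums(g)
  xyz <- rel %*% tetra_vertices()

  # interspecific pulp-mass allometries are tight; noise sd 0.35 log units
  ln_d <- stats::rnorm(n, log(8), 0.4)
  ln_m <- -4 + 2 * ln_d + 0.35 * .phylo_trait(L, config$phylo_share)

  plants <- data.frame(species = sp, diameter = exp(ln_d),
                       pulp_mass = exp(ln_m),
                       nut, xyz, a = a, row.names = NULL)
  truth <- list(brightness_latent = z_a, slopes = slopes,
                allometry_slope = 2, masked = list())
  if (!is.null(mask)) {
    for (col in names(mask)) {
      k <- max(1, round(mask[col] * n))
      idx <- sample.int(n, k)
      truth$masked[[col]] <- stats::setNames(plants[[col]][idx], sp[idx])
      plants[[col]][idx] <- NA
    }
  }
  list(plants = plants, truth = truth)
}

#' Simulate a frugivore table
#'
#' Continuous generalism propensity, zero-inflated migratory distance
#' (residents exactly 0), and a bird phylogeny.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `frugivores` (data frame: frugivore, generalism,
#'   migratory_distance) and `tree`.
#' @export
sim_frugivores <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_frugivores
  tree <- sim_tree(n, seed = seed + 1, prefix = "b")
  gen <- stats::rnorm(n)
  resident <- stats::runif(n) < config$resident_frac
  dist <- ifelse(resident, 0, stats::rgamma(n, shape = 4, scale = 5))
  list(frugivores = data.frame(frugivore = tree$tip.label, generalism = gen,
                               migratory_distance = dist),
       tree = tree)
}

#' Simulate visit records with planted fruit-choice preferences
#'
#' Expected log visitation rate per (plant, frugivore, site, season) is
#' `log(base_rate) + frugivore effect + gamma_g * generalism * brightness
#' - gamma_m * migratory distance (std) * brightness * [migration period]
#' + pair noise`; visit counts are Poisson(rate x effort) converted back to
#' rates per hour. Per-visit consumption is log-normal with a fraction of
#' entries masked to exercise the imputation ladder.
#'
#' @param plants Plant table from [sim_plant_traits()] (needs `species`, `a`).
#' @param frugivores Frugivore table from [sim_frugivores()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `visits` (records for [build_networks()]) and `truth`
#'   (preference coefficients and expected rate array).
#' @export
sim_networks <- function(plants, frugivores, config = sim_config(),
                         seed = 1) {
  set.seed(seed)
  if (config$n_sites < 1 || !length(config$seasons))
    stop("empty site/season grid")
  a_std <- as.numeric(scale(plants$a))
  gen <- frugivores$generalism
  mig <- frugivores$migratory_distance
  mig_std <- if (stats::sd(mig) > 0) mig / stats::sd(mig) else mig
  frug_eff <- stats::rnorm(length(gen), 0, 0.7)
  sites <- paste0("site", seq_len(config$n_sites))

  rows <- list(); exp_rate <- list()
  for (s in sites) for (se in config$seasons) {
    period <- as.numeric(se %in% c("summer", "autumn"))
    lograte <- outer(a_std, gen * config$gamma_generalism) +
      outer(-a_std, mig_std * config$gamma_migration * period) +
      matrix(frug_eff, length(a_std), length(gen), byrow = TRUE) +
      log(config$base_rate) +
      matrix(stats::rnorm(length(a_std) * length(gen), 0, 0.5),
             length(a_std), length(gen))
    lam <- exp(lograte) * config$effort
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    nz <- which(counts > 0, arr.ind = TRUE)
    if (!nrow(nz)) next
    fpv <- exp(stats::rnorm(nrow(nz), log(3), 0.3))
    fpv[stats::runif(nrow(nz)) < config$mask_frac] <- NA
    rows[[paste(s, se)]] <- data.frame(
      site = s, season = se,
      frugivore = frugivores$frugivore[nz[, 2]],
      plant = plants$species[nz[, 1]],
      visits_per_hour = counts[nz] / config$effort,
      fruits_per_visit = fpv)
    exp_rate[[paste(s, se)]] <- exp(lograte)
  }
  list(visits = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(gamma_generalism = config$gamma_generalism,
                    gamma_migration = config$gamma_migration,
                    frug_effect = frug_eff, expected_rate = exp_rate))
}

#' Simulate an observation table for the fruit-choice model
#'
#' Generates, directly at the level the structural equation model consumes
#' (one row per frugivore x site x season), covariates and responses with
#' planted path coefficients on the standardized scale: partner diversity and
#' (zero-coded) migratory distance drive log fruit brightness of the diet,
#' and brightness drives the log nutrient intakes; chromatic coordinates are
#' pure noise. Used for sampler-recovery experiments at a known truth.
#'
#' @param n_obs Number of observation rows (sampled from the species x site x
#'   season grid without replacement).
#' @param n_species,n_sites Grid dimensions.
#' @param seasons Season names.
#' @param paths Named list of planted standardized path coefficients:
#'   `pd_a`, `mig_a`, `a_lipid`, `a_sugar`, `a_protein`, `a_anthocyanin`.
#' @param residual_sd Residual standard deviation of every equation.
#' @param re_sd Standard deviation of each random effect (phylo, species,
#'   site, season).
#' @param tree Optional bird phylogeny (default simulated).
#' @param seed Integer seed.
#' @return List with `roles` (table for [run_submodel3()]), `tree`, `truth`.
#' @export
sim_sem_data <- function(n_obs = 160, n_species = 43, n_sites = 3,
                         seasons = SEASONS,
                         paths = list(pd_a = 0.4, mig_a = -0.3,
                                      a_lipid = 0.4, a_sugar = -0.4,
                                      a_protein = 0, a_anthocyanin = -0.7),
                         residual_sd = 0.5, re_sd = 0.25, tree = NULL,
                         seed = 1) {
  set.seed(seed)
  if (is.null(tree)) tree <- sim_tree(n_species, seed = seed + 1, prefix = "b")
  sp <- tree$tip.label
  grid <- expand.grid(frugivore = sp, site = paste0("site", seq_len(n_sites)),
                      season = seasons, stringsAsFactors = FALSE)
  if (n_obs > nrow(grid)) stop("n_obs exceeds the species x site x season grid")
  grid <- grid[sample.int(nrow(grid), n_obs), ]

  C <- unclass(correlation_from_tree(tree))
  re_draw <- function(corr = NULL, q) {
    if (is.null(corr)) stats::rnorm(q, 0, re_sd)
    else drop(t(chol(corr + diag(1e-10, q))) %*% stats::rnorm(q)) * re_sd
  }
  zeta <- function() {
    re_draw(C, n_species)[match(grid$frugivore, sp)] +
      re_draw(NULL, n_species)[match(grid$frugivore, sp)] +
      re_draw(NULL, n_sites)[match(grid$site, paste0("site", seq_len(n_sites)))] +
      re_draw(NULL, length(seasons))[match(grid$season, seasons)]
  }
  n <- nrow(grid)
  z_pd <- stats::rnorm(n); z_is <- stats::rnorm(n)
  resident <- stats::runif(n_species) < 0.5
  dist <- ifelse(resident, 0, stats::rgamma(n_species, 4, scale = 5))
  grid$migratory_distance <- dist[match(grid$frugivore, sp)]
  migc <- migratory_covariate(grid$migratory_distance, grid$season, "zeroed")
  migs <- if (stats::sd(migc) > 0) (migc - mean(migc)) / stats::sd(migc) else migc

  ln_a <- paths$pd_a * z_pd + paths$mig_a * migs + zeta() +
    stats::rnorm(n, 0, residual_sd)
  ln_a_std <- as.numeric(scale(ln_a))
  nut <- function(coef) exp(-2 + coef * ln_a_std + zeta() +
                              stats::rnorm(n, 0, residual_sd))
  chroma <- function() 0.1 * (zeta() + stats::rnorm(n, 0, residual_sd))

  roles <- data.frame(grid,
                      partner_diversity = exp(-1 + 0.5 * z_pd),
                      interaction_strength = exp(-2 + 0.6 * z_is),
                      x = chroma(), y = chroma(), z = chroma(),
                      a = exp(-1 + 0.5 * ln_a),
                      lipid = nut(paths$a_lipid), sugar = nut(paths$a_sugar),
                      protein = nut(paths$a_protein),
                      anthocyanin = nut(paths$a_anthocyanin),
                      row.names = NULL)
  # planted paths re-expressed on the standardized scale the model reports
  paths_std <- list(
    pd_a = paths$pd_a / stats::sd(ln_a),
    mig_a = paths$mig_a / stats::sd(ln_a),
    a_lipid = paths$a_lipid / stats::sd(log(roles$lipid)),
    a_sugar = paths$a_sugar / stats::sd(log(roles$sugar)),
    a_protein = paths$a_protein / stats::sd(log(roles$protein)),
    a_anthocyanin = paths$a_anthocyanin / stats::sd(log(roles$anthocyanin)))
  list(roles = roles, tree = tree,
       truth = list(paths = paths, paths_std = paths_std,
                    residual_sd = residual_sd, re_sd = re_sd))
}

#' Simulate a complete study
#'
#' Bundles [sim_tree()], [sim_plant_traits()], [sim_frugivores()] and
#' [sim_networks()] under one master seed into the full input set of the
#' pipeline, with the recorded truth.
#'
#' @param config A [sim_config()].
#' @return List: `plant_tree`, `plants`, `frugivores`, `bird_tree`,
#'   `visits`, `truth`.
#' @export
sim_study <- function(config = sim_config()) {
  seed <- config$seed
  plant_tree <- sim_tree(config$n_plants, seed = seed, prefix = "p")
  pt <- sim_plant_traits(plant_tree, config, seed = seed + 1)
  fr <- sim_frugivores(config, seed = seed + 2)
  nw <- sim_networks(pt$plants, fr$frugivores, config, seed = seed + 3)
  list(plant_tree = plant_tree, plants = pt$plants,
       frugivores = fr$frugivores, bird_tree = fr$tree, visits = nw$visits,
       truth = c(pt$truth, nw$truth))
}

#' Synthesize reflectance spectra matching target colour coordinates
#'
#' Inverse mapping for simulation: given target chromatic coordinates and
#' brightness, builds a smooth reflectance spectrum from Gaussian basis
#' functions by non-negative least squares on the quantum-catch equations,
#' so that the colour-space round trip reproduces (x, y, z, a) approximately
#' (within about 0.05 for moderately saturated, mid-brightness targets; the
#' physical constraint 0 <= R <= 1 makes extreme targets infeasible).
#'
#' @param colours Data frame with columns `species`, `x`, `y`, `z`, `a`.
#' @param receptors A `receptor_set` (default blue-tit-like).
#' @return Long-format spectra data frame (`species`, `wavelength_nm`,
#'   `reflectance`).
#' @export
sim_spectra <- function(colours, receptors = make_receptors()) {
  grid <- spectral_grid()
  centres <- seq(320, 690, by = 30)
  B <- cbind(1, vapply(centres, function(m) exp(-(grid - m)^2 / (2 * 45^2)),
                       numeric(length(grid))))
  A_cone <- crossprod(receptors$S, B * .GRID_STEP)      # 4 x nb catch per basis
  A_dbl <- drop(crossprod(receptors$double, B * .GRID_STEP))
  Vb <- rbind(t(tetra_vertices()), 1)                   # barycentric inversion
  out <- lapply(seq_len(nrow(colours)), function(i) {
    rel <- solve(Vb, c(colours$x[i], colours$y[i], colours$z[i], 1))
    rel <- pmax(rel, 1e-6); rel <- rel / sum(rel)
    a <- colours$a[i]
    # match the catch ratios at unit total catch; brightness is set after
    sol <- pracma::lsqnonneg(A_cone, rel)$x
    R <- pmax(drop(B %*% sol), 0)
    # rescaling R preserves the relative catches (chroma) and moves the
    # brightness linearly onto its target; the [0, 1] clip can still bite
    # for extreme (saturated and bright) targets
    a_hat <- sum(receptors$double * R * .GRID_STEP)
    if (a_hat > 0) R <- R * (a / a_hat)
    R <- pmin(R, 1)
    data.frame(species = colours$species[i], wavelength_nm = grid,
               reflectance = R)
  })
  do.call(rbind, out)
}
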