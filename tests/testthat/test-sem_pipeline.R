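test_that("pulp-mass sub-model augments masked species near the truth", {
  cfg <- sim_config(n_plants = 100)
  tr <- sim_tree(100, seed = 101, prefix = "p")
  pt <- sim_plant_traits(tr, cfg, seed = 102, mask = c(pulp_mass = 0.2))
  sm1 <- run_submodel1(pt$plants, tr, config = quick_cfg(seed = 3))
  expect_equal(nrow(sm1$augmented), 20)
  truth <- pt$truth$masked$pulp_mass
  post_log <- colMeans(log(sm1$pulp_mass_draws[, names(truth)]))
  err <- abs(post_log - log(truth))
  expect_gte(mean(err <= 0.5), 0.8)        # within 0.5 log units for >= 80%
  expect_gte(sm1$r2$r2c, sm1$r2$r2m)
  # observed species keep their observed value exactly
  obs <- setdiff(pt$plants$species, names(truth))
  expect_equal(sm1$pulp_mass_hat[obs],
               setNames(pt$plants$pulp_mass[match(obs, pt$plants$species)],
                        obs))
  expect_error(run_submodel1(transform(pt$plants, pulp_mass = NA), tr),
               "observed pulp mass")
})

test_that("no missing pulp masses means an empty augmentation set", {
  tr <- sim_tree(25, seed = 111, prefix = "p")
  pt <- sim_plant_traits(tr, sim_config(n_plants = 25), seed = 112)
  sm1 <- run_submodel1(pt$plants, tr, config = quick_cfg(seed = 4))
  expect_equal(nrow(sm1$augmented), 0)
  expect_true("diameter" %in% sm1$summary$term)
  # allometric slope on standardized logs is strongly positive
  expect_gt(sm1$summary$estimate[sm1$summary$term == "diameter"], 0.3)
})

test_that("colour-reward model selects brightness, not chroma, at weak-cue scale", {
  hits_a <- 0; false_chroma <- 0
  for (rep in 1:10) {
    cfg <- sim_config(n_plants = 44,
                      r2_nutrient = c(lipid = 0.23, sugar = 0, protein = 0,
                                      anthocyanin = 0))
    tr <- sim_tree(44, seed = 120 + rep, prefix = "p")
    pt <- sim_plant_traits(tr, cfg, seed = 220 + rep)
    C <- correlation_from_tree(tr, pt$plants$species)
    fit <- fit_bhm(pt$plants, "lipid", c("x", "y", "z", "a"), phylo = C,
                   species = "species", log_response = TRUE,
                   config = quick_cfg(seed = 320 + rep))
    s <- shrinkage_summary(fit)
    if (s$bf[s$term == "a"] > 2) hits_a <- hits_a + 1
    false_chroma <- false_chroma +
      sum(s$bf[s$term %in% c("x", "y", "z")] > 2)
  }
  expect_gte(hits_a, 8)
  expect_lte(false_chroma / 10, 1)
})

test_that("colour-reward runs are deterministic and structured per response", {
  cfg <- sim_config(n_plants = 20)
  tr <- sim_tree(20, seed = 131, prefix = "p")
  pt <- sim_plant_traits(tr, cfg, seed = 132, mask = c(anthocyanin = 0.2))
  cols <- pt$plants[, c("species", "x", "y", "z", "a")]
  sm2a <- run_submodel2(pt$plants, cols, tr, config = quick_cfg(seed = 7))
  sm2b <- run_submodel2(pt$plants, cols, tr, config = quick_cfg(seed = 7))
  expect_identical(sm2a$summary, sm2b$summary)
  expect_equal(sort(unique(sm2a$summary$response)),
               sort(c("lipid", "sugar", "protein", "anthocyanin")))
  expect_equal(nrow(sm2a$summary), 16)
  expect_error(run_submodel2(transform(pt$plants, lipid = NA), cols, tr),
               "entirely missing")
})

test_that("sem fits the eight equations with the planted paths recoverable", {
  sd1 <- sim_sem_data(seed = 42)
  cfg <- quick_cfg(seed = 9)
  sem <- run_submodel3(sd1$roles, sd1$tree, mode = "main", config = cfg)
  p <- sem$paths
  expect_equal(sort(unique(p$response)),
               sort(c("x", "y", "z", "a", "lipid", "sugar", "protein",
                      "anthocyanin")))
  # colour equations carry 3 trait paths; intake equations add 4 colour paths
  expect_equal(sum(p$response == "x"), 3)
  expect_equal(sum(p$response == "lipid"), 7)
  get <- function(resp, term) p[p$response == resp & p$term == term, ]
  expect_true(get("a", "partner_diversity")$supported)
  expect_gt(get("a", "partner_diversity")$estimate, 0)
  expect_true(get("a", "migratory_distance")$supported)
  expect_lt(get("a", "migratory_distance")$estimate, 0)
  expect_true(get("anthocyanin", "a")$supported)
  expect_lt(get("anthocyanin", "a")$estimate, 0)
  # indirect effects follow supported chains with matching signs
  ind <- sem$indirect
  pd_ant <- ind[ind$trait == "partner_diversity" & ind$mediator == "a" &
                  ind$nutrient == "anthocyanin", ]
  expect_equal(nrow(pd_ant), 1)
  expect_lt(pd_ant$estimate, 0)            # (+) x (-) mediation
})

test_that("alternative migratory codings change the design, not the layout", {
  sd1 <- sim_sem_data(n_obs = 90, n_species = 20, seed = 43)
  cfg <- quick_cfg(chains = 2, iterations = 700, burnin = 100, thin = 2,
                   seed = 11)
  alt2 <- run_submodel3(sd1$roles, sd1$tree, mode = "alt2", config = cfg)
  expect_equal(length(unique(alt2$paths$response)), 8)
  expect_true(all(c("migration_period", "distance_x_period") %in%
                    alt2$paths$term))
  expect_equal(sum(alt2$paths$response == "x"), 5)
  alt1 <- run_submodel3(sd1$roles, sd1$tree, mode = "alt1", config = cfg)
  expect_equal(sum(alt1$paths$response == "x"), 3)
})

test_that("a single sem equation reproduces a direct engine fit seed-for-seed", {
  sd1 <- sim_sem_data(n_obs = 90, n_species = 20, seed = 44)
  cfg <- quick_cfg(chains = 2, iterations = 700, burnin = 100, thin = 2,
                   seed = 21)
  sem <- run_submodel3(sd1$roles, sd1$tree, mode = "main", config = cfg)
  dat <- sd1$roles
  dat$migratory_distance <- migratory_covariate(dat$migratory_distance,
                                                dat$season, "zeroed")
  dat$log_a <- log(dat$a)
  C <- correlation_from_tree(sd1$tree, unique(dat$frugivore))
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 100L   # equation 1 derived seed
  direct <- fit_bhm(dat, "x",
                    c("partner_diversity", "interaction_strength",
                      "migratory_distance"),
                    phylo = C, species = "frugivore", species_iid = TRUE,
                    groups = c("site", "season"),
                    log_predictors = c("partner_diversity",
                                       "interaction_strength"),
                    config = cfg1)
  expect_identical(sem$fits$x$draws, direct$draws)
})

test_that("marginal selection probabilities average the published tables correctly", {
  pub <- published_selection_summaries()
  cr <- pub[pub$model == "colour_reward", ]
  m2 <- marginal_selection(data.frame(component = cr$term, P = cr$P))
  expect_equal(unname(m2["a"]), mean(c(0.95, 0.77, 0.32, 0.97)))
  expect_equal(unname(m2["a"]), 0.7525)
  sem_rows <- pub[pub$model == "sem" &
                    pub$response %in% c("x", "y", "z", "a") &
                    pub$term %in% c("partner_diversity",
                                    "interaction_strength",
                                    "migratory_distance"), ]
  m3 <- marginal_selection(data.frame(component = sem_rows$response,
                                      P = sem_rows$P))
  expect_equal(unname(m3["a"]), mean(c(1.0, 0.22, 0.97)))
  expect_equal(unname(round(m3["a"], 2)), 0.73)
  expect_error(marginal_selection(data.frame(component = "x", P = 1)),
               "absent")
})

test_that("concordance: null indicators give a flat fit, separable give a steep one", {
  fake_sem <- function(pfun, ndraws = 1500) {
    comps <- c("x", "y", "z", "a")
    fits <- lapply(comps, function(cc) {
      pr <- pfun(cc)
      draws <- cbind(ind_partner_diversity = rbinom(ndraws, 1, pr),
                     ind_interaction_strength = rbinom(ndraws, 1, pr),
                     ind_migratory_distance = rbinom(ndraws, 1, pr))
      list(draws = draws)
    })
    names(fits) <- comps
    paths <- do.call(rbind, lapply(comps, function(cc)
      data.frame(response = cc,
                 term = c("partner_diversity", "interaction_strength",
                          "migratory_distance"),
                 P = mean(fits[[cc]]$draws))))
    structure(list(fits = fits, paths = paths), class = "sem_result")
  }
  m2 <- c(x = 0.2, y = 0.4, z = 0.35, a = 0.8)
  set.seed(51)
  flat <- concordance(m2, fake_sem(function(cc) 0.5))
  expect_lt(abs(flat$slope), 0.5)
  steep <- concordance(m2, fake_sem(function(cc)
    ifelse(m2[cc] > 0.5, 0.999, 0.001)))
  expect_gt(steep$slope, 5)
  expect_error(concordance(c(x = 0.5, y = 0.5, z = 0.5, a = 0.5),
                           fake_sem(function(cc) 0.5)), "separation")
})

test_that("monotone coupling yields a positive concordance slope", {
  set.seed(52)
  wins <- 0
  for (rep in 1:10) {
    m2 <- setNames(runif(4, 0.1, 0.9), c("x", "y", "z", "a"))
    comps <- c("x", "y", "z", "a")
    fits <- lapply(comps, function(cc)
      list(draws = cbind(ind_pd = rbinom(800, 1, plogis(-2 + 4 * m2[cc])),
                         ind_is = rbinom(800, 1, plogis(-2 + 4 * m2[cc])),
                         ind_md = rbinom(800, 1, plogis(-2 + 4 * m2[cc])))))
    names(fits) <- comps
    paths <- do.call(rbind, lapply(comps, function(cc)
      data.frame(response = cc, term = c("pd", "is", "md"),
                 P = mean(fits[[cc]]$draws))))
    sem <- structure(list(fits = fits, paths = paths), class = "sem_result")
    if (concordance(m2, sem)$slope > 0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("four-point concordance on the published marginals matches the printed line", {
  pub <- published_selection_summaries()
  cr <- pub[pub$model == "colour_reward", ]
  m2 <- marginal_selection(data.frame(component = cr$term, P = cr$P))
  sem_rows <- pub[pub$model == "sem" &
                    pub$response %in% c("x", "y", "z", "a") &
                    pub$term %in% c("partner_diversity",
                                    "interaction_strength",
                                    "migratory_distance"), ]
  m3 <- marginal_selection(data.frame(component = sem_rows$response,
                                      P = sem_rows$P))
  cc <- concordance(m2, m3)
  expect_equal(cc$intercept, -2.4, tolerance = 0.05)
  expect_equal(cc$slope, 4.6, tolerance = 0.05)
})
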