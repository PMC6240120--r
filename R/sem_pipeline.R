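# Orchestration of the three hierarchical sub-models (pulp-mass imputation;
# colour-reward; fruit-choice structural equation model), the alternative
# migratory-distance codings, and the selection-probability concordance
# analysis.

.NUTRIENTS <- c("lipid", "sugar", "protein", "anthocyanin")
.COLOUR_COMPONENTS <- c("x", "y", "z", "a")

#' Sub-model 1: pulp-mass imputation
#'
#' Fits `ln(pulp mass) ~ ln(fruit diameter)` with a phylogenetic random
#' effect. Species with missing pulp mass are augmented within the sampler;
#' their posterior draws propagate pulp-mass uncertainty into the diet
#' nutrient profiles downstream.
#'
#' @param plants Data frame with `species`, `diameter`, `pulp_mass`
#'   (`NA` allowed in `pulp_mass` only).
#' @param tree Plant phylogeny covering all species.
#' @param config An [mcmc_config()].
#' @param selection Subject the allometric slope to indicator selection
#'   (default FALSE: the slope is always in the model).
#' @return List of class `submodel_result`: `fit`, `summary`
#'   (selection/shrinkage table), `r2`, `augmented` (data frame of augmented
#'   species with posterior mean and CI on the natural scale),
#'   `pulp_mass_hat` (named vector: observed values, posterior means where
#'   missing), `pulp_mass_draws` (draws x species matrix, natural scale).
#' @export
run_submodel1 <- function(plants, tree, config = mcmc_config(),
                          selection = FALSE) {
  plants <- as.data.frame(plants)
  if (anyNA(plants$diameter)) stop("diameters must be present for all plants")
  if (all(is.na(plants$pulp_mass)))
    stop("no species with observed pulp mass")
  C <- correlation_from_tree(tree, plants$species)
  fit <- fit_bhm(plants, response = "pulp_mass", predictors = "diameter",
                 selectable = if (selection) "diameter" else character(),
                 phylo = C, species = "species",
                 log_response = TRUE, log_predictors = "diameter",
                 config = config)
  res <- .submodel_result(fit, response = "pulp_mass")
  mis <- fit$missing_rows
  draws <- matrix(log(plants$pulp_mass[!seq_len(nrow(plants)) %in% mis]),
                  nrow(fit$draws), sum(!is.na(plants$pulp_mass)),
                  byrow = TRUE)
  colnames(draws) <- plants$species[setdiff(seq_len(nrow(plants)), mis)]
  if (length(mis)) {
    md <- fit$draws[, paste0("ymis_", mis), drop = FALSE] *
      fit$scale$y_scale + fit$scale$y_center
    colnames(md) <- plants$species[mis]
    draws <- cbind(draws, md)
  }
  draws <- exp(draws[, plants$species, drop = FALSE])
  hat <- colMeans(draws)
  aug <- if (length(mis)) {
    ci <- apply(draws[, plants$species[mis], drop = FALSE], 2,
                stats::quantile, c(0.025, 0.975))
    data.frame(species = plants$species[mis],
               posterior_mean = hat[plants$species[mis]],
               ci_lower = ci[1, ], ci_upper = ci[2, ], row.names = NULL)
  } else data.frame(species = character(), posterior_mean = numeric(),
                    ci_lower = numeric(), ci_upper = numeric())
  res$augmented <- aug
  res$pulp_mass_hat <- hat
  res$pulp_mass_draws <- draws
  res
}

.submodel_result <- function(fit, response) {
  s <- shrinkage_summary(fit)
  s <- cbind(response = response, s)
  structure(list(fit = fit, summary = s, r2 = r_squared(fit)),
            class = "submodel_result")
}

#' @export
print.submodel_result <- function(x, ...) {
  cat("Hierarchical sub-model result\n")
  print(x$summary, digits = 3)
  cat(sprintf("  r2m = %.3f, r2c = %.3f\n", x$r2$r2m, x$r2$r2c))
  invisible(x)
}

#' Sub-model 2: colour-reward relationships
#'
#' Four selection-enabled regressions of the log nutrient concentrations
#' (lipid, sugar, protein, anthocyanin) on the colour coordinates (x, y, z)
#' and brightness (a), each with a phylogenetic random effect; missing
#' nutrient values are augmented.
#'
#' @param plants Data frame with `species` and the four nutrient columns
#'   (`NA` allowed).
#' @param colours Data frame `species, x, y, z, a` (complete).
#' @param tree Plant phylogeny.
#' @param config An [mcmc_config()]; equation e uses `seed + 100 * e`.
#' @return List of class `colour_reward_result`: `fits` (one `bhm_fit` per
#'   nutrient), `summary` (stacked selection table), `r2` (per response).
#' @export
run_submodel2 <- function(plants, colours, tree, config = mcmc_config()) {
  plants <- as.data.frame(plants)[, c("species", .NUTRIENTS)]
  dat <- cbind(plants,
               colours[match(plants$species, colours$species),
                       .COLOUR_COMPONENTS, drop = FALSE])
  if (anyNA(dat[, .COLOUR_COMPONENTS]))
    stop("colour coordinates must be present for all plants")
  C <- correlation_from_tree(tree, dat$species)
  fits <- list(); summaries <- list(); r2 <- list()
  for (e in seq_along(.NUTRIENTS)) {
    nu <- .NUTRIENTS[e]
    if (all(is.na(dat[[nu]]))) stop("nutrient entirely missing: ", nu)
    cfg <- config; cfg$seed <- config$seed + 100L * e
    fit <- fit_bhm(dat, response = nu, predictors = .COLOUR_COMPONENTS,
                   phylo = C, species = "species", log_response = TRUE,
                   config = cfg)
    fits[[nu]] <- fit
    summaries[[nu]] <- cbind(response = nu, shrinkage_summary(fit))
    r2[[nu]] <- r_squared(fit)[c("r2m", "r2c")]
  }
  structure(list(fits = fits, summary = do.call(rbind, summaries), r2 = r2,
                 species = dat$species),
            class = "colour_reward_result")
}

#' Sub-model 3: fruit-choice structural equation model
#'
#' Eight response equations fitted in one seeded sampler run: each colour
#' component of the diet profile (x, y, z and log brightness a) on partner
#' diversity, interaction strength and the seasonally coded migratory
#' distance; and each log nutrient intake on those three frugivore traits
#' plus the four colour components. Partner diversity, interaction strength,
#' brightness and the intakes are log-transformed; chromatic coordinates
#' (which can be negative) are not. Every equation carries phylogenetic,
#' species, site and season random effects.
#'
#' @param roles Observation table from [frugivore_roles()] or
#'   [sim_sem_data()]: one row per (frugivore, site, season) with columns
#'   `frugivore, site, season, migratory_distance, partner_diversity,
#'   interaction_strength, x, y, z, a` and the four intakes.
#' @param tree Bird phylogeny covering all frugivores.
#' @param mode `"main"` (distance zeroed outside summer/autumn), `"alt1"`
#'   (raw distance), `"alt2"` (distance, period, interaction).
#' @param config An [mcmc_config()]; equation e uses `seed + 100 * e`.
#' @return List of class `sem_result`: `paths` (stacked path table),
#'   `fits`, `r2`, `mode`, `indirect` (products of supported path draws).
#' @export
run_submodel3 <- function(roles, tree, mode = c("main", "alt1", "alt2"),
                          config = mcmc_config()) {
  mode <- match.arg(mode)
  roles <- as.data.frame(roles)
  need <- c("frugivore", "site", "season", "migratory_distance",
            "partner_diversity", "interaction_strength",
            .COLOUR_COMPONENTS, .NUTRIENTS)
  miss <- setdiff(need, names(roles))
  if (length(miss)) stop("missing role metric column(s): ",
                         paste(miss, collapse = ", "))
  coding <- switch(mode, main = "zeroed", alt1 = "raw",
                   alt2 = "period_interaction")
  dat <- roles
  if (coding == "period_interaction") {
    dat$migration_period <- as.numeric(dat$season %in% c("summer", "autumn"))
    dat$distance_x_period <- dat$migratory_distance * dat$migration_period
    trait_terms <- c("partner_diversity", "interaction_strength",
                     "migratory_distance", "migration_period",
                     "distance_x_period")
  } else {
    dat$migratory_distance <-
      migratory_covariate(dat$migratory_distance, dat$season, coding)
    trait_terms <- c("partner_diversity", "interaction_strength",
                     "migratory_distance")
  }
  dat$log_a <- log(dat$a)
  C <- correlation_from_tree(tree, unique(dat$frugivore))
  logged_preds <- c("partner_diversity", "interaction_strength")

  responses <- c(.COLOUR_COMPONENTS, .NUTRIENTS)
  fits <- list(); paths <- list(); r2 <- list()
  for (e in seq_along(responses)) {
    resp <- responses[e]
    is_nut <- resp %in% .NUTRIENTS
    preds <- if (is_nut) c(trait_terms, "x", "y", "z", "log_a")
             else trait_terms
    yname <- if (resp == "a") "log_a" else resp
    cfg <- config; cfg$seed <- config$seed + 100L * e
    fit <- fit_bhm(dat, response = yname, predictors = preds,
                   phylo = C, species = "frugivore", species_iid = TRUE,
                   groups = c("site", "season"),
                   log_response = is_nut,
                   log_predictors = logged_preds,
                   config = cfg)
    fits[[resp]] <- fit
    s <- shrinkage_summary(fit)
    s$term[s$term == "log_a"] <- "a"
    paths[[resp]] <- cbind(response = resp, s)
    r2[[resp]] <- r_squared(fit)[c("r2m", "r2c", "shares")]
  }
  paths <- do.call(rbind, paths)
  structure(list(paths = paths, fits = fits, r2 = r2, mode = mode,
                 indirect = .indirect_effects(paths, fits)),
            class = "sem_result")
}

# Indirect effects: products of posterior path draws along supported
# trait -> colour-component -> nutrient chains.
.indirect_effects <- function(paths, fits) {
  sup <- paths[paths$supported, ]
  first <- sup[sup$response %in% .COLOUR_COMPONENTS, ]
  second <- sup[sup$response %in% .NUTRIENTS &
                  sup$term %in% .COLOUR_COMPONENTS, ]
  out <- list()
  theta_draws <- function(fit, term) {
    tn <- if (term == "a") "log_a" else term
    fit$draws[, paste0("beta_", tn)] * fit$draws[, paste0("ind_", tn)]
  }
  for (i in seq_len(nrow(first))) for (k in seq_len(nrow(second))) {
    if (second$term[k] != first$response[i]) next
    d1 <- theta_draws(fits[[first$response[i]]], first$term[i])
    d2 <- theta_draws(fits[[second$response[k]]], second$term[k])
    pr <- d1 * d2
    ci <- stats::quantile(pr, c(0.025, 0.975), names = FALSE)
    out[[length(out) + 1]] <- data.frame(
      trait = first$term[i], mediator = first$response[i],
      nutrient = second$response[k], estimate = mean(pr),
      ci_lower = ci[1], ci_upper = ci[2])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(trait = character(), mediator = character(),
                  nutrient = character(), estimate = numeric(),
                  ci_lower = numeric(), ci_upper = numeric())
}

#' Marginal selection probability of each colour component
#'
#' For the colour-reward model: the mean inclusion probability of each colour
#' component across the four nutrient responses. For the fruit-choice SEM:
#' the mean inclusion probability of the frugivore-trait predictors within
#' each colour component's own equation.
#'
#' @param result A `colour_reward_result` or `sem_result`, or a data frame
#'   with columns `component` and `P` (averaged per component).
#' @return Named numeric vector over components x, y, z, a.
#' @export
marginal_selection <- function(result) UseMethod("marginal_selection")

#' @export
marginal_selection.colour_reward_result <- function(result) {
  s <- result$summary
  vapply(.COLOUR_COMPONENTS, function(cc)
    mean(s$P[s$term == cc]), 0)
}

#' @export
marginal_selection.sem_result <- function(result) {
  s <- result$paths
  trait_terms <- setdiff(unique(s$term[s$response %in% .COLOUR_COMPONENTS]),
                         .COLOUR_COMPONENTS)
  vapply(.COLOUR_COMPONENTS, function(cc) {
    sub <- s[s$response == cc & s$term %in% trait_terms, ]
    if (!nrow(sub)) stop("component absent: ", cc)
    mean(sub$P)
  }, 0)
}

#' @export
marginal_selection.default <- function(result) {
  df <- as.data.frame(result)
  if (!all(c("component", "P") %in% names(df)))
    stop("need columns `component` and `P`")
  out <- vapply(.COLOUR_COMPONENTS, function(cc) {
    v <- df$P[df$component == cc]
    if (!length(v)) stop("component absent: ", cc)
    mean(v)
  }, 0)
  out
}

#' Concordance of colour-component selection between the two models
#'
#' Tests whether the colour components that indicate rewards across plants
#' are the same ones that mediate fruit choice: logistic regression of the
#' SEM's draw-level frugivore-trait inclusion indicators (pooled within each
#' colour component's equation) on the colour-reward marginal selection
#' probability of the matching component. A four-point probability-level
#' fit is used when only marginals are supplied.
#'
#' @param m2 Named marginal selection probabilities from the colour-reward
#'   model ([marginal_selection()] on a `colour_reward_result`).
#' @param m3 A `sem_result` (draw-level fit, default) or named marginal
#'   probabilities (four-point fallback fit).
#' @return List of class `concordance_result`: `points` (per component: the
#'   two marginals), `intercept`, `slope`, `quasi_separation` flag.
#' @export
concordance <- function(m2, m3) {
  m2 <- m2[.COLOUR_COMPONENTS]
  if (length(unique(round(m2, 10))) < 2)
    stop("fewer than two distinct probability values: separation")
  if (inherits(m3, "sem_result")) {
    sem_marg <- marginal_selection(m3)
    bits <- list(); xs <- list()
    for (cc in .COLOUR_COMPONENTS) {
      fit <- m3$fits[[cc]]
      icol <- grep("^ind_", colnames(fit$draws), value = TRUE)
      b <- as.vector(fit$draws[, icol])
      bits[[cc]] <- b
      xs[[cc]] <- rep(m2[cc], length(b))
    }
    y <- unlist(bits); x <- unlist(xs)
    gl <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    quasi <- !gl$converged || any(abs(stats::coef(gl)) > 20)
  } else {
    sem_marg <- m3[.COLOUR_COMPONENTS]
    gl <- suppressWarnings(
      stats::glm(cbind(round(sem_marg * 1000), round((1 - sem_marg) * 1000)) ~
                   m2, family = stats::binomial()))
    quasi <- !gl$converged || any(abs(stats::coef(gl)) > 20)
  }
  structure(list(points = data.frame(component = .COLOUR_COMPONENTS,
                                     colour_reward_P = as.numeric(m2),
                                     sem_P = as.numeric(sem_marg)),
                 intercept = unname(stats::coef(gl)[1]),
                 slope = unname(stats::coef(gl)[2]),
                 quasi_separation = quasi),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance logistic fit: y = %.2f + %.2f x%s\n",
              x$intercept, x$slope,
              if (x$quasi_separation) " (quasi-separation)" else ""))
  print(x$points, digits = 3)
  invisible(x)
}

#' Run the full pipeline on a simulated or assembled study
#'
#' Executes sub-models 1 -> 2 -> 3 and the concordance analysis on the
#' inputs of a study bundle (e.g. [sim_study()]): builds the consumption
#' networks, computes roles and diet profiles (using sub-model 1's posterior
#' mean pulp masses), and fits the colour-reward and fruit-choice models.
#'
#' @param study List with `plants`, `plant_tree`, `frugivores`, `bird_tree`,
#'   `visits` (as returned by [sim_study()]).
#' @param mode Migratory-distance coding mode for the SEM.
#' @param config An [mcmc_config()] applied to every sub-model (per-equation
#'   seeds are derived from its seed).
#' @return List of class `pipeline_result`: `submodel1`, `submodel2`, `sem`,
#'   `concordance`, `roles`, `networks`, `manifest`.
#' @export
run_pipeline <- function(study, mode = "main", config = mcmc_config()) {
  sm1 <- run_submodel1(study$plants, study$plant_tree, config = config)
  colours <- study$plants[, c("species", .COLOUR_COMPONENTS)]
  sm2 <- run_submodel2(study$plants, colours, study$plant_tree,
                       config = config)
  nets <- build_networks(study$visits, mode = "consumption")
  nutrients <- study$plants[, c("species", .NUTRIENTS)]
  if (anyNA(nutrients[, .NUTRIENTS])) {
    # fill augmented nutrients with their posterior means from sub-model 2
    for (nu in .NUTRIENTS) {
      fit <- sm2$fits[[nu]]
      if (!length(fit$missing_rows)) next
      md <- fit$draws[, paste0("ymis_", fit$missing_rows), drop = FALSE] *
        fit$scale$y_scale + fit$scale$y_center
      aug_sp <- sm2$species[fit$missing_rows]
      nutrients[[nu]][match(aug_sp, nutrients$species)] <- colMeans(exp(md))
    }
  }
  roles <- frugivore_roles(nets, study$frugivores, colours, nutrients,
                           sm1$pulp_mass_hat)
  sem <- run_submodel3(roles, study$bird_tree, mode = mode, config = config)
  conc <- concordance(marginal_selection(sm2), sem)
  structure(list(submodel1 = sm1, submodel2 = sm2, sem = sem,
                 concordance = conc, roles = roles, networks = nets,
                 manifest = list(seed = config$seed, mode = mode,
                                 chains = config$chains,
                                 iterations = config$iterations,
                                 burnin = config$burnin, thin = config$thin,
                                 n_obs = nrow(roles))),
            class = "pipeline_result")
}
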