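# Seasonal plant-frugivore networks, frugivore role metrics, and
# interaction-weighted diet colour / nutrient profiles.

SEASONS <- c("spring", "summer", "autumn", "winter")

.check_visits <- function(visits) {
  need <- c("site", "season", "frugivore", "plant", "visits_per_hour")
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("visit table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(visits$season %in% SEASONS))
    stop("season must be one of: ", paste(SEASONS, collapse = ", "))
  v <- visits$visits_per_hour
  if (any(!is.finite(v)) || any(v < 0))
    stop("visitation rates must be finite and >= 0")
  if (!"fruits_per_visit" %in% names(visits))
    visits$fruits_per_visit <- NA_real_
  fpv <- visits$fruits_per_visit
  if (any(fpv[!is.na(fpv)] < 0)) stop("per-visit consumption must be >= 0")
  visits
}

#' Build seasonal consumption networks from visit records
#'
#' One network per observed (site, season). In `"consumption"` mode the cell
#' rate is visitation rate x fruits per visit (fruits per hour); missing
#' per-visit rates are filled by an imputation ladder: (1) the observed
#' per-visit rate of the same plant-frugivore pair at another site, (2) the
#' mean per-visit rate of that frugivore over other plants, (3) the global
#' mean per-visit rate over all frugivores. In `"visitation"` mode the
#' visitation rates are used directly. Each cell carries a provenance flag.
#'
#' @param visits Data frame with columns `site`, `season`, `frugivore`,
#'   `plant`, `visits_per_hour` and (for consumption mode) `fruits_per_visit`
#'   with `NA` where unobserved.
#' @param mode `"consumption"` (default) or `"visitation"`.
#' @return List of `seasonal_network` objects, each a list with `site`,
#'   `season`, `f` (plants x frugivores rate matrix) and `provenance`
#'   (character matrix of the same shape).
#' @export
build_networks <- function(visits, mode = c("consumption", "visitation")) {
  mode <- match.arg(mode)
  visits <- .check_visits(as.data.frame(visits))

  if (mode == "consumption") {
    obs <- !is.na(visits$fruits_per_visit)
    if (!any(obs))
      stop("all per-visit rates missing: imputation ladder exhausted")
    pair_key <- paste(visits$frugivore, visits$plant, sep = "\r")
    pair_mean <- tapply(visits$fruits_per_visit[obs], pair_key[obs], mean)
    frug_mean <- tapply(visits$fruits_per_visit[obs], visits$frugivore[obs], mean)
    global_mean <- mean(frug_mean)   # mean over frugivore species means
    fpv <- visits$fruits_per_visit
    prov <- ifelse(obs, "observed", NA_character_)
    for (i in which(!obs)) {
      if (!is.na(pm <- pair_mean[pair_key[i]])) {
        fpv[i] <- pm; prov[i] <- "imputed-pair"
      } else if (!is.na(fm <- frug_mean[visits$frugivore[i]])) {
        fpv[i] <- fm; prov[i] <- "imputed-frugivore-mean"
      } else {
        fpv[i] <- global_mean; prov[i] <- "imputed-global-mean"
      }
    }
    rate <- visits$visits_per_hour * fpv
  } else {
    rate <- visits$visits_per_hour
    prov <- rep("observed", nrow(visits))
  }

  keys <- unique(visits[, c("site", "season")])
  nets <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sel <- visits$site == keys$site[k] & visits$season == keys$season[k]
    sub <- visits[sel, ]
    plants <- sort(unique(sub$plant))
    frugs <- sort(unique(sub$frugivore))
    f <- matrix(0, length(plants), length(frugs),
                dimnames = list(plants, frugs))
    pv <- matrix(NA_character_, length(plants), length(frugs),
                 dimnames = list(plants, frugs))
    idx <- cbind(match(sub$plant, plants), match(sub$frugivore, frugs))
    # aggregate duplicate records by summing rates
    for (r in seq_len(nrow(sub))) {
      f[idx[r, 1], idx[r, 2]] <- f[idx[r, 1], idx[r, 2]] + rate[sel][r]
      pv[idx[r, 1], idx[r, 2]] <- prov[sel][r]
    }
    drop_j <- colSums(f) == 0
    if (any(drop_j)) {
      warning(sprintf("dropping %d zero-consumption frugivore(s) from network %s/%s",
                      sum(drop_j), keys$site[k], keys$season[k]))
      f <- f[, !drop_j, drop = FALSE]
      pv <- pv[, !drop_j, drop = FALSE]
    }
    nets[[k]] <- structure(list(site = keys$site[k], season = keys$season[k],
                                f = f, provenance = pv),
                           class = "seasonal_network")
  }
  nets
}

#' @export
print.seasonal_network <- function(x, ...) {
  cat(sprintf("Seasonal network %s/%s: %d plants x %d frugivores, total rate %.3g/h\n",
              x$site, x$season, nrow(x$f), ncol(x$f), sum(x$f)))
  invisible(x)
}

.net_col <- function(net, frugivore) {
  stopifnot(inherits(net, "seasonal_network"))
  if (!frugivore %in% colnames(net$f))
    stop(sprintf("frugivore '%s' absent from network %s/%s", frugivore,
                 net$site, net$season))
  stats::setNames(net$f[, frugivore], rownames(net$f))
}

#' Partner diversity (relative niche breadth) of a frugivore
#'
#' The effective number of plant species consumed, exp of the Shannon entropy
#' of the frugivore's interaction frequencies (natural log), standardized by
#' the number of plant species available in that network, so the value lies
#' in (0, 1].
#'
#' @param net A `seasonal_network`.
#' @param frugivore Frugivore species name (column of the network).
#' @return Scalar in (0, 1].
#' @export
partner_diversity <- function(net, frugivore) {
  fj <- .net_col(net, frugivore)
  tot <- sum(fj)
  if (tot <= 0) stop("frugivore has zero total consumption in this network")
  p <- fj[fj > 0] / tot
  H <- -sum(p * log(p))
  exp(H) / nrow(net$f)
}

#' Interaction strength of a frugivore
#'
#' The frugivore's share of total fruit removal in the network; sums to 1
#' over the frugivores of one network.
#'
#' @inheritParams partner_diversity
#' @return Scalar in [0, 1].
#' @export
interaction_strength <- function(net, frugivore) {
  tot <- sum(net$f)
  if (tot <= 0) stop("empty network: total consumption is zero")
  sum(.net_col(net, frugivore)) / tot
}

#' Interaction-weighted mean colour profile of a frugivore's diet
#'
#' Componentwise weighted mean of the consumed plants' colour coordinates,
#' weights proportional to the interaction frequencies f_ij.
#'
#' @inheritParams partner_diversity
#' @param colours Data frame with columns `species`, `x`, `y`, `z`, `a`.
#' @return Named vector `c(x, y, z, a)`.
#' @export
diet_colour_profile <- function(net, colours, frugivore) {
  fj <- .net_col(net, frugivore)
  consumed <- names(fj)[fj > 0]
  miss <- setdiff(consumed, colours$species)
  if (length(miss))
    stop("consumed plants lacking colours: ", paste(miss, collapse = ", "))
  C <- as.matrix(colours[match(consumed, colours$species),
                         c("x", "y", "z", "a")])
  w <- fj[consumed] / sum(fj[consumed])
  stats::setNames(as.numeric(w %*% C), c("x", "y", "z", "a"))
}

#' Interaction- and mass-weighted mean nutrient intake of a frugivore
#'
#' Mean intake of each nutrient per gram dry pulp mass:
#' n_bar_j = sum_i(n_i m_i f_ij) / sum_i(m_i f_ij).
#'
#' @inheritParams partner_diversity
#' @param nutrients Data frame with column `species` and one column per
#'   nutrient (concentration per g dry pulp).
#' @param pulp_mass Named numeric vector of pulp dry mass per fruit (g),
#'   names are plant species. May come from posterior draws of the pulp-mass
#'   imputation sub-model.
#' @return Named vector, one weighted mean per nutrient column.
#' @export
diet_nutrient_intake <- function(net, nutrients, pulp_mass, frugivore) {
  fj <- .net_col(net, frugivore)
  consumed <- names(fj)[fj > 0]
  miss <- setdiff(consumed, nutrients$species)
  if (length(miss))
    stop("consumed plants lacking nutrients: ", paste(miss, collapse = ", "))
  m <- pulp_mass[consumed]
  if (any(is.na(m)))
    stop("missing pulp mass (no augmentation source) for: ",
         paste(consumed[is.na(m)], collapse = ", "))
  N <- as.matrix(nutrients[match(consumed, nutrients$species),
                           setdiff(names(nutrients), "species"), drop = FALSE])
  if (any(is.na(N)))
    stop("missing nutrient values for consumed plants: ",
         paste(consumed[rowSums(is.na(N)) > 0], collapse = ", "))
  w <- m * fj[consumed]
  stats::setNames(as.numeric((w / sum(w)) %*% N), colnames(N))
}

#' Seasonal coding of migratory distance
#'
#' `"zeroed"` (default analysis): the latitudinal migratory distance enters
#' only during the pre-migration and migration periods (summer, autumn) and
#' is set to zero in winter and spring. `"raw"`: the distance always enters.
#' `"period_interaction"`: returns the raw distance, a migration-period
#' indicator, and their product.
#'
#' @param distance Migratory distance (degrees latitude, >= 0); residents 0.
#' @param season Season name.
#' @param mode Coding mode.
#' @return Scalar (`zeroed`, `raw`) or named length-3 vector
#'   (`period_interaction`).
#' @export
migratory_covariate <- function(distance, season,
                                mode = c("zeroed", "raw", "period_interaction")) {
  mode <- match.arg(mode)
  if (any(distance < 0)) stop("migratory distance must be >= 0")
  if (!all(season %in% SEASONS))
    stop("season must be one of: ", paste(SEASONS, collapse = ", "))
  period <- as.numeric(season %in% c("summer", "autumn"))
  switch(mode,
         zeroed = distance * period,
         raw = distance,
         period_interaction = c(distance = distance, period = period,
                                interaction = distance * period))
}

#' Per-network frugivore roles and diet profiles
#'
#' Computes, for every frugivore in every seasonal network, partner
#' diversity, interaction strength, the seasonally coded migratory covariate,
#' the diet colour profile and the diet nutrient intakes -- the observation
#' table of the fruit-choice structural equation model.
#'
#' @param networks List of `seasonal_network` from [build_networks()].
#' @param frugivores Data frame with columns `frugivore` and
#'   `migratory_distance` (degrees latitude; residents 0).
#' @param colours Data frame `species, x, y, z, a` (per plant).
#' @param nutrients Data frame `species` + nutrient columns (per plant).
#' @param pulp_mass Named vector of pulp dry mass per plant species.
#' @param migratory_coding Passed to [migratory_covariate()].
#' @return Tidy data frame, one row per (site, season, frugivore).
#' @export
frugivore_roles <- function(networks, frugivores, colours, nutrients,
                            pulp_mass,
                            migratory_coding = c("zeroed", "raw",
                                                 "period_interaction")) {
  migratory_coding <- match.arg(migratory_coding)
  rows <- list()
  for (net in networks) {
    for (j in colnames(net$f)) {
      md <- frugivores$migratory_distance[match(j, frugivores$frugivore)]
      if (is.na(md))
        stop(sprintf("frugivore '%s' missing from the frugivore table", j))
      cc <- diet_colour_profile(net, colours, j)
      ni <- diet_nutrient_intake(net, nutrients, pulp_mass, j)
      mig <- migratory_covariate(md, net$season, migratory_coding)
      row <- data.frame(site = net$site, season = net$season, frugivore = j,
                        partner_diversity = partner_diversity(net, j),
                        interaction_strength = interaction_strength(net, j),
                        t(cc), t(ni), row.names = NULL, check.names = FALSE)
      if (migratory_coding == "period_interaction") {
        row$migratory_distance <- mig[["distance"]]
        row$migration_period <- mig[["period"]]
        row$distance_x_period <- mig[["interaction"]]
      } else {
        row$migratory_distance <- as.numeric(mig)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Read an interaction CSV
#'
#' Expects columns `site, season, frugivore, plant, visits_per_hour` and
#' optionally `fruits_per_visit`.
#'
#' @param path File path.
#' @return Data frame of visit records.
#' @export
read_interactions <- function(path) .check_visits(utils::read.csv(path))

#' Write the tidy roles/profiles table to CSV
#'
#' @param roles Output of [frugivore_roles()].
#' @param path File path.
#' @export
write_roles <- function(roles, path) utils::write.csv(roles, path,
                                                      row.names = FALSE)
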