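# Shared fixtures: all built in code, no stored data beyond the bundled
# published summaries.

quick_cfg <- function(chains = 2, iterations = 1500, burnin = 250, thin = 5,
                      seed = 1) {
  mcmc_config(chains = chains, iterations = iterations, burnin = burnin,
              thin = thin, seed = seed)
}

# a minimal seasonal network without going through build_networks()
toy_network <- function(f, site = "s1", season = "autumn") {
  structure(list(site = site, season = season, f = f, provenance = NULL),
            class = "seasonal_network")
}

# a hand-assembled bhm_fit carrying only what summaries need
fake_fit <- function(draws, chain, X = NULL, predictors = character(),
                     selectable = character(), re_names = character()) {
  structure(list(draws = draws, chain = chain, X = X,
                 predictors = predictors, selectable = selectable,
                 re_names = re_names, missing_rows = integer(),
                 control = bhm_control(),
                 config = quick_cfg()),
            class = "bhm_fit")
}

# data with a phylogenetic and a residual variance component (2 obs/species)
sim_phylo_dataset <- function(n_tips = 100, sigma2_a = 1, sigma2_e = 1,
                              n_rep = 2, seed = 1) {
  tree <- sim_tree(n_tips, seed = seed)
  C <- correlation_from_tree(tree)
  L <- t(chol(unclass(C) + diag(1e-10, n_tips)))
  set.seed(seed + 4000)
  a <- sqrt(sigma2_a) * drop(L %*% rnorm(n_tips))
  dat <- data.frame(species = rep(tree$tip.label, n_rep))
  dat$y <- a[match(dat$species, tree$tip.label)] +
    rnorm(n_tips * n_rep, 0, sqrt(sigma2_e))
  list(data = dat, tree = tree, C = C)
}
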