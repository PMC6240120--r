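test_that("consumption networks apply the imputation ladder in order", {
  v <- data.frame(
    site = c("s1", "s1", "s1", "s2", "s1"),
    season = "autumn",
    frugivore = c("f1", "f1", "f1", "f1", "f2"),
    plant = c("p1", "p2", "p3", "p3", "p1"),
    visits_per_hour = c(3, 1, 1, 2, 2),
    fruits_per_visit = c(2, 4, NA, 5, NA))
  nets <- build_networks(v, mode = "consumption")
  n1 <- nets[[which(vapply(nets, function(n) n$site, "") == "s1")]]
  # observed pair: 3 visits/h x 2 fruits/visit
  expect_equal(n1$f["p1", "f1"], 6)
  expect_equal(n1$provenance["p1", "f1"], "observed")
  # ladder step 1: same pair observed at the other site (5 fruits/visit)
  expect_equal(n1$f["p3", "f1"], 1 * 5)
  expect_equal(n1$provenance["p3", "f1"], "imputed-pair")
  # ladder step 3: f2 has no observed rates anywhere -> global frugivore mean
  # f1 species mean = mean(2, 4, 5); global mean over frugivore means = same
  expect_equal(n1$f["p1", "f2"], 2 * mean(c(2, 4, 5)))
  expect_equal(n1$provenance["p1", "f2"], "imputed-global-mean")
})

test_that("frugivore-mean imputation averages the frugivore's other plants", {
  v <- data.frame(site = "s1", season = "autumn", frugivore = "f1",
                  plant = c("p1", "p2", "p3"),
                  visits_per_hour = c(3, 1, 1),
                  fruits_per_visit = c(2, 4, NA))
  net <- build_networks(v)[[1]]
  expect_equal(net$f["p3", "f1"], 1 * 3)     # mean(2, 4) = 3 fruits/visit
  expect_equal(net$provenance["p3", "f1"], "imputed-frugivore-mean")
  expect_error(build_networks(transform(v, fruits_per_visit = NA)),
               "exhausted")
})

test_that("visitation mode passes rates through unchanged", {
  v <- data.frame(site = "s1", season = "winter", frugivore = "f1",
                  plant = c("p1", "p2"), visits_per_hour = c(2.5, 1),
                  fruits_per_visit = c(NA, NA))
  net <- build_networks(v, mode = "visitation")[[1]]
  expect_equal(unname(net$f[, "f1"]), c(2.5, 1))
})

test_that("partner diversity matches the Shannon-exponent formula", {
  f <- matrix(0, 8, 1, dimnames = list(paste0("p", 1:8), "f1"))
  f[1:4, 1] <- 2
  expect_equal(partner_diversity(toy_network(f), "f1"), 0.5)
  f10 <- matrix(0, 10, 1, dimnames = list(paste0("p", 1:10), "f1"))
  f10[1, 1] <- 7
  expect_equal(partner_diversity(toy_network(f10), "f1"), 0.1)
  f2 <- matrix(c(3, 1), 2, 1, dimnames = list(c("p1", "p2"), "f1"))
  expect_equal(partner_diversity(toy_network(f2), "f1"),
               exp(-0.75 * log(0.75) - 0.25 * log(0.25)) / 2)
  expect_equal(partner_diversity(toy_network(f2), "f1"), 0.8773827,
               tolerance = 1e-6)
  expect_error(partner_diversity(toy_network(f2), "nope"), "absent")
})

test_that("interaction strengths are removal shares summing to one", {
  f <- matrix(c(20, 10, 8, 2), 2, 2,
              dimnames = list(c("p1", "p2"), c("f1", "f2")))
  net <- toy_network(f)
  expect_equal(interaction_strength(net, "f1"), 0.75)
  expect_equal(interaction_strength(net, "f2"), 0.25)
  expect_equal(sum(vapply(colnames(f), interaction_strength, 0, net = net)), 1)
  sole <- toy_network(f[, 1, drop = FALSE])
  expect_equal(interaction_strength(sole, "f1"), 1)
})

test_that("diet colour profile is the f-weighted mean and scale invariant", {
  f <- matrix(c(1, 3), 2, 1, dimnames = list(c("p1", "p2"), "f1"))
  cols <- data.frame(species = c("p1", "p2"), x = c(0.1, -0.1),
                     y = c(0, 0.2), z = c(0.3, 0.3), a = c(0.2, 0.6))
  prof <- diet_colour_profile(toy_network(f), cols, "f1")
  expect_equal(unname(prof["a"]), 0.5)               # (0.2*1 + 0.6*3)/4
  expect_equal(prof, diet_colour_profile(toy_network(f * 10), cols, "f1"))
  single <- toy_network(f[1, , drop = FALSE])
  expect_equal(unname(diet_colour_profile(single, cols, "f1")),
               unname(unlist(cols[1, c("x", "y", "z", "a")])))
  expect_error(diet_colour_profile(toy_network(f), cols[1, ], "f1"), "p2")
})

test_that("diet nutrient intake implements the mass-weighted mean", {
  f <- matrix(c(3, 1), 2, 1, dimnames = list(c("p1", "p2"), "f1"))
  nut <- data.frame(species = c("p1", "p2"), lip = c(0.1, 0.3))
  m <- c(p1 = 2, p2 = 1)
  got <- diet_nutrient_intake(toy_network(f), nut, m, "f1")
  expect_equal(unname(got), (0.1 * 6 + 0.3 * 1) / 7)   # 0.9/7 ~ 0.1286
  expect_equal(unname(got), 0.1285714, tolerance = 1e-6)
  # equal masses reduce to the colour-profile (f-weighted) form
  meq <- c(p1 = 5, p2 = 5)
  expect_equal(unname(diet_nutrient_intake(toy_network(f), nut, meq, "f1")),
               (0.1 * 3 + 0.3 * 1) / 4)
  single <- toy_network(f[2, , drop = FALSE])
  expect_equal(unname(diet_nutrient_intake(single, nut, m, "f1")), 0.3)
  expect_error(diet_nutrient_intake(toy_network(f), nut, c(p1 = 2), "f1"),
               "pulp mass")
})

test_that("weighted diet means stay within the consumed trait extrema", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    f <- matrix(rexp(k), k, 1,
                dimnames = list(paste0("p", 1:k), "f1"))
    cols <- data.frame(species = paste0("p", 1:k), x = rnorm(k), y = rnorm(k),
                       z = rnorm(k), a = runif(k))
    prof <- diet_colour_profile(toy_network(f), cols, "f1")
    for (cc in c("x", "y", "z", "a")) {
      expect_gte(prof[cc], min(cols[[cc]]) - 1e-12)
      expect_lte(prof[cc], max(cols[[cc]]) + 1e-12)
    }
  }
})

test_that("equal per-visit rates make consumption and visitation modes coincide", {
  set.seed(8)
  v <- data.frame(site = "s1", season = rep(c("summer", "autumn"), each = 6),
                  frugivore = rep(c("f1", "f2", "f3"), 4),
                  plant = rep(rep(c("p1", "p2"), each = 3), 2),
                  visits_per_hour = rexp(12),
                  fruits_per_visit = 2.5)
  nc <- build_networks(v, mode = "consumption")
  nv <- build_networks(v, mode = "visitation")
  cols <- data.frame(species = c("p1", "p2"), x = c(0.1, -0.2), y = c(0, 0.1),
                     z = c(0.2, 0), a = c(0.3, 0.7))
  for (k in seq_along(nc)) for (j in colnames(nc[[k]]$f)) {
    expect_equal(diet_colour_profile(nc[[k]], cols, j),
                 diet_colour_profile(nv[[k]], cols, j))
    expect_equal(partner_diversity(nc[[k]], j), partner_diversity(nv[[k]], j))
    expect_equal(interaction_strength(nc[[k]], j),
                 interaction_strength(nv[[k]], j))
  }
})

test_that("migratory covariate codings", {
  expect_equal(migratory_covariate(12, "winter", "zeroed"), 0)
  expect_equal(migratory_covariate(12, "spring", "zeroed"), 0)
  expect_equal(migratory_covariate(12, "autumn", "zeroed"), 12)
  expect_equal(migratory_covariate(12, "summer", "zeroed"), 12)
  expect_equal(migratory_covariate(12, "winter", "raw"), 12)
  expect_equal(unname(migratory_covariate(12, "winter", "period_interaction")),
               c(12, 0, 0))
  expect_equal(unname(migratory_covariate(12, "autumn", "period_interaction")),
               c(12, 1, 12))
  expect_error(migratory_covariate(-1, "winter", "zeroed"), ">= 0")
  expect_error(migratory_covariate(3, "monsoon", "zeroed"), "season")
})

test_that("zero-consumption frugivores are dropped with a warning", {
  v <- data.frame(site = "s1", season = "autumn",
                  frugivore = c("f1", "f2"), plant = c("p1", "p1"),
                  visits_per_hour = c(2, 0), fruits_per_visit = c(1, 1))
  expect_warning(nets <- build_networks(v), "zero-consumption")
  expect_equal(colnames(nets[[1]]$f), "f1")
})
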