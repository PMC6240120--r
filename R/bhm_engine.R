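# Bayesian hierarchical linear model with Kuo-Mallick indicator variable
# selection under global adaptation, phylogenetic and crossed iid random
# effects, and data augmentation for missing responses. Fitted by a
# purpose-built Gibbs sampler with a fixed scan order.
#
# Model: y_i ~ Normal(mu_i, sigma_e^2), mu_i = alpha + sum_j theta_j X_ij
#        + a_k[i] + v_k[i] + s_l[i] + t_m[i]
# with theta_j = I_j * beta_j for selectable terms,
#   I_j ~ Bernoulli(0.5), beta_j | sigma_beta^2 ~ Normal(0, sigma_beta^2),
#   sigma_beta^2 ~ Uniform(0, 100)  (global adaptation),
#   a ~ Normal(0, sigma_a^2 C) with C the phylogenetic correlation matrix,
#   v, s, t iid Normal(0, sigma^2 I); all residual / random-effect standard
#   deviations ~ Uniform(0, 100).

#' MCMC configuration
#'
#' Defaults mirror the package's reference protocol: eight parallel chains of
#' 26,000 iterations, a burn-in of 1000 and thinning interval 100, i.e. 250
#' retained draws per chain and 2000 in total.
#'
#' @param chains Number of chains.
#' @param iterations Iterations per chain.
#' @param burnin Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Master seed; chain c uses `seed + c`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 8, iterations = 26000, burnin = 1000,
                        thin = 100, seed = 1) {
  keep <- (iterations - burnin) / thin
  if (keep < 50)
    stop("(iterations - burnin) / thin must be >= 50 retained draws per chain")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), keep = as.integer(floor(keep))),
            class = "mcmc_config")
}

#' Sampler control parameters
#'
#' Prior constants and overrides used mainly by oracle tests.
#'
#' @param prior_inclusion Prior inclusion probability of selectable terms.
#' @param alpha_prior_var Prior variance of the intercept.
#' @param nonselect_prior_var Prior slope variance for non-selectable terms.
#' @param s2_beta_upper Upper bound of the Uniform prior on sigma_beta^2.
#' @param sd_upper Upper bound of the Uniform priors on the residual and
#'   random-effect standard deviations.
#' @param sigma2_e_fixed If non-NULL, fixes the residual variance.
#' @param sigma2_beta_fixed If non-NULL, fixes the shared slope variance.
#' @param ridge Ridge passed to [stable_inverse()] for the phylogenetic term.
#' @return A list of class `bhm_control`.
#' @export
bhm_control <- function(prior_inclusion = 0.5, alpha_prior_var = 1e6,
                        nonselect_prior_var = 100, s2_beta_upper = 100,
                        sd_upper = 100, sigma2_e_fixed = NULL,
                        sigma2_beta_fixed = NULL, ridge = 1e-8) {
  if (prior_inclusion <= 0 || prior_inclusion >= 1)
    stop("prior_inclusion must be in (0, 1)")
  structure(list(prior_inclusion = prior_inclusion,
                 alpha_prior_var = alpha_prior_var,
                 nonselect_prior_var = nonselect_prior_var,
                 s2_beta_upper = s2_beta_upper, sd_upper = sd_upper,
                 sigma2_e_fixed = sigma2_e_fixed,
                 sigma2_beta_fixed = sigma2_beta_fixed, ridge = ridge),
            class = "bhm_control")
}

# Truncated inverse-gamma draw on (0, upper): density x^{-a-1} exp(-b/x).
# Fast path: the untruncated draw is accepted when it lands inside the
# bound (it almost always does); otherwise inverse-CDF on the truncation.
# Falls back to a slice sampler when the shape is non-positive (few terms).
.rtrunc_invgamma <- function(a, b, upper, x0) {
  if (a > 0 && b > 0) {
    y <- stats::rgamma(1L, a, rate = b)
    if (y * upper > 1) return(1 / y)
    plo <- stats::pgamma(1 / upper, a, rate = b)
    u <- stats::runif(1, min(plo, 1 - 1e-12), 1)
    y <- stats::qgamma(u, a, rate = b)
    if (!is.finite(y) || y <= 0) return(upper * stats::runif(1, 0.99, 1))
    return(min(1 / y, upper))
  }
  logf <- function(x) -(a + 1) * log(x) - b / x
  .slice1(x0 = min(max(x0, 1e-8), upper), logf = logf, lower = 1e-12,
          upper = upper, w = max(x0, 0.5))
}

# One univariate slice-sampling update on a bounded interval.
.slice1 <- function(x0, logf, lower, upper, w) {
  ly <- logf(x0) + log(stats::runif(1))
  L <- max(lower, x0 - w * stats::runif(1))
  R <- min(upper, L + w)
  for (i in 1:50) { if (L <= lower || logf(L) < ly) break; L <- max(lower, L - w) }
  for (i in 1:50) { if (R >= upper || logf(R) < ly) break; R <- min(upper, R + w) }
  for (i in 1:100) {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# Build the random-effect term list used by the sampler.
.build_re <- function(data, phylo, species, species_iid, groups, control) {
  re <- list()
  if (!is.null(phylo)) {
    if (is.null(species))
      stop("a phylogenetic term requires `species` naming the species column")
    C <- unclass(as.matrix(phylo))
    sp <- as.character(data[[species]])
    miss <- setdiff(unique(sp), rownames(C))
    if (length(miss))
      stop("species missing from the correlation matrix: ",
           paste(miss, collapse = ", "))
    lev <- rownames(C)[rownames(C) %in% unique(sp)]
    C <- C[lev, lev, drop = FALSE]
    re$phylo <- list(idx = match(sp, lev), q = length(lev),
                     Cinv = stable_inverse(C, control$ridge), levels = lev)
  }
  if (species_iid) {
    if (is.null(species)) stop("species_iid requires `species`")
    f <- factor(data[[species]])
    re$species <- list(idx = as.integer(f), q = nlevels(f), Cinv = NULL,
                       levels = levels(f))
  }
  for (g in groups) {
    if (!g %in% names(data)) stop("grouping column not in data: ", g)
    f <- factor(data[[g]])
    re[[g]] <- list(idx = as.integer(f), q = nlevels(f), Cinv = NULL,
                    levels = levels(f))
  }
  re
}

# Single-chain Gibbs sampler. Returns a draws matrix (keep x npar).
.gibbs_chain <- function(y, X, selectable, re, config, control, chain_seed) {
  set.seed(chain_seed)
  rnorm <- stats::rnorm; runif <- stats::runif   # avoid `::` in the hot loop
  n <- length(y); p <- ncol(X)
  mis <- which(is.na(y))
  sel <- which(selectable); nsel <- length(sel)
  X1 <- cbind(`(Intercept)` = 1, X)
  G <- crossprod(X1)
  xtx <- diag(G)[-1]
  fix_s2e <- !is.null(control$sigma2_e_fixed)
  fix_s2b <- !is.null(control$sigma2_beta_fixed)

  # --- over-dispersed initialization from the priors ---
  ybar <- mean(y, na.rm = TRUE); ysd <- stats::sd(y, na.rm = TRUE)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  alpha <- stats::rnorm(1, ybar, 2 * ysd)
  beta <- stats::rnorm(p, 0, 1)
  ind <- rep(1L, p)
  if (nsel) ind[sel] <- stats::rbinom(nsel, 1, control$prior_inclusion)
  s2b <- if (fix_s2b) control$sigma2_beta_fixed else stats::runif(1, 0.1, 5)
  s2e <- if (fix_s2e) control$sigma2_e_fixed else stats::runif(1, 0.1, 5) * ysd^2
  s2re <- vapply(re, function(t) stats::runif(1, 0.1, 2) * ysd^2, 0)
  u <- Map(function(t, s2) stats::rnorm(t$q, 0, sqrt(s2)), re, s2re)
  ywork <- y
  if (length(mis)) ywork[mis] <- stats::rnorm(length(mis), ybar, ysd)

  re_sum <- rep(0, n)
  for (t in seq_along(re)) re_sum <- re_sum + u[[t]][re[[t]]$idx]
  theta <- beta * ind
  r <- ywork - alpha - drop(X %*% theta) - re_sum

  counts <- lapply(re, function(t) tabulate(t$idx, t$q))
  # 0/1 aggregation matrices: group sums as a dense matrix product
  Zt <- lapply(re, function(t) {
    M <- matrix(0, t$q, n); M[cbind(t$idx, seq_len(n))] <- 1; M
  })
  sd2_upper <- control$sd_upper^2
  lpr_odds <- stats::qlogis(control$prior_inclusion)
  pv_base <- ifelse(selectable, NA_real_, control$nonselect_prior_var)

  keep <- config$keep
  re_names <- names(re)
  cn <- c("alpha",
          if (p) paste0("beta_", colnames(X)),
          if (nsel) paste0("ind_", colnames(X)[sel]),
          "sigma2_beta", "sigma2_e",
          if (length(re)) paste0("sigma2_", re_names),
          if (length(mis)) paste0("ymis_", mis))
  out <- matrix(NA_real_, keep, length(cn), dimnames = list(NULL, cn))
  krow <- 0L

  for (it in seq_len(config$iterations)) {
    if (length(re)) {
      re_sum <- rep(0, n)
      for (t in seq_along(re)) re_sum <- re_sum + u[[t]][re[[t]]$idx]
    }
    ytil <- ywork - re_sum

    # (1) joint conjugate update of (alpha, included betas)
    inc <- c(1L, 1L + which(ind == 1L))
    pv <- pv_base; if (nsel) pv[sel] <- s2b
    pv <- c(control$alpha_prior_var, pv)
    prec <- G[inc, inc, drop = FALSE] / s2e
    diag(prec) <- diag(prec) + 1 / pv[inc]
    bvec <- (crossprod(X1, ytil) / s2e)[inc]
    U <- chol(prec)
    mu <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
    draw <- mu + backsolve(U, rnorm(length(inc)))
    alpha <- draw[1]
    if (length(inc) > 1) beta[inc[-1] - 1L] <- draw[-1]
    excl <- which(ind == 0L)
    if (length(excl))  # refresh excluded slopes from their prior
      beta[excl] <- rnorm(length(excl), 0, sqrt(pv[excl + 1L]))
    theta <- beta * ind
    r <- ytil - alpha - drop(X %*% theta)

    # (2) Kuo-Mallick indicator updates, maintaining v = X'r incrementally
    if (nsel) {
      v <- drop(crossprod(X, r))
      ind0 <- ind
      for (j in sel) {
        bj <- beta[j]
        x_r_wo <- v[j] + ind[j] * bj * xtx[j]
        dSSE <- -2 * bj * x_r_wo + bj^2 * xtx[j]
        z <- lpr_odds - dSSE / (2 * s2e)
        pr_inc <- 1 / (1 + exp(-z))
        new <- (runif(1) < pr_inc) + 0L
        if (new != ind[j]) {
          v <- if (new == 1L) v - bj * G[-1L, j + 1L]
               else v + bj * G[-1L, j + 1L]
          ind[j] <- new
        }
      }
      flip <- which(ind != ind0)
      if (length(flip))
        r <- r - X[, flip, drop = FALSE] %*% ((ind[flip] - ind0[flip]) *
                                                beta[flip])
      theta <- beta * ind
    }

    # (3) shared slope variance under its Uniform(0, upper) prior
    if (nsel && !fix_s2b) {
      S <- sum(beta[sel]^2)
      s2b <- .rtrunc_invgamma(a = nsel / 2 - 1, b = S / 2,
                              upper = control$s2_beta_upper, x0 = s2b)
    }

    # (4) random-effect vectors
    for (t in seq_along(re)) {
      tt <- re[[t]]
      uo <- u[[t]][tt$idx]
      sv <- drop(Zt[[t]] %*% (r + uo))
      if (is.null(tt$Cinv)) {
        pvar <- 1 / (counts[[t]] / s2e + 1 / s2re[t])
        unew <- rnorm(tt$q, pvar * sv / s2e, sqrt(pvar))
      } else {
        P <- tt$Cinv / s2re[t]
        diag(P) <- diag(P) + counts[[t]] / s2e
        U <- chol(P)
        m <- backsolve(U, backsolve(U, sv / s2e, transpose = TRUE))
        unew <- m + backsolve(U, rnorm(tt$q))
      }
      r <- r + uo - unew[tt$idx]
      u[[t]] <- unew
    }

    # (5) variance components
    for (t in seq_along(re)) {
      tt <- re[[t]]
      Q <- if (is.null(tt$Cinv)) sum(u[[t]]^2)
           else drop(u[[t]] %*% tt$Cinv %*% u[[t]])
      s2re[t] <- .rtrunc_invgamma(a = (tt$q - 1) / 2, b = Q / 2,
                                  upper = sd2_upper, x0 = s2re[t])
    }
    if (!fix_s2e)
      s2e <- .rtrunc_invgamma(a = (n - 1) / 2, b = sum(r^2) / 2,
                              upper = sd2_upper, x0 = s2e)
    if (s2e >= sd2_upper * 0.999 && n > 10)
      stop("residual variance diverged to its prior bound; ",
           "check response scaling")

    # (6) augmentation of missing responses from their full conditionals
    if (length(mis)) {
      eps <- rnorm(length(mis), 0, sqrt(s2e))
      ywork[mis] <- (ywork[mis] - r[mis]) + eps
      r[mis] <- eps
    }

    if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
      krow <- krow + 1L
      out[krow, ] <- c(alpha, if (p) beta, if (nsel) ind[sel], s2b, s2e,
                       if (length(re)) s2re, if (length(mis)) ywork[mis])
    }
  }
  out[seq_len(krow), , drop = FALSE]
}

#' Fit the Bayesian hierarchical model
#'
#' Gibbs sampler with a fixed scan order: (1) intercept and included slopes
#' jointly from their conjugate normal conditional; (2) each inclusion
#' indicator from its Bernoulli conditional (Kuo-Mallick form, with excluded
#' slopes refreshed from the prior for irreducibility); (3) the shared slope
#' variance under its Uniform(0, 100) prior; (4) random-effect vectors (the
#' phylogenetic vector jointly via its precision matrix, iid vectors
#' elementwise); (5) variance components; (6) each missing response from its
#' full conditional normal (data augmentation).
#'
#' @param data Data frame containing the response, predictors and grouping
#'   columns. Missing values are allowed in the response only.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @param selectable Subset of `predictors` subject to indicator selection
#'   (default all).
#' @param phylo Optional `phylo_correlation` matrix (see
#'   [correlation_from_tree()]); adds a phylogenetic random effect.
#' @param species Column mapping observations to species (required for
#'   `phylo` and `species_iid`).
#' @param species_iid Add an iid species random effect.
#' @param groups Further iid grouping columns (e.g. `c("site", "season")`).
#' @param log_response Natural-log transform the response first.
#' @param log_predictors Predictors to natural-log transform.
#' @param standardize Z-standardize predictors and response (default TRUE, so
#'   effect sizes are on a comparable unitless scale).
#' @param config An [mcmc_config()].
#' @param control A [bhm_control()].
#' @return An object of class `bhm_fit` with elements `draws` (retained draws
#'   x parameters matrix), `chain` (chain index per draw), `X`, `selectable`,
#'   `re_names`, `missing_rows`, `config`, `scale`.
#' @export
fit_bhm <- function(data, response, predictors = character(),
                    selectable = predictors, phylo = NULL, species = NULL,
                    species_iid = FALSE, groups = character(),
                    log_response = FALSE, log_predictors = character(),
                    standardize = TRUE, config = mcmc_config(),
                    control = bhm_control()) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column not found: ", response)
  miss_p <- setdiff(predictors, names(data))
  if (length(miss_p)) stop("predictor columns not found: ",
                           paste(miss_p, collapse = ", "))
  if (!all(selectable %in% predictors))
    stop("selectable must be a subset of predictors")

  y <- as.numeric(data[[response]])
  if (log_response) {
    if (any(y[!is.na(y)] <= 0)) stop("log_response requires positive values")
    y <- log(y)
  }
  X <- if (length(predictors)) {
    M <- as.matrix(data[, predictors, drop = FALSE])
    for (pp in intersect(log_predictors, predictors)) {
      if (any(M[, pp] <= 0)) stop("log transform requires positive ", pp)
      M[, pp] <- log(M[, pp])
    }
    M
  } else matrix(0, nrow(data), 0)
  if (anyNA(X))
    stop("missing predictor values: augmentation supports missing responses only")

  sc <- list(y_center = 0, y_scale = 1)
  if (standardize) {
    if (ncol(X)) {
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1
      X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      sc$x_center <- mu; sc$x_scale <- sdv
    }
    sc$y_center <- mean(y, na.rm = TRUE)
    sc$y_scale <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(sc$y_scale) || sc$y_scale == 0) sc$y_scale <- 1
    y <- (y - sc$y_center) / sc$y_scale
  }
  if (sum(!is.na(y)) < 3) stop("fewer than 3 observed responses")

  re <- .build_re(data, phylo, species, species_iid, groups, control)
  sel_flag <- colnames(X) %in% selectable

  chains <- lapply(seq_len(config$chains), function(ch)
    .gibbs_chain(y, X, sel_flag, re, config, control,
                 chain_seed = (config$seed + ch) %% .Machine$integer.max))
  draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(config$chains), vapply(chains, nrow, 0L))

  structure(list(draws = draws, chain = chain_id, X = X, y = y,
                 response = response, predictors = colnames(X),
                 selectable = colnames(X)[sel_flag], re_names = names(re),
                 missing_rows = which(is.na(y)), config = config,
                 control = control, scale = sc),
            class = "bhm_fit")
}

#' @export
print.bhm_fit <- function(x, ...) {
  cat(sprintf("Bayesian hierarchical model fit: response '%s', %d draws (%d chains)\n",
              x$response, nrow(x$draws), x$config$chains))
  cat("  predictors:", if (length(x$predictors))
    paste(x$predictors, collapse = ", ") else "(intercept only)", "\n")
  if (length(x$selectable))
    cat("  selectable:", paste(x$selectable, collapse = ", "), "\n")
  if (length(x$re_names))
    cat("  random effects:", paste(x$re_names, collapse = ", "), "\n")
  invisible(x)
}

#' Two-log-e Bayes factor from a posterior inclusion probability
#'
#' `BF = 2 ln[(P/(1-P)) / (p0/(1-p0))]`. When `P` is exactly 1 (or 0) under a
#' finite number of draws, the reported value is the resolution bound
#' `2 ln((n_draws - 0.5)/0.5)` (sign-flipped for 0) and the flag marks it as
#' a bound, mirroring the "> 15" convention of printed summary tables.
#'
#' @param P Posterior inclusion probability (vectorized).
#' @param prior_p Prior inclusion probability (default 0.5).
#' @param n_draws Number of posterior draws behind `P` (for the bound).
#' @return Data frame with columns `bf` and `flag`
#'   (`"exact"`, `"lower_bound"` = true BF above the reported value,
#'   `"upper_bound"` = true BF below it).
#' @export
bayes_factor <- function(P, prior_p = 0.5, n_draws = 2000) {
  if (prior_p <= 0 || prior_p >= 1) stop("prior_p must be in (0, 1)")
  if (any(P < 0 | P > 1)) stop("P must be in [0, 1]")
  prior_lo <- 2 * log(prior_p / (1 - prior_p))
  bound <- 2 * log((n_draws - 0.5) / 0.5) - prior_lo
  bf <- 2 * log(P / (1 - P)) - prior_lo
  flag <- rep("exact", length(P))
  flag[P == 1] <- "lower_bound"; bf[P == 1] <- bound
  flag[P == 0] <- "upper_bound"; bf[P == 0] <- -bound
  data.frame(bf = bf, flag = flag)
}

#' Selection and shrinkage summary of a fit
#'
#' Per predictor: the posterior inclusion probability `P`, the shrinkage
#' estimate (posterior mean of `I_j * beta_j`, zeros from excluded states
#' included), its 95% credible interval, and the 2 log_e Bayes factor.
#' Non-selectable predictors are summarized without `P`/`BF`.
#'
#' @param fit A `bhm_fit`.
#' @param prior_p Prior inclusion probability used for the Bayes factor.
#' @return Data frame of class `selection_summary` with one row per
#'   predictor: `term, estimate, ci_lower, ci_upper, P, bf, bf_flag,
#'   supported`.
#' @export
shrinkage_summary <- function(fit, prior_p = fit$control$prior_inclusion) {
  stopifnot(inherits(fit, "bhm_fit"))
  d <- fit$draws
  out <- lapply(fit$predictors, function(tm) {
    b <- d[, paste0("beta_", tm)]
    if (tm %in% fit$selectable) {
      I <- d[, paste0("ind_", tm)]
      th <- I * b
      P <- mean(I)
      bfrow <- bayes_factor(P, prior_p, n_draws = nrow(d))
    } else {
      th <- b
      P <- NA_real_
      bfrow <- data.frame(bf = NA_real_, flag = "none")
    }
    ci <- stats::quantile(th, c(0.025, 0.975), names = FALSE)
    data.frame(term = tm, estimate = mean(th), ci_lower = ci[1],
               ci_upper = ci[2], P = P, bf = bfrow$bf, bf_flag = bfrow$flag,
               supported = !is.na(bfrow$bf) & bfrow$bf > 2 &
                 bfrow$flag != "upper_bound")
  })
  out <- do.call(rbind, out)
  class(out) <- c("selection_summary", "data.frame")
  out
}

#' Marginal and conditional r-squared of a fit
#'
#' Per retained draw, the fixed-effect variance is the variance over
#' observations of `X theta`; the marginal r^2 divides it by itself plus all
#' random-effect variance components and the residual variance; the
#' conditional r^2 adds the variance components to the numerator. Posterior
#' means are reported, along with per-component variance shares.
#'
#' @param fit A `bhm_fit`.
#' @return List with `r2m`, `r2c`, `shares` (named, including `residual`),
#'   and the per-draw vectors `r2m_draws`, `r2c_draws`.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "bhm_fit"))
  d <- fit$draws
  p <- length(fit$predictors)
  nd <- nrow(d)
  if (p) {
    B <- d[, paste0("beta_", fit$predictors), drop = FALSE]
    for (tm in fit$selectable)
      B[, paste0("beta_", tm)] <-
        B[, paste0("beta_", tm)] * d[, paste0("ind_", tm)]
    FX <- fit$X %*% t(B)                       # n x draws fitted fixed parts
    var_f <- apply(FX, 2, stats::var)
  } else var_f <- rep(0, nd)
  s2e <- d[, "sigma2_e"]
  Vre <- if (length(fit$re_names))
    d[, paste0("sigma2_", fit$re_names), drop = FALSE]
  else matrix(0, nd, 0)
  tot_re <- if (ncol(Vre)) rowSums(Vre) else rep(0, nd)
  denom <- var_f + tot_re + s2e
  if (all(denom == 0)) stop("zero total variance")
  r2m <- var_f / denom
  r2c <- (var_f + tot_re) / denom
  shares <- c(colMeans(Vre / denom),
              residual = mean(s2e / denom))
  if (ncol(Vre)) names(shares)[seq_len(ncol(Vre))] <- fit$re_names
  list(r2m = mean(r2m), r2c = mean(r2c), shares = shares,
       r2m_draws = r2m, r2c_draws = r2c)
}

#' Convergence diagnostics
#'
#' Split-Rhat (each chain halved, between/within variance ratio) and the
#' effective sample size (via [coda::effectiveSize()]) for every recorded
#' parameter; parameters with Rhat > 1.05 are flagged.
#'
#' @param fit A `bhm_fit`, or a draws matrix plus `chain` vector.
#' @param chain Chain index per row when `fit` is a matrix.
#' @return Data frame `parameter, rhat, ess, flagged`.
#' @export
bhm_diagnostics <- function(fit, chain = NULL) {
  if (inherits(fit, "bhm_fit")) { d <- fit$draws; chain <- fit$chain }
  else d <- as.matrix(fit)
  if (is.null(chain)) stop("chain indices required")
  if (length(unique(chain)) < 2)
    warning("fewer than 2 chains: Rhat unavailable")
  rhat <- apply(d, 2, .split_rhat, chain = chain)
  ess <- vapply(colnames(d), function(p) {
    sum(vapply(unique(chain), function(ch)
      as.numeric(coda::effectiveSize(d[chain == ch, p])), 0))
  }, 0)
  data.frame(parameter = colnames(d), rhat = rhat, ess = ess,
             flagged = !is.na(rhat) & rhat > 1.05, row.names = NULL)
}

.split_rhat <- function(x, chain) {
  if (length(unique(chain)) < 2) return(NA_real_)
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(v[1:h]), list(v[(h + 1):(2 * h)]))
  }
  m <- length(halves); nn <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
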