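#' Specification of a zero-inflated beta dyadic model
#'
#' Describes the fixed effects, zero-inflation part, random-effect
#' structure, priors and MCMC settings of a dyadic regression. The
#' response is an SRI edge weight in `[0, 1]`: it is zero with
#' probability `pi` (the zero-inflation part, intercept-only by default)
#' and otherwise follows a Beta distribution with mean `mu` and
#' precision `phi`, with `logit(mu) = X beta + a_focal + m_i + m_j`.
#' `a` is a focal-individual intercept and `m` is the multi-membership
#' term: one effect per individual, drawn from a single Normal
#' distribution, entering additively for both members of the dyad. An
#' alternative reading of "dyad as a random effect" — an intercept per
#' unordered dyad ID — is available via `random_structure$dyad_intercept`.
#'
#' @param fixed_terms Character vector of covariate column names.
#'   Character/factor columns get treatment coding; a `relationship`
#'   column uses `other_adults` as the baseline.
#' @param interactions List of length-2 character vectors naming
#'   covariate pairs whose products enter as interaction columns.
#' @param zi_terms Covariates for the zero-inflation logit (default
#'   none: intercept-only).
#' @param random_structure Switches `focal_intercept`,
#'   `member_multimembership`, `dyad_intercept`.
#' @param priors Named list: `beta_sd` (Normal sd on fixed effects,
#'   default 2.5), `re_sd_scale` (half-Normal scale on random-effect
#'   SDs, default 1), `phi_rate` (Exponential rate on the beta
#'   precision, default 0.1). The zero-inflation intercept gets a
#'   Logistic(0, 1) prior, i.e. uniform on the probability scale.
#' @param chains Number of MCMC chains (>= 2).
#' @param iterations Total iterations per chain.
#' @param warmup Warm-up (burn-in) iterations per chain (< iterations).
#' @param seed Integer seed; chains get derived RNG seeds.
#' @param zero_one_handling How exact responses of 1 (possible with SRI)
#'   enter the beta likelihood: `"epsilon"` maps them to `1 - 1e-6`;
#'   `"compress"` applies the Smithson-Verkuilen transform
#'   `(y (n - 1) + 0.5) / n` to all nonzero responses.
#' @return List of class `zib_spec`.
#' @export
zib_model_spec <- function(fixed_terms,
                           interactions = list(),
                           zi_terms = character(),
                           random_structure = list(
                             focal_intercept = TRUE,
                             member_multimembership = TRUE,
                             dyad_intercept = FALSE),
                           priors = list(beta_sd = 2.5, re_sd_scale = 1,
                                         phi_rate = 0.1),
                           chains = 4, iterations = 4000, warmup = 2000,
                           seed = 1L,
                           zero_one_handling = c("epsilon", "compress")) {
  stopifnot(chains >= 2, warmup < iterations, iterations > 0)
  defaults <- list(focal_intercept = TRUE, member_multimembership = TRUE,
                   dyad_intercept = FALSE)
  defaults[names(random_structure)] <- random_structure
  pr <- list(beta_sd = 2.5, re_sd_scale = 1, phi_rate = 0.1)
  pr[names(priors)] <- priors
  structure(list(fixed_terms = fixed_terms, interactions = interactions,
                 zi_terms = zi_terms, random_structure = defaults,
                 priors = pr, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 zero_one_handling = match.arg(zero_one_handling)),
            class = "zib_spec")
}

#' Build the design of a zero-inflated beta dyadic model
#'
#' Assembles the response, the fixed-effect design matrix (treatment
#' coding; `relationship` is coded against the `other_adults` baseline;
#' interaction columns are elementwise products) and the random-effect
#' index maps for the focal individual and for the two dyad members.
#'
#' @param dyad_table Data frame with `sri`, `focal_id`, `partner_id` and
#'   every covariate named in the spec.
#' @param spec A [zib_model_spec()].
#' @return List with `y`, `X` (including intercept), `terms`, `Xz`
#'   (zero-inflation design), `focal`, `mem1`, `mem2`, `dyad` (integer
#'   index vectors), `focal_levels`, `member_levels`, `dyad_levels`.
#' @export
build_design <- function(dyad_table, spec) {
  stopifnot(inherits(spec, "zib_spec"))
  need <- unique(c("sri", "focal_id", "partner_id", spec$fixed_terms,
                   spec$zi_terms, unlist(spec$interactions)))
  miss <- setdiff(need, names(dyad_table))
  if (length(miss) > 0) {
    stop("dyad table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- dyad_table
  for (v in unique(c(spec$fixed_terms, unlist(spec$interactions)))) {
    if (is.character(df[[v]])) {
      lev <- sort(unique(df[[v]]))
      if (v == "relationship") {
        lev <- intersect(c("other_adults", "parents", "siblings", "peers"),
                         lev)
      }
      df[[v]] <- factor(df[[v]], levels = lev)
    }
  }
  fml_terms <- c(spec$fixed_terms,
                 vapply(spec$interactions,
                        function(p) paste(p, collapse = ":"), ""))
  fml <- as.formula(paste("~", paste(fml_terms, collapse = " + ")))
  X <- model.matrix(fml, df)
  Xz <- if (length(spec$zi_terms) > 0) {
    model.matrix(as.formula(paste("~", paste(spec$zi_terms,
                                             collapse = " + "))), df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  focal_levels <- sort(unique(df$focal_id))
  member_levels <- sort(unique(c(df$focal_id, df$partner_id)))
  dyad_key <- ifelse(df$focal_id < df$partner_id,
                     paste(df$focal_id, df$partner_id, sep = "|"),
                     paste(df$partner_id, df$focal_id, sep = "|"))
  dyad_levels <- sort(unique(dyad_key))
  list(y = df$sri,
       X = X, terms = colnames(X), Xz = Xz,
       focal = match(df$focal_id, focal_levels),
       mem1 = match(df$focal_id, member_levels),
       mem2 = match(df$partner_id, member_levels),
       dyad = match(dyad_key, dyad_levels),
       focal_levels = focal_levels, member_levels = member_levels,
       dyad_levels = dyad_levels)
}

# Assemble the JAGS model text matching the spec's random structure and
# the presence/absence of positive responses.
zib_jags_model <- function(spec, has_pos) {
  rs <- spec$random_structure
  pr <- spec$priors
  lines <- c("model {",
             sprintf("  for (p in 1:P) { beta[p] ~ dnorm(0, %.8f) }",
                     1 / pr$beta_sd^2),
             sprintf("  for (q in 1:Q) { gamma[q] ~ dlogis(0, 1) }"),
             sprintf("  phi ~ dexp(%.8f)", pr$phi_rate))
  tau <- sprintf("T(0,)")
  prec_re <- sprintf("%.8f", 1 / pr$re_sd_scale^2)
  if (rs$focal_intercept) {
    lines <- c(lines,
               sprintf("  sigma_a ~ dnorm(0, %s) %s", prec_re, tau),
               "  for (i in 1:NF) { a[i] ~ dnorm(0, pow(sigma_a, -2)) }")
  }
  if (rs$member_multimembership) {
    lines <- c(lines,
               sprintf("  sigma_m ~ dnorm(0, %s) %s", prec_re, tau),
               "  for (i in 1:NB) { m[i] ~ dnorm(0, pow(sigma_m, -2)) }")
  }
  if (rs$dyad_intercept) {
    lines <- c(lines,
               sprintf("  sigma_d ~ dnorm(0, %s) %s", prec_re, tau),
               "  for (i in 1:ND) { d[i] ~ dnorm(0, pow(sigma_d, -2)) }")
  }
  lines <- c(lines,
             "  for (n in 1:N) {",
             "    logit(pz[n]) <- inprod(Xz[n, ], gamma)",
             "    z[n] ~ dbern(pz[n])",
             "  }")
  if (has_pos) {
    eta <- "inprod(Xp[n, ], beta)"
    if (rs$focal_intercept) eta <- paste0(eta, " + a[fp[n]]")
    if (rs$member_multimembership) {
      eta <- paste0(eta, " + m[m1p[n]] + m[m2p[n]]")
    }
    if (rs$dyad_intercept) eta <- paste0(eta, " + d[dp[n]]")
    lines <- c(lines,
               "  for (n in 1:NP) {",
               sprintf("    logit(mu[n]) <- %s", eta),
               "    yp[n] ~ dbeta(mu[n] * phi, (1 - mu[n]) * phi)",
               "  }")
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit a zero-inflated beta model with multi-membership random effects
#'
#' Samples the posterior of the model described by `spec` on a dyad
#' table. The likelihood is: `y = 0` with probability `pi`; positive `y`
#' follows `Beta(mu phi, (1 - mu) phi)` with `logit(mu) = X beta +
#' a_focal + m_i + m_j`. Because the zero part shares no parameters with
#' the beta part, the sampler sees the zero indicators and the positive
#' responses as two coupled data blocks.
#'
#' The default engine is the package's compiled adaptive
#' Metropolis-within-Gibbs sampler: the fixed-effect block uses a
#' Haario-style adaptive multivariate proposal, the zero-inflation
#' probability is drawn exactly by beta-binomial conjugacy (when the
#' zero part is intercept-only), and proposal scales adapt during
#' warm-up only, leaving the post-warm-up kernel fixed. `engine =
#' "jags"` fits the identical model by Gibbs sampling through
#' \pkg{rjags} instead; it is slower and is used in the package's own
#' validation as an independent cross-check of the default engine.
#' Both engines are bit-reproducible given `spec$seed`.
#'
#' @param dyad_table Data frame (see [build_design()]); `sri` must lie in
#'   `[0, 1]`.
#' @param spec A [zib_model_spec()].
#' @param engine `"adaptive"` (compiled, default) or `"jags"`.
#' @param quiet Suppress progress output (default TRUE).
#' @return Object of class `zib_fit`: `draws` (a [coda::mcmc.list]),
#'   `combined` (draws pooled across chains), `rhat`, `ess`, `design`,
#'   `spec`, `converged` (FALSE, with a warning, if any split-chain
#'   R-hat exceeds 1.05 on the fixed effects, SDs, precision or
#'   zero-inflation parameters).
#' @export
fit_zib_mm <- function(dyad_table, spec, engine = c("adaptive", "jags"),
                       quiet = TRUE) {
  stopifnot(inherits(spec, "zib_spec"))
  engine <- match.arg(engine)
  des <- build_design(dyad_table, spec)
  y <- des$y
  if (any(y < 0 | y > 1)) {
    stop("response must lie in [0, 1]", call. = FALSE)
  }
  z <- as.integer(y == 0)
  pos <- which(z == 0L)
  yp <- y[pos]
  n <- length(yp)
  if (spec$zero_one_handling == "epsilon") {
    yp[yp == 1] <- 1 - 1e-6
  } else if (n > 0) {
    yp <- (yp * (n - 1) + 0.5) / n
  }
  draws <- if (engine == "adaptive") {
    zib_sample_adaptive(des, yp, pos, z, spec)
  } else {
    zib_sample_jags(des, yp, pos, z, spec, quiet)
  }
  combined <- do.call(rbind, lapply(draws, as.matrix))
  rh <- split_rhat(draws)
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e) NULL)
  core <- grep("^(a|m|d)\\[", colnames(combined), invert = TRUE)
  converged <- all(rh[colnames(combined)[core]] <= 1.05, na.rm = TRUE)
  if (!converged) {
    warning("convergence warning: split-chain R-hat > 1.05 for some ",
            "parameters", call. = FALSE)
  }
  structure(list(draws = draws, combined = combined, rhat = rh, ess = ess,
                 design = des, spec = spec, y = y, converged = converged,
                 engine = engine),
            class = "zib_fit")
}

# Compiled adaptive MCMC engine: one call per chain, seeded from the
# spec so runs are reproducible.
zib_sample_adaptive <- function(des, yp, pos, z, spec) {
  rs <- spec$random_structure
  P <- ncol(des$X)
  Q <- ncol(des$Xz)
  NF <- if (rs$focal_intercept) length(des$focal_levels) else 0L
  NB <- if (rs$member_multimembership) length(des$member_levels) else 0L
  ND <- if (rs$dyad_intercept) length(des$dyad_levels) else 0L
  Xp <- des$X[pos, , drop = FALSE]
  # precondition: scale non-intercept columns to unit sd (sampling-space
  # reparameterisation only; draws are mapped back, and the declared
  # Normal(0, beta_sd) priors on the original coefficients are preserved
  # by scaling the per-coordinate prior sds accordingly)
  col_scale <- rep(1, P)
  if (nrow(Xp) > 1) {
    s <- apply(Xp, 2, sd)
    nz <- s > 1e-12 & des$terms != "(Intercept)"
    col_scale[nz] <- s[nz]
  }
  Xs <- sweep(Xp, 2, col_scale, "/")
  beta_prior_sd <- spec$priors$beta_sd * col_scale
  # warm start: least squares on the empirical logit of the positives
  beta_init <- rep(0, P)
  if (nrow(Xs) > P) {
    yl <- qlogis(pmin(pmax(yp, 1e-4), 1 - 1e-4))
    beta_init <- tryCatch(qr.coef(qr(Xs), yl), error = function(e) rep(0, P))
    beta_init[!is.finite(beta_init)] <- 0
  } else if (length(yp) > 0 && des$terms[1] == "(Intercept)") {
    beta_init[1] <- qlogis(min(max(mean(yp), 1e-3), 1 - 1e-3))
  }
  zero_idx <- integer(0)
  cn <- c(paste0("b_", des$terms),
          paste0("zi_", colnames(des$Xz)),
          "phi",
          if (NF > 0) c("sigma_a", sprintf("a[%d]", seq_len(NF))),
          if (NB > 0) c("sigma_m", sprintf("m[%d]", seq_len(NB))),
          if (ND > 0) c("sigma_d", sprintf("d[%d]", seq_len(ND))))
  chains <- lapply(seq_len(spec$chains), function(ch) {
    out <- with_seed((spec$seed * 1009L + ch * 9176L) %% 2147483629L, {
      .zib_mcmc_chain(yp = yp, Xp = Xs,
                      fp = if (NF > 0) des$focal[pos] else zero_idx,
                      m1p = if (NB > 0) des$mem1[pos] else zero_idx,
                      m2p = if (NB > 0) des$mem2[pos] else zero_idx,
                      dp = if (ND > 0) des$dyad[pos] else zero_idx,
                      NF = NF, NB = NB, ND = ND,
                      N = length(z), nz = sum(z),
                      Xz = des$Xz, zvec = z,
                      priors = spec$priors,
                      beta_init = beta_init,
                      beta_prior_sd = beta_prior_sd,
                      n_iter = spec$iterations,
                      n_warmup = spec$warmup,
                      has_intercept = des$terms[1] == "(Intercept)")
    })
    # map the sampling-space coefficients back to the original columns
    out[, seq_len(P)] <- sweep(out[, seq_len(P), drop = FALSE], 2,
                               col_scale, "/")
    colnames(out) <- cn
    coda::mcmc(out, start = 1, thin = 1)
  })
  coda::as.mcmc.list(chains)
}

# Reference engine: the same model sampled through JAGS.
zib_sample_jags <- function(des, yp, pos, z, spec, quiet = TRUE) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("engine = \"jags\" requires the rjags package", call. = FALSE)
  }
  n <- length(yp)
  has_pos <- n > 0
  data <- list(N = length(z), z = z, Xz = des$Xz, Q = ncol(des$Xz),
               P = ncol(des$X))
  rs <- spec$random_structure
  if (rs$focal_intercept) data$NF <- length(des$focal_levels)
  if (rs$member_multimembership) data$NB <- length(des$member_levels)
  if (rs$dyad_intercept) data$ND <- length(des$dyad_levels)
  if (has_pos) {
    data$NP <- n
    data$yp <- yp
    data$Xp <- des$X[pos, , drop = FALSE]
    if (rs$focal_intercept) data$fp <- des$focal[pos]
    if (rs$member_multimembership) {
      data$m1p <- des$mem1[pos]
      data$m2p <- des$mem2[pos]
    }
    if (rs$dyad_intercept) data$dp <- des$dyad[pos]
  }
  monitors <- c("beta", "gamma")
  if (has_pos) monitors <- c(monitors, "phi")
  if (rs$focal_intercept) monitors <- c(monitors, "sigma_a", "a")
  if (rs$member_multimembership) monitors <- c(monitors, "sigma_m", "m")
  if (rs$dyad_intercept) monitors <- c(monitors, "sigma_d", "d")
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (spec$seed * 1009L + ch * 9176L) %% 2147483629L)
  })
  model_txt <- zib_jags_model(spec, has_pos)
  jm <- rjags::jags.model(textConnection(model_txt), data = data,
                          inits = inits, n.chains = spec$chains,
                          quiet = quiet)
  update(jm, spec$warmup, progress.bar = if (quiet) "none" else "text")
  draws <- rjags::coda.samples(jm, monitors,
                               spec$iterations - spec$warmup,
                               progress.bar = if (quiet) "none" else "text")
  coda::as.mcmc.list(lapply(draws, function(d) {
    m <- as.matrix(d)
    coda::mcmc(rename_beta(m, des$terms, ncol(des$Xz), colnames(des$Xz)),
               start = 1, thin = 1)
  }))
}

rename_beta <- function(m, terms, q, zterms) {
  cn <- colnames(m)
  for (p in seq_along(terms)) {
    cn[cn == sprintf("beta[%d]", p)] <- paste0("b_", terms[p])
  }
  if (q == 1) {
    cn[cn == "gamma"] <- "zi_(Intercept)"
  } else {
    for (p in seq_len(q)) {
      cn[cn == sprintf("gamma[%d]", p)] <- paste0("zi_", zterms[p])
    }
  }
  colnames(m) <- cn
  m
}

# Split-chain R-hat (each chain halved, between/within variance ratio).
split_rhat <- function(mcmc_list) {
  mats <- lapply(mcmc_list, as.matrix)
  half <- floor(nrow(mats[[1]]) / 2)
  chains <- list()
  for (m in mats) {
    chains[[length(chains) + 1]] <- m[seq_len(half), , drop = FALSE]
    chains[[length(chains) + 1]] <- m[half + seq_len(half), , drop = FALSE]
  }
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(chains, function(c) mean(c[, j]), 0)
    w <- vapply(chains, function(c) var(c[, j]), 0)
    W <- mean(w)
    B <- half * var(x)
    if (W < .Machine$double.eps) return(1)
    max(1, sqrt(((half - 1) / half * W + B / half) / W))
  }, 0) |> setNames(colnames(mats[[1]]))
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf(
    "<zib_fit: %d obs (%d zero), %d chains x %d draws, %s>\n",
    length(x$y), sum(x$y == 0), length(x$draws),
    nrow(as.matrix(x$draws[[1]])),
    if (x$converged) "converged" else "CONVERGENCE WARNING"))
  invisible(x)
}

#' Summarise fixed effects as odds ratios
#'
#' For each requested fixed-effect term, summarises `exp(beta)` by its
#' posterior mean and 2.5/97.5 percentiles. An effect is flagged
#' significant when the 95% credible interval of the odds ratio excludes
#' 1 (both bounds below, or both above, 1).
#'
#' @param fit A `zib_fit`.
#' @param terms Term names (as in `colnames(fit$design$X)`); default all
#'   fixed-effect terms except the intercept.
#' @return Data frame `term`, `or_mean`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
summarize_odds_ratios <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "zib_fit"))
  all_terms <- fit$design$terms
  if (is.null(terms)) terms <- setdiff(all_terms, "(Intercept)")
  unknown <- setdiff(terms, all_terms)
  if (length(unknown) > 0) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(terms, function(tm) {
    draws <- exp(fit$combined[, paste0("b_", tm)])
    qs <- unname(quantile(draws, c(0.025, 0.975), type = 7))
    data.frame(term = tm, or_mean = mean(draws),
               ci_low = qs[1], ci_high = qs[2],
               significant = qs[1] > 1 || qs[2] < 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior predictive check of a zero-inflated beta fit
#'
#' Replicates the dataset from a thinned subset of posterior draws
#' (fixed effects, random effects, precision and zero-inflation
#' parameters all taken jointly per draw) and locates the observed
#' zero fraction and the observed mean of the nonzero responses within
#' the replicated distributions.
#'
#' @param fit A `zib_fit`.
#' @param n_rep Number of replicated datasets (default 200).
#' @param seed Integer seed for the replication noise.
#' @return List with `n_rep`, and for each statistic (`zero_fraction`,
#'   `mean_nonzero`): the observed value, the replicated values, and the
#'   observed value's quantile within the replicated distribution.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1L) {
  stopifnot(inherits(fit, "zib_fit"))
  des <- fit$design
  rs <- fit$spec$random_structure
  cm <- fit$combined
  idx <- unique(round(seq(1, nrow(cm), length.out = n_rep)))
  with_seed(seed, {
    stats <- vapply(idx, function(i) {
      dr <- cm[i, ]
      pz <- plogis(des$Xz %*% dr[paste0("zi_", colnames(des$Xz))])
      eta <- des$X %*% dr[paste0("b_", des$terms)]
      if (rs$focal_intercept) {
        eta <- eta + dr[sprintf("a[%d]", des$focal)]
      }
      if (rs$member_multimembership) {
        eta <- eta + dr[sprintf("m[%d]", des$mem1)] +
          dr[sprintf("m[%d]", des$mem2)]
      }
      if (rs$dyad_intercept) {
        eta <- eta + dr[sprintf("d[%d]", des$dyad)]
      }
      mu <- plogis(eta)
      phi <- if ("phi" %in% names(dr)) dr["phi"] else 1
      yrep <- ifelse(runif(length(mu)) < pz, 0,
                     rbeta(length(mu), mu * phi, (1 - mu) * phi))
      c(zero_fraction = mean(yrep == 0),
        mean_nonzero = if (any(yrep > 0)) mean(yrep[yrep > 0]) else NA_real_)
    }, c(zero_fraction = 0, mean_nonzero = 0))
    obs_zero <- mean(fit$y == 0)
    obs_mean <- if (any(fit$y > 0)) mean(fit$y[fit$y > 0]) else NA_real_
    list(n_rep = length(idx),
         zero_fraction = list(observed = obs_zero,
                              replicated = unname(stats["zero_fraction", ]),
                              quantile = mean(stats["zero_fraction", ] <=
                                                obs_zero)),
         mean_nonzero = list(observed = obs_mean,
                             replicated = unname(stats["mean_nonzero", ]),
                             quantile = mean(stats["mean_nonzero", ] <=
                                               obs_mean)))
  })
}

#' Simulate a dyad table from the zero-inflated beta model itself
#'
#' Draws a dataset exactly under the model assumptions — known fixed
#' effects, focal and multi-membership random effects, beta precision
#' and zero-inflation probability — for parameter-recovery checks.
#'
#' @param n_birds Number of birds (members / potential focals).
#' @param n_dyads Number of directed dyad rows to sample.
#' @param beta Named fixed-effect vector; must include `(Intercept)`;
#'   remaining names become covariate columns drawn Uniform(0, 1) for
#'   `overlap` and standard Normal otherwise.
#' @param sigma_a,sigma_m Random-effect SDs (focal; member).
#' @param phi Beta precision.
#' @param pi Zero-inflation probability.
#' @param seed Integer seed.
#' @return List with `dyad_table` and `truth`.
#' @export
simulate_zib_data <- function(n_birds = 40, n_dyads = 600,
                              beta = c("(Intercept)" = -2,
                                       overlap = log(2)),
                              sigma_a = 0.3, sigma_m = 0.3,
                              phi = 10, pi = 0.3, seed = 1L) {
  stopifnot("(Intercept)" %in% names(beta))
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_birds))
    pairs <- expand.grid(f = seq_len(n_birds), p = seq_len(n_birds))
    pairs <- pairs[pairs$f != pairs$p, ]
    pick <- sample(nrow(pairs), min(n_dyads, nrow(pairs)))
    pairs <- pairs[pick, ]
    covs <- setdiff(names(beta), "(Intercept)")
    df <- data.frame(focal_id = ids[pairs$f], partner_id = ids[pairs$p],
                     stringsAsFactors = FALSE)
    for (v in covs) {
      df[[v]] <- if (v == "overlap") runif(nrow(df)) else rnorm(nrow(df))
    }
    a <- rnorm(n_birds, 0, sigma_a)
    m <- rnorm(n_birds, 0, sigma_m)
    X <- cbind(1, as.matrix(df[, covs, drop = FALSE]))
    eta <- drop(X %*% beta[c("(Intercept)", covs)]) +
      a[pairs$f] + m[pairs$f] + m[pairs$p]
    mu <- plogis(eta)
    y <- ifelse(runif(nrow(df)) < pi, 0,
                rbeta(nrow(df), mu * phi, (1 - mu) * phi))
    y[y == 1] <- 1 - 1e-6
    df$sri <- y
    list(dyad_table = df,
         truth = list(beta = beta, sigma_a = sigma_a, sigma_m = sigma_m,
                      phi = phi, pi = pi))
  })
}
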