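# Bayesian random-effects network meta-analysis via JAGS.
#
# Model (per study i, arm k; binomial likelihood, logit link):
#   r[i,k] ~ Binomial(p[i,k], n[i,k])
#   logit(p[i,k]) = mu[i] + delta[i,k],   delta[i, baseline] = 0
#   delta[i,k] ~ Normal(d[t[i,k]] - d[t[i,1]], tau^2)   (multi-arm trials use
#     the conditional construction, giving the delta's pairwise correlation 1/2)
#   mu[i], d[k] ~ Normal(0, prior_sd_effects^2),  d[1] = 0,  tau ~ U(0, upper)
#
# Cluster-adjusted counts are non-integer, so the binomial log-likelihood is
# evaluated directly through its log-gamma generalisation (Poisson "zeros
# trick"), a continuous relaxation that agrees exactly with dbin at integers.

#' MCMC configuration for network meta-analysis fits
#'
#' @param prior_sd_effects standard deviation of the vague normal priors on
#'   the basic parameters `d` and study baselines `mu` (log-odds scale)
#' @param prior_tau_upper upper bound of the uniform prior on the
#'   between-study standard deviation `tau` (log-odds-ratio scale)
#' @param chains number of MCMC chains (>= 2)
#' @param iterations posterior iterations kept per chain (after burn-in)
#' @param burn_in iterations discarded per chain
#' @param thin thinning interval
#' @param seed integer seed; fixes the JAGS RNGs so runs are reproducible
#' @param adapt JAGS adaptation steps
#' @param rhat_threshold split-chain convergence diagnostic above which
#'   [fit_nma()] emits a convergence warning
#' @return list of class `nma_config`
#' @export
nma_config <- function(prior_sd_effects = 100, prior_tau_upper = 5,
                       chains = 3, iterations = 10000, burn_in = 4000,
                       thin = 1, seed = 1, adapt = 1000,
                       rhat_threshold = 1.05) {
  if (chains < 2) stop_validation("at least 2 chains are required")
  if (burn_in < 0 || iterations <= 0) {
    stop_validation("iterations must be positive and burn_in non-negative")
  }
  if (burn_in >= iterations) {
    stop_validation("burn_in must be smaller than iterations")
  }
  structure(list(prior_sd_effects = prior_sd_effects,
                 prior_tau_upper = prior_tau_upper, chains = chains,
                 iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = seed, adapt = adapt,
                 rhat_threshold = rhat_threshold),
            class = "nma_config")
}

.jags_likelihood <- "
      logit(p[i,k]) <- mu[i] + delta[i,k]
      ll[i,k] <- loggam(n[i,k] + 1) - loggam(r[i,k] + 1) -
                 loggam(n[i,k] - r[i,k] + 1) +
                 r[i,k] * log(p[i,k]) + (n[i,k] - r[i,k]) * log(1 - p[i,k])
      zeros[i,k] ~ dpois(Cz - ll[i,k])
"

.jags_model_consistency <- function() {
  paste0("model {
  for (i in 1:ns) {
    mu[i] ~ dnorm(0, prec.eff)
    delta[i,1] <- 0
    w[i,1] <- 0
    for (k in 1:na[i]) {", .jags_likelihood, "    }
    for (k in 2:na[i]) {
      delta[i,k] ~ dnorm(md[i,k], taud[i,k])
      md[i,k] <- d[t[i,k]] - d[t[i,1]] + sw[i,k]
      taud[i,k] <- prec * 2 * (k - 1) / k
      w[i,k] <- delta[i,k] - d[t[i,k]] + d[t[i,1]]
      sw[i,k] <- sum(w[i,1:(k-1)]) / (k - 1)
    }
  }
  d[1] <- 0
  for (k in 2:nt) { d[k] ~ dnorm(0, prec.eff) }
  tau ~ dunif(0, tau.upper)
  prec <- pow(tau, -2)
}")
}

# common-effect variant: no study-specific deltas, logits built directly
# from the consistency equations
.jags_model_fixed <- function() {
  paste0("model {
  for (i in 1:ns) {
    mu[i] ~ dnorm(0, prec.eff)
    for (k in 1:na[i]) {
      delta[i,k] <- d[t[i,k]] - d[t[i,1]]", .jags_likelihood, "    }
  }
  d[1] <- 0
  for (k in 2:nt) { d[k] ~ dnorm(0, prec.eff) }
}")
}

# node-split variant: two-arm studies flagged split[i] = 1 inform a separate
# direct-evidence parameter ddir instead of the consistency equation
.jags_model_nodesplit <- function() {
  paste0("model {
  for (i in 1:ns) {
    mu[i] ~ dnorm(0, prec.eff)
    delta[i,1] <- 0
    for (k in 1:na[i]) {", .jags_likelihood, "    }
    delta[i,2] ~ dnorm(md[i,2], prec)
    md[i,2] <- split[i] * dir.sign[i] * ddir +
               (1 - split[i]) * (d[t[i,2]] - d[t[i,1]])
  }
  d[1] <- 0
  for (k in 2:nt) { d[k] ~ dnorm(0, prec.eff) }
  ddir ~ dnorm(0, prec.eff)
  tau ~ dunif(0, tau.upper)
  prec <- pow(tau, -2)
}")
}

# arrange a network into the ragged arrays JAGS expects; arms ordered by
# intervention code so the lowest code is the study baseline
.jags_data <- function(network, config) {
  arms <- correct_network_arms(network$arms)
  sids <- unique(arms$study_id)
  ns <- length(sids)
  na <- vapply(sids, function(s) sum(arms$study_id == s), integer(1))
  mx <- max(na)
  t <- r <- n <- matrix(NA_real_, ns, mx)
  for (i in seq_len(ns)) {
    a <- arms[arms$study_id == sids[i], ]
    a <- a[order(a$intervention), ]
    t[i, seq_len(nrow(a))] <- a$intervention
    r[i, seq_len(nrow(a))] <- a$events
    n[i, seq_len(nrow(a))] <- a$size
  }
  zeros <- matrix(NA_real_, ns, mx)
  for (i in seq_len(ns)) zeros[i, seq_len(na[i])] <- 0
  list(ns = ns, nt = n_interventions(network), na = na, t = t, r = r, n = n,
       zeros = zeros, Cz = 10000,
       prec.eff = 1 / config$prior_sd_effects^2,
       tau.upper = config$prior_tau_upper,
       study_ids = sids)
}

.jags_inits <- function(dat, config, extra = NULL, random_effects = TRUE) {
  mxarm <- ncol(dat$t)
  delta0 <- matrix(NA_real_, dat$ns, mxarm)
  for (i in seq_len(dat$ns)) delta0[i, 2:dat$na[i]] <- 0
  lapply(seq_len(config$chains), function(ch) {
    ini <- list(
      mu = stats::qlogis(pmin(pmax(dat$r[, 1] / dat$n[, 1], 0.02), 0.98)),
      d = c(NA, rep(0, dat$nt - 1)),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (config$seed %% 1000000L) * 1000L + ch)
    if (random_effects) {
      ini$tau <- config$prior_tau_upper / 10
      ini$delta <- delta0
    }
    c(ini, extra)
  })
}

.run_jags <- function(model_string, dat, config, monitor, extra_inits = NULL,
                      random_effects = TRUE) {
  drop <- "study_ids"
  if (!random_effects) drop <- c(drop, "tau.upper")
  dat_model <- dat[setdiff(names(dat), drop)]
  jm <- rjags::jags.model(textConnection(model_string), data = dat_model,
                          inits = .jags_inits(dat, config, extra_inits,
                                              random_effects),
                          n.chains = config$chains, n.adapt = config$adapt,
                          quiet = TRUE)
  update(jm, config$burn_in, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = config$iterations,
                      thin = config$thin, progress.bar = "none")
}

# split-chain potential scale reduction factor (each chain halved)
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  L <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- L * stats::var(means)
  if (W <= .Machine$double.eps) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Fit a random-effects network meta-analysis
#'
#' Fits the binomial-logit random-effects NMA by MCMC (JAGS), with vague
#' normal priors on the basic parameters `d` (log odds ratio of each
#' intervention versus the reference) and study baselines, and a uniform
#' prior on the between-study standard deviation `tau`. Studies with an
#' empty 2x2 cell are continuity-corrected automatically; non-integer
#' (cluster-adjusted) counts are handled by a continuous relaxation of the
#' binomial likelihood. Multi-arm trials use the standard conditional
#' construction for correlated arm effects.
#'
#' A split-chain convergence diagnostic is computed for every basic
#' parameter and `tau`; if any exceeds `config$rhat_threshold` a warning of
#' class `nmarobust_convergence_warning` is raised (never silent success).
#'
#' @param network an [nma_network()] object (must be connected)
#' @param config an [nma_config()]
#' @param random_effects if `FALSE`, fit the common-effect model (`tau`
#'   fixed at 0)
#' @return object of class `nma_fit`: posterior draw matrices `d`
#'   (iterations x K, reference column identically 0), `tau`, `mu`, the
#'   underlying [coda::mcmc.list], split-chain `rhat` per monitored
#'   parameter, and the input network/config.
#' @export
fit_nma <- function(network, config = nma_config(), random_effects = TRUE) {
  stopifnot(inherits(network, "nma_network"))
  dat <- .jags_data(network, config)
  dat$tau.upper <- config$prior_tau_upper
  if (random_effects) {
    sam <- .run_jags(.jags_model_consistency(), dat, config,
                     c("d", "tau", "mu"))
  } else {
    sam <- .run_jags(.jags_model_fixed(), dat, config, c("d", "mu"),
                     random_effects = FALSE)
  }
  .build_fit(sam, network, config, dat, random_effects)
}

.build_fit <- function(sam, network, config, dat, random_effects) {
  K <- dat$nt
  m <- as.matrix(sam)
  dcols <- paste0("d[", seq_len(K), "]")
  d <- m[, dcols, drop = FALSE]
  colnames(d) <- network$interventions$label
  mon <- paste0("d[", 2:K, "]")
  if (random_effects) mon <- c(mon, "tau")
  rhat <- vapply(mon, function(p) {
    split_rhat(lapply(sam, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  fit <- structure(list(
    d = d,
    tau = if (random_effects) as.numeric(m[, "tau"]) else rep(0, nrow(m)),
    mu = m[, grep("^mu\\[", colnames(m)), drop = FALSE],
    mcmc = sam, rhat = rhat, network = network, config = config,
    random_effects = random_effects, study_ids = dat$study_ids),
    class = "nma_fit")
  bad <- rhat[rhat > config$rhat_threshold]
  if (length(bad) > 0) {
    warning(warningCondition(
      paste0("possible non-convergence: split-chain Rhat > ",
             config$rhat_threshold, " for ",
             paste(names(bad), collapse = ", "),
             " (max ", round(max(bad), 3), "); increase iterations"),
      class = c("nmarobust_convergence_warning", "nmarobust_warning")))
  }
  fit
}

#' @export
print.nma_fit <- function(x, ...) {
  K <- ncol(x$d)
  cat("Random-effects NMA fit:", x$network$outcome_label, "\n")
  cat(sprintf("  %d chains x %d iterations (burn-in %d); max split-Rhat %.3f\n",
              x$config$chains, x$config$iterations, x$config$burn_in,
              max(x$rhat)))
  or <- apply(exp(x$d[, -1, drop = FALSE]), 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975))
  cat("  posterior median OR vs", x$network$interventions$label[1], "\n")
  for (k in seq_len(K - 1)) {
    cat(sprintf("    %-60s %6.2f (%.2f, %.2f)\n",
                colnames(x$d)[k + 1], or[1, k], or[2, k], or[3, k]))
  }
  if (x$random_effects) {
    cat(sprintf("  tau posterior median %.3f (log-OR scale)\n",
                stats::median(x$tau)))
  } else cat("  common-effect model (tau ~ 0)\n")
  invisible(x)
}

#' Posterior means of the basic parameters
#' @param object an [fit_nma()] result
#' @param ... unused
#' @return named numeric vector of length K (reference entry 0)
#' @export
coef.nma_fit <- function(object, ...) colMeans(object$d)

#' Relative-effect (odds ratio) table
#'
#' Posterior summaries of `exp(d_k - d_c)` for every ordered intervention
#' pair. Diagonal entries are exactly 1 and the matrix is reciprocal
#' draw-by-draw: `OR(c,k) = 1 / OR(k,c)`.
#'
#' @param fit an [fit_nma()] result
#' @param probs quantiles summarised (default median and 95% interval)
#' @return list of class `relative_effects` with K x K matrices `median`,
#'   `lower`, `upper`; entry `[c, k]` summarises the odds ratio of `k`
#'   versus `c`.
#' @export
relative_effects <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  K <- ncol(fit$d)
  labs <- colnames(fit$d)
  med <- lo <- hi <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (c in seq_len(K)) {
    for (k in seq_len(K)) {
      q <- stats::quantile(exp(fit$d[, k] - fit$d[, c]), probs = probs)
      lo[c, k] <- q[1]; med[c, k] <- q[2]; hi[c, k] <- q[3]
    }
  }
  structure(list(median = med, lower = lo, upper = hi,
                 outcome_label = fit$network$outcome_label),
            class = "relative_effects")
}

#' @export
print.relative_effects <- function(x, digits = 2, ...) {
  cat("Posterior odds ratios (column vs row),", x$outcome_label, "\n")
  print(round(x$median, digits))
  invisible(x)
}

#' Rank interventions by effectiveness
#'
#' Ranks the interventions within every posterior draw (rank 1 = most
#' effective) and summarises the rank distribution. For uptake outcomes a
#' larger log odds of the behaviour is better (`higher_is_better = TRUE`).
#'
#' @param fit an [fit_nma()] result
#' @param higher_is_better direction of benefit
#' @return data frame of class `rank_table` with columns `code`, `label`,
#'   `rank_median`, `rank_lower`, `rank_upper` (95% credible interval,
#'   integer quantiles) and `prob_best` (fraction of draws ranked 1;
#'   sums to 1 across interventions).
#' @export
rank_interventions <- function(fit, higher_is_better = TRUE) {
  d <- fit$d
  if (higher_is_better) d <- -d
  rk <- t(apply(d, 1, rank, ties.method = "first"))
  out <- data.frame(
    code = fit$network$interventions$code,
    label = fit$network$interventions$label,
    rank_median = apply(rk, 2, stats::median),
    rank_lower = apply(rk, 2, stats::quantile, probs = 0.025, type = 1),
    rank_upper = apply(rk, 2, stats::quantile, probs = 0.975, type = 1),
    prob_best = colMeans(rk == 1))
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Pairwise random-effects meta-analysis of one contrast
#'
#' Meta-analyses only the studies that compare the two interventions
#' head-to-head, with the same binomial-logit likelihood and priors as
#' [fit_nma()] restricted to two treatments. Mirrors the lower-triangle
#' entries of the published relative-effect tables.
#'
#' @param network an [nma_network()] object
#' @param contrast integer pair `c(c, k)` with `c < k`
#' @param config an [nma_config()]
#' @return list of class `pairwise_fit` with `or` (posterior median odds
#'   ratio of `k` vs `c`), `lower`, `upper`, `n_studies` and `draws`.
#'   When no study compares the pair directly all numeric entries are `NA`
#'   (matching the NA cells of published tables).
#' @export
fit_pairwise <- function(network, contrast, config = nma_config()) {
  contrast <- sort(as.integer(contrast))
  arms <- network$arms
  keep <- vapply(split(arms, arms$study_id), function(a) {
    setequal(a$intervention, contrast)
  }, logical(1))
  sids <- unique(arms$study_id)[keep]
  if (length(sids) == 0) {
    return(structure(list(contrast = contrast, n_studies = 0L,
                          or = NA_real_, lower = NA_real_, upper = NA_real_,
                          draws = NULL),
                     class = "pairwise_fit"))
  }
  sub <- arms[arms$study_id %in% sids, ]
  sub$intervention <- match(sub$intervention, contrast)
  subnet <- nma_network(sub[setdiff(names(sub), "intervention_label")],
                        interventions = data.frame(
                          code = 1:2,
                          label = network$interventions$label[contrast]),
                        outcome_label = network$outcome_label)
  fit <- suppressWarnings(fit_nma(subnet, config))
  dr <- exp(fit$d[, 2])
  q <- stats::quantile(dr, c(0.025, 0.5, 0.975))
  structure(list(contrast = contrast, n_studies = length(sids),
                 or = unname(q[2]), lower = unname(q[1]),
                 upper = unname(q[3]), draws = dr, fit = fit),
            class = "pairwise_fit")
}

#' @export
print.pairwise_fit <- function(x, ...) {
  cat(sprintf("Pairwise random-effects meta-analysis, %d vs %d (%d studies)\n",
              x$contrast[2], x$contrast[1], x$n_studies))
  if (is.na(x$or)) cat("  no direct evidence: NA\n")
  else cat(sprintf("  OR %.2f (%.2f, %.2f)\n", x$or, x$lower, x$upper))
  invisible(x)
}

#' Contrasts with both direct and indirect evidence
#'
#' A contrast can be node-split when at least one study compares it
#' directly and the network remains connected between the two interventions
#' after removing all of those studies.
#'
#' @param network an [nma_network()] object
#' @return data frame with columns `c`, `k`
#' @export
splittable_contrasts <- function(network) {
  ed <- unique(network_edges(network)[c("c", "k")])
  ok <- vapply(seq_len(nrow(ed)), function(i) {
    .has_indirect(network, c(ed$c[i], ed$k[i]))
  }, logical(1))
  res <- ed[ok, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.direct_study_ids <- function(network, contrast) {
  arms <- network$arms
  keep <- vapply(split(arms, arms$study_id), function(a) {
    all(contrast %in% a$intervention)
  }, logical(1))
  unique(arms$study_id)[keep]
}

.has_indirect <- function(network, contrast) {
  sids <- .direct_study_ids(network, contrast)
  if (length(sids) == 0) return(FALSE)
  ed <- network_edges(network)
  ed <- ed[!ed$study_id %in% sids, ]
  if (nrow(ed) == 0) return(FALSE)
  K <- n_interventions(network)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$c, to = ed$k), directed = FALSE,
    vertices = data.frame(name = seq_len(K)))
  !is.infinite(igraph::distances(g, v = as.character(contrast[1]),
                                 to = as.character(contrast[2]))[1, 1])
}

#' Node-splitting consistency check
#'
#' Splits one contrast into a direct-evidence parameter (informed only by
#' the head-to-head studies) and the indirect estimate implied by the rest
#' of the network, within a single joint model sharing `tau` and the study
#' baselines. The inconsistency p-value is the two-sided posterior tail
#' probability of the direct-minus-indirect difference,
#' `2 * min(Pr(diff > 0), Pr(diff < 0))`.
#'
#' @param network an [nma_network()] object (two-arm studies on the split
#'   contrast)
#' @param contrast integer pair `c(c, k)`, must lie in a closed evidence loop
#' @param config an [nma_config()]
#' @return list of class `node_split`: posterior median and 95% CrI of the
#'   direct and indirect log odds ratios, their difference, and `p_value`.
#' @export
node_split <- function(network, contrast, config = nma_config()) {
  contrast <- sort(as.integer(contrast))
  if (!.has_indirect(network, contrast)) {
    stop_validation("contrast ", contrast[1], " vs ", contrast[2],
                    " is not in a closed loop: no independent indirect ",
                    "evidence, so it cannot be node-split")
  }
  sids <- .direct_study_ids(network, contrast)
  dat <- .jags_data(network, config)
  if (any(dat$na[match(sids, dat$study_ids)] != 2) || max(dat$na) > 2) {
    stop_validation("node_split supports networks of two-arm studies")
  }
  split <- as.numeric(dat$study_ids %in% sids)
  # orientation of each direct study relative to ddir = d[k] - d[c]
  dir.sign <- rep(1, dat$ns)
  for (i in seq_len(dat$ns)) {
    if (split[i] == 1) {
      dir.sign[i] <- if (dat$t[i, 1] == contrast[1]) 1 else -1
    }
  }
  dat$split <- split
  dat$dir.sign <- dir.sign
  sam <- .run_jags(.jags_model_nodesplit(), dat, config,
                   c("d", "tau", "ddir"), extra_inits = list(ddir = 0))
  m <- as.matrix(sam)
  direct <- m[, "ddir"]
  indirect <- m[, paste0("d[", contrast[2], "]")] -
    m[, paste0("d[", contrast[1], "]")]
  diff <- direct - indirect
  p <- 2 * min(mean(diff > 0), mean(diff < 0))
  q <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975))
  structure(list(contrast = contrast,
                 direct = q(direct), indirect = q(indirect),
                 difference = q(diff), p_value = p,
                 n_direct_studies = length(sids)),
            class = "node_split")
}

#' @export
print.node_split <- function(x, ...) {
  cat(sprintf("Node split %d vs %d (%d direct studies)\n",
              x$contrast[2], x$contrast[1], x$n_direct_studies))
  f <- function(q) sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
  cat("  direct  :", f(x$direct), "\n")
  cat("  indirect:", f(x$indirect), "\n")
  cat(sprintf("  inconsistency p-value: %.3f\n", x$p_value))
  invisible(x)
}
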