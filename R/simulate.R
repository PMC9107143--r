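# Synthetic evidence networks with known truth, generated from exactly the
# model the NMA assumes: study baselines mu_i ~ N(baseline_mean,
# baseline_sd^2) on the log-odds scale, study effects delta_i ~
# N(d_k - d_c + bias_i, tau^2), binomial arm counts.

#' Generating truth for a synthetic network
#'
#' @param d_true numeric vector of length K of basic parameters (log odds
#'   ratios versus intervention 1); the first entry must be 0
#' @param tau non-negative between-study SD on the log-OR scale
#' @param baseline_mean,baseline_sd distribution of study baseline log odds.
#'   The defaults give mid-range uptake proportions comparable to the
#'   packaged networks.
#' @param biases optional named numeric vector of additive log-OR biases,
#'   names = study indices (as characters)
#' @param seed integer seed making the generated network reproducible
#' @return list of class `synthetic_truth`
#' @export
synthetic_truth <- function(d_true, tau, baseline_mean = -0.5,
                            baseline_sd = 0.5, biases = NULL, seed = 1) {
  if (d_true[1] != 0) stop_validation("d_true[1] (reference) must be 0")
  if (tau < 0) stop_validation("tau must be non-negative")
  structure(list(d_true = as.numeric(d_true), tau = tau,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 biases = biases, seed = as.integer(seed)),
            class = "synthetic_truth")
}

.default_contrasts <- function(K, n_studies) {
  # spanning comparisons first (each non-reference intervention vs 1),
  # then pairs cycled deterministically; randomness only through the seed
  base <- lapply(2:K, function(k) c(1L, k))
  if (n_studies < length(base)) {
    stop_validation("need at least K - 1 studies to connect ", K,
                    " interventions")
  }
  extra <- n_studies - length(base)
  pool <- utils::combn(K, 2)
  idx <- (seq_len(extra) - 1L) %% ncol(pool) + 1L
  c(base, lapply(idx, function(i) pool[, i]))
}

#' Simulate an evidence network with known truth
#'
#' Draws a network of (by default two-arm) studies from the random-effects
#' binomial-logit model. The contrast layout guarantees a connected
#' comparison graph: unless `contrasts` is supplied, the first `K - 1`
#' studies compare each intervention against the reference and the rest
#' cycle through all pairs. With `multi_arm_prob > 0`, some studies gain a
#' third arm; their arm effects are drawn jointly with the standard
#' compound-symmetric covariance (variance `tau^2`, correlation 1/2).
#'
#' @param K number of interventions (>= 2)
#' @param n_studies number of studies (>= K - 1)
#' @param truth a [synthetic_truth()]
#' @param arm_size households per arm
#' @param contrasts optional list of integer pairs, one per study
#' @param multi_arm_prob probability a study gets a third arm
#' @return list with the simulated `network` and the `truth` used
#' @export
simulate_network <- function(K, n_studies, truth, arm_size = 200,
                             contrasts = NULL, multi_arm_prob = 0) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (K < 2) stop_validation("K must be >= 2")
  if (length(truth$d_true) != K) {
    stop_validation("length(d_true) must equal K")
  }
  if (is.null(contrasts)) contrasts <- .default_contrasts(K, n_studies)
  if (length(contrasts) != n_studies) {
    stop_validation("need one contrast per study")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)

  rows <- list()
  for (i in seq_len(n_studies)) {
    tt <- sort(unique(as.integer(contrasts[[i]])))
    if (multi_arm_prob > 0 && stats::runif(1) < multi_arm_prob && K > 2) {
      cand <- setdiff(seq_len(K), tt)
      if (length(cand) > 0) tt <- sort(c(tt, sample(cand, 1)))
    }
    mu <- stats::rnorm(1, truth$baseline_mean, truth$baseline_sd)
    bias <- 0
    if (!is.null(truth$biases)) {
      b <- truth$biases[as.character(i)]
      if (!is.na(b)) bias <- unname(b)
    }
    m <- length(tt)
    dmean <- truth$d_true[tt[-1]] - truth$d_true[tt[1]] + bias
    if (m == 2) {
      delta <- c(0, stats::rnorm(1, dmean, truth$tau))
    } else {
      Cov <- truth$tau^2 * (diag(m - 1) + 1) / 2
      delta <- c(0, MASS::mvrnorm(1, dmean, Cov))
    }
    p <- stats::plogis(mu + delta)
    r <- stats::rbinom(m, arm_size, p)
    rows[[i]] <- data.frame(study_id = i, study_name = paste("sim", i),
                            design = "RCT", intervention = tt,
                            events = r, size = arm_size)
  }
  net <- nma_network(do.call(rbind, rows),
                     outcome_label = "simulated binary uptake")
  list(network = net, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic network with the poisoning-prevention topology
#'
#' Generates a network with the same shape as the packaged
#' poisoning-prevention evidence base: 7 interventions, 15 two-arm studies
#' on the same contrasts with comparable arm sizes. Truth defaults to
#' effects of the magnitude seen in that analysis and substantial
#' heterogeneity; all generating parameters can be overridden.
#'
#' @param seed integer seed
#' @param d_true,tau,baseline_mean,baseline_sd see [synthetic_truth()]
#' @param biases optional per-study additive biases (see [synthetic_truth()])
#' @return list with `network` and `truth`
#' @export
poison_like_scenario <- function(seed = 1,
                                 d_true = c(0, 0.25, 0.8, 0.95, 0.3, 1.0, -1.4),
                                 tau = 0.8, baseline_mean = -0.5,
                                 baseline_sd = 0.5, biases = NULL) {
  contrasts <- list(c(1, 2), c(1, 2), c(1, 2), c(1, 2), c(1, 2),
                    c(1, 3), c(1, 3),
                    c(1, 4), c(1, 4), c(1, 4),
                    c(1, 5), c(2, 3), c(2, 5), c(3, 7), c(4, 6))
  sizes <- c(55, 87, 59, 68, 109, 150, 82, 365, 58, 39, 681, 48, 45, 102, 476)
  truth <- synthetic_truth(d_true, tau, baseline_mean, baseline_sd,
                           biases, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  rows <- list()
  for (i in seq_along(contrasts)) {
    tt <- contrasts[[i]]
    mu <- stats::rnorm(1, baseline_mean, baseline_sd)
    bias <- 0
    if (!is.null(biases)) {
      b <- biases[as.character(i)]
      if (!is.na(b)) bias <- unname(b)
    }
    delta <- stats::rnorm(1, d_true[tt[2]] - d_true[tt[1]] + bias, tau)
    p <- stats::plogis(c(mu, mu + delta))
    r <- stats::rbinom(2, sizes[i], p)
    rows[[i]] <- data.frame(study_id = i, study_name = paste("sim", i),
                            design = "RCT", intervention = tt,
                            events = r, size = sizes[i])
  }
  net <- nma_network(do.call(rbind, rows),
                     outcome_label = "simulated poisoning-prevention uptake")
  list(network = net, truth = truth)
}
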