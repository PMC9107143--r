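# Threshold (bias-adjustment) analysis: how much any one piece of evidence
# could change, on the log odds ratio scale, before the recommended
# intervention changes.
#
# The machinery is a first-order Bayesian approximation. Writing y for the
# vector of data points (study log ORs, or pooled direct log ORs per
# contrast), an additive bias eps in data point j moves the posterior means
# of the basic parameters d approximately linearly,
#     dhat' = dhat + U[, j] * eps,    U = Sigma_post X' V^{-1},
# where Sigma_post is the posterior covariance of (d_2, ..., d_K) estimated
# from the MCMC draws, X maps basic parameters to each data point's contrast
# (+1/-1 coding) and V is the diagonal likelihood covariance of the data
# points under the random-effects marginal (v_j + tau^2 at study level;
# pooled variance + tau^2 / m_j at contrast level, m_j = number of direct
# studies). Equating dhat'_a with dhat'_{k*} for every rival a of the base
# optimum k* yields the positive and negative thresholds in closed form.

#' Optimal intervention under the expected-effect decision rule
#'
#' Returns the intervention with the highest expected effect (posterior mean
#' of the basic parameter, reference entry 0). Ties are broken towards the
#' lowest code, with a warning.
#'
#' @param d_means numeric vector of length K; entry 1 (reference) must be 0
#' @return integer intervention code
#' @export
optimal_intervention <- function(d_means) {
  best <- max(d_means)
  hits <- unname(which(d_means >= best - 1e-12))
  if (length(hits) > 1) {
    warning("tie for the optimal intervention between codes ",
            paste(hits, collapse = ", "), "; taking the lowest code")
  }
  hits[1]
}

#' Influence of each data point on the basic parameters
#'
#' First-order influence matrix `U` whose entry `[k, j]` is the change in the
#' posterior mean of basic parameter `d_k` per unit additive bias in data
#' point `j` (see the construction above). At study level the data points
#' are the per-study log odds ratios; at contrast level they are the
#' inverse-variance pooled direct estimates per observed contrast.
#'
#' @param network an [nma_network()] object
#' @param fit the matching [fit_nma()] result
#' @param level `"study"` or `"contrast"`
#' @param tau_estimate plug-in for the heterogeneity SD entering the
#'   likelihood covariance: posterior `"median"` (default) or `"mean"`
#' @param sigma how the posterior covariance of the basic parameters is
#'   obtained: `"draws"` (default) takes the empirical covariance of the
#'   MCMC draws, marginal over the heterogeneity; `"conditional"` uses the
#'   two-stage normal approximation at the plug-in heterogeneity,
#'   `(X'V^{-1}X + prior precision)^{-1}`. The two agree when `tau` is well
#'   identified by the data; with very few studies the marginal covariance
#'   is inflated by prior-driven `tau` uncertainty and `"conditional"` is
#'   the better-calibrated linearisation.
#' @return object of class `influence_matrix`: `U` ((K-1) x J, rows named by
#'   non-reference interventions), `data_points` (with `id`, `c`, `k`,
#'   `estimate`, `variance`, `n_studies`, and 95% interval columns),
#'   `d_means`, `tau_hat`, `Sigma`, `level`.
#' @export
influence_matrix <- function(network, fit, level = c("study", "contrast"),
                             tau_estimate = c("median", "mean"),
                             sigma = c("draws", "conditional")) {
  level <- match.arg(level)
  tau_estimate <- match.arg(tau_estimate)
  sigma <- match.arg(sigma)
  stopifnot(inherits(fit, "nma_fit"))
  K <- n_interventions(network)

  tau_hat <- if (!fit$random_effects) 0
  else if (tau_estimate == "median") stats::median(fit$tau)
  else mean(fit$tau)

  if (level == "study") {
    sc <- study_contrasts(network)
    dp <- data.frame(id = sc$study_id, label = sc$study_name,
                     c = sc$c, k = sc$k, estimate = sc$estimate,
                     variance = sc$variance, n_studies = 1L)
    Vdiag <- dp$variance + tau_hat^2
    # delta-method normal confidence interval of the study estimate
    hw <- stats::qnorm(0.975) * sqrt(dp$variance)
    dp$ci_low <- dp$estimate - hw
    dp$ci_high <- dp$estimate + hw
  } else {
    pc <- pooled_contrasts(network)
    dp <- data.frame(id = paste0(pc$k, " vs ", pc$c),
                     label = paste0(pc$k, " vs ", pc$c),
                     c = pc$c, k = pc$k, estimate = pc$estimate,
                     variance = pc$variance, n_studies = pc$n_studies)
    Vdiag <- dp$variance + tau_hat^2 / dp$n_studies
    hw <- stats::qnorm(0.975) * sqrt(dp$variance)
    dp$ci_low <- dp$estimate - hw
    dp$ci_high <- dp$estimate + hw
    # posterior credible interval of the combined (NMA) contrast, for
    # reference alongside the pooled-direct confidence interval
    cri <- t(vapply(seq_len(nrow(dp)), function(j) {
      stats::quantile(fit$d[, dp$k[j]] - fit$d[, dp$c[j]], c(0.025, 0.975))
    }, numeric(2)))
    dp$cri_low <- cri[, 1]
    dp$cri_high <- cri[, 2]
  }
  if (any(Vdiag <= 0)) {
    stop_validation("non-positive likelihood variance for data point ",
                    dp$id[which(Vdiag <= 0)[1]])
  }

  J <- nrow(dp)
  X <- matrix(0, J, K - 1)
  for (j in seq_len(J)) {
    if (dp$c[j] > 1) X[j, dp$c[j] - 1] <- -1
    X[j, dp$k[j] - 1] <- 1
  }
  Sigma <- if (sigma == "draws") {
    stats::cov(fit$d[, -1, drop = FALSE])
  } else {
    prior_prec <- 1 / fit$config$prior_sd_effects^2
    solve(t(X) %*% diag(1 / Vdiag, J) %*% X + diag(prior_prec, K - 1))
  }
  U <- Sigma %*% t(X) %*% diag(1 / Vdiag, J)
  rownames(U) <- network$interventions$label[-1]
  colnames(U) <- as.character(dp$id)

  structure(list(U = U, data_points = dp, d_means = colMeans(fit$d),
                 tau_hat = tau_hat, Sigma = Sigma, level = level,
                 interventions = network$interventions),
            class = "influence_matrix")
}

#' Bias-adjustment thresholds and decision-invariant intervals
#'
#' For every data point, the smallest negative and positive additive biases
#' (log-OR scale) that would change the recommended intervention, obtained
#' from the linearised influence of the data point on the basic parameters.
#' The invariant interval is the range of values the estimate could take
#' without changing the recommendation; a side with no finite threshold is
#' reported as `-Inf`/`Inf` and printed as "NT" (no threshold). A data point
#' is robust when its 95% interval lies inside the invariant interval.
#'
#' At contrast level the robustness interval defaults to the pooled
#' direct-evidence confidence interval so that a contrast observed by a
#' single study agrees with the study-level analysis; set
#' `interval = "posterior"` to judge robustness against the NMA posterior
#' credible interval instead.
#'
#' @param infl an [influence_matrix()] object
#' @param interval interval used for the robustness flag at contrast level
#' @return object of class `threshold_report`: `level`, the base optimal
#'   intervention `k_star`, and `rows`, a data frame with one row per data
#'   point (`id`, `c`, `k`, `estimate`, `ci_low`, `ci_high`, `eps_neg`,
#'   `eps_pos`, `inv_low`, `inv_high`, `new_opt_low`, `new_opt_high`,
#'   `robust`).
#' @export
compute_thresholds <- function(infl, interval = c("pooled", "posterior")) {
  stopifnot(inherits(infl, "influence_matrix"))
  interval <- match.arg(interval)
  d_means <- infl$d_means
  K <- length(d_means)
  dp <- infl$data_points
  J <- nrow(dp)
  if (ncol(infl$U) != J || nrow(infl$U) != K - 1) {
    stop_validation("influence matrix dimensions do not match the data points")
  }
  k_star <- optimal_intervention(d_means)
  Ufull <- rbind(0, infl$U) # reference row: zero influence by construction

  eps_neg <- eps_pos <- numeric(J)
  new_lo <- new_hi <- rep(NA_integer_, J)
  rivals <- setdiff(seq_len(K), k_star)
  for (j in seq_len(J)) {
    den <- Ufull[rivals, j] - Ufull[k_star, j]
    num <- d_means[k_star] - d_means[rivals]
    keep <- abs(den) > 1e-12
    cand <- num[keep] / den[keep]
    rv <- rivals[keep]
    pos <- cand > 0
    if (any(pos)) {
      eps_pos[j] <- min(cand[pos])
      new_hi[j] <- rv[pos][which.min(cand[pos])]
    } else eps_pos[j] <- Inf
    neg <- cand < 0
    if (any(neg)) {
      eps_neg[j] <- max(cand[neg])
      new_lo[j] <- rv[neg][which.max(cand[neg])]
    } else eps_neg[j] <- -Inf
  }

  if (infl$level == "contrast" && interval == "posterior") {
    lo <- dp$cri_low; hi <- dp$cri_high
  } else {
    lo <- dp$ci_low; hi <- dp$ci_high
  }
  rows <- data.frame(
    id = dp$id, label = dp$label, c = dp$c, k = dp$k,
    estimate = dp$estimate, ci_low = lo, ci_high = hi,
    eps_neg = eps_neg, eps_pos = eps_pos,
    inv_low = dp$estimate + eps_neg, inv_high = dp$estimate + eps_pos,
    new_opt_low = new_lo, new_opt_high = new_hi,
    robust = lo >= dp$estimate + eps_neg & hi <= dp$estimate + eps_pos)
  if (!is.null(dp$cri_low)) {
    rows$cri_low <- dp$cri_low
    rows$cri_high <- dp$cri_high
  }
  structure(list(level = infl$level, k_star = k_star, rows = rows,
                 tau_hat = infl$tau_hat, interventions = infl$interventions),
            class = "threshold_report")
}

#' One-call threshold analysis
#'
#' Convenience wrapper: [influence_matrix()] followed by
#' [compute_thresholds()].
#'
#' @inheritParams influence_matrix
#' @inheritParams compute_thresholds
#' @return a `threshold_report` (see [compute_thresholds()])
#' @export
threshold_analysis <- function(network, fit, level = c("study", "contrast"),
                               tau_estimate = c("median", "mean"),
                               sigma = c("draws", "conditional"),
                               interval = c("pooled", "posterior")) {
  compute_thresholds(influence_matrix(network, fit, level, tau_estimate,
                                      sigma),
                     interval = interval)
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("%s-level threshold analysis; base optimal intervention: %d (%s)\n",
              x$level, x$k_star, x$interventions$label[x$k_star]))
  nr <- sum(!x$rows$robust)
  cat(sprintf("  %d of %d data points non-robust\n", nr, nrow(x$rows)))
  print(threshold_forest_table(x)$table, row.names = FALSE)
  invisible(x)
}

.fmt_nt <- function(x, digits = 2) {
  ifelse(is.finite(x), formatC(x, digits = digits, format = "f"), "NT")
}

#' Tabular (forest-plot style) export of a threshold report
#'
#' One row per data point with thresholds and invariant interval, unbounded
#' sides rendered as the literal string "NT", plus summary counts of
#' non-robust rows.
#'
#' @param report a `threshold_report` from [compute_thresholds()]
#' @return list with `table` (data frame of formatted rows),
#'   `n_nonrobust`, and `nonrobust_ids`
#' @export
threshold_forest_table <- function(report) {
  r <- report$rows
  tab <- data.frame(
    id = r$id, contrast = paste0(r$k, " vs ", r$c),
    estimate = round(r$estimate, 2),
    ci = sprintf("(%.2f, %.2f)", r$ci_low, r$ci_high),
    eps_neg = .fmt_nt(r$eps_neg), eps_pos = .fmt_nt(r$eps_pos),
    invariant = paste0("(", .fmt_nt(r$inv_low), ", ", .fmt_nt(r$inv_high), ")"),
    new_opt_low = r$new_opt_low, new_opt_high = r$new_opt_high,
    robust = r$robust)
  list(table = tab, n_nonrobust = sum(!r$robust),
       nonrobust_ids = r$id[!r$robust])
}

#' Forest-style plot of a threshold report
#'
#' Point estimates with 95% intervals and the decision-invariant interval
#' per data point; non-robust rows are drawn in red. Requires ggplot2.
#'
#' @param x a `threshold_report`
#' @param ... unused
#' @export
plot.threshold_report <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting a threshold_report requires the ggplot2 package")
  }
  r <- x$rows
  r$id <- factor(r$id, levels = rev(unique(r$id)))
  r$status <- ifelse(r$robust, "robust", "non-robust")
  lim <- max(abs(c(r$ci_low, r$ci_high, r$estimate))) * 2 + 1
  r$inv_lo_clip <- pmax(r$inv_low, -lim)
  r$inv_hi_clip <- pmin(r$inv_high, lim)
  ggplot2::ggplot(r, ggplot2::aes(y = id)) +
    ggplot2::geom_segment(ggplot2::aes(x = inv_lo_clip, xend = inv_hi_clip,
                                       yend = id),
                          linewidth = 4, alpha = 0.25) +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = ci_low, xmax = ci_high,
                                        colour = status),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(x = estimate, colour = status)) +
    ggplot2::scale_colour_manual(values = c(robust = "black",
                                            `non-robust` = "red")) +
    ggplot2::labs(x = "log odds ratio", y = NULL, colour = NULL,
                  title = sprintf("%s-level thresholds (optimum: %s)",
                                  x$level,
                                  x$interventions$label[x$k_star]))
}

#' Brute-force decision-flip oracle
#'
#' Validates the linear threshold approximation by refitting the NMA under
#' additive biases on a grid: the chosen study's non-baseline arm log odds
#' are shifted by `eps` (scanning outward from 0 in steps of `grid`, each
#' sign separately) and the first value at which the optimal intervention
#' changes is returned. Sides with no flip within `max_bias` are reported
#' as unbounded (`-Inf`/`Inf`), the analogue of "NT".
#'
#' Every grid point is a full MCMC refit, so this is intended for small
#' synthetic networks and modest `config` settings.
#'
#' @param network an [nma_network()] object of two-arm studies
#' @param study_id the data point (study) to perturb
#' @param config an [nma_config()] used for every refit
#' @param grid step size on the log-OR scale (<= 0.05 recommended)
#' @param max_bias scan limit
#' @param side `"both"`, `"negative"` or `"positive"`
#' @param random_effects passed to [fit_nma()] for every refit
#' @return list with `eps_neg`, `eps_pos` (first flipping bias per side) and
#'   `k_star` (the unperturbed optimum)
#' @export
brute_force_decision_flip <- function(network, study_id,
                                      config = nma_config(),
                                      grid = 0.05, max_bias = 5,
                                      side = c("both", "negative", "positive"),
                                      random_effects = TRUE) {
  side <- match.arg(side)
  base <- suppressWarnings(fit_nma(network, config, random_effects))
  k_star <- optimal_intervention(coef(base))
  signs <- switch(side, both = c(-1, 1), negative = -1, positive = 1)
  out <- list(eps_neg = -Inf, eps_pos = Inf, k_star = k_star)
  for (s in signs) {
    nstep <- floor(max_bias / grid)
    for (step in seq_len(nstep)) {
      eps <- s * step * grid
      pert <- perturb_study(network, study_id, eps)
      cfg <- config
      cfg$seed <- config$seed + 7919L * step + as.integer(s > 0)
      fit <- suppressWarnings(fit_nma(pert, cfg, random_effects))
      if (optimal_intervention(coef(fit)) != k_star) {
        if (s < 0) out$eps_neg <- eps else out$eps_pos <- eps
        break
      }
    }
  }
  out
}

#' Apply an additive log-odds bias to one study
#'
#' Shifts the log odds of a (two-arm) study's non-baseline arm by `eps`,
#' holding the denominator fixed — the elementary perturbation used by
#' [brute_force_decision_flip()]. Continuity correction is applied first,
#' so the perturbed network is exactly what a fit would consume.
#'
#' @param network an [nma_network()] object
#' @param study_id the study to perturb
#' @param eps additive bias on the log-odds (= log odds ratio) scale
#' @return a new [nma_network()]
#' @export
perturb_study <- function(network, study_id, eps) {
  arms <- correct_network_arms(network$arms)
  i <- which(arms$study_id == study_id)
  if (length(i) != 2) {
    stop_validation("perturbation requires a two-arm study; study ",
                    study_id, " not found or not two-arm")
  }
  i <- i[order(arms$intervention[i])]
  j <- i[2]
  odds <- arms$events[j] / (arms$size[j] - arms$events[j]) * exp(eps)
  arms$events[j] <- arms$size[j] * odds / (1 + odds)
  nma_network(arms, network$interventions, network$outcome_label)
}
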