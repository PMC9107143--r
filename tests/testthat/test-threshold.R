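# Threshold analysis: decision rule, influence matrix, closed-form
# thresholds, and agreement with refitting oracles on small networks.

test_that("the decision rule picks the highest expected effect", {
  expect_equal(optimal_intervention(c(0, 0.2, 0.8, 0.1)), 3)
  expect_warning(tie <- optimal_intervention(c(0, 0, 0)), "tie")
  expect_equal(tie, 1)
})

test_that("single-study two-treatment influence approaches unity", {
  arms <- data.frame(study_id = 1, study_name = "only", design = "RCT",
                     intervention = 1:2, events = c(120, 150),
                     size = c(300, 300))
  net <- nma_network(rbind(arms[1, ], arms[2, ]))
  fit <- suppressWarnings(fit_nma(net, quick_config(seed = 14,
                                                    iterations = 6000),
                                  random_effects = FALSE))
  infl <- influence_matrix(net, fit, "study")
  expect_equal(dim(infl$U), c(1, 1))
  expect_equal(infl$U[1, 1], 1, tolerance = 0.1)
})

test_that("thresholds solve the linear decision boundary in closed form", {
  # hand-built influence object: K = 2, one data point with unit influence
  infl <- structure(list(
    U = matrix(1, 1, 1),
    data_points = data.frame(id = 1, label = "dp", c = 1, k = 2,
                             estimate = 0.5, variance = 0.04, n_studies = 1,
                             ci_low = 0.5 - 1.96 * 0.2,
                             ci_high = 0.5 + 1.96 * 0.2),
    d_means = c(0, 0.5), tau_hat = 0, Sigma = matrix(0.04),
    level = "study",
    interventions = data.frame(code = 1:2, label = c("ref", "trt"))),
    class = "influence_matrix")
  rep <- compute_thresholds(infl)
  expect_equal(rep$k_star, 2)
  expect_equal(rep$rows$eps_neg, -0.5)
  expect_equal(rep$rows$eps_pos, Inf)
  expect_equal(rep$rows$inv_low, 0)
  expect_equal(rep$rows$new_opt_low, 1)
  expect_true(is.na(rep$rows$new_opt_high))
  # signs are structural: eps_neg <= 0 <= eps_pos
  expect_lte(rep$rows$eps_neg, 0)
  expect_gte(rep$rows$eps_pos, 0)

  bad <- infl
  bad$U <- matrix(1, 1, 2)
  expect_error(compute_thresholds(bad), class = "nmarobust_validation_error")
})

test_that("influence respects the network topology (tree separation)", {
  # pure chain 1 - 2 - 3: evidence on edge (2,3) cannot move d_12
  sim <- chain_network(n = 500, seed = 31, d_true = c(0, 0.3, 0.5),
                       tau = 0,
                       contrasts = list(c(1, 2), c(1, 2), c(2, 3), c(2, 3)))
  net <- sim$network
  fit <- suppressWarnings(fit_nma(net, quick_config(seed = 16,
                                                    iterations = 5000),
                                  random_effects = FALSE))
  infl <- influence_matrix(net, fit, "study")
  sc <- study_contrasts(net)
  j23 <- which(sc$c == 2 & sc$k == 3)[1]
  j12 <- which(sc$c == 1 & sc$k == 2)[1]
  expect_lt(abs(infl$U[1, j23]), 0.12)      # d_12 untouched by (2,3) evidence
  expect_gt(infl$U[2, j23], 0.2)            # but d_13 responds
  expect_gt(infl$U[1, j12], 0.2)

  # brute-force confirmation: perturbing a (2,3) study leaves d_12 alone
  pert <- perturb_study(net, sc$study_id[j23], 0.8)
  refit <- suppressWarnings(fit_nma(pert, quick_config(seed = 16,
                                                       iterations = 5000),
                                    random_effects = FALSE))
  expect_lt(abs(coef(refit)[2] - coef(fit)[2]), 0.1)
  expect_gt(coef(refit)[3] - coef(fit)[3], 0.1)

  # with few studies the marginal draw covariance is tau-inflated relative
  # to the plug-in likelihood covariance; the conditional linearisation
  # restores the separation structure under the random-effects fit
  fit_re <- suppressWarnings(fit_nma(net, quick_config(seed = 16,
                                                       iterations = 5000)))
  infl_re <- influence_matrix(net, fit_re, "study", sigma = "conditional")
  expect_lt(abs(infl_re$U[1, j23]), 0.12)
  expect_gt(infl_re$U[2, j23], 0.2)
})

test_that("shrinking a data point's variance tightens its thresholds", {
  net <- poison_network()
  infl <- influence_matrix(net, poison_fit(), "study")
  before <- compute_thresholds(infl)$rows
  j <- which(infl$data_points$id == 10)
  # halve the variance of study 10's estimate: influence scales up, so the
  # invariant interval must not widen
  infl2 <- infl
  v_old <- infl2$data_points$variance[j] + infl2$tau_hat^2
  infl2$data_points$variance[j] <- infl2$data_points$variance[j] / 2
  v_new <- infl2$data_points$variance[j] + infl2$tau_hat^2
  infl2$U[, j] <- infl2$U[, j] * v_old / v_new
  after <- compute_thresholds(infl2)$rows
  expect_gte(after$eps_neg[j], before$eps_neg[j])
  expect_lte(after$eps_pos[j], before$eps_pos[j])
})

test_that("single-study contrasts agree exactly across analysis levels", {
  net <- poison_network()
  fit <- poison_fit()
  st <- compute_thresholds(influence_matrix(net, fit, "study"))$rows
  ct <- compute_thresholds(influence_matrix(net, fit, "contrast"))$rows
  # contrasts observed by exactly one study: (1,5), (2,3), (2,5), (3,7), (4,6)
  singles <- list(c(11, "5 vs 1"), c(12, "3 vs 2"), c(13, "5 vs 2"),
                  c(14, "7 vs 3"), c(15, "6 vs 4"))
  for (s in singles) {
    srow <- st[st$id == as.integer(s[1]), ]
    crow <- ct[ct$id == s[2], ]
    expect_equal(crow$estimate, srow$estimate)
    expect_equal(crow$eps_neg, srow$eps_neg, tolerance = 1e-10)
    expect_equal(crow$eps_pos, srow$eps_pos, tolerance = 1e-10)
    expect_equal(crow$robust, srow$robust)
  }
})

test_that("a lone study flips the decision at minus its own estimate", {
  arms <- data.frame(study_id = c(1, 1), study_name = "only", design = "RCT",
                     intervention = 1:2, events = c(150, 210),
                     size = c(400, 400))
  net <- nma_network(arms)
  y <- study_contrasts(net)$estimate
  flip <- brute_force_decision_flip(net, 1,
                                    quick_config(seed = 18,
                                                 iterations = 3000),
                                    grid = 0.05, max_bias = 2,
                                    side = "negative",
                                    random_effects = FALSE)
  expect_equal(flip$k_star, 2)
  expect_equal(flip$eps_neg, -y, tolerance = 0.1 + 0.05)
})

test_that("threshold exports carry NT markers and robustness counts", {
  rep <- compute_thresholds(influence_matrix(poison_network(), poison_fit(),
                                             "study"))
  ft <- threshold_forest_table(rep)
  expect_equal(nrow(ft$table), 15)
  expect_equal(ft$n_nonrobust, sum(!rep$rows$robust))
  s15 <- ft$table[ft$table$id == 15, ]
  expect_equal(s15$eps_pos, "NT")
  expect_match(s15$invariant, "NT")
  # eps signs structural across all rows and both levels
  repc <- compute_thresholds(influence_matrix(poison_network(), poison_fit(),
                                              "contrast"))
  for (r in list(rep$rows, repc$rows)) {
    expect_true(all(r$eps_neg <= 0))
    expect_true(all(r$eps_pos >= 0))
    expect_true(all(r$inv_low <= r$estimate & r$estimate <= r$inv_high))
  }
})
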