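# Network construction, CSV I/O and the data-preparation computations.

test_that("packaged networks load with the published dimensions and counts", {
  poison <- poison_network()
  expect_s3_class(poison, "nma_network")
  expect_equal(n_studies(poison), 15)
  expect_equal(n_interventions(poison), 7)

  stair <- stair_gate_network()
  expect_equal(n_studies(stair), 12)
  expect_equal(n_interventions(stair), 7)

  # spot-check arm counts against the published tables, including the
  # cluster-adjusted real-valued figures and the uncorrected zero-event arm
  a <- poison$arms
  swart <- a[a$study_id == 9, ]
  expect_equal(sort(swart$events), c(46.86, 50.87))
  expect_equal(sort(swart$size), c(57.96, 58.27))
  dersh <- a[a$study_id == 14, ]
  expect_equal(dersh$events[order(dersh$intervention)], c(1, 0))
  expect_equal(dersh$size[order(dersh$intervention)], c(101, 104))
  king <- a[a$study_id == 15, ]
  expect_equal(king$events[order(king$intervention)], c(261, 273))
  expect_equal(king$intervention[order(king$intervention)], c(4, 6))

  b <- stair$arms
  kendrick <- b[b$study_id == 6, ]
  expect_equal(sort(kendrick$events), c(214.26, 223.15))
  expect_true(all(kendrick$size == 323.61))
  phelan <- b[b$study_id == 8, ]
  expect_equal(phelan$events[order(phelan$intervention)], c(78, 131))
})

test_that("network validation rejects malformed input", {
  good <- data.frame(study_id = c(1, 1), study_name = "s", design = "RCT",
                     intervention = 1:2, events = c(5, 6), size = c(10, 10))
  expect_s3_class(nma_network(good), "nma_network")

  bad <- good
  bad$events[1] <- 11
  expect_error(nma_network(bad), class = "nmarobust_validation_error")

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(good[setdiff(names(good), "events")], f, row.names = FALSE)
  expect_error(read_network(f), class = "nmarobust_format_error")
  expect_error(read_network("no/such/file.csv"),
               class = "nmarobust_format_error")

  # two studies whose intervention sets never touch: disconnected graph
  disc <- data.frame(study_id = c(1, 1, 2, 2), study_name = "s",
                     design = "RCT", intervention = c(1, 2, 3, 4),
                     events = 5, size = 10)
  expect_error(nma_network(disc), class = "nmarobust_connectivity_error")

  onearm <- good[1, ]
  onearm$study_id <- 3
  expect_error(nma_network(rbind(good, onearm)),
               class = "nmarobust_validation_error")
})

test_that("networks round-trip through CSV bit-exactly", {
  for (net in list(poison_network(), stair_gate_network())) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_network(net, f)
    back <- read_network(f, outcome_label = net$outcome_label)
    expect_equal(back$arms, net$arms)
    expect_equal(back$interventions, net$interventions)
  }
})

test_that("continuity correction follows the 0.5 / +1 rule per study", {
  expect_equal(continuity_correct(0, 104), data.frame(events = 0.5, size = 105))
  expect_equal(continuity_correct(1, 101), data.frame(events = 1.5, size = 102))
  expect_error(continuity_correct(-1, 10),
               class = "nmarobust_validation_error")

  # studies without an empty cell pass through study_contrasts untouched
  sc <- study_contrasts(poison_network())
  s1 <- sc[sc$study_id == 1, ]
  expect_equal(s1$estimate,
               log_odds_ratio(43, 54, 49, 55)$estimate)
  # the zero-event study is corrected in all arms before the log OR
  s14 <- sc[sc$study_id == 14, ]
  expect_equal(s14$estimate,
               log((0.5 / 104.5) / (1.5 / 100.5)))
})

test_that("design-effect adjustment rescales counts and preserves proportions", {
  expect_equal(cluster_adjust(100, 200, 5, 0.05),
               data.frame(events = 100 / 1.2, size = 200 / 1.2))
  expect_equal(cluster_adjust(7, 31, 4, 0), data.frame(events = 7, size = 31))
  expect_equal(cluster_adjust(7, 31, 1, 0.9), data.frame(events = 7, size = 31))
  expect_error(cluster_adjust(1, 2, 5, 1), class = "nmarobust_validation_error")

  set.seed(4)
  for (i in 1:20) {
    ev <- runif(1, 1, 50); sz <- ev + runif(1, 1, 100)
    adj <- cluster_adjust(ev, sz, runif(1, 1, 30), runif(1, 0, 0.3))
    expect_equal(adj$events / adj$size, ev / sz)
  }
})

test_that("log odds ratios match the published study summaries", {
  s10 <- log_odds_ratio(14, 40, 34, 38)
  expect_equal(s10$estimate, 2.76, tolerance = 0.005)
  s15 <- log_odds_ratio(261, 469, 273, 482)
  expect_equal(s15$estimate, 0.04, tolerance = 0.01)

  same <- log_odds_ratio(10, 20, 10, 20)
  expect_equal(same$estimate, 0)
  expect_equal(same$variance, 0.4)

  expect_error(log_odds_ratio(0, 10, 5, 10),
               class = "nmarobust_validation_error")

  # antisymmetry: flipping the arms negates the estimate, same variance
  set.seed(9)
  for (i in 1:20) {
    n1 <- runif(1, 10, 500); r1 <- runif(1, 0.5, n1 - 0.5)
    n2 <- runif(1, 10, 500); r2 <- runif(1, 0.5, n2 - 0.5)
    ab <- log_odds_ratio(r1, n1, r2, n2)
    ba <- log_odds_ratio(r2, n2, r1, n1)
    expect_equal(ab$estimate, -ba$estimate)
    expect_equal(ab$variance, ba$variance)
  }
})

test_that("pooled direct evidence aggregates per contrast", {
  pc <- pooled_contrasts(poison_network())
  expect_equal(nrow(pc), 8)
  expect_equal(pc$n_studies[pc$c == 1 & pc$k == 2], 5)
  # single-study contrasts inherit the study estimate exactly
  sc <- study_contrasts(poison_network())
  s15 <- sc[sc$study_id == 15, ]
  p46 <- pc[pc$c == 4 & pc$k == 6, ]
  expect_equal(p46$estimate, s15$estimate)
  expect_equal(p46$variance, s15$variance)
  # pooled estimate is a weighted mean: lies inside the study range
  s12 <- sc[sc$c == 1 & sc$k == 4, ]
  p14 <- pc[pc$c == 1 & pc$k == 4, ]
  expect_gt(p14$estimate, min(s12$estimate))
  expect_lt(p14$estimate, max(s12$estimate))
})
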