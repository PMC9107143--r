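# Small data-preparation computations: continuity correction, design-effect
# adjustment, study-level log odds ratios and pooled direct evidence.

#' Haldane-Anscombe continuity correction
#'
#' Adds 0.5 to the event count and 1 to the denominator of an arm, the
#' standard correction for 2x2 tables with an empty cell. It is meant to be
#' applied to *all* arms of a study in which any arm has `events = 0` or
#' `events = size`; [study_contrasts()] and [fit_nma()] do this automatically.
#'
#' @param events,size non-negative arm counts (vectorised)
#' @return data frame with corrected `events` and `size`
#' @examples
#' continuity_correct(0, 104)  # 0.5 / 105
#' @export
continuity_correct <- function(events, size) {
  if (any(events < 0) || any(size < 0)) {
    stop_validation("events and size must be non-negative")
  }
  data.frame(events = events + 0.5, size = size + 1)
}

has_zero_cell <- function(events, size) any(events <= 0 | events >= size)

# apply the correction study-wise where any arm has an empty cell
correct_network_arms <- function(arms) {
  for (sid in unique(arms$study_id)) {
    i <- arms$study_id == sid
    if (has_zero_cell(arms$events[i], arms$size[i])) {
      cc <- continuity_correct(arms$events[i], arms$size[i])
      arms$events[i] <- cc$events
      arms$size[i] <- cc$size
    }
  }
  arms
}

#' Design-effect adjustment for cluster-randomised arms
#'
#' Divides events and denominator by the design effect
#' `DEFF = 1 + (mean_cluster_size - 1) * icc`, the effective-sample-size
#' correction for clustering. The observed proportion is preserved exactly.
#'
#' @param events,size arm counts
#' @param mean_cluster_size average cluster size (>= 1)
#' @param icc intraclass correlation coefficient, in `[0, 1)`
#' @return data frame with adjusted `events` and `size`
#' @examples
#' cluster_adjust(100, 200, mean_cluster_size = 5, icc = 0.05)  # DEFF = 1.2
#' @export
cluster_adjust <- function(events, size, mean_cluster_size, icc) {
  if (any(icc < 0) || any(icc >= 1)) {
    stop_validation("icc must lie in [0, 1)")
  }
  if (any(mean_cluster_size < 1)) {
    stop_validation("mean_cluster_size must be >= 1")
  }
  deff <- 1 + (mean_cluster_size - 1) * icc
  data.frame(events = events / deff, size = size / deff)
}

#' Log odds ratio of one arm versus another
#'
#' Delta-method summary of a 2x2 table: the log odds ratio of the comparator
#' arm `k` versus the control arm `c` and its large-sample variance
#' `1/r_k + 1/(n_k - r_k) + 1/r_c + 1/(n_c - r_c)`. Counts may be
#' real-valued. Empty cells must be continuity-corrected first (see
#' [continuity_correct()]); reaching this function with an empty cell is an
#' error.
#'
#' @param events_c,size_c control arm counts
#' @param events_k,size_k comparator arm counts
#' @return list with `estimate` and `variance`
#' @examples
#' log_odds_ratio(14, 40, 34, 38)  # approx 2.76
#' @export
log_odds_ratio <- function(events_c, size_c, events_k, size_k) {
  cells <- c(events_c, size_c - events_c, events_k, size_k - events_k)
  if (any(cells <= 0)) {
    stop_validation("empty 2x2 cell: apply continuity_correct() before ",
                    "computing log odds ratios")
  }
  list(estimate = log((events_k / (size_k - events_k)) /
                        (events_c / (size_c - events_c))),
       variance = 1 / events_k + 1 / (size_k - events_k) +
         1 / events_c + 1 / (size_c - events_c))
}

#' Study-level contrast estimates
#'
#' One log-odds-ratio summary per (two-arm) study: the estimate of the
#' higher-coded intervention versus the lower-coded one, with delta-method
#' variance. Studies with an empty cell are continuity-corrected (all arms)
#' first. These are the data points of the study-level threshold analysis.
#'
#' @param network an [nma_network()] object
#' @return data frame with columns `study_id`, `study_name`, `c`, `k`,
#'   `estimate`, `variance`
#' @export
study_contrasts <- function(network) {
  arms <- correct_network_arms(network$arms)
  out <- lapply(split(arms, arms$study_id), function(a) {
    if (nrow(a) != 2) {
      stop_validation("study-level contrast summaries are defined for ",
                      "two-arm studies; study ", a$study_id[1], " has ",
                      nrow(a), " arms")
    }
    a <- a[order(a$intervention), ]
    lor <- log_odds_ratio(a$events[1], a$size[1], a$events[2], a$size[2])
    data.frame(study_id = a$study_id[1], study_name = a$study_name[1],
               c = a$intervention[1], k = a$intervention[2],
               estimate = lor$estimate, variance = lor$variance)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$study_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pooled direct evidence per contrast
#'
#' Fixed-effect inverse-variance pooling of the study-level log odds ratios
#' for each intervention pair observed head-to-head. These are the data
#' points of the contrast-level threshold analysis.
#'
#' @param network an [nma_network()] object
#' @return data frame with columns `c`, `k`, `estimate`, `variance`
#'   (variance of the pooled estimate) and `n_studies`
#' @export
pooled_contrasts <- function(network) {
  sc <- study_contrasts(network)
  key <- paste(sc$c, sc$k)
  out <- lapply(unique(key), function(kk) {
    s <- sc[key == kk, ]
    w <- 1 / s$variance
    data.frame(c = s$c[1], k = s$k[1],
               estimate = sum(w * s$estimate) / sum(w),
               variance = 1 / sum(w), n_studies = nrow(s))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$c, res$k), , drop = FALSE]
  rownames(res) <- NULL
  res
}
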