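# Evidence networks of arm-level binary outcome data.

.designs <- c("RCT", "NRCT", "clusterRCT", "clusterNRCT")

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("nmarobust_validation_error",
                                             "nmarobust_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("nmarobust_format_error",
                                             "nmarobust_validation_error",
                                             "nmarobust_error")))
}

#' Construct an evidence network
#'
#' Bundles arm-level binary outcome data (one row per study arm) with the
#' intervention coding into a validated network object. Intervention codes
#' must be contiguous integers starting at 1; code 1 is the network reference
#' (usual care in the packaged networks). Events and sizes may be real-valued
#' to admit design-effect (cluster) adjusted figures.
#'
#' @param arms data frame with columns `study_id`, `study_name`, `design`
#'   (one of `"RCT"`, `"NRCT"`, `"clusterRCT"`, `"clusterNRCT"`),
#'   `intervention` (integer code), `events`, `size`; optional
#'   `intervention_label`, `cluster_adjusted`, `quality`.
#' @param interventions optional data frame with columns `code`, `label`.
#'   Defaults to labels taken from `arms$intervention_label` where present.
#' @param outcome_label short description of the (binary, higher-is-better)
#'   outcome the events count.
#' @return an object of class `nma_network` with elements `arms`,
#'   `interventions` and `outcome_label`.
#' @seealso [read_network()], [poison_network()], [stair_gate_network()]
#' @export
nma_network <- function(arms, interventions = NULL, outcome_label = "") {
  required <- c("study_id", "study_name", "design", "intervention",
                "events", "size")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols) > 0) {
    stop_format("arm table is missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  arms$intervention <- as.integer(arms$intervention)
  arms$events <- as.numeric(arms$events)
  arms$size <- as.numeric(arms$size)
  if (is.null(arms$cluster_adjusted)) arms$cluster_adjusted <- FALSE
  if (anyNA(arms$events) || anyNA(arms$size) || anyNA(arms$intervention)) {
    stop_format("arm table contains missing values in counts or codes")
  }
  if (any(!arms$design %in% .designs)) {
    stop_validation("unknown study design(s): ",
                    paste(unique(setdiff(arms$design, .designs)), collapse = ", "),
                    " (expected ", paste(.designs, collapse = "/"), ")")
  }
  if (any(arms$size <= 0)) stop_validation("arm sizes must be positive")
  if (any(arms$events < 0) || any(arms$events > arms$size)) {
    stop_validation("arm events must satisfy 0 <= events <= size")
  }

  codes <- sort(unique(arms$intervention))
  if (!identical(codes, seq_along(codes))) {
    stop_validation("intervention codes must be contiguous integers 1..K; got ",
                    paste(codes, collapse = ", "))
  }
  if (is.null(interventions)) {
    labels <- vapply(codes, function(k) {
      if (!is.null(arms$intervention_label)) {
        lab <- unique(arms$intervention_label[arms$intervention == k])
        if (length(lab) == 1 && nzchar(lab)) return(lab)
      }
      paste("intervention", k)
    }, character(1))
    interventions <- data.frame(code = codes, label = labels,
                                stringsAsFactors = FALSE)
  } else {
    interventions <- as.data.frame(interventions)
    if (!all(c("code", "label") %in% names(interventions))) {
      stop_format("interventions must have columns code and label")
    }
    interventions <- interventions[order(interventions$code), , drop = FALSE]
    if (!identical(as.integer(interventions$code), seq_along(codes)) ||
        !all(codes %in% interventions$code)) {
      stop_validation("interventions table does not cover arm codes 1..K")
    }
  }

  # per-study structure
  for (sid in unique(arms$study_id)) {
    a <- arms[arms$study_id == sid, ]
    if (nrow(a) < 2) {
      stop_validation("study ", sid, " has fewer than 2 arms")
    }
    if (anyDuplicated(a$intervention)) {
      stop_validation("study ", sid, " repeats an intervention code")
    }
  }

  net <- structure(list(arms = arms, interventions = interventions,
                        outcome_label = outcome_label),
                   class = "nma_network")
  if (!network_connected(net)) {
    stop(errorCondition(
      "comparison graph is not connected: some interventions share no direct or indirect comparison",
      class = c("nmarobust_connectivity_error", "nmarobust_validation_error",
                "nmarobust_error")))
  }
  net
}

#' Number of studies / interventions in a network
#' @param network an [nma_network()] object
#' @return integer count
#' @export
n_studies <- function(network) length(unique(network$arms$study_id))

#' @rdname n_studies
#' @export
n_interventions <- function(network) nrow(network$interventions)

#' Within-study comparison edges of a network
#'
#' One row per unordered intervention pair compared within a study,
#' ordered `c < k`.
#'
#' @param network an [nma_network()] object
#' @return data frame with columns `study_id`, `c`, `k`
#' @export
network_edges <- function(network) {
  out <- lapply(split(network$arms, network$arms$study_id), function(a) {
    tt <- sort(a$intervention)
    pr <- t(utils::combn(tt, 2))
    data.frame(study_id = a$study_id[1], c = pr[, 1], k = pr[, 2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$study_id), , drop = FALSE]
}

network_connected <- function(network, drop_studies = NULL) {
  ed <- network_edges(network)
  if (!is.null(drop_studies)) ed <- ed[!ed$study_id %in% drop_studies, ]
  K <- n_interventions(network)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$c, to = ed$k), directed = FALSE,
    vertices = data.frame(name = seq_len(K)))
  igraph::is_connected(g)
}

#' @export
print.nma_network <- function(x, ...) {
  cat("Evidence network:", if (nzchar(x$outcome_label)) x$outcome_label else "(unnamed outcome)", "\n")
  cat(sprintf("  %d studies, %d interventions, %d arms\n",
              n_studies(x), n_interventions(x), nrow(x$arms)))
  des <- table(vapply(split(x$arms$design, x$arms$study_id), `[`, "", 1))
  cat("  designs:", paste(sprintf("%s=%d", names(des), des), collapse = ", "), "\n")
  cat("  reference:", x$interventions$label[1], "\n")
  invisible(x)
}

#' Read / write an evidence network as CSV
#'
#' The CSV holds one row per study arm with columns `study_id`, `study_name`,
#' `design`, `intervention`, `events`, `size`, plus optional
#' `intervention_label`, `cluster_adjusted` and `quality` columns, which are
#' carried through round-trips unchanged.
#'
#' @param path file path
#' @param outcome_label outcome description attached to the network
#' @return `read_network()` returns a validated [nma_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path, outcome_label = "") {
  if (!file.exists(path)) {
    stop_format("input file does not exist: ", path)
  }
  arms <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nma_network(arms, outcome_label = outcome_label)
}

#' @rdname read_network
#' @param network an [nma_network()] object
#' @export
write_network <- function(network, path) {
  utils::write.csv(network$arms, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The packaged accident-prevention evidence networks
#'
#' `poison_network()` is the safe-storage-of-household-products network
#' (15 studies, 7 interventions; poisoning prevention) and
#' `stair_gate_network()` the fitted-stair-gate network (12 studies, 7
#' interventions; falls prevention), both for households with children under
#' five. Counts are as published, including design-effect adjusted
#' (non-integer) figures for cluster-randomised trials; the Dershewitz arm
#' with zero events is stored uncorrected and continuity correction is
#' applied downstream.
#'
#' @return an [nma_network()] object
#' @export
poison_network <- function() {
  read_network(system.file("extdata", "poison_safe_storage.csv",
                           package = "nmarobust", mustWork = TRUE),
               outcome_label = "safe storage of other household products")
}

#' @rdname poison_network
#' @export
stair_gate_network <- function() {
  read_network(system.file("extdata", "stair_gates.csv",
                           package = "nmarobust", mustWork = TRUE),
               outcome_label = "possession of a fitted stair gate")
}
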