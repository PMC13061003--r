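#' Construct a clinical-phase table
#'
#' Stores the maximum clinical development phase of each (drug, indication)
#' pair: 0 = never investigated, 4 = approved. Pairs absent from the table
#' are phase 0.
#'
#' @param df data frame with columns `drug_id`, `indication`, `max_phase`
#'   (integers in 0..4).
#' @return a data frame of class `phase_table`.
#' @export
phase_table <- function(df) {
  df <- as.data.frame(df)
  req <- c("drug_id", "indication", "max_phase")
  if (!all(req %in% names(df))) stop("phase table needs drug_id, indication, max_phase")
  if (any(df$max_phase < 0 | df$max_phase > 4 | df$max_phase != round(df$max_phase))) {
    stop("max_phase must be an integer in 0..4")
  }
  if (anyDuplicated(df[c("drug_id", "indication")]) > 0L) {
    stop("duplicate (drug, indication) pairs")
  }
  class(df) <- c("phase_table", "data.frame")
  df
}

#' Read a clinical-phase table from CSV
#' @param path CSV with columns `drug_id`, `indication`, `max_phase`.
#' @return a `phase_table`.
#' @export
read_phase_table <- function(path) {
  phase_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Clinical phase lookup
#' @param table a `phase_table`.
#' @param drugs drug identifiers.
#' @param indication indication name.
#' @return integer phases, 0 for pairs absent from the table.
#' @keywords internal
phase_of <- function(table, drugs, indication) {
  sub <- table[table$indication == indication, , drop = FALSE]
  ph <- sub$max_phase[match(drugs, sub$drug_id)]
  ph[is.na(ph)] <- 0L
  ph
}

#' Mean clinical phase of a drug set for an indication
#'
#' Arithmetic mean of the maximum clinical phase over the given drugs, with
#' pairs absent from the table counted as phase 0 (never investigated).
#'
#' @param drugs non-empty vector of drug identifiers.
#' @param indication indication name.
#' @param table a `phase_table`.
#' @return mean phase, a number in `[0, 4]`.
#' @export
mean_phase <- function(drugs, indication, table) {
  if (length(drugs) == 0L) stop("mean_phase: empty drug set")
  mean(phase_of(table, drugs, indication))
}

#' Rediscovery rate of the top-k versus bottom-l ranked drugs
#'
#' The ratio of the mean clinical phase of the top-k drugs of a consensus
#' ranking to that of the bottom-l drugs, for one indication. Values above 1
#' indicate that highly ranked drugs are enriched in clinically investigated
#' compounds. When the bottom-l mean phase is zero the rate is undefined
#' (`defined = FALSE`, rate `NA`), not infinite.
#'
#' @param consensus ranked drug list (best first).
#' @param table a `phase_table`.
#' @param indication indication name.
#' @param k number of top drugs.
#' @param l number of bottom drugs; `k + l` must not exceed the list length.
#' @return list with `indication`, `k`, `l`, `phi_top`, `phi_bottom`,
#'   `rate`, `defined`.
#' @export
rediscovery_rate <- function(consensus, table, indication, k, l) {
  n <- length(consensus)
  if (k < 1L || l < 1L) stop("k and l must be positive")
  if (k + l > n) stop("k + l exceeds the list length; top and bottom sets must be disjoint")
  phi_top <- mean_phase(head(consensus, k), indication, table)
  phi_bottom <- mean_phase(tail(consensus, l), indication, table)
  defined <- phi_bottom > 0
  list(indication = indication, k = as.integer(k), l = as.integer(l),
       phi_top = phi_top, phi_bottom = phi_bottom,
       rate = if (defined) phi_top / phi_bottom else NA_real_,
       defined = defined)
}

#' Rediscovery-rate curve over a grid of k at fixed l
#'
#' @param consensus ranked drug list.
#' @param table a `phase_table`.
#' @param indication indication name.
#' @param k_values vector of top-set sizes.
#' @param l bottom-set size, held constant. Defaults to 1808 when the list
#'   is long enough (k_max + 1808 <= n), else `floor(n / 3)`.
#' @return data frame with one row per k: columns `indication`, `k`, `l`,
#'   `phi_top`, `phi_bottom`, `rate`, `defined`.
#' @export
rediscovery_curve <- function(consensus, table, indication, k_values, l = NULL) {
  n <- length(consensus)
  if (is.null(l)) {
    l <- if (max(k_values) + 1808L <= n) 1808L else max(1L, floor(n / 3))
  }
  rows <- lapply(k_values, function(k) {
    as.data.frame(rediscovery_rate(consensus, table, indication, k, l))
  })
  do.call(rbind, rows)
}

#' Indications with sufficient clinical data for a rediscovery report
#'
#' Keeps indications with at least `min_drugs` drugs at phase
#' `>= min_phase`, mirroring the inclusion rule used for multi-indication
#' rediscovery reporting.
#'
#' @param table a `phase_table`.
#' @param min_drugs minimum number of qualifying drugs (default 100).
#' @param min_phase minimum phase that counts as investigated (default 1).
#' @return character vector of eligible indication names.
#' @export
eligible_indications <- function(table, min_drugs = 100L, min_phase = 1L) {
  sub <- table[table$max_phase >= min_phase, , drop = FALSE]
  counts <- table(sub$indication)
  names(counts)[counts >= min_drugs]
}
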