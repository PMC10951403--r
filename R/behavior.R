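# Signal-detection analysis of go/no-go sessions and the table linking
# stimulus statistics, neural decoding, and behavioral discriminability.

#' Session d' from a go/no-go trial log
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)` with the inverse standard-normal
#' transform. Rates of exactly 0 or 1 are adjusted by the 1/(2N) rule before
#' the transform (recorded in the output).
#'
#' @param log Data frame with logical columns `go` and `response`, or a list
#'   with counts `hits`, `misses`, `false_alarms`, `correct_rejects`.
#' @return List: `dprime`, `hit_rate`, `fa_rate`, `n_go`, `n_nogo`,
#'   `adjusted` (logical).
#' @export
session_dprime <- function(log) {
  if (is.data.frame(log)) {
    n_go <- sum(log$go)
    n_nogo <- sum(!log$go)
    hits <- sum(log$go & log$response)
    fas <- sum(!log$go & log$response)
  } else {
    n_go <- log$hits + log$misses
    n_nogo <- log$false_alarms + log$correct_rejects
    hits <- log$hits
    fas <- log$false_alarms
  }
  if (n_go < 1 || n_nogo < 1) stop("need at least one go and one no-go trial")
  hr <- hits / n_go
  fr <- fas / n_nogo
  adj <- FALSE
  if (hr == 0) { hr <- 1 / (2 * n_go); adj <- TRUE }
  if (hr == 1) { hr <- 1 - 1 / (2 * n_go); adj <- TRUE }
  if (fr == 0) { fr <- 1 / (2 * n_nogo); adj <- TRUE }
  if (fr == 1) { fr <- 1 - 1 / (2 * n_nogo); adj <- TRUE }
  list(dprime = qnorm(hr) - qnorm(fr), hit_rate = hr, fa_rate = fr,
       n_go = n_go, n_nogo = n_nogo, adjusted = adj)
}

#' Training-completion criterion
#'
#' First index ending a run of `run_length` consecutive sessions with
#' d' above `threshold`; `NA` when no such run exists.
#'
#' @param session_dprimes Ordered numeric vector of session d' values.
#' @param threshold d' threshold; default 1.
#' @param run_length Required consecutive sessions; default 10.
#' @return Integer index (1-based) or `NA`.
#' @export
training_criterion <- function(session_dprimes, threshold = 1, run_length = 10) {
  above <- session_dprimes > threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= run_length) return(i)
  }
  NA_integer_
}

#' Link stimulus statistics, neural decoding, and behavior
#'
#' Joins per-family behavioral d' (mean and SE across sessions), decoder
#' accuracy, and energy-statistics normalized texture-scramble distances,
#' and reports Spearman rank correlations of the behavioral and neural
#' measures with the statistical distances, with bootstrap confidence
#' intervals over sessions.
#'
#' @param behavior_logs Trial data frame from
#'   [simulate_behavior_sessions()] or equivalent (columns family, session,
#'   go, response).
#' @param decoder_acc Named numeric vector: decoder accuracy per family.
#' @param stat_distances Named numeric vector: energy-subspace normalized
#'   texture-scramble distance per family.
#' @param n_boot Bootstrap replicates for the correlation CIs; default 1000.
#' @param rng_seed Seed.
#' @return List: `table` (per-family joined measures), `rho_behavior`,
#'   `rho_decoder` (Spearman correlations with distance), `ci_behavior`
#'   bootstrap CI.
#' @export
build_link_table <- function(behavior_logs, decoder_acc, stat_distances,
                             n_boot = 1000, rng_seed = 1L) {
  fams <- names(stat_distances)
  per_session <- do.call(rbind, lapply(fams, function(f) {
    logs <- behavior_logs[behavior_logs$family == f, ]
    data.frame(family = f, session = unique(logs$session),
               dprime = vapply(unique(logs$session), function(s)
                 session_dprime(logs[logs$session == s, ])$dprime, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  tab <- do.call(rbind, lapply(fams, function(f) {
    d <- per_session$dprime[per_session$family == f]
    data.frame(family = f,
               behav_dprime = mean(d),
               behav_se = sd(d) / sqrt(length(d)),
               decoder_accuracy = unname(decoder_acc[f]),
               stat_distance = unname(stat_distances[f]),
               stringsAsFactors = FALSE)
  }))
  const <- function(x) length(unique(x)) <= 1 || all(!is.finite(x))
  rho_b <- if (const(tab$stat_distance) || const(tab$behav_dprime)) NA_real_ else
    cor(tab$behav_dprime, tab$stat_distance, method = "spearman")
  rho_d <- if (const(tab$stat_distance) || const(tab$decoder_accuracy)) NA_real_ else
    cor(tab$decoder_accuracy, tab$stat_distance, method = "spearman")
  ci_b <- if (is.na(rho_b)) c(NA_real_, NA_real_) else with_seed(rng_seed, {
    boots <- replicate(n_boot, {
      d <- vapply(fams, function(f) {
        x <- per_session$dprime[per_session$family == f]
        mean(sample(x, length(x), replace = TRUE))
      }, numeric(1))
      if (length(unique(d)) <= 1) NA_real_ else
        suppressWarnings(cor(d, tab$stat_distance, method = "spearman"))
    })
    quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  })
  list(table = tab, rho_behavior = rho_b, rho_decoder = rho_d,
       ci_behavior = unname(ci_b))
}
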