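## Clinical endpoints: HPV status calling from viral oncogene read counts,
## the Kaplan-Meier product-limit estimator, the two-group log-rank test,
## and disease-free survival stratified by peptide presentation.

#' Call HPV status from oncogene read counts
#'
#' A sample is HPV-positive when it has at least 500 reads for E6, at least
#' 500 for E7, or at least 500 summed over all eight HPV oncogenes
#' (E1, E2, E4, E5, E6, E7, L1, L2). "At least" is inclusive.
#'
#' @param counts an [hpv_read_counts()] table (or a single named vector of
#'   the eight genes).
#' @param threshold read-count threshold.
#' @return named character vector (`"positive"`/`"negative"`) per patient.
#' @export
call_hpv_status <- function(counts, threshold = 500) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- hpv_read_counts(
      data.frame(patient_id = "sample", as.list(counts),
                 check.names = FALSE, stringsAsFactors = FALSE))
  }
  stopifnot(inherits(counts, "hpv_read_counts"))
  m <- as.matrix(as.data.frame(counts)[, HPV_GENES])
  if (any(m < 0)) stop("negative HPV read counts", call. = FALSE)
  pos <- m[, "E6"] >= threshold | m[, "E7"] >= threshold |
    rowSums(m) >= threshold
  stats::setNames(ifelse(pos, "positive", "negative"), counts$patient_id)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` over distinct event times.
#' Censoring at a time t is processed after the events at t (standard
#' convention), i.e. censored subjects at t are still in the risk set for
#' events at t.
#'
#' @param times non-negative event/censoring times.
#' @param events logical (or 0/1): TRUE for an event, FALSE for censoring.
#' @return object of class `"km_curve"`: data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` over the distinct observed times.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  events <- as.logical(events)
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times))
  n <- length(times)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk[i] <- sum(times >= t)
    n_event[i] <- sum(times == t & events)
    n_censor[i] <- sum(times == t & !events)
    if (n_event[i] > 0) s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank: observed minus expected events in group A summed
#' over distinct event times, with the hypergeometric variance at each
#' time; `chi2 = (O - E)^2 / V`, two-sided p from the chi-squared
#' distribution with 1 df.
#'
#' @param times_a,events_a times and event indicators for group A.
#' @param times_b,events_b times and event indicators for group B.
#' @return list `chi2`, `p`, `observed`, `expected` (group A),
#'   `computable`. With no events in either group the result is flagged
#'   not computable.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty", call. = FALSE)
  events_a <- as.logical(events_a); events_b <- as.logical(events_b)
  if (!any(events_a) && !any(events_b))
    return(list(chi2 = NA_real_, p = NA_real_, observed = 0, expected = 0,
                computable = FALSE))
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  group_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  ev_times <- sort(unique(times[events]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & group_a)
    d <- sum(times == t & events)
    d_a <- sum(times == t & events & group_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (V == 0)
    return(list(chi2 = NA_real_, p = NA_real_, observed = O, expected = E,
                computable = FALSE))
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = O, expected = E, computable = TRUE)
}

#' Disease-free survival split by peptide presentation
#'
#' Partitions patients by presence of a peptide in the presentation matrix
#' and runs the log-rank test on their DFS, optionally within a clinical
#' stratum (e.g. `stratum = "low_stage"`, mirroring a low-stage-only
#' analysis).
#'
#' @param clinical a [clinical_table()].
#' @param pm a peptide-level [presentation_matrix()].
#' @param peptide_id row name of the peptide of interest.
#' @param stratum one of `"all"`, `"hpv_pos"`, `"hpv_neg"`, `"low_stage"`,
#'   `"high_stage"`.
#' @return list `test` (the [logrank_test()] result), `n_present`,
#'   `n_absent`, `km_present`, `km_absent` (each a [km_estimate()] curve),
#'   `computable`.
#' @export
dfs_by_presentation <- function(clinical, pm, peptide_id, stratum = "all") {
  stopifnot(inherits(clinical, "clinical_table"),
            inherits(pm, "presentation_matrix"))
  if (!peptide_id %in% rownames(pm))
    stop(sprintf("peptide '%s' not in presentation matrix", peptide_id),
         call. = FALSE)
  cl <- clinical[match(colnames(pm), clinical$patient_id), ]
  sel <- switch(stratum,
                all = rep(TRUE, nrow(cl)),
                hpv_pos = cl$hpv_status == "positive",
                hpv_neg = cl$hpv_status == "negative",
                low_stage = cl$stage_group == "low",
                high_stage = cl$stage_group == "high",
                stop(sprintf("unknown stratum '%s'", stratum), call. = FALSE))
  present <- pm[peptide_id, ] == 1 & sel
  absent <- pm[peptide_id, ] == 0 & sel
  if (!any(present) || !any(absent)) {
    return(list(test = NULL, n_present = sum(present), n_absent = sum(absent),
                km_present = NULL, km_absent = NULL, computable = FALSE))
  }
  lr <- logrank_test(cl$dfs_time[present], cl$dfs_event[present],
                     cl$dfs_time[absent], cl$dfs_event[absent])
  list(test = lr,
       n_present = sum(present), n_absent = sum(absent),
       km_present = km_estimate(cl$dfs_time[present], cl$dfs_event[present]),
       km_absent = km_estimate(cl$dfs_time[absent], cl$dfs_event[absent]),
       computable = lr$computable)
}
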