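## Endpoint construction and survival analysis.
##
## Two endpoints: overall survival (OS), measured from diagnosis to death;
## metastasis-free survival (MFS), measured from surgery to metastasis.
## Death without metastasis censors MFS by default (no competing-risk
## modelling); the convention is explicit and toggleable. The product-
## limit estimator and the Mantel-Cox log-rank test are implemented from
## their closed forms; the survival package serves as an independent
## cross-check in the test suite, not as the computational path.

#' Build survival records from a clinical table
#'
#' @param clinical data.frame in the [read_clinical_table()] schema: times
#'   in months from diagnosis (`surgery_offset_months`, `followup_months`,
#'   `death_months`/`death_event`, `metastasis_months`/`metastasis_event`).
#' @param endpoint `"OS"` (diagnosis to death) or `"MFS"` (surgery to
#'   metastasis).
#' @param mfs_death_as_event treat death without metastasis as an MFS
#'   event (`FALSE` by default: such deaths censor).
#' @return data.frame `patient_id, endpoint, time, event` (time in
#'   months, event logical).
#' @export
build_endpoints <- function(clinical, endpoint = c("OS", "MFS"),
                            mfs_death_as_event = FALSE) {
  endpoint <- match.arg(endpoint)
  validate_clinical(clinical)
  n <- nrow(clinical)
  death_ev <- as.logical(clinical$death_event %||% rep(FALSE, n))
  death_t <- clinical$death_months %||% rep(NA_real_, n)
  fup <- clinical$followup_months
  if (endpoint == "OS") {
    time <- ifelse(death_ev, death_t, fup)
    event <- death_ev
  } else {
    surg <- clinical$surgery_offset_months %||% rep(0, n)
    met_ev <- as.logical(clinical$metastasis_event %||% rep(FALSE, n))
    met_t <- clinical$metastasis_months %||% rep(NA_real_, n)
    end <- ifelse(met_ev, met_t,
                  ifelse(death_ev & !mfs_death_as_event,
                         pmin(death_t, fup), fup))
    event <- met_ev | (mfs_death_as_event & death_ev & !met_ev)
    time <- end - surg
  }
  if (any(!is.finite(time)) || any(time < 0))
    stopf("inconsistent clinical data: negative or missing %s time", endpoint)
  data.frame(patient_id = clinical$patient_id, endpoint = endpoint,
             time = time, event = event, stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit estimate with the events-before-censorings tie
#' convention: subjects censored at time t remain at risk for events at t.
#'
#' @param records data.frame with `time` and `event` columns (event
#'   logical or 0/1).
#' @return a `km_curve`: data.frame `time, n_risk, n_event, n_censor,
#'   surv` over the distinct observed times, with `S(0) = 1` implicit.
#' @export
kaplan_meier <- function(records) {
  if (!nrow(records)) stopf("no survival records")
  tm <- records$time; ev <- as.logical(records$event)
  ut <- sort(unique(tm))
  n_risk <- vapply(ut, function(t) sum(tm >= t), 0L)
  n_event <- vapply(ut, function(t) sum(tm == t & ev), 0L)
  n_censor <- vapply(ut, function(t) sum(tm == t & !ev), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [kaplan_meier()] result.
#' @param times numeric vector.
#' @return `S(times)` (right-continuous step function, `S(t) = 1` before
#'   the first observed time).
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, 0)
}

#' Log-rank (Mantel-Cox) test for k groups
#'
#' Observed-minus-expected chi-square statistic over the pooled distinct
#' event times, with the hypergeometric covariance; `df = k - 1`.
#'
#' @param groups named list of data.frames, each with `time` and `event`;
#'   or a single data.frame plus a `labels` vector.
#' @param labels optional grouping vector when `groups` is one data.frame.
#' @return list `statistic, df, p_value, observed, expected, n` of class
#'   `logrank_result`.
#' @export
log_rank <- function(groups, labels = NULL) {
  if (is.data.frame(groups)) {
    if (is.null(labels)) stopf("labels required with a single data.frame")
    groups <- split(groups, labels)
  }
  k <- length(groups)
  if (k < 2) stopf("log-rank needs >= 2 groups")
  if (any(!vapply(groups, nrow, 0L))) stopf("empty group in log-rank test")
  nm <- names(groups) %||% paste0("g", seq_len(k))
  tm <- unlist(lapply(groups, `[[`, "time"), use.names = FALSE)
  ev <- as.logical(unlist(lapply(groups, `[[`, "event"), use.names = FALSE))
  gr <- rep(seq_len(k), vapply(groups, nrow, 0L))
  ut <- sort(unique(tm[ev]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at <- tm >= t
    n_j <- vapply(seq_len(k), function(j) sum(at & gr == j), 0L)
    d_j <- vapply(seq_len(k), function(j) sum(tm == t & ev & gr == j), 0L)
    N <- sum(n_j); D <- sum(d_j)
    O <- O + d_j
    E <- E + D * n_j / N
    if (N > 1) {
      w <- D * (N - D) / (N - 1)
      P <- n_j / N
      V <- V + w * (diag(P) - outer(P, P))
    }
  }
  # chi-square via the pseudo-inverse of the singular covariance (rank
  # k-1 in regular designs; lower when a small stratum never shares risk
  # sets), mirroring the standard Mantel-Cox implementation
  d <- O - E
  eg <- eigen(V, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-10
  rank <- sum(pos)
  stat <- if (all(abs(d) < 1e-12) || rank == 0) 0 else {
    proj <- crossprod(eg$vectors[, pos, drop = FALSE], d)
    sum(proj^2 / eg$values[pos])
  }
  df <- max(1L, min(k - 1L, rank))
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = stats::setNames(O, nm),
                 expected = stats::setNames(E, nm),
                 n = stats::setNames(vapply(groups, nrow, 0L), nm)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<log-rank> chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)))
  invisible(x)
}

#' Median-stratified Kaplan-Meier analysis, one or two markers
#'
#' One marker yields high/low groups; two markers yield the four-group
#' high/high, high/low, low/high, low/low stratification. Groups with no
#' patients are reported absent (small cohorts routinely leave a
#' subgroup too thin for analysis); if only one non-empty group remains,
#' the log-rank test is skipped with a warning.
#'
#' @param labels a [stratify_by_median()] data.frame for one marker, or a
#'   list of two such data.frames.
#' @param records a [build_endpoints()] data.frame.
#' @return list: `curves` (named list of `km_curve`), `logrank` (or
#'   `NULL` when degenerate), `group_sizes`, `absent_groups`.
#' @export
stratified_km <- function(labels, records) {
  if (is.data.frame(labels)) labels <- list(labels)
  if (!length(labels) %in% 1:2) stopf("stratify on 1 or 2 markers")
  lab <- labels[[1]][, c("patient_id", "label")]
  names(lab)[2] <- "l1"
  mk1 <- labels[[1]]$marker[1]
  if (length(labels) == 2) {
    l2 <- labels[[2]][, c("patient_id", "label")]
    names(l2)[2] <- "l2"
    lab <- merge(lab, l2, by = "patient_id")
    mk2 <- labels[[2]]$marker[1]
    lab$group <- paste0(mk1, "_", lab$l1, "/", mk2, "_", lab$l2)
    all_groups <- as.vector(outer(paste0(mk1, c("_high", "_low")),
                                  paste0(mk2, c("_high", "_low")),
                                  paste, sep = "/"))
  } else {
    lab$group <- paste0(mk1 %||% "marker", "_", lab$l1)
    all_groups <- paste0(mk1 %||% "marker", c("_high", "_low"))
  }
  m <- merge(records, lab[, c("patient_id", "group")], by = "patient_id")
  groups <- split(m, m$group)
  absent <- setdiff(all_groups, names(groups))
  curves <- lapply(groups, kaplan_meier)
  lr <- NULL
  if (length(groups) >= 2) lr <- log_rank(groups)
  else warnf("all patients fall in one stratum ('%s'): log-rank skipped",
             names(groups))
  list(curves = curves, logrank = lr,
       group_sizes = vapply(groups, nrow, 0L), absent_groups = absent)
}
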