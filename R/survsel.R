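# Survival statistics and the SPPS (survival-predictive power) selection of
# copy-number aberrations whose carriers relapse earlier.

#' Two-group log-rank test
#'
#' Classic 1-df log-rank chi-square computed from the pooled risk table:
#' at each distinct event time, the observed minus hypergeometric-expected
#' events in group A are accumulated together with the hypergeometric
#' variance; the statistic is (O-E)^2 / V with a chi-square(1) upper-tail
#' p-value. Implemented directly (rather than via survdiff) so it can serve
#' as one leg of the Cox score-test cross-check.
#'
#' @param times_a,events_a follow-up times and 0/1 event indicators, group A.
#' @param times_b,events_b same for group B.
#' @return list with `statistic`, `p`, `n_a`, `n_b`, `observed_a`,
#'   `expected_a`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  stopifnot(length(times_a) == length(events_a), length(times_b) == length(events_b),
            all(events_a %in% 0:1), all(events_b %in% 0:1),
            all(times_a >= 0), all(times_b >= 0))
  if (sum(events_a) + sum(events_b) == 0) stop("log-rank undefined with zero events")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  obs_a <- 0
  exp_a <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp_a)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp_a)
    e1 <- d * n1 / n
    obs_a <- obs_a + d1
    exp_a <- exp_a + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  p <- if (v > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p = p, n_a = length(times_a), n_b = length(times_b),
       observed_a = obs_a, expected_a = exp_a)
}

#' Univariate Cox proportional-hazards fit
#'
#' Thin wrapper around [survival::coxph()] with Efron handling of tied event
#' times, returning the coefficient (log hazard ratio per unit covariate),
#' its standard error, the Wald p-value and the score-test statistic. A
#' negative coefficient means higher covariate values carry lower hazard
#' (better prognosis).
#'
#' @param covariate numeric covariate, one value per sample.
#' @param times,events follow-up and 0/1 event indicator.
#' @return list of class `cox_fit` with `coef`, `se`, `p`, `score_stat`,
#'   `n`, `n_events`, `separation` (TRUE when the partial likelihood is
#'   monotone / the groups are perfectly separated).
#' @export
cox_fit <- function(covariate, times, events) {
  stopifnot(length(covariate) == length(times), length(times) == length(events))
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (length(unique(covariate)) < 2L) stop("covariate is constant: Cox coefficient undefined")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  structure(list(
    coef = unname(stats::coef(fit)[1]),
    se = unname(sqrt(diag(fit$var))[1]),
    p = unname(s$coefficients[1, "Pr(>|z|)"]),
    score_stat = unname(s$sctest["test"]),
    n = fit$n, n_events = fit$nevent,
    separation = separation
  ), class = "cox_fit")
}

#' Kaplan-Meier survival curve
#'
#' @param times,events follow-up and 0/1 event indicator.
#' @return data.frame `time`, `n_risk`, `surv` (product-limit estimate).
#' @export
km_curve <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, surv = fit$surv)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to `tau` (default: last observed
#' time), the usual definition of "mean survival" for censored follow-up.
#'
#' @inheritParams km_curve
#' @param tau horizon; defaults to the largest observed time.
#' @return scalar RMST in the units of `times`.
#' @export
rmst <- function(times, events, tau = max(times)) {
  km <- km_curve(times, events)
  km <- km[km$time <= tau, , drop = FALSE]
  ts <- c(0, km$time, tau)
  ss <- c(1, km$surv, if (nrow(km)) km$surv[nrow(km)] else 1)
  sum(diff(ts) * ss[-length(ss)])
}

#' SPPS: select survival-predictive aberration regions
#'
#' For each candidate region, the In-Group is the set of samples whose
#' same-direction calls cover at least `min_cover` of the region; the
#' Out-Group is everyone else. Disease-free survival is compared by
#' [logrank_test()] and the restricted mean survival time is reported per
#' group. Regions with an empty In- or Out-Group are skipped with a warning.
#'
#' @param regions data.frame `chrom`, `start`, `end`, `direction` (extra
#'   columns are carried through).
#' @param calls per-sample aberration calls ([segment_profile()] format).
#' @param clinical data.frame with `sample_id`, `<endpoint>_time`,
#'   `<endpoint>_event`; only its samples are eligible.
#' @param min_cover fraction of the region a sample's calls must cover
#'   (default 0.5).
#' @param alpha log-rank significance level (default 0.05).
#' @param endpoint "dfs" or "os".
#' @param keep_all return all evaluated regions (with a `selected` flag)
#'   instead of only the significant ones.
#' @return data.frame with region columns plus `n_in`, `n_out`, `statistic`,
#'   `p`, `rmst_in`, `rmst_out`, `selected`.
#' @export
spps_select <- function(regions, calls, clinical, min_cover = 0.5,
                        alpha = 0.05, endpoint = "dfs", keep_all = FALSE) {
  stopifnot(endpoint %in% c("dfs", "os"))
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  stopifnot(all(c("sample_id", tcol, ecol) %in% names(clinical)))
  samples <- clinical$sample_id
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    width <- rg$end - rg$start
    cov <- vapply(samples, function(s) {
      cs <- calls[calls$sample_id == s & calls$direction == rg$direction &
                    calls$chrom == rg$chrom & calls$start < rg$end &
                    calls$end > rg$start, , drop = FALSE]
      if (!nrow(cs)) return(0)
      iv <- IRanges::reduce(IRanges::IRanges(
        start = pmax(cs$start, rg$start) + 1L, end = pmin(cs$end, rg$end)))
      sum(IRanges::width(iv)) / width
    }, 0)
    in_grp <- cov >= min_cover
    if (!any(in_grp) || all(in_grp)) {
      warning(sprintf("region %s:%g-%g (%s) skipped: empty %s-group",
                      rg$chrom, rg$start, rg$end, rg$direction,
                      if (!any(in_grp)) "In" else "Out"))
      next
    }
    lr <- logrank_test(clinical[[tcol]][in_grp], clinical[[ecol]][in_grp],
                       clinical[[tcol]][!in_grp], clinical[[ecol]][!in_grp])
    tau <- max(clinical[[tcol]])
    rows[[length(rows) + 1L]] <- cbind(
      rg,
      data.frame(n_in = sum(in_grp), n_out = sum(!in_grp),
                 statistic = lr$statistic, p = lr$p,
                 rmst_in = rmst(clinical[[tcol]][in_grp], clinical[[ecol]][in_grp], tau),
                 rmst_out = rmst(clinical[[tcol]][!in_grp], clinical[[ecol]][!in_grp], tau),
                 selected = lr$p < alpha)
    )
  }
  if (!length(rows)) {
    out <- cbind(regions[0, , drop = FALSE],
                 data.frame(n_in = integer(0), n_out = integer(0),
                            statistic = numeric(0), p = numeric(0),
                            rmst_in = numeric(0), rmst_out = numeric(0),
                            selected = logical(0)))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_all) out else out[out$selected, , drop = FALSE]
}
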