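#' Construct a survival sample
#'
#' @param time years from initial diagnosis to death or censoring.
#' @param event logical (or 0/1): `TRUE` when death was observed, `FALSE`
#'   when the subject was censored alive.
#' @return Object of class `"survival_sample"`: data.frame `time`, `event`.
#' @export
survival_sample <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (!length(time)) stop("survival sample must contain at least one subject")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(time < 0)) stop("survival times must be >= 0")
  if (anyNA(time) || anyNA(event)) stop("missing values in survival sample")
  structure(data.frame(time = time, event = event),
            class = c("survival_sample", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct death time t with d deaths among r subjects at risk, the
#' survivor estimate multiplies by (1 - d/r); censored subjects leave the
#' risk set after their time (deaths at a tied time are processed first, the
#' standard convention).
#'
#' @param sample a [survival_sample()].
#' @return Object of class `"km_curve"`: list with `time` (ascending distinct
#'   observation times), `surv`, `n_risk`, `n_event`, `n_censor`, `n`.
#' @examples
#' km <- km_estimate(survival_sample(c(1, 2, 3), c(TRUE, TRUE, TRUE)))
#' km$surv
#' @export
km_estimate <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  fit <- survival::survfit(
    survival::Surv(sample$time, as.integer(sample$event)) ~ 1,
    conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = nrow(sample)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$n_event), "deaths,",
      sum(x$n_censor), "censored\n")
  ev <- x$n_event > 0
  df <- data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = round(x$surv, 4))[ev, , drop = FALSE]
  if (nrow(df) > 10) {
    print(utils::head(df, 5), row.names = FALSE)
    cat("  ... (", nrow(df) - 10, " rows omitted)\n", sep = "")
    print(utils::tail(df, 5), row.names = FALSE)
  } else print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "years since diagnosis",
                          ylab = "survival probability", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation. Beyond the last observed time
#' the last estimate is carried forward and flagged as an extrapolation.
#'
#' @param curve a `"km_curve"`.
#' @param t time in years (scalar, `>= 0`).
#' @return Survival probability, with attribute `extrapolated` when `t`
#'   exceeds the last observation.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), length(t) == 1L)
  if (t < 0) stop("t must be >= 0")
  if (!length(curve$time)) return(1)
  s <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)(t)
  if (t > max(curve$time)) attr(s, "extrapolated") <- TRUE
  s
}

#' Hazard ratio between two survival samples
#'
#' `rate_ratio` (default) compares the constant event rates
#' (deaths per person-year): the ratio of rates of `a` over `b` — the direct
#' reading of "group A dies at twice the rate of group B". `log_rank` forms
#' the ratio of observed-over-expected event counts (O_a/E_a)/(O_b/E_b) from
#' the log-rank decomposition.
#'
#' @param a,b [survival_sample()]s; each must contain at least one event.
#' @param method `"rate_ratio"` or `"log_rank"`.
#' @return Positive hazard ratio of `a` over `b`; `NA` with a warning when
#'   `b` has no events.
#' @export
hazard_ratio <- function(a, b, method = c("rate_ratio", "log_rank")) {
  stopifnot(inherits(a, "survival_sample"), inherits(b, "survival_sample"))
  method <- match.arg(method)
  if (sum(b$event) == 0L) {
    warning("no events in reference group; hazard ratio undefined")
    return(NA_real_)
  }
  if (sum(a$event) == 0L)
    warning("no events in group a; hazard ratio is zero")
  if (method == "rate_ratio") {
    (sum(a$event) / sum(a$time)) / (sum(b$event) / sum(b$time))
  } else {
    time <- c(a$time, b$time)
    event <- c(a$event, b$event)
    grp <- rep(c("a", "b"), c(nrow(a), nrow(b)))
    sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ grp)
    (sd$obs[1] / sd$exp[1]) / (sd$obs[2] / sd$exp[2])
  }
}

#' Group a cohort into survival samples
#'
#' Grouping criteria mirror the standard prognostic splits for metastatic
#' progression: `first_site_solitary` keeps patients whose first relapse is a
#' single site and groups them by that site; `n_first_mets` groups all
#' relapsed patients by the size of their first site-set (1, 2, more than 2);
#' `subgroup` groups by ER/HER2 status (unknown-status patients excluded).
#' Patients without the defining feature (e.g. no relapse, or a multi-site
#' first relapse under `first_site_solitary`) are excluded and counted in the
#' `excluded` attribute.
#'
#' @param cohort a [metacohort()].
#' @param by `"first_site_solitary"`, `"n_first_mets"` or `"subgroup"`.
#' @param window_years,co_tolerance pathway-extraction parameters used to
#'   identify first relapse site-sets (see [extract_pathways()]); the
#'   survival times themselves always run from diagnosis to death/censoring.
#' @param eligible_only when `TRUE` (default) restrict to patients meeting
#'   the observation-window eligibility rule.
#' @return Named list of [survival_sample()]s with attribute `excluded`.
#' @export
group_cohort <- function(cohort,
                         by = c("first_site_solitary", "n_first_mets",
                                "subgroup"),
                         window_years = 10, co_tolerance = 14 / 365.25,
                         eligible_only = TRUE) {
  stopifnot(inherits(cohort, "metacohort"))
  by <- match.arg(by)
  pts <- cohort$patients
  eligible <- pts$followup_years >= window_years |
    (pts$vital_status == "deceased" & pts$followup_years <= window_years)
  if (!eligible_only) eligible <- rep(TRUE, nrow(pts))
  if (by == "subgroup") {
    sg <- subgroup_of(pts)
    keep <- eligible & sg != "unknown"
    groups <- split(which(keep), sg[keep])
  } else {
    # first-relapse site-set: events within co_tolerance of the earliest one
    firsts <- lapply(split(cohort$events, cohort$events$patient_id),
                     function(e) {
                       e <- e[e$time <= e$time[which.min(e$time)] +
                                co_tolerance, , drop = FALSE]
                       unique(e$site)
                     })
    idx <- match(names(firsts), pts$patient_id)
    ok <- eligible[idx] &
      vapply(split(cohort$events$time, cohort$events$patient_id), min,
             numeric(1)) <= pmin(window_years, pts$followup_years[idx])
    firsts <- firsts[ok]; idx <- idx[ok]
    if (by == "first_site_solitary") {
      solo <- vapply(firsts, length, integer(1)) == 1L
      key <- unlist(firsts[solo])
      groups <- split(idx[solo], key)
    } else {
      nsz <- vapply(firsts, length, integer(1))
      key <- ifelse(nsz == 1L, "1", ifelse(nsz == 2L, "2", ">2"))
      groups <- split(idx, factor(key, levels = c("1", "2", ">2")))
      groups <- groups[vapply(groups, length, integer(1)) > 0]
    }
  }
  out <- lapply(groups, function(ix)
    survival_sample(pts$followup_years[ix],
                    pts$vital_status[ix] == "deceased"))
  attr(out, "excluded") <- nrow(pts) - length(unlist(groups))
  out
}

#' Mean number of distinct metastatic sites at death
#'
#' Over deceased patients, the mean count of distinct anatomical sites
#' (excluding the primary) with at least one recorded metastatic event before
#' death.
#'
#' @param cohort a [metacohort()].
#' @return Mean count; `NA` with a warning when no patient is deceased.
#' @export
mean_sites_at_death <- function(cohort) {
  stopifnot(inherits(cohort, "metacohort"))
  dead <- cohort$patients$patient_id[
    cohort$patients$vital_status == "deceased"]
  if (!length(dead)) {
    warning("no deceased patients; mean sites at death undefined")
    return(NA_real_)
  }
  ev <- cohort$events[cohort$events$patient_id %in% dead, , drop = FALSE]
  counts <- tapply(ev$site, ev$patient_id, function(s) length(unique(s)))
  # deceased patients without any recorded event contribute zero sites
  mean(c(counts, rep(0, length(dead) - length(counts))))
}

#' Export a Kaplan-Meier curve as CSV
#'
#' Columns: `time`, `survival`, `at_risk`, `censored`.
#'
#' @param curve a `"km_curve"`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(data.frame(time = curve$time, survival = curve$surv,
                              at_risk = curve$n_risk,
                              censored = curve$n_censor),
                   path, row.names = FALSE)
  invisible(path)
}
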