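#' Construct a metastatic pathway
#'
#' A pathway is the ordered sequence of site-sets a patient's disease visits:
#' step 0 is always the primary (`{breast}`), each later step is a non-empty
#' set of sites detected together, and `{deceased}`, if present, is the final
#' singleton step.
#'
#' @param steps list of character vectors of taxonomy sites; the first must be
#'   `"breast"`.
#' @param patient_id optional identifier carried along for bookkeeping.
#' @return An object of class `"pathway"`.
#' @keywords internal
#' @export
pathway <- function(steps, patient_id = NA_character_) {
  stopifnot(is.list(steps), length(steps) >= 1L)
  steps <- lapply(steps, function(s) {
    s <- unique(canonicalize_sites(s))
    s[order(match(s, met_sites()))]
  })
  if (!identical(steps[[1L]], SITE_ORIGIN))
    stop("pathway must start with the singleton {breast}")
  has_dec <- vapply(steps, function(s) SITE_ABSORBING %in% s, logical(1))
  if (any(has_dec)) {
    k <- which(has_dec)
    if (length(k) > 1L || k != length(steps) ||
        length(steps[[k]]) != 1L)
      stop("'deceased' may appear only as the final singleton step")
  }
  structure(list(steps = steps, patient_id = patient_id,
                 terminal = any(has_dec)),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(paste(vapply(x$steps, site_set_label, character(1)),
            collapse = " -> "), "\n")
  invisible(x)
}

#' @export
format.pathway <- function(x, ...) {
  paste(vapply(x$steps, site_set_label, character(1)), collapse = " -> ")
}

#' Extract eligible metastatic pathways from a cohort
#'
#' Reduces timed event records to ordered pathways over a fixed observation
#' window. A patient is eligible if followed (alive) for at least
#' `window_years`, or if they died before the window closed — their full
#' progression is then known. Events after the window are dropped; death
#' within the window appends a terminal `{deceased}` step. Events whose times
#' differ by at most `co_tolerance` are merged into a single co-occurring
#' site-set (clinically, metastases reported at the same visit).
#'
#' @param cohort a [metacohort()].
#' @param window_years observation window in years (default 10).
#' @param co_tolerance co-occurrence tolerance in years; events this close in
#'   time share a site-set. Default 14 days, reflecting typical between-exam
#'   spacing of 1-3 months.
#' @return List of [pathway()] objects, one per eligible patient.
#' @examples
#' pts <- data.frame(patient_id = c("a", "b"),
#'                   er_status = "positive", her2_status = "negative",
#'                   vital_status = c("deceased", "alive"),
#'                   followup_years = c(4, 12))
#' ev <- data.frame(patient_id = c("a", "a"), site = c("bone", "liver"),
#'                  time = c(2, 3.1))
#' extract_pathways(metacohort(pts, ev))
#' @export
extract_pathways <- function(cohort, window_years = 10,
                             co_tolerance = 14 / 365.25) {
  stopifnot(inherits(cohort, "metacohort"))
  if (!is.numeric(window_years) || window_years <= 0)
    stop("window_years must be a positive number")
  if (!is.numeric(co_tolerance) || co_tolerance < 0)
    stop("co_tolerance must be non-negative")
  ev_by <- split(cohort$events, cohort$events$patient_id)
  out <- vector("list", nrow(cohort$patients))
  n_out <- 0L
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, ]
    died_in_window <- p$vital_status == "deceased" &&
      p$followup_years <= window_years
    eligible <- p$followup_years >= window_years || died_in_window
    if (!eligible) next
    e <- ev_by[[p$patient_id]]
    steps <- list(SITE_ORIGIN)
    if (!is.null(e)) {
      e <- e[e$time <= window_years, , drop = FALSE]
      if (died_in_window) e <- e[e$time <= p$followup_years, , drop = FALSE]
      if (nrow(e)) {
        # greedy left-to-right merge: an event joins the open set while its
        # time is within co_tolerance of the set's anchor (first) event
        grp <- integer(nrow(e))
        g <- 1L; anchor <- e$time[1L]; grp[1L] <- 1L
        for (j in seq_len(nrow(e))[-1L]) {
          if (e$time[j] - anchor > co_tolerance) {
            g <- g + 1L; anchor <- e$time[j]
          }
          grp[j] <- g
        }
        steps <- c(steps, unname(split(e$site, grp)))
      }
    }
    if (died_in_window) steps <- c(steps, SITE_ABSORBING)
    n_out <- n_out + 1L
    out[[n_out]] <- pathway(steps, p$patient_id)
  }
  out[seq_len(n_out)]
}

#' Count distinct pathways
#'
#' Two pathways are identical when their site-set sequences are equal (the
#' order of sites inside a co-occurring set is ignored).
#'
#' @param pathways list of [pathway()] objects.
#' @return Number of unique pathways.
#' @export
count_distinct_pathways <- function(pathways) {
  if (!length(pathways)) return(0L)
  keys <- vapply(pathways, format.pathway, character(1))
  length(unique(keys))
}

#' Tabulate first metastatic site-sets
#'
#' Frequency of each first-relapse site-set over a pathway list; used for the
#' first ring of the progression diagram and for eyeballing calibrations.
#'
#' @param pathways list of [pathway()] objects.
#' @return Named table of counts, descending.
#' @export
first_site_table <- function(pathways) {
  firsts <- vapply(pathways, function(p) {
    if (length(p$steps) < 2L) return(NA_character_)
    site_set_label(p$steps[[2L]])
  }, character(1))
  sort(table(firsts[!is.na(firsts)]), decreasing = TRUE)
}
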