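#' Construct a longitudinal metastatic cohort
#'
#' A cohort holds one row per patient plus one row per timed metastatic event.
#' Times are years since the initial breast cancer diagnosis. No patient has
#' metastatic disease at diagnosis; events record where and when metastases
#' were subsequently detected.
#'
#' @param patients data.frame with columns `patient_id`, `er_status`
#'   (`positive`/`negative`/`unknown`), `her2_status` (same levels),
#'   `vital_status` (`alive`/`deceased`) and `followup_years` (years from
#'   diagnosis to death or last follow-up).
#' @param events data.frame with columns `patient_id`, `site` (a taxonomy
#'   label, see [met_sites()]) and `time` (years since diagnosis, `>= 0`).
#'   May have zero rows.
#' @return An object of class `"metacohort"`: a list with elements `patients`
#'   and `events` (events sorted by patient and time).
#' @examples
#' pts <- data.frame(patient_id = "p1", er_status = "positive",
#'                   her2_status = "negative", vital_status = "alive",
#'                   followup_years = 12)
#' ev <- data.frame(patient_id = "p1", site = "bone", time = 3.2)
#' metacohort(pts, ev)
#' @export
metacohort <- function(patients, events = NULL) {
  req <- c("patient_id", "er_status", "her2_status", "vital_status",
           "followup_years")
  miss <- setdiff(req, names(patients))
  if (length(miss))
    stop("patients table is missing required column(s): ",
         paste(miss, collapse = ", "))
  patients <- as.data.frame(patients)[req]
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "))
  patients$er_status <- match_status(patients$er_status, "er_status")
  patients$her2_status <- match_status(patients$her2_status, "her2_status")
  if (!all(patients$vital_status %in% c("alive", "deceased")))
    stop("vital_status must be 'alive' or 'deceased'")
  if (any(patients$followup_years < 0)) stop("followup_years must be >= 0")

  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(patient_id = character(), site = character(),
                         time = numeric())
  } else {
    reqe <- c("patient_id", "site", "time")
    misse <- setdiff(reqe, names(events))
    if (length(misse))
      stop("events table is missing required column(s): ",
           paste(misse, collapse = ", "))
    events <- as.data.frame(events)[reqe]
    events$patient_id <- as.character(events$patient_id)
    events$site <- canonicalize_sites(events$site)
    events$time <- as.numeric(events$time)
    if (any(events$site == SITE_ORIGIN))
      stop("events are metastases: site cannot be 'breast'")
    if (any(events$time < 0)) stop("event times must be >= 0")
    orphan <- setdiff(events$patient_id, patients$patient_id)
    if (length(orphan))
      stop("events refer to unknown patient_id: ",
           paste(orphan, collapse = ", "))
    # repair unsorted event times with a warning rather than failing
    unsorted <- vapply(split(events$time, events$patient_id),
                       is.unsorted, logical(1))
    if (any(unsorted))
      warning("event times were not sorted for patient(s): ",
              paste(names(unsorted)[unsorted], collapse = ", "),
              "; sorted by time", call. = FALSE)
    events <- events[order(match(events$patient_id, patients$patient_id),
                           events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  # death must not precede the last recorded event
  dead <- patients$vital_status == "deceased"
  if (any(dead) && nrow(events)) {
    last_ev <- tapply(events$time, events$patient_id, max)
    idx <- match(patients$patient_id[dead], names(last_ev))
    bad <- !is.na(idx) &
      patients$followup_years[dead] < last_ev[idx] - 1e-9
    if (any(bad))
      stop("deceased patient(s) with events after death time: ",
           paste(patients$patient_id[dead][bad], collapse = ", "))
  }
  rownames(patients) <- NULL
  structure(list(patients = patients, events = events), class = "metacohort")
}

match_status <- function(x, what) {
  x <- as.character(x)
  ok <- x %in% c("positive", "negative", "unknown")
  if (!all(ok))
    stop(what, " must be 'positive', 'negative' or 'unknown' (got: ",
         paste(unique(x[!ok]), collapse = ", "), ")")
  x
}

#' @export
print.metacohort <- function(x, ...) {
  np <- nrow(x$patients)
  ne <- nrow(x$events)
  nd <- sum(x$patients$vital_status == "deceased")
  cat("Metastatic cohort: ", np, " patients, ", ne, " metastatic events, ",
      nd, " deceased\n", sep = "")
  tab <- table(factor(subgroup_of(x$patients),
                      levels = c("er_pos_her2_neg", "er_neg_her2_neg",
                                 "her2_pos", "unknown")))
  cat("Subgroups: ER+/HER2- ", tab[["er_pos_her2_neg"]],
      ", ER-/HER2- ", tab[["er_neg_her2_neg"]],
      ", HER2+ ", tab[["her2_pos"]],
      ", unknown ", tab[["unknown"]], "\n", sep = "")
  invisible(x)
}

# subgroup label per patient row; "unknown" when receptor status insufficient
subgroup_of <- function(patients) {
  out <- rep("unknown", nrow(patients))
  out[patients$her2_status == "positive"] <- "her2_pos"
  out[patients$er_status == "positive" &
        patients$her2_status == "negative"] <- "er_pos_her2_neg"
  out[patients$er_status == "negative" &
        patients$her2_status == "negative"] <- "er_neg_her2_neg"
  out
}

#' Restrict a cohort to a receptor-status subgroup
#'
#' Subgroups follow the standard breast-cancer taxonomy: ER+/HER2-
#' (`er_pos_her2_neg`), triple-negative-like ER-/HER2- (`er_neg_her2_neg`),
#' and HER2+ (`her2_pos`, regardless of ER). Patients with unknown receptor
#' status are retained only under `"all"`.
#'
#' @param cohort a [metacohort()].
#' @param subgroup one of `"all"`, `"er_pos_her2_neg"`, `"er_neg_her2_neg"`,
#'   `"her2_pos"`.
#' @return A `metacohort` containing the matching patients and their events.
#' @export
filter_subgroup <- function(cohort,
                            subgroup = c("all", "er_pos_her2_neg",
                                         "er_neg_her2_neg", "her2_pos")) {
  stopifnot(inherits(cohort, "metacohort"))
  subgroup <- match.arg(subgroup)
  if (subgroup == "all") return(cohort)
  keep <- subgroup_of(cohort$patients) == subgroup
  pts <- cohort$patients[keep, , drop = FALSE]
  ev <- cohort$events[cohort$events$patient_id %in% pts$patient_id, ,
                      drop = FALSE]
  metacohort(pts, ev)
}

#' Read a cohort from disk
#'
#' Two on-disk layouts are supported. `csv_pair` expects `patients.csv`
#' (header `patient_id,er_status,her2_status,vital_status,followup_years`)
#' and `events.csv` (header `patient_id,site,event_years`) in the directory
#' `path`. `json` expects a single document with a top-level `patients` array,
#' each patient carrying an inline `events` array of `{site, time}` objects;
#' this layout round-trips bit-identically through [write_cohort()].
#'
#' @param path directory (for `csv_pair`) or file (for `json`).
#' @param format `"csv_pair"` or `"json"`.
#' @return A [metacohort()].
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("csv_pair", "json")) {
  format <- match.arg(format)
  if (format == "csv_pair") {
    pf <- file.path(path, "patients.csv")
    ef <- file.path(path, "events.csv")
    if (!file.exists(pf)) stop("missing file: ", pf)
    patients <- utils::read.csv(pf, stringsAsFactors = FALSE)
    events <- NULL
    if (file.exists(ef)) {
      events <- utils::read.csv(ef, stringsAsFactors = FALSE)
      if (nrow(events)) {
        if (!"event_years" %in% names(events))
          stop("events table is missing required column(s): event_years")
        names(events)[names(events) == "event_years"] <- "time"
      } else events <- NULL
    }
    metacohort(patients, events)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$patients)) stop("json cohort must have a 'patients' array")
    pts <- do.call(rbind, lapply(doc$patients, function(p) {
      data.frame(patient_id = as.character(p$patient_id),
                 er_status = p$er_status, her2_status = p$her2_status,
                 vital_status = p$vital_status,
                 followup_years = as.numeric(p$followup_years))
    }))
    evs <- do.call(rbind, lapply(doc$patients, function(p) {
      if (is.null(p$events) || !length(p$events)) return(NULL)
      data.frame(patient_id = as.character(p$patient_id),
                 site = vapply(p$events, function(e) as.character(e$site),
                               character(1)),
                 time = vapply(p$events, function(e) as.numeric(e$time),
                               numeric(1)))
    }))
    metacohort(pts, evs)
  }
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]; the `json` layout round-trips exactly.
#'
#' @param cohort a [metacohort()].
#' @param path directory (`csv_pair`) or file path (`json`).
#' @param format `"csv_pair"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv_pair", "json")) {
  stopifnot(inherits(cohort, "metacohort"))
  format <- match.arg(format)
  if (format == "csv_pair") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort$patients, file.path(path, "patients.csv"),
                     row.names = FALSE, quote = FALSE)
    ev <- cohort$events
    names(ev)[names(ev) == "time"] <- "event_years"
    utils::write.csv(ev, file.path(path, "events.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    ev_by <- split(cohort$events, cohort$events$patient_id)
    plist <- lapply(seq_len(nrow(cohort$patients)), function(i) {
      p <- cohort$patients[i, ]
      e <- ev_by[[p$patient_id]]
      list(patient_id = p$patient_id, er_status = p$er_status,
           her2_status = p$her2_status, vital_status = p$vital_status,
           followup_years = p$followup_years,
           events = if (is.null(e)) list() else
             lapply(seq_len(nrow(e)), function(j)
               list(site = e$site[j], time = e$time[j])))
    })
    jsonlite::write_json(list(patients = plist), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
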