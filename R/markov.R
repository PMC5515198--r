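#' Estimate a transition matrix by enumeration of progression events
#'
#' Transition probabilities are obtained empirically: every progression from
#' one site-set to the next contributes counts, and rows of the count matrix
#' are normalised to probabilities. For a transition from site-set S to
#' site-set T, each site j in T contributes one unit of count, split equally
#' over the sites of S (fractional counts), so the total mass of the
#' transition equals |T|. A repeat event at an already-affected site counts as
#' a self-transition. The `deceased` row is forced absorbing. Non-deceased
#' rows with no observed exits are made self-absorbing with a warning
#' (`smoothing = "none"`) or receive uniform add-one counts
#' (`smoothing = "add_one"`).
#'
#' @param pathways list of [pathway()] objects, at least one of which
#'   progresses beyond the primary.
#' @param taxonomy ordered state labels; defaults to [met_sites()].
#' @param smoothing `"none"` (default) or `"add_one"`.
#' @return An object of class `"transition_matrix"`: list with `probs`
#'   (row-stochastic matrix), `counts` (possibly fractional), `taxonomy`.
#' @examples
#' pw <- replicate(4, pathway(list("breast", "bone")), simplify = FALSE)
#' estimate_transition_matrix(pw)$probs["breast", "bone"]
#' @export
estimate_transition_matrix <- function(pathways, taxonomy = met_sites(),
                                       smoothing = c("none", "add_one")) {
  smoothing <- match.arg(smoothing)
  if (!length(pathways)) stop("empty pathway list")
  if (!any(vapply(pathways, function(p) length(p$steps) > 1L, logical(1))))
    stop("no pathway progresses beyond the primary")
  n <- length(taxonomy)
  counts <- matrix(0, n, n, dimnames = list(taxonomy, taxonomy))
  for (p in pathways) {
    if (!inherits(p, "pathway")) stop("pathways must be 'pathway' objects")
    steps <- p$steps
    for (k in seq_len(length(steps) - 1L)) {
      from <- steps[[k]]; to <- steps[[k + 1L]]
      w <- 1 / length(from)
      for (j in to) counts[from, j] <- counts[from, j] + w
    }
  }
  as_transition_matrix(counts, taxonomy, smoothing)
}

# normalise a count matrix into a transition_matrix object; raw counts are
# stored unmodified, zero-exit handling only affects the probabilities
as_transition_matrix <- function(counts, taxonomy, smoothing = "none") {
  n <- length(taxonomy)
  dec <- match(SITE_ABSORBING, taxonomy)
  work <- counts
  rs <- rowSums(work)
  empty <- which(rs == 0 & seq_len(n) != dec)
  if (length(empty)) {
    if (smoothing == "add_one") {
      work[empty, -match(SITE_ORIGIN, taxonomy)] <-
        work[empty, -match(SITE_ORIGIN, taxonomy)] + 1
    } else {
      warning("state(s) with no observed exits made self-absorbing: ",
              paste(taxonomy[empty], collapse = ", "), call. = FALSE)
      work[cbind(empty, empty)] <- 1
    }
    rs <- rowSums(work)
  }
  probs <- work / rs
  probs[dec, ] <- 0
  probs[dec, dec] <- 1
  structure(list(probs = probs, counts = counts, taxonomy = taxonomy),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Transition matrix over", length(x$taxonomy), "states",
      "(rows sum to 1; 'deceased' absorbing)\n")
  print(round(x$probs, digits))
  invisible(x)
}

validate_transition_matrix <- function(A) {
  stopifnot(inherits(A, "transition_matrix"))
  if (any(abs(rowSums(A$probs) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  if (any(A$probs < -1e-12 | A$probs > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]")
  invisible(A)
}

#' Construct a state vector over the site taxonomy
#'
#' @param probs named or ordered numeric vector of probabilities summing to 1.
#' @param taxonomy ordered state labels.
#' @return Object of class `"state_vector"`.
#' @export
state_vector <- function(probs = NULL, taxonomy = met_sites()) {
  if (is.null(probs)) {
    probs <- stats::setNames(numeric(length(taxonomy)), taxonomy)
    probs[SITE_ORIGIN] <- 1
  }
  if (is.null(names(probs))) names(probs) <- taxonomy
  if (!setequal(names(probs), taxonomy))
    stop("state vector names must match the taxonomy")
  probs <- probs[taxonomy]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("state vector entries must be non-negative and sum to 1")
  structure(probs, class = "state_vector")
}

#' @export
print.state_vector <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Propagate a state vector through the chain
#'
#' One model step is one metastatic progression event; the state vector after
#' k steps gives the probability of disease occupying each site. The update
#' is right-multiplication by the transition matrix, so mass accumulates in
#' the absorbing `deceased` state.
#'
#' @param v a [state_vector()] (default: all mass on `breast`).
#' @param A a `transition_matrix`.
#' @param k number of steps (non-negative integer).
#' @return A [state_vector()] equal to `v %*% A^k`.
#' @export
propagate <- function(v, A, k) {
  validate_transition_matrix(A)
  if (is.null(v)) v <- state_vector(taxonomy = A$taxonomy)
  stopifnot(inherits(v, "state_vector"))
  if (!setequal(names(v), A$taxonomy))
    stop("state vector and transition matrix taxonomies differ")
  if (k < 0 || k != round(k)) stop("k must be a non-negative integer")
  out <- unclass(v)[A$taxonomy]
  for (i in seq_len(k)) out <- drop(out %*% A$probs)
  state_vector(out, A$taxonomy)
}

#' Empirical next-step distribution after a pathway prefix
#'
#' Restricts to pathways whose opening steps are exactly the given singleton
#' prefix (e.g. breast, bone, lung/pleura) and tabulates where the disease
#' goes next. Co-occurring next steps split their unit mass equally over the
#' sites of the set. Pathways that match the prefix but end there are counted
#' in `n_matched` but contribute no mass; the distribution is normalised over
#' the `n_continued` pathways that progress further.
#'
#' @param pathways list of [pathway()] objects.
#' @param prefix character vector of single sites beginning with `"breast"`.
#' @return List with `distribution` (named probabilities, descending),
#'   `n_matched`, and `n_continued`. Empty distribution when nothing matches.
#' @export
conditional_next_distribution <- function(pathways, prefix) {
  prefix <- canonicalize_sites(prefix)
  if (!length(prefix) || prefix[1L] != SITE_ORIGIN)
    stop("prefix must begin with 'breast'")
  m <- length(prefix)
  mass <- stats::setNames(numeric(length(met_sites())), met_sites())
  n_matched <- 0L; n_continued <- 0L
  for (p in pathways) {
    if (length(p$steps) < m) next
    head_sets <- p$steps[seq_len(m)]
    if (!all(vapply(head_sets, length, integer(1)) == 1L)) next
    if (!identical(unlist(head_sets), prefix)) next
    n_matched <- n_matched + 1L
    if (length(p$steps) > m) {
      n_continued <- n_continued + 1L
      nxt <- p$steps[[m + 1L]]
      mass[nxt] <- mass[nxt] + 1 / length(nxt)
    }
  }
  dist <- if (n_continued > 0L) mass / n_continued else mass[0]
  dist <- sort(dist[dist > 0], decreasing = TRUE)
  list(distribution = dist, n_matched = n_matched, n_continued = n_continued)
}

#' Fit a Markov chain progression model to a cohort
#'
#' The central model fit: extracts eligible pathways from a cohort (or takes
#' a pathway list directly), estimates the site-to-site transition matrix by
#' enumeration of progression events, and returns a model object supporting
#' `print`, `summary`, `coef`, `predict` (state-vector propagation),
#' `simulate` (synthetic cohorts from the fitted chain) and `plot`.
#'
#' @param cohort a [metacohort()], or a list of [pathway()] objects.
#' @param subgroup receptor-status subgroup to fit (see [filter_subgroup()]).
#' @param window_years,co_tolerance pathway-extraction parameters, see
#'   [extract_pathways()].
#' @param smoothing passed to [estimate_transition_matrix()].
#' @param taxonomy ordered state labels.
#' @return An object of class `"metachain"`.
#' @examples
#' coh <- simulate_cohort(default_config(n_patients = 80, seed = 7))
#' fit <- metachain_fit(coh)
#' coef(fit)["breast", "bone"]
#' predict(fit, k = 2)
#' @export
metachain_fit <- function(cohort, subgroup = "all", window_years = 10,
                          co_tolerance = 14 / 365.25,
                          smoothing = c("none", "add_one"),
                          taxonomy = met_sites()) {
  smoothing <- match.arg(smoothing)
  cl <- match.call()
  if (inherits(cohort, "metacohort")) {
    sub <- filter_subgroup(cohort, subgroup)
    pw <- extract_pathways(sub, window_years = window_years,
                           co_tolerance = co_tolerance)
    n_patients <- nrow(sub$patients)
  } else if (is.list(cohort) && all(vapply(cohort, inherits, logical(1),
                                           "pathway"))) {
    pw <- cohort
    n_patients <- length(pw)
  } else stop("cohort must be a metacohort or a list of pathways")
  A <- estimate_transition_matrix(pw, taxonomy, smoothing)
  structure(list(transition = A, pathways = pw, subgroup = subgroup,
                 window_years = window_years, n_patients = n_patients,
                 n_pathways = length(pw), call = cl),
            class = "metachain")
}

#' @export
print.metachain <- function(x, ...) {
  cat("Markov chain model of metastatic progression\n")
  cat("  subgroup:", x$subgroup, "  eligible pathways:", x$n_pathways,
      " (of", x$n_patients, "patients)\n")
  cat("  distinct pathways:", count_distinct_pathways(x$pathways), "\n")
  br <- sort(x$transition$probs[SITE_ORIGIN, ], decreasing = TRUE)
  br <- br[br > 0][seq_len(min(3, sum(br > 0)))]
  cat("  leading first-metastasis probabilities:",
      paste(sprintf("%s %.3f", names(br), br), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.metachain <- function(object, ...) object$transition$probs

#' Summarise a fitted progression model
#'
#' Reports cohort composition, leading first-metastasis sites, and the
#' spreader/sponge classification of the fitted chain.
#'
#' @param object a `"metachain"` fit.
#' @param ... unused.
#' @return An object of class `"summary.metachain"`.
#' @export
summary.metachain <- function(object, ...) {
  cls <- classify_sites(object$transition)
  structure(list(fit = object, classification = cls,
                 n_distinct = count_distinct_pathways(object$pathways),
                 first_sites = first_site_table(object$pathways)),
            class = "summary.metachain")
}

#' @export
print.summary.metachain <- function(x, ...) {
  print(x$fit)
  cat("\nFirst metastatic site-sets (top 5):\n")
  fs <- x$first_sites[seq_len(min(5, length(x$first_sites)))]
  print(fs)
  cat("\nSpreader/sponge classification (two-step flows):\n")
  print(x$classification$table, digits = 3)
  invisible(x)
}

#' Predict site occupancy after k progression steps
#'
#' @param object a `"metachain"` fit.
#' @param k number of steps, or a vector of step counts.
#' @param v0 initial [state_vector()]; defaults to all mass on breast.
#' @param ... unused.
#' @return For scalar `k` a [state_vector()]; for vector `k` a matrix with
#'   one row per step count.
#' @export
predict.metachain <- function(object, k = 1, v0 = NULL, ...) {
  if (length(k) == 1L) return(propagate(v0, object$transition, k))
  out <- t(vapply(k, function(kk)
    unclass(propagate(v0, object$transition, kk)),
    numeric(length(object$transition$taxonomy))))
  rownames(out) <- paste0("k=", k)
  out
}

#' Simulate cohorts from a fitted progression model
#'
#' Wraps [simulate_cohort()] with the fitted transition matrix substituted
#' for all subgroups; other generator settings come from [default_config()].
#'
#' @param object a `"metachain"` fit.
#' @param nsim number of patients to simulate.
#' @param seed integer seed (reproducible draws).
#' @param ... overrides passed to [default_config()].
#' @return A [metacohort()].
#' @export
simulate.metachain <- function(object, nsim = 446, seed = NULL, ...) {
  cfg <- default_config(n_patients = nsim, seed = seed, ...)
  A <- object$transition$probs
  cfg$transition_matrices <- list(er_pos_her2_neg = A,
                                  er_neg_her2_neg = A, her2_pos = A)
  simulate_cohort(cfg)
}

#' Plot the state-occupancy evolution of a fitted chain
#'
#' Draws the probability of each anatomical state against the model step k,
#' starting from all mass on the breast; the monotone curve reaching 1 is the
#' absorbing deceased state.
#'
#' @param x a `"metachain"` fit.
#' @param k_max largest step to draw.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the k_max+1 by n matrix of state vectors.
#' @export
plot.metachain <- function(x, k_max = 15, ...) {
  states <- predict(x, k = 0:k_max)
  graphics::matplot(0:k_max, states, type = "l", lty = 1,
                    xlab = "model step k", ylab = "state probability", ...)
  graphics::legend("right", legend = colnames(states), lty = 1,
                   col = seq_len(ncol(states)), cex = 0.7, bty = "n")
  invisible(states)
}

#' Export or import a transition matrix
#'
#' CSV layout: site labels as header row and first column. JSON layout:
#' `{"taxonomy": [...], "probs": [[...]], "counts": [[...]]}`.
#'
#' @param A a `transition_matrix`.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path` invisibly (write); a `transition_matrix` (read).
#' @export
write_transition_matrix <- function(A, path, format = c("csv", "json")) {
  validate_transition_matrix(A)
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(A$probs), path, row.names = TRUE)
  } else {
    jsonlite::write_json(list(taxonomy = A$taxonomy, probs = A$probs,
                              counts = A$counts),
                         path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    probs <- as.matrix(df)
    taxonomy <- rownames(probs)
    colnames(probs) <- taxonomy
    structure(list(probs = probs, counts = probs * NA, taxonomy = taxonomy),
              class = "transition_matrix")
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    dn <- list(doc$taxonomy, doc$taxonomy)
    probs <- doc$probs; counts <- doc$counts
    dimnames(probs) <- dn; dimnames(counts) <- dn
    structure(list(probs = probs, counts = counts, taxonomy = doc$taxonomy),
              class = "transition_matrix")
  }
}
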