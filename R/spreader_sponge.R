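#' Enumerate two-step pathways from the primary
#'
#' A two-step pathway breast -> i -> j has probability
#' `a(breast, i) * a(i, j)`, for every intermediate metastatic site i (not
#' breast or deceased) and every terminal state j. Pathways are returned in
#' descending probability (ties broken by taxonomy order), together with the
#' percentage of total two-step probability mass they cover.
#'
#' @param A a `transition_matrix`.
#' @param top_n number of pathways to keep, or `"all"`.
#' @return List with `pathways` (data.frame `intermediate`, `terminal`,
#'   `probability`) and `coverage` (percent of total two-step mass retained).
#' @examples
#' coh <- simulate_cohort(default_config(n_patients = 120, seed = 3))
#' fit <- metachain_fit(coh)
#' enumerate_two_step_pathways(fit$transition, top_n = 5)
#' @export
enumerate_two_step_pathways <- function(A, top_n = "all") {
  validate_transition_matrix(A)
  if (!identical(top_n, "all") && (!is.numeric(top_n) || top_n < 1))
    stop("top_n must be a positive integer or \"all\"")
  taxonomy <- A$taxonomy
  inter <- setdiff(taxonomy, c(SITE_ORIGIN, SITE_ABSORBING))
  grid <- expand.grid(intermediate = inter, terminal = taxonomy,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$probability <- A$probs[SITE_ORIGIN, grid$intermediate] *
    A$probs[cbind(grid$intermediate, grid$terminal)]
  # deterministic order: probability desc, then taxonomy order of (i, j)
  ord <- order(-grid$probability, match(grid$intermediate, taxonomy),
               match(grid$terminal, taxonomy))
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  total <- sum(grid$probability)
  keep <- if (identical(top_n, "all")) nrow(grid) else
    min(as.integer(top_n), nrow(grid))
  out <- grid[seq_len(keep), , drop = FALSE]
  coverage <- if (total > 0) 100 * sum(out$probability) / total else 100
  list(pathways = out, coverage = coverage)
}

#' Classify metastatic sites as spreaders or sponges
#'
#' A spreader is a net exporter of progression: the two-step probability mass
#' flowing out of it (as the intermediate step of breast -> s -> j pathways)
#' exceeds the mass flowing into it (as the terminal step of
#' breast -> i -> s pathways). Its amplification factor — outgoing over
#' incoming mass — exceeds one. A sponge absorbs more than it re-exports
#' (absorption factor below one). The `one_step` mode is a sensitivity
#' variant using plain off-diagonal row/column sums of the transition matrix
#' instead of two-step masses. Breast and deceased, being the origin and the
#' absorbing state, are never labelled; a site with zero incoming mass has an
#' undefined factor and is flagged instead of labelled.
#'
#' @param A a `transition_matrix`.
#' @param mode `"two_step"` (default, matches the ratio of two-step flow
#'   masses) or `"one_step"`.
#' @return Object of class `"spreader_sponge"`: list with `table`
#'   (data.frame `site`, `outgoing`, `incoming`, `factor`, `label`) and
#'   `mode`.
#' @export
classify_sites <- function(A, mode = c("two_step", "one_step")) {
  validate_transition_matrix(A)
  mode <- match.arg(mode)
  taxonomy <- A$taxonomy
  sites <- setdiff(taxonomy, c(SITE_ORIGIN, SITE_ABSORBING))
  P <- A$probs
  if (mode == "two_step") {
    outgoing <- vapply(sites, function(s)
      sum(P[SITE_ORIGIN, s] * P[s, ]), numeric(1))
    incoming <- vapply(sites, function(s)
      sum(P[SITE_ORIGIN, sites] * P[sites, s]), numeric(1))
  } else {
    outgoing <- vapply(sites, function(s) sum(P[s, -match(s, taxonomy)]),
                       numeric(1))
    incoming <- vapply(sites, function(s) sum(P[-match(s, taxonomy), s]),
                       numeric(1))
  }
  factor <- ifelse(incoming > 0, outgoing / incoming, NA_real_)
  label <- rep("undefined", length(sites))
  ok <- incoming > 0
  label[ok & abs(factor - 1) <= 1e-12] <- "neutral"
  label[ok & factor > 1 + 1e-12] <- "spreader"
  label[ok & factor < 1 - 1e-12] <- "sponge"
  tab <- data.frame(site = sites, outgoing = outgoing, incoming = incoming,
                    factor = factor, label = label, row.names = NULL)
  structure(list(table = tab, mode = mode), class = "spreader_sponge")
}

#' @export
print.spreader_sponge <- function(x, digits = 3, ...) {
  cat("Spreader/sponge classification (", x$mode, " flows)\n", sep = "")
  tab <- x$table
  tab$outgoing <- round(tab$outgoing, digits)
  tab$incoming <- round(tab$incoming, digits)
  tab$factor <- round(tab$factor, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' One-step exit distribution of a site
#'
#' The row of the transition matrix for `site`, truncated to its `top_k`
#' most probable destinations, with the percentage of the row's mass those
#' destinations retain.
#'
#' @param A a `transition_matrix`.
#' @param site a non-deceased taxonomy site.
#' @param top_k number of destinations to keep.
#' @return List with `distribution` (named, descending) and `retained_pct`.
#' @export
site_exit_distribution <- function(A, site, top_k = 9) {
  validate_transition_matrix(A)
  site <- canonicalize_sites(site)
  if (!site %in% A$taxonomy) stop("unknown site: ", site)
  if (site == SITE_ABSORBING)
    stop("the absorbing 'deceased' row is not an exit profile")
  if (top_k < 1) stop("top_k must be a positive integer")
  row <- A$probs[site, ]
  ord <- order(-row, match(names(row), A$taxonomy))
  keep <- ord[seq_len(min(top_k, length(row)))]
  dist <- row[keep]
  list(distribution = dist, retained_pct = 100 * sum(dist) / sum(row))
}

#' Export a chain as chord-diagram data
#'
#' Nodes and weighted directed links suitable for standard chord or sankey
#' renderers; links with zero probability are omitted.
#'
#' @param A a `transition_matrix`.
#' @param path optional file; when given the JSON document is written there.
#' @return List with `nodes` and `links` (data.frame `source`, `target`,
#'   `probability`), invisibly when `path` is given.
#' @export
export_chord <- function(A, path = NULL) {
  validate_transition_matrix(A)
  idx <- which(A$probs > 0, arr.ind = TRUE)
  links <- data.frame(source = A$taxonomy[idx[, 1]],
                      target = A$taxonomy[idx[, 2]],
                      probability = A$probs[idx], row.names = NULL)
  links <- links[order(match(links$source, A$taxonomy),
                       match(links$target, A$taxonomy)), , drop = FALSE]
  rownames(links) <- NULL
  out <- list(nodes = A$taxonomy, links = links)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(out))
  }
  out
}

#' Export a spreader/sponge classification as JSON
#'
#' @param x a `"spreader_sponge"` result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_classification <- function(x, path) {
  stopifnot(inherits(x, "spreader_sponge"))
  jsonlite::write_json(list(mode = x$mode, sites = x$table), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
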