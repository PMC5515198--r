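#' Anatomical site taxonomy
#'
#' The model state space is a fixed, closed taxonomy of anatomical sites.
#' `breast` is the unique origin state (the primary tumour); `deceased` is the
#' unique absorbing terminal state. All other labels are metastatic sites.
#' Input labels outside the taxonomy are coerced to `"other"` with a warning,
#' so the state space is always closed.
#'
#' @return Character vector of the ten state labels, in canonical order
#'   (`breast` first, `deceased` last).
#' @examples
#' met_sites()
#' @export
met_sites <- function() {
  c("breast", "bone", "chest_wall", "ln_mammary", "ln_distant",
    "lung_pleura", "liver", "brain", "other", "deceased")
}

#' @rdname met_sites
#' @format NULL
SITE_ORIGIN <- "breast"

#' @rdname met_sites
#' @format NULL
SITE_ABSORBING <- "deceased"

#' Coerce site labels into the closed taxonomy
#'
#' Unknown labels are mapped to `"other"`; a single warning lists them.
#'
#' @param x character vector of site labels.
#' @return Character vector of the same length, every element in [met_sites()].
#' @keywords internal
canonicalize_sites <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% met_sites())
  if (any(bad)) {
    warning("unknown site label(s) mapped to 'other': ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    x[bad] <- "other"
  }
  x
}

# canonical label for a site-set: sites in taxonomy order joined by "+"
site_set_label <- function(sites) {
  paste(sites[order(match(sites, met_sites()))], collapse = "+")
}
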