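#' Read and write odor parameter sets
#'
#' Parameter sets are stored as delimited text with a header, one record per
#' odor: `name, n, eta, K`. `read_odor_params()` returns a named list of
#' [odor()] objects; `write_odor_params()` writes one.
#'
#' @param path File path (CSV).
#' @param odors A list of [odor()] objects (names taken from the objects or
#'   the list names).
#' @return `read_odor_params()`: a named list of [odor()]s.
#' @export
read_odor_params <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("name", "n", "eta", "K")
  if (!all(need %in% names(tab))) {
    stop("parameter file must have columns: name, n, eta, K", call. = FALSE)
  }
  out <- purrr::pmap(tab[need], function(name, n, eta, K) {
    odor(n = n, eta = eta, K = K, name = name)
  })
  stats::setNames(out, tab$name)
}

#' @rdname read_odor_params
#' @export
write_odor_params <- function(odors, path) {
  if (is_odor(odors)) odors <- list(odors)
  tab <- odor_table(odors)
  if (any(is.na(tab$name))) {
    nms <- names(odors) %||% rep(NA_character_, length(odors))
    tab$name <- dplyr::coalesce(tab$name, nms)
  }
  readr::write_csv(tab[c("name", "n", "eta", "K")], path)
  invisible(path)
}

#' Read a dose-response table
#'
#' Reads delimited text with a header into the `(conc, response)` layout the
#' fitting functions expect. Concentrations stored as log10 values are
#' converted back to linear units when `units = "log10"`.
#'
#' @param path File path (CSV).
#' @param units `"linear"` (default) or `"log10"` for the concentration
#'   column.
#' @return A tibble with columns `conc` and `response`.
#' @export
read_dose_response <- function(path, units = c("linear", "log10")) {
  units <- match.arg(units)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("conc", "response") %in% names(tab))) {
    stop("dose-response file must have columns: conc, response", call. = FALSE)
  }
  if (units == "log10") tab$conc <- 10^tab$conc
  check_conc(tab$conc)
  tibble::as_tibble(tab[c("conc", "response")])
}
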