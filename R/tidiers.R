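# broom-style accessors for fitted/report objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an alien chromosome call report
#'
#' @param x An `alien_call_report`.
#' @param ... Unused.
#' @return A plain tibble with one row per donor chromosome.
#' @method tidy alien_call_report
#' @export
tidy.alien_call_report <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an alien chromosome call report
#'
#' @param x An `alien_call_report`.
#' @param ... Unused.
#' @return A one-row tibble: chromosome counts, the called set, and the call
#'   thresholds used.
#' @method glance alien_call_report
#' @export
glance.alien_call_report <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_chromosomes = nrow(x),
         n_present = sum(x$present),
         present = paste(x$chrom[x$present], collapse = ","),
         depth = p$depth,
         read_length = p$read_length,
         min_window_support = p$min_window_support,
         min_window_frac = p$min_window_frac,
         min_run_frac = p$min_run_frac)
}
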