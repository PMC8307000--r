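# Degree-day offset forecast: first catch at a fixed DD after 1 January,
# then fixed-length generations, optionally widened by a host-development
# delay for larvae feeding on apples.

#' Phenology forecast model parameters
#'
#' The forecast predicts the first moth catch at `biofix_dd` accumulated
#' degree days after 1 January and a fixed egg-to-egg generation time of
#' `generation_dd`. Development on apples is slower than on peaches; the
#' maximum reported delay is 60 DD per generation, applied through
#' `host_delay_dd` (0 for peach, 60 for apple).
#'
#' @param biofix_dd DD after 1 January at which the first catch is
#'   predicted (default 126).
#' @param generation_dd Egg-to-egg generation time in DD (default 535).
#' @param host_delay_dd Per-generation host development delay in DD
#'   (default 0 = peach; use 60 for apple).
#' @param n_generations Number of generations to project (default 5, the
#'   number flying in a Mediterranean season).
#' @return An object of class `phenology_params`.
#' @examples
#' phenology_params()                      # peach defaults
#' phenology_params(host_delay_dd = 60)    # apple
#' @export
phenology_params <- function(biofix_dd = 126, generation_dd = 535,
                             host_delay_dd = 0, n_generations = 5L) {
  stopifnot(biofix_dd >= 0, generation_dd > 0, host_delay_dd >= 0,
            n_generations >= 1)
  structure(list(biofix_dd = biofix_dd, generation_dd = generation_dd,
                 host_delay_dd = host_delay_dd,
                 n_generations = as.integer(n_generations)),
            class = "phenology_params")
}

#' @export
print.phenology_params <- function(x, ...) {
  cat("Phenology model: first catch at ", x$biofix_dd, " DD, generation ",
      x$generation_dd, " DD", sep = "")
  if (x$host_delay_dd > 0)
    cat(" + ", x$host_delay_dd, " DD host delay (", effective_generation_dd(x),
        " DD in total)", sep = "")
  cat(", ", x$n_generations, " generations\n", sep = "")
  invisible(x)
}

#' Effective per-generation degree-day requirement
#'
#' Generation time plus the host delay: 535 DD on peach, 595 DD in total
#' with the 60 DD apple delay.
#'
#' @param params A [phenology_params()].
#' @return Degree days per generation.
#' @export
effective_generation_dd <- function(params) {
  stopifnot(inherits(params, "phenology_params"))
  params$generation_dd + params$host_delay_dd
}

#' Predicted generation windows on the degree-day axis
#'
#' Window k spans `[biofix_dd + (k-1)*G, biofix_dd + k*G)` with
#' `G = effective_generation_dd(params)`. Windows are half-open so a catch
#' exactly at a boundary belongs to the later generation; consecutive
#' windows tile without gaps.
#'
#' @param params A [phenology_params()].
#' @return Data frame of class `generation_windows` with columns `index`,
#'   `dd_start`, `dd_end`.
#' @examples
#' generation_windows(phenology_params(n_generations = 2))
#' @export
generation_windows <- function(params = phenology_params()) {
  stopifnot(inherits(params, "phenology_params"))
  G <- effective_generation_dd(params)
  k <- seq_len(params$n_generations)
  structure(
    data.frame(index = k,
               dd_start = params$biofix_dd + (k - 1) * G,
               dd_end   = params$biofix_dd + k * G),
    params = params,
    class = c("generation_windows", "data.frame"))
}

#' Project generation windows onto the calendar
#'
#' Adds `date_start`/`date_end` to each window by looking up the first
#' date whose cumulative DD reaches the window boundary. Windows whose
#' start or end lies beyond the year's accumulated DD are marked
#' `unreached` with `NA` dates; DD fields are never altered.
#'
#' @param windows Output of [generation_windows()].
#' @param dds A `dd_series` from [accumulate_dd()].
#' @param year Calendar year; defaults to the first year in `dds`.
#' @return `windows` with columns `date_start`, `date_end`, `unreached`.
#' @export
windows_to_calendar <- function(windows, dds, year = NULL) {
  stopifnot(inherits(windows, "generation_windows"),
            inherits(dds, "dd_series"))
  if (is.null(year))
    year <- as.integer(format(dds$date[1L], "%Y"))
  lookup <- function(target) {
    tryCatch(date_at_dd(dds, target, year),
             ddphen_not_reached = function(e) as.Date(NA))
  }
  windows$date_start <- as.Date(vapply(windows$dd_start,
                                       function(t) as.character(lookup(t)),
                                       character(1)))
  windows$date_end <- as.Date(vapply(windows$dd_end,
                                     function(t) as.character(lookup(t)),
                                     character(1)))
  windows$unreached <- is.na(windows$date_start) | is.na(windows$date_end)
  windows
}
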