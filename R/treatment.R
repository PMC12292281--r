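#' The finite treatment-action grid
#'
#' Actions are pairs `(e, d)`: the electric-field control variable and the
#' fluoxetine control variable, each on a uniform grid over
#' `[0, max_level]`. The default `max_level = 0.25` puts the argmax of
#' `sin(2*pi*e)` on the grid, so the full printed modulation amplitude of
#' 0.1/day is reachable, and the no-treatment action `(0, 0)` is on-grid.
#'
#' @param n_levels Number of levels per channel (default 6).
#' @param max_level Upper end of each channel (default 0.25).
#' @param channels `"joint"` for the full `(e, d)` product grid, `"ef"` or
#'   `"flx"` for a single-channel grid with the other channel fixed at 0.
#' @return A tibble with columns `action_id`, `e`, `d`.
#' @examples
#' treatment_grid()           # 36 joint actions
#' treatment_grid(channels = "ef")
#' @export
treatment_grid <- function(n_levels = 6L, max_level = 0.25,
                           channels = c("joint", "ef", "flx")) {
  channels <- match.arg(channels)
  if (n_levels < 1L) abort("`n_levels` must be >= 1")
  lv <- seq(0, max_level, length.out = n_levels)
  grid <- switch(channels,
    joint = tidyr::expand_grid(e = lv, d = lv),
    ef    = tibble::tibble(e = lv, d = 0),
    flx   = tibble::tibble(e = 0, d = lv)
  )
  dplyr::mutate(grid, action_id = dplyr::row_number(), .before = 1)
}

#' Treatment-effect modulation of the actuated rates
#'
#' The in-silico treatment-effect model: the electric-field variable `e`
#' modulates the actuated I -> P rate and the fluoxetine variable `d` the
#' P -> M rate, each by `0.1 * sigma * sin(2*pi*level)` where `sigma = +1`
#' while maturation `m <= 0.5` and `-1` afterwards (treatment helps early,
#' hinders late). Modulated rates are clipped at zero. The H -> I rate is not
#' modulated.
#'
#' @param act Base actuated [rate_constants()].
#' @param e,d Treatment levels (each usually on the [treatment_grid()]).
#' @param m Current maturation fraction in \[0, 1\].
#' @return Modulated `rate_constants`.
#' @examples
#' modulated_rates(rate_constants(0.1, 0.1, 0.1), e = 0.25, d = 0, m = 0.3)
#' @export
modulated_rates <- function(act, e, d, m) {
  if (!inherits(act, "rate_constants")) act <- do.call(rate_constants, as.list(act))
  check_number(m, "m", lower = 0, upper = 1)
  sigma <- if (m <= 0.5) 1 else -1
  rate_constants(
    act[[1]],
    max(0, act[[2]] + 0.1 * sigma * sin(2 * pi * e)),
    max(0, act[[3]] + 0.1 * sigma * sin(2 * pi * d))
  )
}
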