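# Decomposing the change in attributable deaths between two periods into
# climate, population-size, and aging contributions by sequential factor
# substitution averaged over all factor orderings (a Shapley decomposition:
# exact additivity holds by telescoping within each ordering).

#' Bundle the switchable factors describing one period
#'
#' The three drivers are encoded so they can be switched independently:
#' `climate` is the period's window-mean heatwave calendar, `size` the total
#' population per cell, and `aging` the age-structure shares per cell (the
#' age-specific mortality rates ride along in the evaluator); size times
#' shares reconstructs the age-specific populations.
#'
#' @param climate Tibble (cell_id, month, hw_days): window-mean heatwave
#'   days per cell-month.
#' @param size Tibble (cell_id, size): total persons per cell.
#' @param aging Tibble (cell_id, age_group, share): age shares per cell,
#'   summing to 1 within each cell.
#' @return A `factor_state` list.
#' @export
factor_state <- function(climate, size, aging) {
  bad <- aging |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(s = sum(.data$share), .groups = "drop") |>
    dplyr::filter(abs(.data$s - 1) > 1e-6)
  if (nrow(bad)) stop("age shares must sum to 1 per cell", call. = FALSE)
  structure(list(climate = climate, size = size, aging = aging),
            class = "factor_state")
}

#' Build a period's factor state from demography and a heatwave calendar
#'
#' Window means: heatwave days per cell-month, total population per cell,
#' and age-group shares per cell, each averaged over the window years.
#'
#' @param dem A [demography()] object.
#' @param cal Heatwave calendar (cell_id, year, month, hw_days).
#' @param window Year range defining the period.
#' @return A [factor_state()].
#' @export
build_factor_state <- function(dem, cal, window) {
  climate <- cal |>
    dplyr::filter(.data$year %in% window) |>
    dplyr::group_by(.data$cell_id, .data$month) |>
    dplyr::summarise(hw_days = mean(.data$hw_days), .groups = "drop")
  pop_w <- dem$population |>
    dplyr::filter(.data$year %in% window) |>
    dplyr::group_by(.data$cell_id, .data$age_group) |>
    dplyr::summarise(population = mean(.data$population), .groups = "drop")
  size <- pop_w |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(size = sum(.data$population), .groups = "drop")
  aging <- pop_w |>
    dplyr::inner_join(size, by = "cell_id") |>
    dplyr::mutate(share = .data$population / .data$size) |>
    dplyr::select("cell_id", "age_group", "share")
  factor_state(climate, size, aging)
}

#' Build the national-AN evaluator used by the decomposition
#'
#' Returns a closure over the fixed (non-factor) ingredients — attributable
#' fractions, age-specific mortality rates, monthly proportions — that
#' evaluates national attributable deaths for any mixed combination of
#' factor settings.
#'
#' @param af_field Tibble (cell_id, af).
#' @param rates Tibble (age_group, yearly_rate): frozen age-specific rates.
#' @param monthly_prop Tibble (month, proportion).
#' @return `function(climate, size, aging) -> scalar AN`.
#' @export
make_an_evaluator <- function(af_field, rates, monthly_prop = monthly_proportions()) {
  mp <- monthly_prop |>
    dplyr::mutate(daily_frac = .data$proportion / days_in_month(.data$month)) |>
    dplyr::select("month", "daily_frac")
  function(climate, size, aging) {
    cell_rate <- aging |>
      dplyr::inner_join(rates, by = "age_group") |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(rate = sum(.data$share * .data$yearly_rate),
                       .groups = "drop") |>
      dplyr::inner_join(size, by = "cell_id") |>
      dplyr::mutate(base_deaths = .data$size * .data$rate)
    climate |>
      dplyr::inner_join(mp, by = "month") |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(hw_term = sum(.data$hw_days * .data$daily_frac),
                       .groups = "drop") |>
      dplyr::inner_join(cell_rate, by = "cell_id") |>
      dplyr::inner_join(dplyr::select(af_field, "cell_id", "af"), by = "cell_id") |>
      dplyr::summarise(an = sum(.data$hw_term * .data$base_deaths * .data$af)) |>
      dplyr::pull(.data$an)
  }
}

#' Decompose the change in attributable deaths into factor contributions
#'
#' For each of the `3! = 6` orderings of the factors, walks from `state_1`
#' to `state_2` switching one factor at a time; a factor's contribution in
#' an ordering is the change in the evaluated burden at its switch step.
#' The reported contribution is the mean over all orderings, so the
#' contributions sum exactly to the total change.
#'
#' @param state_1,state_2 [factor_state()] objects (or any named lists with
#'   identical names accepted by `an_evaluator`).
#' @param an_evaluator Function taking the named factors and returning a
#'   scalar burden; see [make_an_evaluator()].
#' @return A `contribution_result`: list with `contributions` (tibble:
#'   factor, contribution), `total` (AN2 - AN1), `an_1`, `an_2`,
#'   `n_orderings`.
#' @export
decompose_change <- function(state_1, state_2, an_evaluator) {
  factors <- names(state_1)
  if (!identical(sort(factors), sort(names(state_2)))) {
    stop("states must share factor names", call. = FALSE)
  }
  eval_state <- function(s) do.call(an_evaluator, as.list(s)[factors])
  an_1 <- eval_state(state_1)
  an_2 <- eval_state(state_2)
  perms <- all_permutations(factors)
  contrib <- stats::setNames(numeric(length(factors)), factors)
  for (ord in perms) {
    cur <- as.list(state_1)[factors]
    prev_an <- an_1
    for (f in ord) {
      cur[[f]] <- state_2[[f]]
      new_an <- eval_state(cur)
      contrib[[f]] <- contrib[[f]] + (new_an - prev_an)
      prev_an <- new_an
    }
  }
  contrib <- contrib / length(perms)
  structure(
    list(
      contributions = tibble::tibble(factor = factors,
                                     contribution = unname(contrib[factors])),
      total = an_2 - an_1, an_1 = an_1, an_2 = an_2,
      n_orderings = length(perms)
    ),
    class = "contribution_result"
  )
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Express factor contributions as percentages of the total change
#'
#' When every contribution shares the sign of the total, shares are
#' `contribution / total * 100` and sum to 100. With mixed signs, each
#' contribution is expressed relative to the sum of the positive
#' contributions (so the positive shares sum to 100 and negative factors
#' appear as negative percentages), and the result is flagged
#' `mixed_sign = TRUE`.
#'
#' @param res A `contribution_result` from [decompose_change()].
#' @return Tibble (factor, contribution, share_pct, convention) with
#'   attribute `mixed_sign`.
#' @export
contribution_shares <- function(res) {
  stopifnot(inherits(res, "contribution_result"))
  if (res$total == 0) stop("total change is zero; shares undefined", call. = FALSE)
  ct <- res$contributions
  same_sign <- all(sign(ct$contribution[ct$contribution != 0]) == sign(res$total))
  if (same_sign) {
    out <- ct |>
      dplyr::mutate(share_pct = .data$contribution / res$total * 100,
                    convention = "of_total")
    attr(out, "mixed_sign") <- FALSE
  } else {
    pos <- sum(ct$contribution[ct$contribution > 0])
    out <- ct |>
      dplyr::mutate(share_pct = .data$contribution / pos * 100,
                    convention = "of_positive_sum")
    attr(out, "mixed_sign") <- TRUE
  }
  out
}
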