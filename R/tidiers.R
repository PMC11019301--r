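# broom-style tidiers for reconstruction objects.

#' Tidy an ancestral reconstruction
#'
#' @param x An `ancestral_fit`.
#' @param ... Unused.
#' @return The per-node assignment tibble (`node`, `label`, `is_tip`,
#'   `state`, plus `state_set` for parsimony fits or `p_<state>` posterior
#'   columns for ML fits).
#' @method tidy ancestral_fit
#' @export
tidy.ancestral_fit <- function(x, ...) x$assignment

#' One-row summary of an ancestral reconstruction
#'
#' @param x An `ancestral_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_tips`, `n_states`, `root_state`,
#'   and `min_changes` (parsimony) or `loglik`/`rate` (ML).
#' @method glance ancestral_fit
#' @export
glance.ancestral_fit <- function(x, ...) {
  root <- ape::Ntip(x$tree) + 1L
  base <- tibble(
    method = x$method,
    n_tips = ape::Ntip(x$tree),
    n_states = length(x$states),
    root_state = x$assignment$state[[root]]
  )
  if (x$method == "fitch") {
    mutate(base, min_changes = x$min_changes)
  } else {
    mutate(base, loglik = x$loglik, rate = x$rate)
  }
}

#' Tidy a gain/loss parsimony report
#'
#' @param x A `gain_report`.
#' @param ... Unused.
#' @return Tibble of inferred events, one row per gain/loss branch.
#' @method tidy gain_report
#' @export
tidy.gain_report <- function(x, ...) {
  bind_rows(
    mutate(x$gain_branches, event = "gain"),
    mutate(x$loss_branches, event = "loss")
  ) |>
    select("event", "parent", "child", "branch")
}

#' One-row summary of a gain/loss parsimony report
#'
#' @param x A `gain_report`.
#' @param ... Unused.
#' @return A one-row tibble: `n_gains`, `n_losses`, `total_cost`,
#'   `gain_cost`, `loss_cost`.
#' @method glance gain_report
#' @export
glance.gain_report <- function(x, ...) {
  tibble(n_gains = x$n_gains, n_losses = x$n_losses,
         total_cost = x$total_cost, gain_cost = x$gain_cost,
         loss_cost = x$loss_cost)
}
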