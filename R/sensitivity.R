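#' Decimal-error sensitivity analysis
#'
#' A known feed corruption (comma decimal separators) gave some
#' products wrong displayed health letters. This re-runs the primary
#' health models (i) with the affected products that anyone selected
#' removed from baskets, and (ii) additionally removing participants in
#' the health position & labels arm who selected an affected product --
#' the arm where a wrong label could have steered choice. An audit
#' reports how many of the corrupted products' letters change once the
#' feed is corrected.
#'
#' @param trial a `shop_trial`.
#' @param catalog the fully scored catalog (carrying
#'   `comma_corrupted` provenance flags and both letter columns).
#' @param ids participant ids retained by [apply_exclusions()]; default
#'   applies the exclusions here.
#' @param dimension analysis dimension, default "health".
#' @return list with `fit_excluding_products`,
#'   `fit_excluding_purchasers` (both `trial_fit`s) and `audit` (counts
#'   of affected products/purchasers and the letter-change fraction).
#' @export
decimal_error_sensitivity <- function(trial, catalog, ids = NULL,
                                      dimension = "health") {
  if (is.null(catalog$comma_corrupted))
    abort("catalog lacks comma-corruption provenance flags")
  if (is.null(ids)) ids <- apply_exclusions(trial)$included
  items <- trial$items[trial$items$id %in% ids, , drop = FALSE]

  corrupted_ids <- catalog$product_id[catalog$comma_corrupted]
  affected_selected <- intersect(corrupted_ids, items$product_id)

  # (i) baskets minus the affected products themselves
  items_i <- items[!(items$product_id %in% affected_selected), , drop = FALSE]
  out_i <- basket_outcomes(items_i, catalog)
  out_i <- merge(trial$participants[, c("id", "arm")], out_i, by = "id")
  out_i$full_compliance <- FALSE # not used by the primary sample
  fit_i <- fit_primary(out_i, dimension)

  # (ii) minus purchasers of affected products in the health
  # position & labels arm
  arm_of <- trial$participants$arm[match(items$id, trial$participants$id)]
  purchasers <- unique(items$id[items$product_id %in% affected_selected &
                                  arm_of == "health_position_labels"])
  out_ii <- basket_outcomes(items[!(items$id %in% purchasers), , drop = FALSE],
                            catalog)
  out_ii <- merge(trial$participants[, c("id", "arm")], out_ii, by = "id")
  out_ii$full_compliance <- FALSE
  fit_ii <- fit_primary(out_ii, dimension)

  corr <- catalog[catalog$comma_corrupted, , drop = FALSE]
  letter_changed <- corr$display_nutri_letter != corr$nutri_letter
  audit <- list(
    n_corrupted = nrow(corr),
    n_affected_selected = length(affected_selected),
    n_purchasers_dropped = length(purchasers),
    letter_change_fraction = if (nrow(corr)) mean(letter_changed) else NA_real_,
    letter_shift_table = if (nrow(corr))
      table(abs(match(corr$display_nutri_letter, LETTERS5) -
                  match(corr$nutri_letter, LETTERS5)))
    else table(integer())
  )
  list(fit_excluding_products = fit_i, fit_excluding_purchasers = fit_ii,
       audit = audit)
}
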