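#' Basket-level outcomes
#'
#' Computes, per participant, the arithmetic means over basket items of
#' the scaled Nutri-Score, the eco composite, energy density (kcal/100g),
#' salt, fat and sugar (g/100g) and the four environmental indicators
#' (per-100g units), plus the summed basket price (GBP). Joined to the
#' participants' arm, demographics and compliance status when a
#' `shop_trial` is supplied.
#'
#' @param trial a `shop_trial`, or a long items data frame with columns
#'   `id` and `product_id`.
#' @param catalog the fully scored `shop_catalog` the trial ran on.
#' @param ids optional participant ids to restrict to (e.g. the
#'   `included` set from [apply_exclusions()]).
#' @return data frame of class `basket_outcomes`, one row per
#'   participant with a non-empty basket.
#' @export
basket_outcomes <- function(trial, catalog, ids = NULL) {
  items <- if (inherits(trial, "shop_trial")) trial$items else trial
  if (!is.null(ids)) items <- items[items$id %in% ids, , drop = FALSE]
  if (nrow(items) == 0) abort("no basket items to aggregate")
  ridx <- match(items$product_id, catalog$product_id)
  if (anyNA(ridx)) abort("basket items missing from catalog")
  val_cols <- c(mean_nutriscore = "nutri_scaled", mean_eco = "eco_composite",
                mean_energy = "energy_kcal", mean_salt = "salt_g",
                mean_fat = "fat_g", mean_sugar = "sugar_g",
                mean_ghg = "ghg", mean_water = "water",
                mean_biodiversity = "biodiversity",
                mean_eutrophication = "eutrophication")
  missing_cols <- setdiff(val_cols, names(catalog))
  if (length(missing_cols))
    abort("catalog is not fully scored; missing: %s",
          paste(missing_cols, collapse = ", "))
  vals <- as.matrix(catalog[ridx, val_cols])
  if (anyNA(vals)) abort("catalog contains unscored items in baskets")
  g <- factor(items$id)
  agg <- rowsum(cbind(vals, price = catalog$price[ridx]), g) /
    as.vector(table(g))
  out <- data.frame(id = as.integer(levels(g)), agg, row.names = NULL)
  names(out) <- c("id", names(val_cols), "mean_price")
  out$total_price <- out$mean_price * as.vector(table(g))
  out$mean_price <- NULL
  if (inherits(trial, "shop_trial")) {
    pp <- merge(trial$participants, trial$sessions[, c("id", "n_items",
                                                       "n_categories",
                                                       "full_compliance")],
                by = "id")
    out <- merge(pp, out, by = "id")
  }
  class(out) <- c("basket_outcomes", "data.frame")
  out
}

#' IQR outlier rule
#'
#' Retains values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (bounds
#' inclusive), quartiles by linear interpolation (type 7).
#'
#' @param values numeric vector (length >= 4).
#' @return the retained values.
#' @export
#' @examples
#' iqr_outlier_filter(c(1:9, 100)) # drops 100
iqr_outlier_filter <- function(values) {
  values[iqr_keep(values)]
}

# logical mask version used by the model pipeline
iqr_keep <- function(values) {
  if (length(values) < 4) abort("need at least 4 observations")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}
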