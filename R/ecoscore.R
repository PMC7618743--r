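#' Within-catalog percentile of an environmental indicator
#'
#' Empirical cumulative percentile with midranks for ties:
#' `(midrank - 0.5) / n * 100`. All-tied columns map to 50; the
#' smallest of `n` distinct values maps to `50/n`.
#'
#' @param values strictly positive indicator values (per 100 g).
#' @param ref reference column defining the distribution (defaults to
#'   `values` itself); percentiles of `values` are computed within `ref`.
#' @return percentiles in (0, 100).
#' @export
#' @examples
#' indicator_percentile(c(1, 2, 3, 4)) # 12.5 37.5 62.5 87.5
indicator_percentile <- function(values, ref = values) {
  if (any(!is.finite(values)) || any(values <= 0) || any(ref <= 0))
    abort("environmental indicators must be strictly positive")
  n <- length(ref)
  # midrank of each value within ref: average of "strictly below" count
  # and "at or below" count, + 1/2
  below <- findInterval(values, sort(ref), left.open = TRUE)
  at_or_below <- findInterval(values, sort(ref))
  midrank <- (below + at_or_below + 1) / 2
  (midrank - 0.5) / n * 100
}

#' Composite eco score from four indicator percentiles
#'
#' Arithmetic mean of the greenhouse-gas, water-use, biodiversity-loss
#' and eutrophication percentiles; lies in \[0, 100\], higher = less
#' sustainable.
#'
#' @param p matrix or data frame with four percentile columns in
#'   \[0, 100\].
#' @return numeric composite per row.
#' @export
eco_composite <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 4) abort("expected four indicator percentile columns")
  if (any(p < 0 | p > 100)) abort("percentiles must lie in [0, 100]")
  rowMeans(p)
}

#' Quintile-based A--E eco letter
#'
#' Quintile edges sit at the 20/40/60/80th percentiles (type-7) of the
#' catalog composite distribution; a composite exactly on an edge takes
#' the better (earlier) letter.
#'
#' @param composite composites to letter.
#' @param ref catalog composites defining the quintiles (>= 5 values);
#'   defaults to `composite`.
#' @return character vector of letters.
#' @export
eco_letter <- function(composite, ref = composite) {
  if (length(ref) < 5) abort("need at least 5 products to form quintiles")
  edges <- quantile(ref, c(0.2, 0.4, 0.6, 0.8), names = FALSE, type = 7)
  idx <- 1L + (composite > edges[1]) + (composite > edges[2]) +
    (composite > edges[3]) + (composite > edges[4])
  LETTERS5[idx]
}

#' Score a catalog on the environmental dimension
#'
#' Adds per-indicator percentile columns, the composite `eco_composite`
#' and the quintile `eco_letter`. Percentiles and quintiles are taken
#' within the supplied catalog (post-filter), matching the scale the
#' labels were built on.
#'
#' @param catalog a `shop_catalog` with positive `ghg`, `water`,
#'   `biodiversity` and `eutrophication` columns.
#' @return the catalog with eco score columns added.
#' @export
score_eco <- function(catalog) {
  inds <- c("ghg", "water", "biodiversity", "eutrophication")
  pm <- sapply(inds, function(i) indicator_percentile(catalog[[i]]))
  colnames(pm) <- paste0("pct_", inds)
  for (j in colnames(pm)) catalog[[j]] <- pm[, j]
  catalog$eco_composite <- eco_composite(pm)
  catalog$eco_letter <- eco_letter(catalog$eco_composite)
  catalog
}

#' Clean and score a catalog in one step
#'
#' Runs [clean_catalog()], [score_health()] and [score_eco()], and adds
#' the letters a participant would have seen on the supermarket shelf:
#' `display_nutri_letter` equals `nutri_letter` except for
#' comma-corrupted products, whose displayed letter is recomputed from
#' the mis-parsed feed (see [clean_catalog()]), reproducing the
#' labelling error the decimal-error sensitivity analysis addresses.
#' Eco letters are unaffected by the corruption.
#'
#' @param catalog a raw `shop_catalog` (post [alcohol_and_missing_filter()]).
#' @inheritParams score_health
#' @return a fully scored catalog.
#' @export
score_catalog <- function(catalog, category = "general",
                          scaling_range = c(-15, 40)) {
  catalog <- clean_catalog(catalog)
  catalog <- score_health(catalog, category, scaling_range)
  catalog <- score_eco(catalog)
  catalog$display_nutri_letter <- catalog$nutri_letter
  bad <- which(catalog$comma_corrupted)
  if (length(bad)) {
    corr <- clean_catalog(catalog[bad, , drop = FALSE], use_corrupted = TRUE)
    ok <- stats::complete.cases(corr[, c("energy_kcal", "sugar_g", "sodium_mg")])
    if (any(ok)) {
      p <- suppressWarnings(nps_points(
        corr$energy_kcal[ok], corr$sugar_g[ok], corr$satfat_g[ok],
        corr$sodium_mg[ok], corr$fruitveg_pct[ok], corr$fibre_g[ok],
        corr$protein_g[ok], fat_g = corr$fat_g[ok], category = category))
      # the feed's raw scores can spill past the theoretical range; the
      # displayed letter is still a plain cut-point lookup
      catalog$display_nutri_letter[bad[ok]] <- health_letter(p$raw, category)
    }
  }
  catalog
}
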