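# FSAm-NPS / Nutri-Score points. Component tables and letter cut points
# ship as CSV data files under inst/extdata and are cached per session.

.ns_cache <- new.env(parent = emptyenv())

ns_tables <- function() {
  if (is.null(.ns_cache$points)) {
    .ns_cache$points <- read.csv(system.file("extdata", "nutriscore_points.csv",
                                             package = "shelfnudge"),
                                 stringsAsFactors = FALSE)
    .ns_cache$letters <- read.csv(system.file("extdata", "nutriscore_letters.csv",
                                              package = "shelfnudge"),
                                  stringsAsFactors = FALSE)
  }
  .ns_cache
}

# points for one component: value > gt (strict) earns that row's points
ns_component_points <- function(value, component, category = "general") {
  tab <- ns_tables()$points
  rows <- tab[tab$component == component &
                tab$category == if (any(tab$category == category &
                                        tab$component == component))
                  category else "general", , drop = FALSE]
  rows <- rows[order(rows$gt), ]
  idx <- findInterval(value, rows$gt, left.open = TRUE)
  pts <- c(0, rows$points)[idx + 1L]
  pts[is.na(value)] <- NA_integer_
  pts
}

#' Compute FSAm-NPS (Nutri-Score) points for products
#'
#' Negative points (0--10 each) accrue for energy, total sugars,
#' saturated fat and sodium; positive points for fruit/veg/nuts
#' (0--5, beverages 0--10), fibre and protein (0--5 each). For general
#' foods, protein points only count when negative points are below 11
#' or the fruit/veg component is maximal; cheese always counts protein.
#' For added fats the saturated-fat component is replaced by the
#' saturated-to-total-fat ratio. Energy arrives in kcal and is
#' converted to kJ (x 4.184) before lookup.
#'
#' Missing optional components (fruit/veg, fibre, saturated fat) score
#' zero points with a warning; missing energy, sugar or sodium is an
#' error.
#'
#' @param energy_kcal,sugar_g,satfat_g,sodium_mg,fruitveg_pct,fibre_g,protein_g
#'   numeric vectors of cleaned per-100g values ([clean_catalog()]).
#' @param fat_g total fat, required for `category = "added_fat"`.
#' @param category scoring variant: "general", "beverage", "added_fat"
#'   or "cheese" (scalar or vector).
#' @return a data frame with per-component points, `negative_points`,
#'   `positive_points` (as counted), `protein_counted` and the `raw`
#'   score in \[-15, 40\].
#' @export
nps_points <- function(energy_kcal, sugar_g, satfat_g, sodium_mg,
                       fruitveg_pct = 0, fibre_g = 0, protein_g = 0,
                       fat_g = NULL, category = "general") {
  n <- length(energy_kcal)
  category <- rep_len(category, n)
  if (!all(category %in% c("general", "beverage", "added_fat", "cheese")))
    abort("unknown Nutri-Score category")
  if (anyNA(energy_kcal) || anyNA(sugar_g) || anyNA(sodium_mg))
    abort("energy, sugar and sodium must be present to score")
  fill0 <- function(x, what) {
    x <- rep_len(if (is.null(x)) NA_real_ else x, n)
    if (anyNA(x)) {
      warning(sprintf("missing %s treated as 0 points for %d product(s)",
                      what, sum(is.na(x))), call. = FALSE)
      x[is.na(x)] <- 0
    }
    x
  }
  satfat_g <- fill0(satfat_g, "saturated fat")
  fruitveg_pct <- fill0(fruitveg_pct, "fruit/veg %")
  fibre_g <- fill0(fibre_g, "fibre")
  protein_g <- rep_len(protein_g, n)
  protein_g[is.na(protein_g)] <- 0

  pts_by_cat <- function(value, component) {
    out <- integer(n)
    for (cc in unique(category)) {
      i <- category == cc
      out[i] <- ns_component_points(value[i], component, cc)
    }
    out
  }
  energy_pts <- pts_by_cat(energy_kcal * 4.184, "energy_kj")
  sugar_pts <- pts_by_cat(sugar_g, "sugars_g")
  satfat_pts <- integer(n)
  af <- category == "added_fat"
  if (any(af)) {
    if (is.null(fat_g)) abort("fat_g required for added_fat scoring")
    fat_g <- rep_len(fat_g, n)
    ratio <- ifelse(fat_g[af] > 0, 100 * satfat_g[af] / fat_g[af], 0)
    satfat_pts[af] <- ns_component_points(ratio, "satfat_ratio_pct", "added_fat")
  }
  satfat_pts[!af] <- pts_by_cat(satfat_g, "satfat_g")[!af]
  sodium_pts <- pts_by_cat(sodium_mg, "sodium_mg")
  fv_pts <- pts_by_cat(fruitveg_pct, "fruitveg_pct")
  fibre_pts <- pts_by_cat(fibre_g, "fibre_g")
  protein_pts <- pts_by_cat(protein_g, "protein_g")

  negative_points <- energy_pts + sugar_pts + satfat_pts + sodium_pts
  fv_max <- ifelse(category == "beverage", 10L, 5L)
  protein_counted <- category == "cheese" | negative_points < 11 | fv_pts == fv_max
  positive_points <- fv_pts + fibre_pts + ifelse(protein_counted, protein_pts, 0L)
  data.frame(
    energy_pts = energy_pts, sugar_pts = sugar_pts, satfat_pts = satfat_pts,
    sodium_pts = sodium_pts, fv_pts = fv_pts, fibre_pts = fibre_pts,
    protein_pts = protein_pts, negative_points = negative_points,
    positive_points = positive_points, protein_counted = protein_counted,
    raw = negative_points - positive_points
  )
}

#' Scale a raw Nutri-Score onto 0--100
#'
#' Affine map of the theoretical raw range \[-15, 40\] onto \[0, 100\]
#' (higher = less healthy). Pass the observed catalog range as `range`
#' for min-max scaling instead.
#'
#' @param raw numeric raw scores.
#' @param range length-2 numeric; values outside it are an error.
#' @return numeric scaled scores in \[0, 100\].
#' @export
#' @examples
#' scale_health(c(-15, 12, 40))
scale_health <- function(raw, range = c(-15, 40)) {
  if (any(!is.finite(raw)) || any(raw < range[1] | raw > range[2]))
    abort("raw score outside [%s, %s]", range[1], range[2])
  (raw - range[1]) * 100 / diff(range)
}

#' Assign the A--E health letter
#'
#' Letter boundaries follow the published category cut points (general
#' foods: A at raw <= -1, B to 2, C to 10, D to 18, E above; beverages
#' are never A and cut at 1/5/9). Cheese and added fats use the general
#' bounds.
#'
#' @param raw integer raw scores.
#' @param category "general", "cheese", "added_fat" or "beverage".
#' @return character vector of letters.
#' @export
health_letter <- function(raw, category = "general") {
  tab <- ns_tables()$letters
  cat_key <- if (identical(category, "beverage")) "beverage" else "general"
  rows <- tab[tab$category == cat_key, ]
  rows <- rows[order(rows$max_raw), ]
  rows$letter[1L + findInterval(raw, rows$max_raw, left.open = TRUE)]
}

#' Score a catalog on the health dimension
#'
#' Adds `nutri_raw`, `nutri_scaled` and `nutri_letter` columns. The
#' catalog must already carry cleaned numeric nutrients
#' ([clean_catalog()]). All synthetic products are scored as general
#' foods (alcohol is excluded upstream and the shopping list holds no
#' beverages).
#'
#' @param catalog a cleaned `shop_catalog`.
#' @param category Nutri-Score variant applied to every product.
#' @param scaling_range passed to [scale_health()].
#' @return the catalog with health score columns added.
#' @export
score_health <- function(catalog, category = "general",
                         scaling_range = c(-15, 40)) {
  if (is.null(catalog$energy_kcal))
    abort("catalog has no cleaned nutrients; run clean_catalog() first")
  p <- nps_points(catalog$energy_kcal, catalog$sugar_g, catalog$satfat_g,
                  catalog$sodium_mg, catalog$fruitveg_pct, catalog$fibre_g,
                  catalog$protein_g, fat_g = catalog$fat_g,
                  category = category)
  catalog$nutri_raw <- p$raw
  catalog$nutri_scaled <- scale_health(p$raw, scaling_range)
  catalog$nutri_letter <- health_letter(p$raw, category)
  catalog
}
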