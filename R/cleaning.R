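#' Repair comma decimal separators
#'
#' Some retailer feeds use "," between digits as the decimal separator
#' ("1,2" for 1.2). The comma is replaced by "." only when flanked by
#' digits; all other strings pass through unchanged.
#'
#' @param raw character vector of raw nutrient declarations.
#' @return character vector of the same length.
#' @export
#' @examples
#' fix_decimal_commas(c("1,2", "0.5", "trace"))
fix_decimal_commas <- function(raw) {
  gsub("(?<=[0-9]),(?=[0-9])", ".", as.character(raw), perl = TRUE)
}

TRACE_WORDS <- c("trace", "nil", "negligible")

#' Parse a raw nutrient declaration into a numeric per-100g value
#'
#' Applies, in order: comma-decimal repair; the trace-word recode
#' ("trace"/"nil"/"negligible" read as zero for fat, sugar and salt);
#' "<"-prefix stripping; and the small-value recodes (fat or sugar
#' below 0.5 g and salt below 0.01 g read as zero -- a "<"-prefixed salt
#' value of at least 0.01 keeps its numeric part). Energy, fibre,
#' protein and fruit/veg percentages are parsed as plain numerics.
#' Anything unparseable becomes `NA` (a missing-value marker picked up
#' by [alcohol_and_missing_filter()]), never a silent zero.
#'
#' @param raw character vector of declarations.
#' @param kind one of "fat", "satfat", "sugar", "salt", "energy",
#'   "fibre", "protein", "fruitveg".
#' @return numeric vector; `NA` where unparseable.
#' @export
#' @examples
#' parse_nutrient("trace", "salt")   # 0
#' parse_nutrient("<0.02", "salt")   # 0.02
#' parse_nutrient("0.4", "fat")      # 0
parse_nutrient <- function(raw,
                           kind = c("fat", "satfat", "sugar", "salt",
                                    "energy", "fibre", "protein", "fruitveg")) {
  kind <- match.arg(kind)
  x <- trimws(fix_decimal_commas(raw))
  out <- rep(NA_real_, length(x))

  thresholded <- kind %in% c("fat", "satfat", "sugar", "salt")
  if (thresholded) out[tolower(x) %in% TRACE_WORDS] <- 0

  # strip "<" for the thresholded nutrients; the small-value recode below
  # then decides whether the numeric part survives
  has_lt <- thresholded & startsWith(x, "<")
  num_str <- ifelse(has_lt, substring(x, 2), x)
  val <- suppressWarnings(as.numeric(num_str))
  val[!is.na(val) & val < 0] <- NA # negative declarations are invalid, not small
  plain <- is.na(out) & !is.na(val)
  out[plain] <- val[plain]

  if (kind %in% c("fat", "satfat", "sugar")) out[!is.na(out) & out < 0.5] <- 0
  if (kind == "salt") out[!is.na(out) & out < 0.01] <- 0
  if (kind == "fruitveg") out[!is.na(out) & out > 100] <- NA
  out
}

#' Add cleaned numeric nutrient columns to a catalog
#'
#' Parses every raw nutrient string column with [parse_nutrient()] and
#' derives sodium (mg/100g = salt g/100g x 400). When
#' `use_corrupted = TRUE` the comma repair is withheld for products
#' flagged `comma_corrupted`, reproducing the mis-parse the raw feed
#' would induce (commas read as digit-group separators): used to model
#' the as-displayed scores in the label-corruption sensitivity analysis.
#'
#' @param catalog a `shop_catalog`.
#' @param use_corrupted logical; parse flagged products as the buggy
#'   feed would (see Details).
#' @return the catalog with numeric columns `energy_kcal`, `fat_g`,
#'   `satfat_g`, `sugar_g`, `salt_g`, `fibre_g`, `protein_g`,
#'   `fruitveg_pct`, `sodium_mg` added (or replaced).
#' @export
clean_catalog <- function(catalog, use_corrupted = FALSE) {
  cols <- c(energy_kcal = "energy_str", fat_g = "fat_str",
            satfat_g = "satfat_str", sugar_g = "sugar_str",
            salt_g = "salt_str", fibre_g = "fibre_str",
            protein_g = "protein_str", fruitveg_pct = "fruitveg_pct_str")
  kinds <- c("energy", "fat", "satfat", "sugar", "salt", "fibre",
             "protein", "fruitveg")
  for (i in seq_along(cols)) {
    s <- catalog[[cols[[i]]]]
    if (use_corrupted && any(catalog$comma_corrupted)) {
      # drop the comma outright ("1,2" -> "12"), as a naive numeric cast would
      bad <- catalog$comma_corrupted
      s[bad] <- gsub(",", "", s[bad], fixed = TRUE)
    }
    catalog[[names(cols)[i]]] <- parse_nutrient(s, kinds[i])
  }
  catalog$sodium_mg <- catalog$salt_g * 400
  catalog
}
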