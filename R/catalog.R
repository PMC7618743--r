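#' Configure a synthetic product catalog
#'
#' Builds the configuration object consumed by [generate_catalog()]. The
#' defaults emulate a foodDB-like catalog of 8400 products: the ten
#' shopping-list shelves (800 products, sized 32--120 so most shelves
#' paginate at 28 products per page) plus 95 filler shelves of 80
#' products each, with the raw-data quirks observed in real retailer
#' feeds (comma decimal separators, "trace"/"nil"/"negligible" entries,
#' "<"-prefixed values, missing fields).
#'
#' Environmental indicators are drawn on the log scale. Filler shelves
#' sit `eco_log_gap` log-units above the shopping-list shelves, so
#' shopping-list products occupy the bottom of the catalog-wide
#' percentile distribution and basket mean eco scores land in the
#' single digits on the 0--100 composite scale, while the heavy right
#' tail (`eco_sdlog_target`) pushes a minority of shopping-list
#' products into the higher eco-letter quintiles.
#'
#' @param target_shelf_sizes named integer vector of products per
#'   shopping-list shelf; names must be the ten shopping-list categories.
#' @param n_filler_shelves,filler_shelf_size number and size of
#'   non-target shelves participants could browse but are not asked to
#'   shop from.
#' @param comma_decimal_rate fraction of products whose nutrient strings
#'   use "," as the decimal separator (a product-level corruption flag).
#'   The default reproduces 326 affected products in a catalog of 8400.
#' @param trace_word_rate per-string probability that a fat/sugar/salt
#'   declaration reads "trace", "nil" or "negligible".
#' @param lt_prefix_rate per-string probability of a "<" prefix on a
#'   fat/sugar/salt declaration.
#' @param missing_rate per-product probability that one of the four
#'   required fields (energy, salt, sugar, fat) is empty.
#' @param alcohol_rate probability that a filler-shelf product is
#'   alcoholic (flagged, later removed by [alcohol_and_missing_filter()]).
#' @param eco_log_gap,eco_sdlog_target,eco_sdlog_filler log-normal
#'   parameters of the environmental indicators (see Details).
#' @param shelf_params optional data frame overriding the per-shelf
#'   nutrient distribution parameters; see [default_shelf_params()].
#' @param seed integer seed stored in the config; [generate_catalog()]
#'   seeds the RNG with it so identical configs yield identical catalogs.
#' @return an object of class `catalog_config` (a list).
#' @export
catalog_config <- function(target_shelf_sizes = c(
                             savoury_pies = 56, cheese = 112, frozen_pizza = 48,
                             sandwiches = 64, yogurt = 96, ready_meals = 120,
                             meat_and_alternatives = 112, soup = 72,
                             desserts = 88, crackers = 32),
                           n_filler_shelves = 95,
                           filler_shelf_size = 80,
                           comma_decimal_rate = 326 / 8400,
                           trace_word_rate = 0.02,
                           lt_prefix_rate = 0.02,
                           missing_rate = 0.01,
                           alcohol_rate = 0.02,
                           eco_log_gap = 3,
                           eco_sdlog_target = 1.5,
                           eco_sdlog_filler = 0.8,
                           shelf_params = default_shelf_params(),
                           seed = 1L) {
  if (is.null(names(target_shelf_sizes)) ||
      !setequal(names(target_shelf_sizes), SHOPPING_LIST))
    abort("target_shelf_sizes must be named with the 10 shopping-list categories")
  if (any(target_shelf_sizes < 1))
    abort("zero-size shelf for shopping-list category: %s",
          paste(names(target_shelf_sizes)[target_shelf_sizes < 1], collapse = ", "))
  for (r in c(comma_decimal_rate, trace_word_rate, lt_prefix_rate,
              missing_rate, alcohol_rate))
    if (!is_prob(r)) abort("quirk rates must be probabilities in [0, 1]")
  if (!is_count(n_filler_shelves) || (n_filler_shelves > 0 && filler_shelf_size < 1))
    abort("invalid filler shelf configuration")
  target_shelf_sizes <- target_shelf_sizes[SHOPPING_LIST]
  structure(list(
    target_shelf_sizes = target_shelf_sizes,
    n_filler_shelves = n_filler_shelves,
    filler_shelf_size = filler_shelf_size,
    n_products = sum(target_shelf_sizes) + n_filler_shelves * filler_shelf_size,
    comma_decimal_rate = comma_decimal_rate,
    trace_word_rate = trace_word_rate,
    lt_prefix_rate = lt_prefix_rate,
    missing_rate = missing_rate,
    alcohol_rate = alcohol_rate,
    eco_log_gap = eco_log_gap,
    eco_sdlog_target = eco_sdlog_target,
    eco_sdlog_filler = eco_sdlog_filler,
    shelf_params = shelf_params,
    seed = as.integer(seed)
  ), class = "catalog_config")
}

#' Default per-shelf nutrient distribution parameters
#'
#' One row per shopping-list shelf plus a `filler` row. Nutrient means
#' and standard deviations are per 100 g (kcal for energy); `satfat_ratio`
#' is the expected saturated/total fat ratio; `fv_p` the probability of a
#' non-zero fruit/veg/nuts percentage; `eco_offset` a shelf-level shift
#' of the environmental log-means (animal-based shelves higher);
#' `price_gbp` the median price.
#'
#' @return a data frame keyed by `shelf`.
#' @export
default_shelf_params <- function() {
  p <- read.csv(text = "
shelf,energy_m,energy_sd,fat_m,fat_sd,sugar_m,sugar_sd,salt_m,salt_sd,fibre_m,protein_m,satfat_ratio,fv_p,eco_offset,price_gbp
savoury_pies,280,50,16,5,3,1.5,0.9,0.35,1.5,9,0.40,0.10,0.5,3.0
cheese,350,80,27,7,2,1.2,1.6,0.50,0.2,22,0.65,0.00,0.8,3.5
frozen_pizza,230,40,8,3,4,1.5,1.2,0.35,2.0,10,0.40,0.30,0.2,3.2
sandwiches,220,40,9,4,4,1.5,1.1,0.30,2.0,10,0.35,0.40,0.2,2.8
yogurt,90,35,3.5,2,10,4,0.15,0.06,0.3,5,0.65,0.30,-0.2,1.5
ready_meals,140,40,6,3,3.5,1.8,0.7,0.25,1.8,8,0.35,0.50,0.3,3.5
meat_and_alternatives,180,60,10,5,1.5,1,0.8,0.35,1.0,18,0.40,0.10,1.0,4.0
soup,45,15,1.5,1,3,1.5,0.6,0.20,1.0,2,0.30,0.70,-0.3,1.8
desserts,220,60,10,4,20,7,0.2,0.10,0.8,4,0.55,0.10,0.0,2.5
crackers,440,50,14,5,4,2,1.5,0.45,4.0,9,0.35,0.00,-0.2,1.6
filler,200,90,8,5,8,7,0.8,0.45,2.0,7,0.40,0.30,0.0,2.5
", stringsAsFactors = FALSE)
  p
}

# log-scale base levels of the four environmental indicators for
# shopping-list shelves (filler shelves sit eco_log_gap above)
ECO_BASE_MEANLOG <- c(ghg = log(0.15), water = log(50),
                      biodiversity = log(2), eutrophication = log(1.5))

#' Generate a synthetic product catalog
#'
#' Draws `config$n_products` products with raw (string) nutrient
#' declarations, four positive environmental indicators per 100 g, a
#' price, an alcohol flag, and the configured data quirks. Nutrients are
#' drawn from truncated normals per shelf with energy and fat coupled
#' through a shared latent factor; environmental indicators are
#' log-normal, correlated within product. The same config (including its
#' seed) always produces an identical catalog.
#'
#' @param config a [catalog_config()] object.
#' @return a data frame of class `shop_catalog`, one row per product,
#'   with the generating config attached as attribute `config`.
#' @export
generate_catalog <- function(config = catalog_config()) {
  if (!inherits(config, "catalog_config")) abort("config must be a catalog_config")
  set.seed(config$seed)

  filler_names <- if (config$n_filler_shelves > 0)
    sprintf("filler_%03d", seq_len(config$n_filler_shelves)) else character()
  shelves <- c(rep(names(config$target_shelf_sizes), config$target_shelf_sizes),
               rep(filler_names, each = config$filler_shelf_size))
  n <- length(shelves)
  is_target <- shelves %in% SHOPPING_LIST

  sp <- config$shelf_params
  prow <- match(ifelse(is_target, shelves, "filler"), sp$shelf)
  par <- sp[prow, ]

  tnorm <- function(m, s, lo = 0) pmax(lo, rnorm(n, m, s))
  z <- rnorm(n) # latent factor coupling energy and fat
  energy <- pmax(5, par$energy_m + par$energy_sd * (0.6 * z + 0.8 * rnorm(n)))
  fat <- pmax(0, par$fat_m + par$fat_sd * (0.6 * z + 0.8 * rnorm(n)))
  satfat <- fat * pmin(1, pmax(0.05, rnorm(n, par$satfat_ratio, 0.08)))
  sugar <- tnorm(par$sugar_m, par$sugar_sd)
  salt <- tnorm(par$salt_m, par$salt_sd)
  fibre <- tnorm(par$fibre_m, pmax(0.3, par$fibre_m * 0.5))
  protein <- tnorm(par$protein_m, pmax(0.5, par$protein_m * 0.4))
  fruitveg <- ifelse(runif(n) < par$fv_p,
                     pmin(100, round(runif(n, 5, 85))), 0)
  price <- rlnorm(n, log(par$price_gbp), 0.35)

  eco_mean_shift <- ifelse(is_target, par$eco_offset,
                           par$eco_offset + config$eco_log_gap)
  eco_sd <- ifelse(is_target, config$eco_sdlog_target, config$eco_sdlog_filler)
  w <- rnorm(n) # latent factor correlating the four indicators
  eco_draw <- function(ind) {
    exp(ECO_BASE_MEANLOG[[ind]] + eco_mean_shift +
          eco_sd * (0.7 * w + sqrt(1 - 0.7^2) * rnorm(n)))
  }
  ghg <- eco_draw("ghg")
  water <- eco_draw("water")
  biodiversity <- eco_draw("biodiversity")
  eutrophication <- eco_draw("eutrophication")

  alcohol <- !is_target & runif(n) < config$alcohol_rate

  fmt <- function(x, digits) formatC(round(x, digits), format = "f", digits = digits)
  str_of <- list(
    energy_str = fmt(energy, 0), fat_str = fmt(fat, 1),
    satfat_str = fmt(satfat, 1), sugar_str = fmt(sugar, 1),
    salt_str = fmt(salt, 2), fibre_str = fmt(fibre, 1),
    protein_str = fmt(protein, 1), fruitveg_pct_str = fmt(fruitveg, 0)
  )

  # quirks: missing fields, trace words, "<" prefixes, then comma decimals
  if (config$missing_rate > 0) {
    hit <- runif(n) < config$missing_rate
    which_field <- sample(c("energy_str", "salt_str", "sugar_str", "fat_str"),
                          n, replace = TRUE)
    for (f in c("energy_str", "salt_str", "sugar_str", "fat_str"))
      str_of[[f]][hit & which_field == f] <- ""
  }
  for (f in c("fat_str", "sugar_str", "salt_str")) {
    ok <- str_of[[f]] != ""
    tr <- ok & runif(n) < config$trace_word_rate
    str_of[[f]][tr] <- sample(c("trace", "nil", "negligible"), sum(tr), replace = TRUE)
    lt <- ok & !tr & runif(n) < config$lt_prefix_rate
    str_of[[f]][lt] <- paste0("<", str_of[[f]][lt])
  }
  comma_corrupted <- runif(n) < config$comma_decimal_rate
  for (f in names(str_of))
    str_of[[f]][comma_corrupted] <- sub(".", ",", str_of[[f]][comma_corrupted],
                                        fixed = TRUE)

  cat_df <- data.frame(
    product_id = sprintf("P%05d", seq_len(n)),
    shelf = shelves,
    is_target = is_target,
    alcohol = alcohol,
    str_of,
    ghg = ghg, water = water, biodiversity = biodiversity,
    eutrophication = eutrophication,
    price = price,
    comma_corrupted = comma_corrupted,
    stringsAsFactors = FALSE
  )
  structure(cat_df, class = c("shop_catalog", "data.frame"), config = config)
}

#' Remove alcoholic products and products with incomplete key nutrients
#'
#' Mirrors the study's catalog exclusions: alcoholic products (and their
#' no/low-alcohol equivalents, here a single flag) are dropped, as are
#' products whose energy, salt, sugar or fat declaration does not parse
#' to a numeric value after cleaning.
#'
#' @param catalog a `shop_catalog` data frame.
#' @return the filtered catalog (class preserved).
#' @export
alcohol_and_missing_filter <- function(catalog) {
  need <- cbind(
    parse_nutrient(catalog$energy_str, "energy"),
    parse_nutrient(catalog$salt_str, "salt"),
    parse_nutrient(catalog$sugar_str, "sugar"),
    parse_nutrient(catalog$fat_str, "fat")
  )
  keep <- !catalog$alcohol & complete.cases(need)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a catalog as CSV
#'
#' The CSV preserves the raw nutrient strings verbatim. If `jsonlite`
#' is installed, `write_catalog()` also writes a `<path>.json` sidecar
#' holding the generating configuration.
#'
#' @param catalog a `shop_catalog`.
#' @param path CSV file path.
#' @return `read_catalog()` returns a `shop_catalog` data frame.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(catalog, path, row.names = FALSE)
  cfg <- attr(catalog, "config")
  if (!is.null(cfg) && requireNamespace("jsonlite", quietly = TRUE)) {
    side <- cfg[setdiff(names(cfg), "shelf_params")]
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(product_id = "character"))
  str_cols <- grep("_str$", names(df), value = TRUE)
  for (f in str_cols) df[[f]] <- ifelse(is.na(df[[f]]), "", as.character(df[[f]]))
  structure(df, class = c("shop_catalog", "data.frame"))
}

#' @export
print.shop_catalog <- function(x, ...) {
  cat(sprintf("<shop_catalog> %d products on %d shelves (%d shopping-list)\n",
              nrow(x), length(unique(x$shelf)),
              length(intersect(unique(x$shelf), SHOPPING_LIST))))
  if (any(x$comma_corrupted))
    cat(sprintf("  %d products carry comma decimal separators\n",
                sum(x$comma_corrupted)))
  scored <- intersect(c("nutri_raw", "eco_composite"), names(x))
  if (length(scored)) cat("  scored columns:", paste(scored, collapse = ", "), "\n")
  print(head(as.data.frame(x)[, seq_len(min(8, ncol(x)))], 4))
  invisible(x)
}
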