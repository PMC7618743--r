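# Per-letter sort-key ranges for the intervention arms; the control arm
# draws U(1, 6) regardless of letter.
KEY_RANGES_INTERVENTION <- matrix(
  c(1.0, 2, 1.1, 3, 1.2, 4, 1.3, 5, 1.4, 6),
  ncol = 2, byrow = TRUE,
  dimnames = list(c("A", "B", "C", "D", "E"), c("low", "high"))
)

PAGE_SIZE <- 28L

#' Specification of one trial arm
#'
#' Captures an arm's sort-key ranges, which label dimension (if any) is
#' shown to participants, which letter dimension drives the ordering,
#' and the price-match decoy rate (10% in every arm).
#'
#' @param arm one of "control", "health_position",
#'   "health_position_labels", "eco_position", "eco_position_labels".
#' @return an object of class `arm_spec`.
#' @export
arm_spec <- function(arm = ARMS) {
  arm <- match.arg(arm)
  position_dim <- switch(arm,
    control = "none",
    health_position = , health_position_labels = "health",
    eco_position = , eco_position_labels = "eco")
  labels_visible <- switch(arm,
    health_position_labels = "health",
    eco_position_labels = "eco",
    "none")
  key_ranges <- if (arm == "control") {
    matrix(rep(c(1, 6), each = 5), ncol = 2,
           dimnames = dimnames(KEY_RANGES_INTERVENTION))
  } else KEY_RANGES_INTERVENTION
  structure(list(arm = arm, position_dim = position_dim,
                 labels_visible = labels_visible, key_ranges = key_ranges,
                 price_match_rate = 0.10),
            class = "arm_spec")
}

#' Draw uniform sort keys for products given their letters
#'
#' Intervention arms draw uniformly inside the letter's range (A: 1--2,
#' B: 1.1--3, C: 1.2--4, D: 1.3--5, E: 1.4--6); the control arm draws
#' U(1, 6) for every product. Shelves are then ordered ascending on
#' these keys, so better-lettered products stochastically surface
#' earlier.
#'
#' @param letter character vector of A--E letters.
#' @param spec an [arm_spec()].
#' @return numeric keys, one per letter.
#' @export
draw_sort_key <- function(letter, spec) {
  if (!inherits(spec, "arm_spec")) abort("spec must be an arm_spec")
  r <- spec$key_ranges[letter, , drop = FALSE]
  runif(length(letter), r[, "low"], r[, "high"])
}

#' Order one shelf for one session
#'
#' Draws fresh sort keys, sorts ascending (ties broken by product id for
#' reproducibility) and paginates into pages of at most 28 products.
#'
#' @param products data frame with `product_id` and (unless control) a
#'   letter column for the arm's position dimension (`nutri_letter` /
#'   `display_nutri_letter` for health arms, `eco_letter` for eco arms).
#' @param spec an [arm_spec()].
#' @param letter_col name of the letter column used for key ranges;
#'   defaults per arm.
#' @return a `shelf_layout` data frame: rank, page, product_id, key.
#' @export
order_shelf <- function(products, spec,
                        letter_col = switch(spec$position_dim,
                          health = "display_nutri_letter",
                          eco = "eco_letter", "none")) {
  if (nrow(products) == 0) abort("shelf is empty")
  letters <- if (spec$position_dim == "none") rep("A", nrow(products))
             else products[[letter_col]]
  key <- if (spec$arm == "control") runif(nrow(products), 1, 6)
         else draw_sort_key(letters, spec)
  ord <- order(key, products$product_id)
  n <- length(ord)
  structure(data.frame(
    rank = seq_len(n),
    page = ((seq_len(n) - 1L) %/% PAGE_SIZE) + 1L,
    product_id = products$product_id[ord],
    key = key[ord],
    row = ord, # row index into `products`, used by the simulator
    stringsAsFactors = FALSE
  ), class = c("shelf_layout", "data.frame"))
}

#' Flag the price-match decoy subset
#'
#' A fixed random 10% (by default) of catalog products carry a
#' price-match label in every arm, masking the study's labelling
#' purpose. The subset is drawn once per study instance and reused
#' across arms.
#'
#' @param catalog a `shop_catalog`.
#' @param rate fraction flagged (rounded to the nearest count).
#' @return character vector of flagged product ids.
#' @export
flag_price_match <- function(catalog, rate = 0.10) {
  if (!is_prob(rate)) abort("rate must be in [0, 1]")
  k <- round(nrow(catalog) * rate)
  if (k == 0) return(character())
  sort(sample(catalog$product_id, k))
}
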