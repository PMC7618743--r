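#' Shopper behaviour parameters
#'
#' The synthetic stand-in for human choice. Within a shelf, a product's
#' choice utility is
#' `-rank / tau + beta_label * grade - beta_price * price` plus Gumbel
#' noise (i.e. a multinomial logit), where `grade` maps the visible
#' label letter A..E to +2..-2 and is only active in label arms. Small
#' `tau` concentrates choice on the first page, matching the
#' observation that online grocery choices are almost all made there;
#' `tau = Inf` with zero `beta`s gives the uniform null shopper.
#'
#' @param tau position tolerance (ranks); smaller = stronger first-page
#'   preference.
#' @param beta_label utility per label grade step when labels are shown.
#' @param beta_price utility per GBP.
#' @param p_skip probability of skipping each shopping-list category.
#' @param extra_item_rate expected number of unprompted extra items
#'   (Poisson).
#' @param p_incomplete probability of abandoning before checkout.
#' @param p_speeder probability of rushing (completion time scaled by
#'   0.2, tripping the speeder exclusion).
#' @return an object of class `shopper_behaviour`.
#' @export
shopper_behaviour <- function(tau = 10, beta_label = 0.25, beta_price = 0.01,
                              p_skip = 0.03, extra_item_rate = 0.3,
                              p_incomplete = 0.02, p_speeder = 0.01) {
  stopifnot(tau > 0, is_prob(p_skip), is_prob(p_incomplete), is_prob(p_speeder),
            extra_item_rate >= 0, is.finite(beta_label), is.finite(beta_price))
  structure(list(tau = tau, beta_label = beta_label, beta_price = beta_price,
                 p_skip = p_skip, extra_item_rate = extra_item_rate,
                 p_incomplete = p_incomplete, p_speeder = p_speeder),
            class = "shopper_behaviour")
}

#' @rdname shopper_behaviour
#' @export
null_shopper <- function(p_skip = 0.02, extra_item_rate = 0.1,
                         p_incomplete = 0.02, p_speeder = 0.01) {
  shopper_behaviour(tau = Inf, beta_label = 0, beta_price = 0,
                    p_skip = p_skip, extra_item_rate = extra_item_rate,
                    p_incomplete = p_incomplete, p_speeder = p_speeder)
}

#' Randomise participants to arms on a 1:5:5:5:5 basis
#'
#' Control receives probability 1/21, each intervention arm 5/21.
#'
#' @param n number of participants.
#' @return factor of arm assignments with levels in the canonical order.
#' @export
randomise_arm <- function(n) {
  factor(sample(ARMS, n, replace = TRUE, prob = c(1, 5, 5, 5, 5) / 21),
         levels = ARMS)
}

# Table-2-like marginal distributions for the synthetic population
DEMO_DIST <- list(
  gender = c(female = 0.514, male = 0.483, other = 0.003),
  age_group = c("18-24" = 0.105, "25-34" = 0.164, "35-44" = 0.164,
                "45-54" = 0.167, "55-64" = 0.165, "65+" = 0.235),
  education = c(none = 0.059, up_to_4_gcse = 0.163, gcse5_or_1alevel = 0.209,
                alevels2plus = 0.200, degree_plus = 0.369),
  income = c(below_15.5k = 0.142, "15.5k-25k" = 0.179, "25k-39k" = 0.244,
             "40k_plus" = 0.393, prefer_not_to_say = 0.042),
  # weekly frequency answer 0..5 for meat/dairy at each of three meals
  meat_answer = c(0.10, 0.12, 0.20, 0.25, 0.18, 0.15)
)

#' Draw a synthetic participant population
#'
#' Demographics follow the study sample's marginal distributions
#' (gender, age band, education, household income band) and three
#' meat/dairy frequency answers (breakfast, lunch, dinner) on the 0--5
#' points scale, aggregated by [meat_score()].
#'
#' @param n number of participants.
#' @return data frame with one row per participant.
#' @export
sample_participants <- function(n) {
  draw <- function(d) factor(sample(names(d), n, replace = TRUE, prob = d),
                             levels = names(d))
  meat <- function() sample(0:5, n, replace = TRUE, prob = DEMO_DIST$meat_answer)
  mb <- meat(); ml <- meat(); md <- meat()
  ms <- meat_score(mb, ml, md)
  data.frame(
    id = seq_len(n),
    gender = draw(DEMO_DIST$gender),
    age_group = draw(DEMO_DIST$age_group),
    education = draw(DEMO_DIST$education),
    income = draw(DEMO_DIST$income),
    meat_breakfast = mb, meat_lunch = ml, meat_dinner = md,
    meat_points = ms$points,
    meat_level = ms$level
  )
}

#' Aggregate meat/dairy consumption answers into a score and level
#'
#' Each of the three meal-frequency answers scores 0 ("Never") to 5
#' ("Every day"); the summed 0--15 score is banded low (0--5), medium
#' (6--10), high (11--15). `scheme = "table2"` applies the alternative
#' 0--4 points coding with bands 0--4 / 5--8 / 9--12.
#'
#' @param breakfast,lunch,dinner integer answers 0..5 (or 0..4 under
#'   "table2"); `NA` answers give an `NA` level.
#' @param scheme points scheme, "points5" (default) or "table2".
#' @return data frame with `points` and ordered factor `level`.
#' @export
#' @examples
#' meat_score(5, 5, 5)       # 15, high
#' meat_score(2, 3, 0)       # 5, low
meat_score <- function(breakfast, lunch, dinner, scheme = c("points5", "table2")) {
  scheme <- match.arg(scheme)
  mx <- if (scheme == "points5") 5 else 4
  for (a in list(breakfast, lunch, dinner))
    if (any(!is.na(a) & (a < 0 | a > mx | a != round(a))))
      abort("answers must be integers in 0..%d", mx)
  pts <- breakfast + lunch + dinner
  cuts <- if (scheme == "points5") c(5, 10) else c(4, 8)
  lvl <- ifelse(pts <= cuts[1], "low", ifelse(pts <= cuts[2], "medium", "high"))
  data.frame(points = pts,
             level = factor(lvl, levels = c("low", "medium", "high"),
                            ordered = TRUE))
}

GRADE_VALUE <- c(A = 2, B = 1, C = 0, D = -1, E = -2)

# Precompute per-shelf vectors the choice loop needs.
shelf_data <- function(catalog) {
  if (is.null(catalog$display_nutri_letter) || is.null(catalog$eco_letter))
    abort("catalog must be fully scored (score_catalog())")
  lapply(setNames(SHOPPING_LIST, SHOPPING_LIST), function(s) {
    rows <- which(catalog$shelf == s)
    if (!length(rows)) abort("shopping-list shelf '%s' missing from catalog", s)
    list(row = rows,
         id = catalog$product_id[rows],
         hl = catalog$display_nutri_letter[rows],
         el = catalog$eco_letter[rows],
         hg = unname(GRADE_VALUE[catalog$display_nutri_letter[rows]]),
         eg = unname(GRADE_VALUE[catalog$eco_letter[rows]]),
         price = catalog$price[rows])
  })
}

# One multinomial-logit pick from one shelf; returns c(local_row, rank).
.choose_from_shelf <- function(sd, spec, beh) {
  m <- length(sd$id)
  key <- if (spec$position_dim == "none") runif(m, 1, 6)
  else {
    letters <- if (spec$position_dim == "health") sd$hl else sd$el
    r <- spec$key_ranges[letters, , drop = FALSE]
    runif(m, r[, 1L], r[, 2L])
  }
  ord <- order(key)
  u <- -seq_len(m) / beh$tau - beh$beta_price * sd$price[ord]
  if (spec$labels_visible == "health") u <- u + beh$beta_label * sd$hg[ord]
  else if (spec$labels_visible == "eco") u <- u + beh$beta_label * sd$eg[ord]
  w <- exp(u - max(u))
  j <- sample.int(m, 1L, prob = w)
  c(ord[j], j)
}

#' Choose one product from a laid-out shelf
#'
#' A single draw from the shopper choice model given an explicit
#' [order_shelf()] layout: utility decays in rank, rises in the visible
#' label grade, falls in price; choice is multinomial logit.
#'
#' @param layout a `shelf_layout` from [order_shelf()].
#' @param products the shelf's products (same frame passed to
#'   [order_shelf()]), providing price and letter columns.
#' @param behaviour a [shopper_behaviour()].
#' @param labels_visible "none", "health" or "eco".
#' @return the chosen `product_id` with the selection rank as attribute
#'   `rank`.
#' @export
choose_item <- function(layout, products, behaviour,
                        labels_visible = c("none", "health", "eco")) {
  labels_visible <- match.arg(labels_visible)
  m <- nrow(layout)
  if (m == 0) abort("shelf is empty")
  prod <- products[layout$row, , drop = FALSE]
  u <- -layout$rank / behaviour$tau - behaviour$beta_price * prod$price
  if (labels_visible == "health")
    u <- u + behaviour$beta_label * GRADE_VALUE[prod$display_nutri_letter]
  else if (labels_visible == "eco")
    u <- u + behaviour$beta_label * GRADE_VALUE[prod$eco_letter]
  w <- exp(u - max(u))
  j <- sample.int(m, 1L, prob = w)
  structure(layout$product_id[j], rank = layout$rank[j])
}

# Core of one shopping session against precomputed shelf data.
.run_session_core <- function(spec, beh, sdat) {
  picks_shelf <- character(14L); picks_row <- integer(14L)
  picks_rank <- integer(14L); k <- 0L
  visit <- runif(10L) >= beh$p_skip
  for (ci in which(visit)) {
    sel <- .choose_from_shelf(sdat[[ci]], spec, beh)
    k <- k + 1L
    picks_shelf[k] <- SHOPPING_LIST[ci]
    picks_row[k] <- sdat[[ci]]$row[sel[1L]]
    picks_rank[k] <- sel[2L]
  }
  n_extra <- rpois(1L, beh$extra_item_rate) + max(0L, 10L - k)
  tries <- 0L
  while (n_extra > 0L && tries < 50L) {
    tries <- tries + 1L
    ci <- sample.int(10L, 1L)
    sel <- .choose_from_shelf(sdat[[ci]], spec, beh)
    row <- sdat[[ci]]$row[sel[1L]]
    if (row %in% picks_row[seq_len(k)]) next # items must be distinct
    k <- k + 1L
    if (k > length(picks_row)) {
      length(picks_shelf) <- length(picks_row) <- length(picks_rank) <- k + 8L
    }
    picks_shelf[k] <- SHOPPING_LIST[ci]
    picks_row[k] <- row
    picks_rank[k] <- sel[2L]
    n_extra <- n_extra - 1L
  }
  completed <- runif(1L) >= beh$p_incomplete
  if (!completed && k > 0L) k <- sample.int(k, 1L) # abandoned part-way
  time <- rlnorm(1L, log(240), 0.45) + k * runif(1L, 8, 25)
  if (runif(1L) < beh$p_speeder) time <- time * 0.2
  list(shelf = picks_shelf[seq_len(k)], row = picks_row[seq_len(k)],
       rank = picks_rank[seq_len(k)], completed = completed, time = time)
}

#' Run one shopping session
#'
#' Iterates the ten shopping-list categories (each independently
#' skipped with `p_skip`), draws one product per visited category from
#' the arm's biased layout, then adds unprompted extra items and, when
#' skipping has left fewer than the 10-item checkout minimum, fills up
#' with additional items from random list shelves.
#'
#' @param arm arm name (see [arm_spec()]).
#' @param catalog a fully scored `shop_catalog`.
#' @param behaviour a [shopper_behaviour()].
#' @return list with `basket` (data frame: product_id, shelf, rank),
#'   `completed`, and `completion_time` (seconds).
#' @export
run_session <- function(arm, catalog, behaviour = shopper_behaviour()) {
  spec <- arm_spec(arm)
  sdat <- shelf_data(catalog)
  s <- .run_session_core(spec, behaviour, sdat)
  list(basket = data.frame(product_id = catalog$product_id[s$row],
                           shelf = s$shelf, rank = s$rank,
                           page = ((s$rank - 1L) %/% PAGE_SIZE) + 1L,
                           stringsAsFactors = FALSE),
       completed = s$completed, completion_time = s$time)
}

#' Simulate the full randomised trial
#'
#' Draws a participant population, randomises 1:5:5:5:5, flags the
#' shared price-match decoy subset, and runs every shopping session
#' under the arm's positioning/labelling rules.
#'
#' @param n number of randomised participants.
#' @param catalog a fully scored `shop_catalog` ([score_catalog()]).
#' @param behaviour a [shopper_behaviour()] shared by all participants.
#' @param seed optional integer seed.
#' @return an object of class `shop_trial`: list with `participants`
#'   (demographics + arm), `sessions` (per-participant summary:
#'   n_items, n_categories, completed, completion_time,
#'   full_compliance), `items` (long session log: id, product_id,
#'   shelf, rank, page) and `price_match_ids`.
#' @export
simulate_trial <- function(n, catalog, behaviour = shopper_behaviour(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec_of <- lapply(setNames(ARMS, ARMS), arm_spec)
  sdat <- shelf_data(catalog)
  participants <- sample_participants(n)
  participants$arm <- randomise_arm(n)
  price_match_ids <- flag_price_match(catalog)

  res_shelf <- vector("list", n); res_row <- vector("list", n)
  res_rank <- vector("list", n)
  n_items <- integer(n); n_cat <- integer(n)
  completed <- logical(n); ctime <- numeric(n); full_comp <- logical(n)
  for (i in seq_len(n)) {
    s <- .run_session_core(spec_of[[as.character(participants$arm[i])]],
                           behaviour, sdat)
    res_shelf[[i]] <- s$shelf; res_row[[i]] <- s$row; res_rank[[i]] <- s$rank
    n_items[i] <- length(s$row)
    n_cat[i] <- length(unique(s$shelf))
    completed[i] <- s$completed; ctime[i] <- s$time
    full_comp[i] <- compliance_full(s$shelf)
  }
  items <- data.frame(
    id = rep.int(participants$id, n_items),
    product_id = catalog$product_id[unlist(res_row)],
    shelf = unlist(res_shelf),
    rank = unlist(res_rank),
    stringsAsFactors = FALSE
  )
  items$page <- ((items$rank - 1L) %/% PAGE_SIZE) + 1L
  sessions <- data.frame(
    id = participants$id, arm = participants$arm,
    n_items = n_items, n_categories = n_cat,
    completed = completed, completion_time = ctime,
    full_compliance = full_comp
  )
  structure(list(participants = participants, sessions = sessions,
                 items = items, price_match_ids = price_match_ids,
                 behaviour = behaviour),
            class = "shop_trial")
}

#' @export
print.shop_trial <- function(x, ...) {
  cat(sprintf("<shop_trial> %d participants, %d items selected\n",
              nrow(x$sessions), nrow(x$items)))
  print(table(arm = x$sessions$arm))
  invisible(x)
}

#' Was a basket fully compliant?
#'
#' Full compliance means exactly one product for each of the ten
#' shopping-list categories and no additional items.
#'
#' @param shelves character vector: the shelf of origin of each basket
#'   item.
#' @return logical scalar.
#' @export
compliance_full <- function(shelves) {
  length(shelves) == 10L && !anyDuplicated(shelves) &&
    all(SHOPPING_LIST %in% shelves)
}

#' Apply the pre-registered exclusion criteria
#'
#' Excludes, in order (first failing rule attributed): sessions not
#' completed; baskets of more than 20 products; "speeders" finishing in
#' under 30% of the median completion time of completed sessions; and
#' participants covering fewer than 7 of the 10 required categories.
#'
#' @param trial a `shop_trial` (or its `sessions` data frame).
#' @return list with `included` (participant ids), `counts` (named
#'   per-reason exclusion counts plus `included` and `total`), and the
#'   filtered `sessions` data frame.
#' @export
apply_exclusions <- function(trial) {
  ses <- if (inherits(trial, "shop_trial")) trial$sessions else trial
  med <- median(ses$completion_time[ses$completed])
  reason <- rep(NA_character_, nrow(ses))
  reason[is.na(reason) & !ses$completed] <- "incomplete"
  reason[is.na(reason) & ses$n_items > 20] <- "too_many_items"
  reason[is.na(reason) & ses$completion_time < 0.30 * med] <- "speeder"
  reason[is.na(reason) & ses$n_categories < 7] <- "low_category_coverage"
  keep <- is.na(reason)
  counts <- c(table(factor(reason, levels = c("incomplete", "too_many_items",
                                              "speeder", "low_category_coverage"))),
              included = sum(keep), total = nrow(ses))
  list(included = ses$id[keep], counts = counts,
       sessions = ses[keep, , drop = FALSE])
}
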