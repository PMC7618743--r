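test_that("randomisation follows the 1:5:5:5:5 allocation", {
  set.seed(10)
  a <- randomise_arm(21000)
  n_ctrl <- sum(a == "control")
  band <- qbinom(c(0.005, 0.995), 21000, 1 / 21)
  expect_gte(n_ctrl, band[1])
  expect_lte(n_ctrl, band[2])
  # joint GOF at larger n
  a2 <- randomise_arm(1e5)
  p <- chisq.test(table(a2), p = c(1, 5, 5, 5, 5) / 21)$p.value
  expect_gt(p, 0.001)
  set.seed(77); r1 <- randomise_arm(50)
  set.seed(77); r2 <- randomise_arm(50)
  expect_identical(r1, r2)
})

test_that("meat consumption scoring follows the 0-15 points bands", {
  expect_equal(meat_score(5, 5, 5)$points, 15)
  expect_equal(as.character(meat_score(5, 5, 5)$level), "high")
  expect_equal(as.character(meat_score(0, 0, 0)$level), "low")
  expect_equal(meat_score(2, 3, 0)$points, 5)
  expect_equal(as.character(meat_score(2, 3, 0)$level), "low")
  expect_equal(as.character(meat_score(2, 3, 1)$level), "medium")
  expect_equal(as.character(meat_score(4, 4, 3)$level), "high")
  expect_true(is.na(meat_score(NA, 3, 1)$level))
  # the alternative 0-4 coding with 0-4/5-8/9-12 bands
  expect_equal(as.character(meat_score(4, 4, 4, scheme = "table2")$level), "high")
  expect_equal(as.character(meat_score(2, 2, 0, scheme = "table2")$level), "low")
  expect_error(meat_score(6, 0, 0), "0..5")
  expect_error(meat_score(5, 0, 0, scheme = "table2"), "0..4")
})

test_that("full compliance means one item per category and nothing else", {
  expect_true(compliance_full(SHELVES10))
  expect_false(compliance_full(c(SHELVES10, "cheese")))         # extra item
  expect_false(compliance_full(c(SHELVES10[-1], "cheese")))     # duplicate
  expect_false(compliance_full(SHELVES10[-1]))                  # 9 items
})

test_that("a fully compliant shopper buys exactly one item per category", {
  sc <- small_scored_catalog()
  beh <- shopper_behaviour(p_skip = 0, extra_item_rate = 0,
                           p_incomplete = 0, p_speeder = 0)
  set.seed(3)
  s <- run_session("control", sc, beh)
  expect_equal(nrow(s$basket), 10)
  expect_setequal(s$basket$shelf, SHELVES10)
  expect_true(s$completed)
  expect_gt(s$completion_time, 0)
  set.seed(9); s1 <- run_session("health_position", sc, beh)
  set.seed(9); s2 <- run_session("health_position", sc, beh)
  expect_identical(s1, s2)
})

test_that("skipping reduces category coverage as a binomial", {
  sc <- small_scored_catalog()
  beh <- shopper_behaviour(p_skip = 0.5, extra_item_rate = 0,
                           p_incomplete = 0, p_speeder = 0)
  set.seed(4)
  cov <- replicate(300, length(unique(run_session("control", sc, beh)$basket$shelf)))
  # mean coverage ~ 5 from list visits; fill-to-10 adds items to covered
  # shelves at random, raising coverage above the plain binomial mean
  expect_gt(mean(cov), 4)
  expect_lt(mean(cov), 9)
})

test_that("null shopper chooses uniformly; position and label sensitivity bite", {
  sc <- small_scored_catalog()
  shelf <- sc[sc$shelf == "yogurt", ]
  spec <- arm_spec("health_position_labels")
  set.seed(12)
  # uniform under the null shopper
  nul <- null_shopper()
  lay <- order_shelf(shelf, spec)
  picks <- replicate(3000, choose_item(lay, shelf, nul, "none"))
  p <- chisq.test(table(factor(picks, levels = shelf$product_id)))$p.value
  expect_gt(p, 0.001)
  # small tau concentrates choice on page 1
  beh <- shopper_behaviour(tau = 5, beta_label = 0, beta_price = 0)
  picks2 <- replicate(800, {
    l <- order_shelf(shelf, spec)
    it <- choose_item(l, shelf, beh, "none")
    attr(it, "rank") <= 28
  })
  expect_gt(mean(picks2), 28 / nrow(shelf) + 0.2)
  # label sensitivity improves the mean chosen grade under the same seeds
  gval <- c(A = 2, B = 1, C = 0, D = -1, E = -2)
  beh_l <- shopper_behaviour(tau = 1e6, beta_label = 1, beta_price = 0)
  grade_mean <- function(visible) {
    set.seed(555)
    mean(replicate(600, {
      l <- order_shelf(shelf, spec)
      it <- choose_item(l, shelf, beh_l, visible)
      gval[shelf$display_nutri_letter[match(it, shelf$product_id)]]
    }))
  }
  expect_gt(grade_mean("health"), grade_mean("none"))
})

test_that("exclusion rules attribute the first failing reason, counts are exhaustive", {
  ses <- planted_sessions()
  ex <- apply_exclusions(ses)
  expect_setequal(ex$included, c(1, 6, 7, 10))
  expect_equal(unname(ex$counts["incomplete"]), 1)
  expect_equal(unname(ex$counts["too_many_items"]), 2)
  expect_equal(unname(ex$counts["speeder"]), 1)
  expect_equal(unname(ex$counts["low_category_coverage"]), 2)
  expect_equal(unname(ex$counts["included"]), 4)
  # included + sum(excluded by reason) = total
  expect_equal(sum(ex$counts[1:5]), unname(ex$counts["total"]))
  # a 21-item basket is excluded, a 7-category basket retained
  expect_false(2 %in% ex$included)
  expect_true(6 %in% ex$included)
})

test_that("simulated trial is reproducible and internally consistent", {
  sc <- small_scored_catalog()
  tr <- simulate_trial(150, sc, seed = 21)
  tr2 <- simulate_trial(150, sc, seed = 21)
  expect_identical(tr$items, tr2$items)
  expect_identical(tr$sessions, tr2$sessions)
  expect_equal(nrow(tr$sessions), 150)
  expect_equal(sum(tr$sessions$n_items), nrow(tr$items))
  expect_true(all(tr$items$product_id %in% sc$product_id))
  # items per participant are distinct
  dup <- tapply(tr$items$product_id, tr$items$id, anyDuplicated)
  expect_true(all(dup == 0))
  expect_length(tr$price_match_ids, round(nrow(sc) * 0.10))
})

test_that("under the null shopper the arms' outcomes are exchangeable", {
  sc <- small_scored_catalog()
  set.seed(61)
  rej <- replicate(15, {
    tr <- simulate_trial(420, sc, behaviour = null_shopper())
    oc <- basket_outcomes(tr, sc, ids = apply_exclusions(tr)$included)
    x <- oc$mean_nutriscore[oc$arm == "health_position"]
    y <- oc$mean_nutriscore[oc$arm == "eco_position"]
    suppressWarnings(ks.test(x, y)$p.value) < 0.05
  })
  expect_lte(sum(rej), 4) # ~5% nominal, 15 draws
})

test_that("position-sensitive shoppers move both outcome dimensions the right way", {
  sc <- small_scored_catalog()
  set.seed(90)
  signs <- replicate(8, {
    tr <- simulate_trial(700, sc)
    oc <- basket_outcomes(tr, sc, ids = apply_exclusions(tr)$included)
    m <- tapply(oc$mean_nutriscore, oc$arm, mean)
    e <- tapply(oc$mean_eco, oc$arm, mean)
    c(health = unname(m["health_position"] < m["control"]),
      eco = unname(e["eco_position"] < e["control"]))
  })
  expect_gte(mean(signs["health", ]), 7 / 8)
  expect_gte(mean(signs["eco", ]), 7 / 8)
})
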