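make_outcomes <- function(n_per_arm, means, sd = 1, ycol = "mean_nutriscore",
                          arms = c("control", "health_position",
                                   "health_position_labels"),
                          generator = rnorm) {
  df <- do.call(rbind, lapply(seq_along(arms), function(i) {
    y <- generator(n_per_arm, means[i], sd)
    data.frame(id = seq_len(n_per_arm) + (i - 1) * n_per_arm,
               arm = arms[i], y = y, stringsAsFactors = FALSE)
  }))
  df$arm <- factor(df$arm, levels = shelfnudge:::ARMS)
  df[[ycol]] <- df$y
  df$full_compliance <- TRUE
  df
}

test_that("basket outcomes are per-item means and a price sum", {
  sc <- small_scored_catalog()
  one <- data.frame(id = 1L, product_id = sc$product_id[5])
  o1 <- basket_outcomes(one, sc)
  expect_equal(o1$mean_nutriscore, sc$nutri_scaled[5])
  expect_equal(o1$mean_eco, sc$eco_composite[5])
  expect_equal(o1$total_price, sc$price[5])
  two <- data.frame(id = c(1L, 1L), product_id = sc$product_id[c(5, 9)])
  o2 <- basket_outcomes(two, sc)
  expect_equal(o2$mean_nutriscore, mean(sc$nutri_scaled[c(5, 9)]))
  expect_equal(o2$mean_salt, mean(sc$salt_g[c(5, 9)]))
  expect_equal(o2$total_price, sum(sc$price[c(5, 9)]))
  # ten-item basket: every column is the hand-computed mean
  rows <- 11:20
  ten <- data.frame(id = 7L, product_id = sc$product_id[rows])
  o10 <- basket_outcomes(ten, sc)
  expect_equal(o10$mean_energy, mean(sc$energy_kcal[rows]))
  expect_equal(o10$mean_ghg, mean(sc$ghg[rows]))
  expect_equal(o10$mean_eutrophication, mean(sc$eutrophication[rows]))
  expect_error(basket_outcomes(data.frame(id = 1, product_id = "nope"), sc),
               "missing from catalog")
})

test_that("IQR rule drops only values beyond the 1.5 IQR fences", {
  expect_equal(iqr_outlier_filter(c(1:9, 100)), 1:9)
  expect_equal(iqr_outlier_filter(rep(5, 6)), rep(5, 6)) # constant kept
  x <- c(-50, -4:4, 50)
  expect_equal(iqr_outlier_filter(x), -4:4) # symmetric bounds
  expect_error(iqr_outlier_filter(1:3), "at least 4")
})

test_that("null data give null estimates; multiplicative plants are recovered exactly", {
  # identical outcome values in every arm: estimates exactly zero
  oc <- make_outcomes(30, c(10, 10, 10), sd = 0,
                      generator = function(n, m, s) rep(m, n))
  f <- suppressWarnings(fit_primary(oc, "health")) # perfect-fit warning expected

  expect_equal(f$estimate, rep(0, 3))
  # noisy null: no effect, p ~ U(0,1), estimate near 0
  set.seed(1)
  oc2 <- make_outcomes(400, c(35, 35, 35), sd = 3)
  f2 <- fit_primary(oc2, "health")
  expect_true(all(abs(f2$estimate) < 1))
  expect_true(all(f2$p > 0.001))
  # exact multiplicative plant: arm values are control times 0.76
  base <- exp(rnorm(50, 1.5, 0.4))
  oce <- rbind(
    data.frame(id = 1:50, arm = "control", mean_eco = base),
    data.frame(id = 51:100, arm = "eco_position", mean_eco = base * 0.76),
    data.frame(id = 101:150, arm = "eco_position_labels", mean_eco = base * 0.70)
  )
  oce$arm <- factor(oce$arm, levels = shelfnudge:::ARMS)
  oce$full_compliance <- TRUE
  fe <- fit_primary(oce, "eco")
  expect_equal(fe$estimate[1], 0.76, tolerance = 1e-10)
  expect_equal(fe$estimate[2], 0.70, tolerance = 1e-10)
  expect_equal(fe$transform, rep("exp", 3))
  expect_equal(fe$threshold, rep(0.025, 3))
  # non-positive eco outcome names the offending basket
  oce$mean_eco[3] <- 0
  expect_error(fit_primary(oce, "eco"), "participant")
})

test_that("sensitivity samples subset as documented", {
  set.seed(2)
  # bounded noise so the only IQR outlier is the planted one
  oc <- make_outcomes(200, c(35, 33, 33), sd = 3,
                      generator = function(n, m, s) m + runif(n, -s, s))
  oc$full_compliance <- rep(c(TRUE, FALSE), length.out = nrow(oc))
  f_all <- fit_primary(oc, "health")
  f_fc <- fit_primary(oc, "health", sample = "full_compliance")
  expect_equal(f_fc$n[1], sum(oc$full_compliance))
  expect_lt(f_fc$n[1], f_all$n[1])
  oc$mean_nutriscore[1] <- 1e5 # gross outlier
  f_out <- fit_primary(oc, "health", sample = "outlier_filtered")
  expect_equal(f_out$n[1], nrow(oc) - 1)
})

test_that("secondary models log-transform environmental outcomes and flag 0.005", {
  set.seed(3)
  arms_eco <- c("control", "eco_position", "eco_position_labels")
  oc <- make_outcomes(100, c(0, 0, 0), sd = 0.3, ycol = "mean_ghg",
                      arms = arms_eco, generator = function(n, m, s)
                        exp(rnorm(n, m, s)))
  oc$mean_ghg[oc$arm == "eco_position"] <-
    oc$mean_ghg[oc$arm == "control"] * 0.76 # exact multiplicative shift
  for (yc in c("mean_water", "mean_biodiversity", "mean_eutrophication"))
    oc[[yc]] <- exp(rnorm(nrow(oc), 0, 0.3))
  fs <- fit_secondary(oc, "eco")
  expect_equal(nrow(fs), 8) # 4 outcomes x 2 contrasts
  ghg_row <- fs[fs$outcome == "mean_ghg" & fs$comparison == "eco_position", ]
  expect_equal(ghg_row$estimate, 0.76, tolerance = 1e-10)
  expect_equal(unique(fs$threshold), 0.005)
  expect_equal(unique(fs$transform), "exp")
  # health dimension: identity transforms on nutrients
  oc2 <- make_outcomes(100, c(250, 245, 244), sd = 20, ycol = "mean_energy")
  for (yc in c("mean_salt", "mean_fat", "mean_sugar"))
    oc2[[yc]] <- rnorm(nrow(oc2), 5, 1)
  fh <- fit_secondary(oc2, "health")
  expect_equal(unique(fh$transform), "identity")
  expect_setequal(unique(fh$outcome),
                  c("mean_energy", "mean_salt", "mean_fat", "mean_sugar"))
})

test_that("spill-over models swap outcomes and carry no threshold", {
  set.seed(4)
  oc <- make_outcomes(150, c(0, 0, 0), sd = 0.3, ycol = "mean_eco",
                      generator = function(n, m, s) exp(rnorm(n, m, s)))
  oc$mean_nutriscore <- rnorm(nrow(oc), 35, 3)
  fsp <- fit_spillover(oc, "health")
  expect_equal(fsp$outcome, rep("mean_eco", 3))
  expect_equal(unique(fsp$transform), "exp")
  expect_true(all(is.na(fsp$threshold)))
  expect_true(all(is.na(fsp$significant)))
  # eco-neutral behaviour: spill-over estimates around exp(0) = 1
  expect_true(all(abs(fsp$estimate - 1) < 0.2))
})

test_that("interaction models use a joint F test and drop excluded categories", {
  set.seed(5)
  n <- 600
  oc <- make_outcomes(n, c(35, 33, 33), sd = 3)
  oc$gender <- factor(sample(c("female", "male", "other"), nrow(oc), TRUE,
                             prob = c(0.5, 0.49, 0.01)))
  oc$income <- factor(sample(c("below_15.5k", "40k_plus", "prefer_not_to_say"),
                             nrow(oc), TRUE, prob = c(0.45, 0.45, 0.1)))
  oc$education <- factor(sample(c("none", "up_to_4_gcse", "degree_plus"),
                                nrow(oc), TRUE))
  oc$age_group <- factor(sample(c("18-24", "65+"), nrow(oc), TRUE))
  oc$meat_level <- factor(sample(c("low", "medium", "high", NA), nrow(oc), TRUE))
  fi <- fit_interactions(oc, "gender", "health")
  expect_equal(nrow(fi), 1)
  expect_equal(fi$threshold, 0.005)
  expect_gt(fi$p, 0.005) # no planted modification
  # dropped categories reduce n
  expect_lt(fi$n, nrow(oc[as.character(oc$arm) %in%
                            shelfnudge:::DIM_ARMS$health, ]))
  fi2 <- fit_interactions(oc, "income", "health")
  expect_lt(fi2$n, fi$n + sum(oc$income == "prefer_not_to_say"))
  # planted subgroup-specific effect is detected
  oc2 <- make_outcomes(n, c(35, 35, 35), sd = 2)
  oc2$gender <- factor(rep(c("female", "male"), length.out = nrow(oc2)))
  mod <- oc2$gender == "male" & as.character(oc2$arm) != "control"
  oc2$mean_nutriscore[mod] <- oc2$mean_nutriscore[mod] - 3
  fp <- fit_interactions(oc2, "gender", "health")
  expect_lt(fp$p, 0.005)
  # single-level covariate errors
  oc$gender <- factor("female", levels = c("female", "male"))
  expect_error(fit_interactions(oc, "gender", "health"), "single level")
})

test_that("price comparisons branch on Levene and report pairwise contrasts", {
  set.seed(6)
  # equal variances: classic ANOVA + Tukey
  oc <- make_outcomes(200, c(24, 23, 23), sd = 4, ycol = "total_price")
  pt <- price_test(oc, "health")
  expect_equal(attr(pt, "anova_method"), "anova+tukey_hsd")
  expect_equal(nrow(pt), 3)
  expect_equal(unique(pt$threshold), 0.025)
  # planted heteroscedasticity: Welch + Games-Howell
  oc2 <- make_outcomes(200, c(24, 23, 23), sd = 4, ycol = "total_price")
  big <- as.character(oc2$arm) == "control"
  oc2$total_price[big] <- rnorm(sum(big), 24, 16)
  pt2 <- price_test(oc2, "health")
  expect_equal(attr(pt2, "anova_method"), "welch_anova+games_howell")
  expect_lt(attr(pt2, "levene_p"), 0.05)
  # identical groups: post-hoc p-values near 1
  y <- rnorm(120, 20, 2)
  oc3 <- rbind(
    data.frame(id = 1:120, arm = "control", total_price = y),
    data.frame(id = 121:240, arm = "health_position", total_price = y),
    data.frame(id = 241:360, arm = "health_position_labels", total_price = y)
  )
  oc3$arm <- factor(oc3$arm, levels = shelfnudge:::ARMS)
  oc3$full_compliance <- TRUE
  pt3 <- price_test(oc3, "health")
  expect_true(all(pt3$p > 0.99))
  expect_true(all(abs(pt3$estimate) < 1e-10))
})

test_that("decimal-error sensitivity reproduces the primary fit when nothing is corrupted", {
  sc <- small_scored_catalog()
  sc$comma_corrupted <- FALSE
  sc$display_nutri_letter <- sc$nutri_letter
  tr <- simulate_trial(400, sc, seed = 33)
  ids <- apply_exclusions(tr)$included
  oc <- basket_outcomes(tr, sc, ids = ids)
  ref <- fit_primary(oc, "health")
  ds <- decimal_error_sensitivity(tr, sc, ids = ids)
  expect_equal(ds$fit_excluding_products$estimate, ref$estimate)
  expect_equal(ds$fit_excluding_purchasers$p, ref$p)
  expect_equal(ds$audit$n_corrupted, 0)
  expect_equal(ds$audit$n_purchasers_dropped, 0)
})

test_that("decimal-error sensitivity drops planted products and purchasers", {
  sc <- small_scored_catalog(seed = 8)
  tr <- simulate_trial(500, sc, seed = 44)
  ids <- apply_exclusions(tr)$included
  ds <- decimal_error_sensitivity(tr, sc, ids = ids)
  items <- tr$items[tr$items$id %in% ids, ]
  corrupted <- sc$product_id[sc$comma_corrupted]
  expect_equal(ds$audit$n_affected_selected,
               length(intersect(corrupted, items$product_id)))
  arm_of <- tr$participants$arm[match(items$id, tr$participants$id)]
  expect_equal(ds$audit$n_purchasers_dropped,
               length(unique(items$id[items$product_id %in% corrupted &
                                        arm_of == "health_position_labels"])))
  expect_true(ds$audit$letter_change_fraction >= 0 &&
                ds$audit$letter_change_fraction <= 1)
})
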