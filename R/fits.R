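# Arm subsets analysed per dimension
DIM_ARMS <- list(
  health = c("control", "health_position", "health_position_labels"),
  eco = c("control", "eco_position", "eco_position_labels")
)

new_trial_fit <- function(rows, dimension, analysis) {
  structure(rows, class = c("trial_fit", "data.frame"),
            dimension = dimension, analysis = analysis)
}

# One OLS model: outcome ~ arm with `ref` as reference level; returns one
# ModelResult row per comparison arm. Log-scale fits are exponentiated.
.lm_contrasts <- function(data, ycol, ref, comps, log_transform, threshold,
                          outcome_name = ycol) {
  d <- data[as.character(data$arm) %in% c(ref, comps), , drop = FALSE]
  y <- d[[ycol]]
  if (log_transform && any(y <= 0)) {
    bad <- d$id[y <= 0]
    abort("non-positive %s in basket(s) of participant(s) %s: cannot log",
          ycol, paste(head(bad, 5), collapse = ", "))
  }
  if (log_transform) y <- log(y)
  arm <- factor(as.character(d$arm), levels = c(ref, comps))
  m <- lm(y ~ arm)
  cf <- summary(m)$coefficients
  ci <- suppressMessages(stats::confint(m))
  rows <- lapply(comps, function(cmp) {
    k <- paste0("arm", cmp)
    est <- cf[k, "Estimate"]; lo <- ci[k, 1]; hi <- ci[k, 2]
    if (log_transform) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
    data.frame(outcome = outcome_name, reference = ref, comparison = cmp,
               estimate = unname(est), ci_low = unname(lo),
               ci_high = unname(hi), p = unname(cf[k, "Pr(>|t|)"]),
               transform = if (log_transform) "exp" else "identity",
               threshold = threshold,
               significant = if (is.na(threshold)) NA
                             else cf[k, "Pr(>|t|)"] < threshold,
               n = length(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Primary regression models
#'
#' Basket mean scaled Nutri-Score (health dimension, untransformed) or
#' basket mean eco score (eco dimension, natural-log transformed with
#' exponentiated estimates and CIs) compared by OLS: the two
#' intervention arms against control, plus a separate model comparing
#' position & labels against position (reference). Pre-registered
#' significance threshold 0.025.
#'
#' @param outcomes a [basket_outcomes()] frame with an `arm` column.
#' @param dimension "health" or "eco".
#' @param sample "primary" (all included participants),
#'   "full_compliance", or "outlier_filtered" (IQR rule applied to the
#'   outcome within the analysed arms).
#' @return a `trial_fit` data frame, one row per contrast.
#' @export
fit_primary <- function(outcomes, dimension = c("health", "eco"),
                        sample = c("primary", "full_compliance",
                                   "outlier_filtered")) {
  dimension <- match.arg(dimension)
  sample <- match.arg(sample)
  arms <- DIM_ARMS[[dimension]]
  ycol <- if (dimension == "health") "mean_nutriscore" else "mean_eco"
  logt <- dimension == "eco"
  d <- outcomes[as.character(outcomes$arm) %in% arms, , drop = FALSE]
  if (sample == "full_compliance") d <- d[d$full_compliance, , drop = FALSE]
  if (sample == "outlier_filtered") d <- d[iqr_keep(d[[ycol]]), , drop = FALSE]
  rows <- rbind(
    .lm_contrasts(d, ycol, arms[1], arms[2:3], logt, 0.025),
    .lm_contrasts(d, ycol, arms[2], arms[3], logt, 0.025)
  )
  new_trial_fit(rows, dimension, paste0("primary:", sample))
}

#' Secondary nutrient / environmental-indicator models
#'
#' Health dimension: basket mean energy density, salt, fat and sugar,
#' untransformed. Eco dimension: basket mean greenhouse gas emissions,
#' water use, biodiversity loss and eutrophication, log-transformed and
#' exponentiated. One OLS model per outcome, intervention arms vs
#' control, Bonferroni-style fixed threshold 0.005.
#'
#' @inheritParams fit_primary
#' @return a `trial_fit`, two contrast rows per outcome.
#' @export
fit_secondary <- function(outcomes, dimension = c("health", "eco")) {
  dimension <- match.arg(dimension)
  arms <- DIM_ARMS[[dimension]]
  d <- outcomes[as.character(outcomes$arm) %in% arms, , drop = FALSE]
  spec <- if (dimension == "health") {
    list(cols = c("mean_energy", "mean_salt", "mean_fat", "mean_sugar"),
         logt = FALSE)
  } else {
    list(cols = c("mean_ghg", "mean_water", "mean_biodiversity",
                  "mean_eutrophication"),
         logt = TRUE)
  }
  rows <- do.call(rbind, lapply(spec$cols, function(yc)
    .lm_contrasts(d, yc, arms[1], arms[2:3], spec$logt, 0.005)))
  new_trial_fit(rows, dimension, "secondary")
}

#' Spill-over (cross-dimension) models
#'
#' The primary contrasts re-run with the outcome swapped across
#' dimensions: health arms on the (logged, exponentiated) eco score,
#' eco arms on the untransformed Nutri-Score. Exploratory: p-values are
#' reported but no significance threshold applies.
#'
#' @inheritParams fit_primary
#' @return a `trial_fit` flagged exploratory.
#' @export
fit_spillover <- function(outcomes, dimension = c("health", "eco")) {
  dimension <- match.arg(dimension)
  arms <- DIM_ARMS[[dimension]]
  ycol <- if (dimension == "health") "mean_eco" else "mean_nutriscore"
  logt <- dimension == "health"
  d <- outcomes[as.character(outcomes$arm) %in% arms, , drop = FALSE]
  rows <- rbind(
    .lm_contrasts(d, ycol, arms[1], arms[2:3], logt, NA_real_),
    .lm_contrasts(d, ycol, arms[2], arms[3], logt, NA_real_)
  )
  new_trial_fit(rows, dimension, "spillover:exploratory")
}

# covariate preparation per the analysis plan: small categories merged
# or dropped before interaction models
.prep_covariate <- function(outcomes, covariate) {
  d <- outcomes
  v <- switch(covariate,
    gender = {
      d <- d[as.character(d$gender) != "other", , drop = FALSE]
      droplevels(factor(as.character(d$gender)))
    },
    age = factor(as.character(d$age_group)),
    education = {
      e <- as.character(d$education)
      e[e == "none"] <- "up_to_4_gcse" # merged with the lowest band
      factor(e)
    },
    income = {
      d <- d[as.character(d$income) != "prefer_not_to_say", , drop = FALSE]
      droplevels(factor(as.character(d$income)))
    },
    meat_level = {
      d <- d[!is.na(d$meat_level), , drop = FALSE]
      factor(as.character(d$meat_level))
    },
    abort("unknown covariate '%s'", covariate))
  d$covariate <- v
  d
}

#' Arm-by-covariate interaction models
#'
#' Tests whether the intervention effect is modified by a participant
#' characteristic: OLS with arm x covariate interaction terms, reported
#' as the joint F-test of the interaction block at threshold 0.005.
#' Participants with "other" gender identity, income "prefer not to
#' say", or a missing meat-consumption level are dropped; education
#' "none" is merged with the lowest qualification band.
#'
#' @inheritParams fit_primary
#' @param covariate one of "gender", "age", "education", "income",
#'   "meat_level".
#' @return a `trial_fit` with one interaction row (F statistic as the
#'   estimate).
#' @export
fit_interactions <- function(outcomes, covariate = c("gender", "age",
                                                     "education", "income",
                                                     "meat_level"),
                             dimension = c("health", "eco")) {
  covariate <- match.arg(covariate)
  dimension <- match.arg(dimension)
  arms <- DIM_ARMS[[dimension]]
  ycol <- if (dimension == "health") "mean_nutriscore" else "mean_eco"
  d <- outcomes[as.character(outcomes$arm) %in% arms, , drop = FALSE]
  d <- .prep_covariate(d, covariate)
  if (nlevels(d$covariate) < 2) abort("covariate has a single level")
  y <- d[[ycol]]
  if (dimension == "eco") y <- log(y)
  arm <- factor(as.character(d$arm), levels = arms)
  m0 <- lm(y ~ arm + d$covariate)
  m1 <- lm(y ~ arm * d$covariate)
  a <- anova(m0, m1)
  rows <- data.frame(
    outcome = ycol, reference = "main-effects model",
    comparison = sprintf("arm x %s", covariate),
    estimate = a$F[2], ci_low = NA_real_, ci_high = NA_real_,
    p = a$`Pr(>F)`[2], transform = "identity", threshold = 0.005,
    significant = a$`Pr(>F)`[2] < 0.005, n = length(y),
    stringsAsFactors = FALSE
  )
  new_trial_fit(rows, dimension, sprintf("interaction:%s", covariate))
}

# Games-Howell pairwise comparisons after a Welch ANOVA
games_howell <- function(y, g, conf.level = 0.95) {
  g <- droplevels(factor(g))
  lv <- levels(g); k <- length(lv)
  mi <- tapply(y, g, mean); vi <- tapply(y, g, var); ni <- tapply(y, g, length)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se2i <- vi[i] / ni[i]; se2j <- vi[j] / ni[j]
    se <- sqrt(se2i + se2j)
    df <- (se2i + se2j)^2 /
      (se2i^2 / (ni[i] - 1) + se2j^2 / (ni[j] - 1))
    diff <- mi[j] - mi[i]
    p <- ptukey(abs(diff / se) * sqrt(2), k, df, lower.tail = FALSE)
    hw <- qtukey(conf.level, k, df) / sqrt(2) * se
    out <- rbind(out, data.frame(
      reference = lv[i], comparison = lv[j], estimate = unname(diff),
      ci_low = unname(diff - hw), ci_high = unname(diff + hw),
      p = unname(p), stringsAsFactors = FALSE))
  }
  out
}

#' Basket price comparison (Levene-gated ANOVA with post-hoc tests)
#'
#' Tests whether the interventions changed the total basket price.
#' Levene's test (median-centred) on the three analysed arms decides
#' the branch: significant at 0.05 gives a Welch ANOVA with
#' Games-Howell post-hoc comparisons, otherwise a classic ANOVA with
#' Tukey HSD. Pairwise contrasts are judged at threshold 0.025.
#'
#' @inheritParams fit_primary
#' @return a `trial_fit` of pairwise price contrasts, with attributes
#'   `levene_p`, `anova_method` and `anova_p`.
#' @export
price_test <- function(outcomes, dimension = c("health", "eco")) {
  dimension <- match.arg(dimension)
  arms <- DIM_ARMS[[dimension]]
  d <- outcomes[as.character(outcomes$arm) %in% arms, , drop = FALSE]
  arm <- factor(as.character(d$arm), levels = arms)
  if (nlevels(droplevels(arm)) < 2) abort("need at least 2 groups")
  y <- d$total_price
  lev <- car::leveneTest(y ~ arm)
  lev_p <- lev[["Pr(>F)"]][1]
  if (lev_p < 0.05) {
    ow <- oneway.test(y ~ arm, var.equal = FALSE)
    method <- "welch_anova+games_howell"
    anova_p <- ow$p.value
    rows <- games_howell(y, arm)
  } else {
    m <- aov(y ~ arm)
    method <- "anova+tukey_hsd"
    anova_p <- summary(m)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(m)$arm
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    rows <- data.frame(
      reference = vapply(cmp, `[`, "", 2), comparison = vapply(cmp, `[`, "", 1),
      estimate = tk[, "diff"], ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
      p = tk[, "p adj"], stringsAsFactors = FALSE, row.names = NULL)
  }
  rows <- data.frame(outcome = "total_price", rows,
                     transform = "identity", threshold = 0.025,
                     significant = rows$p < 0.025, n = length(y),
                     stringsAsFactors = FALSE)
  ft <- new_trial_fit(rows, dimension, sprintf("price:%s", method))
  attr(ft, "levene_p") <- lev_p
  attr(ft, "anova_method") <- method
  attr(ft, "anova_p") <- anova_p
  ft
}

#' @export
print.trial_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<trial_fit> %s dimension, analysis: %s\n",
              attr(x, "dimension"), attr(x, "analysis")))
  if (!is.null(attr(x, "levene_p")))
    cat(sprintf("  Levene p = %.3f -> %s (overall p = %.4g)\n",
                attr(x, "levene_p"), attr(x, "anova_method"),
                attr(x, "anova_p")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.trial_fit <- function(object, ...) {
  cat(sprintf("%d contrasts; %d significant at their threshold\n",
              nrow(object), sum(object$significant, na.rm = TRUE)))
  invisible(print(object, ...))
}
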