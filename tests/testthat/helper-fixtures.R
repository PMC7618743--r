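# shared fixtures, built in code at test time

SHELVES10 <- shelfnudge:::SHOPPING_LIST

# a small scored catalog: 10 target shelves + a filler block, all quirks on
small_scored_catalog <- function(seed = 3, shelf_size = 40, fillers = 20) {
  cfg <- catalog_config(
    target_shelf_sizes = setNames(rep(shelf_size, 10), SHELVES10),
    n_filler_shelves = fillers, filler_shelf_size = 60, seed = seed
  )
  score_catalog(alcohol_and_missing_filter(generate_catalog(cfg)))
}

# independent per-component FSAm-NPS lookup oracle (general foods),
# written as explicit threshold chains, no shared code with the package
oracle_nps_general <- function(energy_kcal, sugar, satfat, sodium,
                               fv = 0, fibre = 0, protein = 0) {
  pts_steps <- function(x, steps) sum(x > steps)
  kj <- energy_kcal * 4.184
  e <- pts_steps(kj, c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350))
  s <- pts_steps(sugar, c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45))
  sf <- pts_steps(satfat, 1:10)
  so <- pts_steps(sodium, seq(90, 900, by = 90))
  fvp <- if (fv > 80) 5 else if (fv > 60) 2 else if (fv > 40) 1 else 0
  fb <- pts_steps(fibre, c(0.9, 1.9, 2.8, 3.7, 4.7))
  pr <- pts_steps(protein, c(1.6, 3.2, 4.8, 6.4, 8))
  neg <- e + s + sf + so
  pos <- fvp + fb + if (neg < 11 || fvp == 5) pr else 0
  neg - pos
}

# exact P(X < Y) for X~U(a,b), Y~U(c,d), by numeric integration
uniform_less_prob <- function(a, b, c, d) {
  stats::integrate(function(y) punif(y, a, b) * dunif(y, c, d), c, d,
                   rel.tol = 1e-10)$value
}

# hand-rolled reference nutrient parser used by the fuzz test: follows the
# published recode rules directly on one string at a time
reference_parse <- function(x, kind) {
  x <- trimws(x)
  x <- gsub("(\\d),(\\d)", "\\1.\\2", x)
  thr <- kind %in% c("fat", "satfat", "sugar", "salt")
  if (thr && tolower(x) %in% c("trace", "nil", "negligible")) return(0)
  if (thr && substr(x, 1, 1) == "<") x <- substr(x, 2, nchar(x))
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v < 0) return(NA_real_)
  if (kind %in% c("fat", "satfat", "sugar") && v < 0.5) return(0)
  if (kind == "salt" && v < 0.01) return(0)
  v
}

# sessions data frame with hand-planted exclusion violations
planted_sessions <- function() {
  data.frame(
    id = 1:10,
    arm = factor(rep("control", 10), levels = shelfnudge:::ARMS),
    n_items = c(10, 21, 10, 10, 10, 12, 10, 25, 10, 10),
    n_categories = c(10, 10, 10, 6, 10, 7, 10, 10, 5, 10),
    completed = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    completion_time = c(400, 420, 380, 410, 50, 430, 390, 405, 415, 395),
    full_compliance = rep(FALSE, 10)
  )
}
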