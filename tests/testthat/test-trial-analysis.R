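test_that("production classification covers correct, competitor and other", {
  # profesor-like item: target syllable 3, competitor 2
  expect_equal(classify_production(3, 3, 2), "correct_L2")
  expect_equal(classify_production(2, 3, 2), "incorrect_L1")
  expect_equal(classify_production(1, 3, 2), "other")
  # matching item: the target is also the competitor
  expect_equal(classify_production(2, 2, 2), "correct_L2")
  expect_equal(classify_production(1, 2, 2), "other")
})

test_that("asynchrony sign convention: negative = hand leads speech", {
  expect_equal(compute_asynchrony(1.00, 1.00), 0)
  expect_equal(compute_asynchrony(0.95, 1.00), -50)
  expect_equal(compute_asynchrony(1.05, 1.00), 50)
  # antisymmetry
  set.seed(50)
  a <- runif(20); b <- runif(20)
  expect_equal(compute_asynchrony(a, b), -compute_asynchrony(b, a))
})

test_that("condition labels depend only on matching, distance sign and class", {
  expect_equal(label_condition(FALSE, 3, 2, "correct_L2"), "precede_correct")
  expect_equal(label_condition(FALSE, 1, 2, "correct_L2"), "follow_correct")
  expect_equal(label_condition(FALSE, 3, 2, "incorrect_L1"), "follow_incorrect")
  expect_equal(label_condition(FALSE, 1, 2, "incorrect_L1"), "precede_incorrect")
  expect_equal(label_condition(TRUE, 2, 2, "correct_L2"), "matching_correct")

  # exhaustive over the label-determining triple
  for (m in c(TRUE, FALSE)) for (cls in c("correct_L2", "incorrect_L1", "other")) {
    for (sgn in if (m) 0 else c(-1, 1)) {
      tg <- 2; cp <- tg + sgn
      got <- label_condition(m, tg, cp, cls)
      want <-
        if (cls == "other") "excluded"
        else if (m) { if (cls == "correct_L2") "matching_correct" else "excluded" }
        else if (cls == "correct_L2") { if (cp < tg) "precede_correct" else "follow_correct" }
        else { if (tg < cp) "precede_incorrect" else "follow_incorrect" }
      expect_equal(got, want, info = paste(m, cls, sgn))
    }
  }
})

make_timing_records <- function(n_sp, n_it, means, noise_sd = 0, seed = 60) {
  set.seed(seed)
  conds <- names(means)
  grid <- expand.grid(speaker_id = sprintf("S%02d", seq_len(n_sp)),
                      item_id = sprintf("I%02d", seq_len(n_it)),
                      condition = conds, stringsAsFactors = FALSE)
  tibble::tibble(
    speaker_id = grid$speaker_id, item_id = grid$item_id,
    movement = TRUE, condition = grid$condition,
    asynchrony_ms = means[grid$condition] + rnorm(nrow(grid), 0, noise_sd),
    distance = dplyr::case_when(grid$condition == "precede_correct" ~ -1,
                                grid$condition == "follow_correct" ~ 1,
                                TRUE ~ 0)
  )
}

test_that("condition model recovers per-condition means in the degenerate limit", {
  means <- c(matching_correct = -48, precede_correct = -88, follow_correct = 45)
  d <- make_timing_records(4, 6, means, noise_sd = 0)
  fit <- fit_condition_model(d)
  est <- tidy_fit(fit)
  expect_equal(est$estimate[match(names(means), est$term)], unname(means),
               tolerance = 1e-6)
})

test_that("balanced data with no grouping structure reduces to raw means", {
  means <- c(matching_correct = -40, precede_correct = -90)
  d <- make_timing_records(6, 6, means, noise_sd = 30, seed = 61)
  fit <- fit_condition_model(d)
  est <- tidy_fit(fit)
  raw <- tapply(d$asynchrony_ms, d$condition, mean)
  expect_equal(est$estimate[match(names(raw), est$term)], as.numeric(raw),
               tolerance = 1e-6)
})

test_that("gradient model recovers a noiseless linear attraction exactly", {
  set.seed(62)
  grid <- expand.grid(speaker_id = sprintf("S%02d", 1:5),
                      item_id = sprintf("I%02d", 1:8),
                      stringsAsFactors = FALSE)
  grid$distance <- rep(c(-2, -1, 1, 2), length.out = nrow(grid))
  d <- tibble::tibble(
    speaker_id = grid$speaker_id, item_id = grid$item_id, movement = TRUE,
    condition = ifelse(grid$distance < 0, "precede_correct", "follow_correct"),
    distance = grid$distance,
    asynchrony_ms = -77 * grid$distance
  )
  fit <- fit_gradient_model(d)
  est <- tidy_fit(fit)
  expect_equal(est$estimate[est$term == "distance"], -77, tolerance = 1e-6)

  # slope-zero null: estimate near zero and non-significant
  d0 <- d
  set.seed(63)
  d0$asynchrony_ms <- rnorm(nrow(d0), 0, 20)
  est0 <- tidy_fit(fit_gradient_model(d0))
  expect_false(est0$significant[est0$term == "distance"])

  d$distance <- 1
  expect_error(fit_gradient_model(d), "constant")
})

test_that("movement boost test equals the injected intensity difference", {
  grid <- expand.grid(speaker_id = sprintf("S%02d", 1:5),
                      item_id = sprintf("I%02d", 1:8),
                      movement = c(TRUE, FALSE), stringsAsFactors = FALSE)
  d <- tibble::tibble(speaker_id = grid$speaker_id, item_id = grid$item_id,
                      movement = grid$movement,
                      peak_intensity = 0.2 + 0.05 * grid$movement)
  est <- tidy_fit(movement_boost_test(d))
  expect_equal(est$estimate[est$term == "movementTRUE"], 0.05, tolerance = 1e-6)

  d$peak_intensity <- 0.2
  est0 <- tidy_fit(movement_boost_test(d))
  expect_equal(est0$estimate[est0$term == "movementTRUE"], 0, tolerance = 1e-8)

  expect_error(movement_boost_test(d[d$movement, ]), "both movement")
})

test_that("accuracy-by-movement logistic model finds a real gap and not a null", {
  set.seed(64)
  grid <- expand.grid(speaker_id = sprintf("S%02d", 1:12),
                      item_id = sprintf("I%02d", 1:16),
                      movement = c(TRUE, FALSE), stringsAsFactors = FALSE)
  p <- ifelse(grid$movement, 0.9, 0.5)
  d <- tibble::tibble(speaker_id = grid$speaker_id, item_id = grid$item_id,
                      movement = grid$movement,
                      production_class = ifelse(runif(nrow(grid)) < p,
                                                "correct_L2", "other"))
  est <- tidy_fit(accuracy_by_movement_test(d))
  eff <- est[est$term == "movementTRUE", ]
  expect_true(eff$significant)
  expect_gt(eff$estimate, 0)
  # two-proportion oracle: log odds ratio of the realized proportions
  p1 <- mean(d$production_class[d$movement] == "correct_L2")
  p0 <- mean(d$production_class[!d$movement] == "correct_L2")
  lor <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  expect_equal(eff$estimate, lor, tolerance = 0.35)

  set.seed(65)
  d$production_class <- ifelse(runif(nrow(d)) < 0.6, "correct_L2", "other")
  est0 <- tidy_fit(accuracy_by_movement_test(d))
  expect_false(est0$significant[est0$term == "movementTRUE"])
})

test_that("verification agreement is the exact match fraction", {
  ann <- tibble::tibble(item_id = c("a", "b"), stress_syll = c(1, 2))
  rec <- tibble::tibble(item_id = c("a", "a", "b", "b"), nominated = c(1, 1, 2, 2))
  expect_equal(verification_agreement(rec, ann), 1.0)
  rec$nominated <- c(2, 2, 1, 1)
  expect_equal(verification_agreement(rec, ann), 0.0)
  rec$item_id[1] <- "zz"
  expect_error(verification_agreement(rec, ann), "missing stress annotation")
})

test_that("phonologically anchored asynchrony uses the target-syllable peak", {
  rec <- tibble::tibble(t_ext = c(1.0, 1.0), t_peak_env = c(0.9, 0.9),
                        t_peak_env_target = c(0.9, 1.1))
  anchored <- phonological_anchor_asynchrony(rec)
  # coincident anchors: identical to the standard asynchrony
  expect_equal(anchored[1], compute_asynchrony(rec$t_ext[1], rec$t_peak_env[1]))
  # divergent anchors: computed against the target interval's peak
  expect_equal(anchored[2], -100)
})

test_that("production classes partition every item subset", {
  set.seed(66)
  items <- default_item_table()
  idx <- sample(nrow(items), 200, replace = TRUE)
  nominated <- vapply(items$n_syll[idx], function(n) sample.int(n, 1), integer(1))
  cls <- classify_production(nominated, items$target_syll[idx],
                             items$competitor_syll[idx])
  expect_true(all(cls %in% c("correct_L2", "incorrect_L1", "other")))
  for (sub in list(items$matching[idx], !items$matching[idx], items$n_syll[idx] > 3)) {
    if (!any(sub)) next
    shares <- table(factor(cls[sub], c("correct_L2", "incorrect_L1", "other")))
    expect_equal(sum(shares) / sum(sub), 1)
  }
})
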