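test_that("energy-validity filter keeps the closed 600-4800 window", {
  intake <- data.frame(participant_id = c("A", "A", "A"), visit_id = 1:3,
                       energy_kcal = c(500, 2000, 5000))
  out <- filter_valid_visits(intake)
  expect_equal(nrow(out), 1L)
  expect_equal(out$energy_kcal, 2000)
  expect_equal(attr(out, "n_removed"), 2L)

  # boundaries are inclusive
  boundary <- data.frame(participant_id = "A", visit_id = 1:2,
                         energy_kcal = c(600, 4800))
  expect_equal(nrow(filter_valid_visits(boundary)), 2L)

  # all-valid table passes through unchanged
  ok <- data.frame(participant_id = c("A", "B"), visit_id = 1,
                   energy_kcal = c(1500, 2500))
  expect_equal(filter_valid_visits(ok)$energy_kcal, ok$energy_kcal)

  expect_error(filter_valid_visits(
    data.frame(participant_id = "A", visit_id = 1, energy_kcal = 100)),
    "no visits remain")
  expect_error(filter_valid_visits(
    data.frame(participant_id = "A", visit_id = 1, energy_kcal = -5)),
    "positive")
})

test_that("visit averaging is the arithmetic mean over valid visits only", {
  intake <- data.frame(participant_id = c("A", "A", "B"),
                       visit_id = c(1, 2, 1),
                       energy_kcal = c(1800, 2200, 2000),
                       veg_srv_d = c(1, 3, 5))
  avg <- average_visits(intake)
  expect_equal(avg$veg_srv_d, c(2, 5))
  expect_equal(avg$n_valid_visits, c(2L, 1L))

  # single visit passes through
  one <- average_visits(intake[3, ])
  expect_equal(one$veg_srv_d, 5)

  # mixed valid/invalid: mean over the valid subset only
  mixed <- data.frame(participant_id = "A", visit_id = 1:3,
                      energy_kcal = c(2000, 5000, 3000),
                      veg_srv_d = c(1, 100, 3))
  expect_equal(average_visits(filter_valid_visits(mixed))$veg_srv_d, 2)
})

test_that("MDS median rule scores a dominance pair 9 vs 1", {
  pair <- mds_dominance_pair()
  s <- score_mds(pair, sex = c("female", "female"))
  expect_equal(s$mds[s$participant_id == "A"], 9)
  expect_equal(s$mds[s$participant_id == "B"], 1)

  # dominated participant with zero alcohol reaches the minimum of 0
  pair0 <- mds_dominance_pair(alcohol_b = 0)
  s0 <- score_mds(pair0, sex = c("female", "female"))
  expect_equal(s0$mds[s0$participant_id == "B"], 0)

  # missing component column is a schema error naming the column
  expect_error(score_mds(pair[setdiff(names(pair), "veg_srv_d")],
                         sex = c("female", "female")), "veg_srv_d")
  expect_error(score_mds(pair[1, ], sex = "female"), "at least 2")
})

test_that("MDS beneficial indicators have within-sample mean >= 0.5", {
  set.seed(42)
  n <- 51
  intake <- data.frame(participant_id = sprintf("P%02d", 1:n),
                       veg_srv_d = rlnorm(n), legume_srv_d = rlnorm(n),
                       fruit_srv_d = rlnorm(n), wholegrain_srv_d = rlnorm(n),
                       fish_srv_wk = rlnorm(n), mufa_g_d = rlnorm(n, 3),
                       sfa_g_d = rlnorm(n, 3), meat_srv_d = rlnorm(n),
                       dairy_srv_d = rlnorm(n), alcohol_g_d = rlnorm(n, 2))
  s <- score_mds(intake, sex = rep("female", n))
  benef <- c("mds_vegetables", "mds_legumes", "mds_fruits_nuts",
             "mds_whole_grains", "mds_fish", "mds_mufa_sfa_ratio")
  expect_true(all(colMeans(s[benef]) >= 0.5))
})

test_that("MIND scoring hits its extremes and moves on the half-point grid", {
  rub <- load_rubric("MIND")
  full <- extreme_profile(rub, "full")
  expect_equal(score_mind(full)$mind, 15)

  zero <- full
  zero[, ] <- 0
  # zero consumption earns only the five detrimental full credits
  expect_equal(score_mind(zero)$mind, 5)

  # moving one group from mid to full credit adds exactly 0.5
  mid <- zero
  mid$green_leafy_srv_wk <- 3    # half credit band (2, 6)
  expect_equal(score_mind(mid)$mind, 5.5)
  mid$green_leafy_srv_wk <- 6    # full credit
  expect_equal(score_mind(mid)$mind, 6)

  # wine window: full credit only near one glass/day
  w <- zero
  w$wine_srv_wk <- 7
  expect_equal(score_mind(w)$mind, 6)
  w$wine_srv_wk <- 20
  expect_equal(score_mind(w)$mind, 5)

  # scores land on the half-integer grid
  expect_true(all(score_mind(full)$mind * 2 == round(score_mind(full)$mind * 2)))
})

test_that("AHEI proportional scoring interpolates between anchors", {
  rub <- load_rubric("AHEI")
  full <- extreme_profile(rub, "full", sex = "female")
  expect_equal(score_ahei(full, sex = "female")$ahei, 110)

  zero <- extreme_profile(rub, "zero", sex = "female")
  expect_equal(score_ahei(zero, sex = "female")$ahei, 0)

  # vegetables halfway between anchors contribute exactly 5 points
  mid <- zero
  mid$veg_srv_d <- 2.5
  expect_equal(score_ahei(mid, sex = "female")$ahei, 5)

  # sex-specific whole grain anchor: 75 g/d is full credit for women only
  g <- zero
  g$alcohol_drinks_d <- 10   # beyond the zero anchor for either sex
  g$wholegrain_g_d <- 75
  expect_equal(score_ahei(g, sex = "female")$ahei, 10)
  expect_equal(score_ahei(g, sex = "male")$ahei, 10 * 75 / 90)
})

test_that("rubric validation rejects malformed components", {
  rub <- load_rubric("AHEI")
  rub$components[[1]]$anchor_zero <- rub$components[[1]]$anchor_full
  expect_error(validate_rubric(unclass(rub)), "anchor")

  rub2 <- load_rubric("MIND")
  rub2$components[[1]]$half_cutoff <- 10   # above full cutoff (beneficial)
  expect_error(validate_rubric(unclass(rub2)), "monotone")

  expect_error(validate_rubric(list(instrument = "MDS",
                                    components = vector("list", 3))),
               "9 components")
})

test_that("raising beneficial intake never lowers scores; detrimental never raises them", {
  set.seed(7)
  co <- generate_cohort(synth_config(n_participants = 40, n_metabolites = 10,
                                     n_planted = 3, seed = 21))
  ds0 <- suppressWarnings(diet_scores(co$intake, co$phenotypes))
  up <- function(col, delta) {
    intake <- co$intake
    intake[[col]] <- intake[[col]] + delta
    suppressWarnings(diet_scores(intake, co$phenotypes))
  }
  for (col in c("veg_srv_d", "green_leafy_srv_wk", "fruit_srv_d")) {
    ds1 <- up(col, 2)
    expect_true(all(ds1$mds - ds0$mds >= 0))
    expect_true(all(ds1$mind - ds0$mind >= 0))
    expect_true(all(ds1$ahei - ds0$ahei >= 0))
  }
  for (col in c("meat_srv_d", "redmeat_srv_wk", "sodium_mg_d")) {
    ds1 <- up(col, if (col == "sodium_mg_d") 800 else 2)
    expect_true(all(ds1$mds - ds0$mds <= 0))
    expect_true(all(ds1$mind - ds0$mind <= 0))
    expect_true(all(ds1$ahei - ds0$ahei <= 0))
  }
})

test_that("cohort scoring returns complete scores in range for every retained participant", {
  co <- generate_cohort(synth_config(n_participants = 120, n_metabolites = 10,
                                     n_planted = 3, seed = 13))
  ds <- suppressWarnings(diet_scores(co$intake, co$phenotypes))
  expect_false(anyNA(ds$mds))
  expect_false(anyNA(ds$mind))
  expect_false(anyNA(ds$ahei))
  expect_true(all(ds$mds >= 0 & ds$mds <= 9 & ds$mds == round(ds$mds)))
  # per-visit MIND scores sit on the half-point grid; participant-level
  # values are means of those and stay inside the range
  mind_v <- attr(ds, "audit")$mind_per_visit$mind
  expect_true(all(2 * mind_v == round(2 * mind_v)))
  expect_true(all(ds$mind >= 0 & ds$mind <= 15))
  expect_true(all(ds$ahei >= 0 & ds$ahei <= 110))
  expect_true(all(ds$n_valid_visits >= 1))
})
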