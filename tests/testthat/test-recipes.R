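test_that("the lagged laying response covers days +2 to +4", {
  laying <- data.frame(
    female_id = "f1",
    date = as.character(as.Date("2014-10-01") + 0:9),
    egg_laid = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0))  # egg on day +3 of Oct 1
  ev <- data.frame(female_id = "f1", date = "2014-10-01")
  expect_equal(build_lagged_laying_response(laying, ev)$laid, 1L)

  # eggs only on days +1 and +5 do not count
  laying2 <- laying
  laying2$egg_laid <- c(0, 1, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(build_lagged_laying_response(laying2, ev)$laid, 0L)

  # uncovered window: event dropped and logged
  ev2 <- data.frame(female_id = "f1", date = "2014-10-08")
  out <- build_lagged_laying_response(laying, ev2)
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "drops")), 1L)

  # response ignores relabeling of laying days outside the window
  laying3 <- laying
  laying3$egg_laid[c(1, 2, 7, 10)] <- 1 - laying3$egg_laid[c(1, 2, 7, 10)]
  expect_equal(build_lagged_laying_response(laying3, ev)$laid, 1L)
})

make_selection_fixture <- function() {
  days <- as.character(as.Date("2014-09-01") + 0:119)
  females <- c("f1", "f2", "f3")
  laying <- expand.grid(female_id = females, date = days,
                        stringsAsFactors = FALSE)
  laying <- laying[order(laying$female_id, laying$date), ]
  set.seed(10)
  laying$egg_laid <- rbinom(nrow(laying), 1, 0.4)
  # f3 lays almost nothing: fails the 10-egg screen
  laying$egg_laid[laying$female_id == "f3"] <- 0
  laying$egg_laid[laying$female_id == "f3"][1] <- 1  # defines season start
  # hot days with hourly weather
  wdays <- as.character(as.Date("2014-09-01") + c(44, 45, 60, 61))
  weather <- do.call(rbind, lapply(wdays, function(d) {
    data.frame(date = d, hour = 0:23,
               air_t = 22 + 10 * cos(2 * pi * (0:23 - 14) / 24))
  }))
  frame <- data.frame(
    image_id = sprintf("i%02d", 1:8),
    individual_id = rep(c("f1", "f2", "f3", "f1"), 2),
    date = rep(wdays, each = 2),
    year = 2014L,
    enclosure_id = "E1",
    subspecies_class = "SAB",
    air_t = c(31, 25, 31, 25, 31, 25, 31, 25),
    head_neck_dev = rnorm(8),
    stringsAsFactors = FALSE)
  list(frame = frame, laying = laying, weather = weather)
}

test_that("selection filters apply the season, productivity and hot-day screens", {
  fx <- make_selection_fixture()
  sel <- apply_selection_filters(fx$frame, fx$laying, fx$weather)
  # season starts Sep 1 (first laying date): events on day 45 removed,
  # day 46 kept
  expect_false(any(sel$date == as.character(as.Date("2014-09-01") + 44)))
  expect_true(any(sel$date == as.character(as.Date("2014-09-01") + 45)))
  # f3 laid once all season: removed by the 10-egg screen
  expect_false("f3" %in% sel$female_id)
  # period labels follow air temperature at image time
  expect_equal(as.character(sel$period_category[sel$air_t >= 30]),
               rep("hot", sum(sel$air_t >= 30)))
  expect_true(all(as.character(sel$period_category) %in% c("benign", "hot")))
  # standardized deviation over retained events
  expect_lt(abs(mean(sel$head_neck_dev_std)), 1e-8)
  expect_lt(abs(sd(sel$head_neck_dev_std) - 1), 1e-8)
})

test_that("selection filters are masks on the unfiltered data (order cannot matter)", {
  fx <- make_selection_fixture()
  sel <- apply_selection_filters(fx$frame, fx$laying, fx$weather)
  # shuffling event order leaves the retained set identical
  shuf <- fx$frame[rev(seq_len(nrow(fx$frame))), ]
  sel2 <- apply_selection_filters(shuf, fx$laying, fx$weather)
  key <- function(s) sort(paste(s$female_id, s$date, s$air_t))
  expect_equal(key(sel), key(sel2))
})

test_that("the category recipe declares the published model structure", {
  obs <- tiny_observations()
  ped <- pedigree(paste0("F", 1:12))
  rec <- recipe_headneck_category_model(obs, ped)
  m <- rec$model
  expect_equal(m$response, "head_neck_dev")
  expect_equal(m$residual, "by:category")
  expect_setequal(names(m$random),
                  c("year", "enclosure", "date", "individual", "animal"))
  expect_true(m$random$animal$pedigree)
  expect_equal(m$random$individual$design, "cat(category)")
  # the default schedule is the long production one
  expect_equal(m$settings$nitt, 5100000)
  # without a pedigree there is no animal term and heritability() errors
  rec0 <- recipe_headneck_category_model(obs)
  expect_false("animal" %in% names(rec0$model$random))
  fit0 <- qgfit(rec0, settings = qg_settings(400, 100, 3), seed = 1)
  expect_error(heritability(fit0, "cold"), "pedigree")
})

test_that("the body-part recipe stacks head and neck rows with an image term", {
  obs <- tiny_observations()
  rec <- recipe_body_part_model(obs)
  expect_equal(nrow(rec$data), 2L * nrow(obs))
  expect_setequal(levels(rec$data$body_part), c("head", "neck"))
  expect_true("image" %in% names(rec$model$random))
  expect_equal(rec$model$random$individual$design, c("1", "tc_dec", "tc_inc"))
  # head and neck rows of one image share the response source
  one <- rec$data[rec$data$image_id == obs$image_id[1], ]
  expect_equal(sort(one$surface_t), sort(c(obs$head_t[1], obs$neck_t[1])))
  expect_error(recipe_body_part_model(obs[, setdiff(names(obs), "neck_t")]),
               "neck_t")
})

test_that("identical head and neck series give body-part contrasts centered at zero", {
  obs <- tiny_observations(200, seed = 33)
  obs$neck_t <- obs$head_t  # perfectly symmetric body parts
  rec <- recipe_body_part_model(obs)
  fit <- qgfit(rec, settings = qg_settings(2500, 500, 4), seed = 8)
  bp <- grep("body_partneck", colnames(fit$samples), value = TRUE)
  for (p in bp) {
    h <- hpd_interval(fit$samples[, p])
    expect_true(h[1] < 0 && h[2] > 0)
  }
})

test_that("the selection recipe is a threshold model demanding standardized input", {
  fx <- make_selection_fixture()
  sel <- apply_selection_filters(fx$frame, fx$laying, fx$weather)
  rec <- recipe_selection_model(sel)
  expect_equal(rec$model$family, "threshold")
  expect_equal(rec$model$settings$nitt, 31500000)
  bad <- sel
  bad$head_neck_dev_std <- bad$head_neck_dev
  expect_error(recipe_selection_model(bad), "standardized")
})

test_that("the reaction-norm recipe drops subspecies terms for a single class", {
  obs <- tiny_observations()
  obs$subspecies_class <- "SAB"
  ped <- pedigree(paste0("F", 1:12))
  rec <- recipe_subspecies_reaction_norm(obs, ped)
  expect_false(grepl("subspecies", rec$model$fixed))
  fit <- qgfit(rec, settings = qg_settings(400, 100, 3), seed = 2)
  expect_s3_class(fit, "qgfit")
  expect_true("animal.(Intercept):(Intercept)" %in% colnames(fit$samples))
})
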