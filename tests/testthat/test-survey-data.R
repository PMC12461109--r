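test_that("load_detections builds tensors, masks, and validates", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    species = c("sp1", "sp2", "sp1", "sp2", "sp2"),
    site = c("s1", "s1", "s2", "s2", "s1"),
    method = c("mist_net", "mist_net", "mist_net", "mist_net", "aru"),
    seasons_surveyed = c(3, 3, 2, 2, 3),
    seasons_detected = c(2, 0, 1, 0, 3)
  ), csv, row.names = FALSE)
  d <- load_detections(csv)
  expect_equal(d$species, c("sp1", "sp2"))
  expect_equal(d$sites, c("s1", "s2"))
  expect_equal(dim(d$Y$mist_net), c(2, 2))
  expect_equal(d$N$mist_net, c(s1 = 3L, s2 = 2L))
  # sp1 has no aru rows -> masked out of the aru likelihood
  expect_false(d$mask$aru[["sp1"]])
  expect_true(d$mask$aru[["sp2"]])
  expect_equal(d$Y$aru["s1", "sp2"], 3L)
})

test_that("load_detections rejects invalid rows", {
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "a", site = "s", method = "mist_net",
                       seasons_surveyed = 2, seasons_detected = 3),
            bad, row.names = FALSE)
  expect_error(load_detections(bad), "seasons_detected")
  bad2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "a", site = "s", method = "harp_trap",
                       seasons_surveyed = 2, seasons_detected = 1),
            bad2, row.names = FALSE)
  expect_error(load_detections(bad2), "unknown method")
})

test_that("write -> load round-trips exactly", {
  d <- tiny_world$data
  f <- tempfile(fileext = ".csv")
  write_detections(d, f)
  d2 <- load_detections(f)
  expect_identical(d2$Y, d$Y)
  expect_identical(d2$N, d$N)
  expect_identical(d2$mask, d$mask)
})

test_that("detection_data invariants are enforced", {
  expect_error(detection_data(
    "sp", "s",
    Y = list(sonar = matrix(0L, 1, 1)), N = list(sonar = 1L),
    mask = list(sonar = TRUE)), "unknown method")
  expect_error(detection_data(
    "sp", "s",
    Y = list(mist_net = matrix(2L, 1, 1)), N = list(mist_net = 1L),
    mask = list(mist_net = TRUE)), "exceed")
  expect_error(detection_data(
    "sp", "s",
    Y = list(mist_net = matrix(1L, 1, 1)), N = list(mist_net = 1L),
    mask = list(mist_net = FALSE)), "masked out")
})

test_that("standardize z-scores with population SD and is idempotent", {
  cv <- toy_covariates(3)
  cv$temperature <- c(1, 2, 3)
  s <- standardize(cv)
  expect_equal(s$temperature, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  for (v in c("elevation", "temperature", "precipitation", "forest_cover")) {
    expect_lt(abs(mean(s[[v]])), 1e-10)
    expect_lt(abs(sqrt(mean((s[[v]] - mean(s[[v]]))^2)) - 1), 1e-10)
  }
  expect_equal(as.data.frame(standardize(s)), as.data.frame(s),
               tolerance = 1e-12)
  cv$temperature <- rep(5, 3)
  expect_error(standardize(cv), "constant")
})

test_that("collinearity screen: closed forms and affine invariance", {
  cv <- toy_covariates(8)
  # orthogonal predictors
  x <- c(1, 1, -1, -1, 1, -1, 1, -1)
  z <- c(1, -1, 1, -1, -1, 1, 1, -1)
  cv$temperature <- x; cv$precipitation <- z
  scr <- collinearity_screen(cv, c("temperature", "precipitation"))
  expect_equal(scr$r["temperature", "precipitation"], 0)
  expect_equal(unname(scr$vif), c(1, 1))

  # exact r = 0.8 pair -> VIF = 1/(1-0.64) = 2.7778
  sx <- (x - mean(x)) / sd(x); sz <- (z - mean(z)) / sd(z)
  cv$precipitation <- 0.8 * sx + 0.6 * sz
  cv$temperature <- sx
  scr2 <- collinearity_screen(cv, c("temperature", "precipitation"))
  expect_equal(scr2$r["temperature", "precipitation"], 0.8, tolerance = 1e-12)
  expect_equal(unname(scr2$vif), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)

  # VIF invariant to affine rescaling
  cv2 <- cv
  cv2$temperature <- 3 + 100 * cv2$temperature
  scr3 <- collinearity_screen(cv2, c("temperature", "precipitation"))
  expect_equal(scr3$vif, scr2$vif, tolerance = 1e-8)

  # perfect collinearity flagged as Inf, not an error
  cv$forest_cover <- 2 * cv$temperature + 1
  scr4 <- collinearity_screen(cv, c("temperature", "forest_cover"))
  expect_true(all(is.infinite(scr4$vif)))
})

test_that("sampling-effort arithmetic is exactly multiplicative", {
  expect_identical(mistnet_effort(900, 32), 28800)
  expect_identical(mistnet_effort(900, 0), 0)
  expect_equal(mistnet_night_effort(900 / 35, 7, 5), 900, tolerance = 1e-10)
  expect_identical(aru_effort(2, 3, 720, 10), 12)
  expect_identical(aru_files(2, 3, 720), 4320)
  expect_identical(aru_effort(2, 111, 720, 10), 444)
  expect_identical(aru_effort(4, 9, 100, 0), 0)
  # integer-arithmetic cross-check
  for (r in 1:10) {
    set.seed(r)
    v <- as.numeric(sample(0:20, 4, replace = TRUE))
    expect_equal(aru_files(v[1], v[2], v[3]), prod(v[1:3]))
    expect_equal(mistnet_effort(v[1] * v[3], v[2]), v[1] * v[3] * v[2])
  }
})
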