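# Viability classification, time of death, fluorescence, motility, and
# population summaries.

test_that("the adaptive viability threshold is neighborhood mean plus frame sd", {
  # worm of darkness 0.5 on a frame whose ring mean and sd are controlled
  dark <- matrix(0.2, 60, 60)
  px <- rectPixels(26:35, 21:40)
  dark[px] <- 0.5
  f <- frameFromDarkness(dark)
  inst <- instanceFromPixels(px)
  out <- classifyViability(inst, f)
  expect_equal(out$opacity, 0.5)
  expect_equal(out$threshold, 0.2 + sd(dark), tolerance = 1e-12)
  expect_equal(out$viability, "alive")
  expect_false(out$fallback)
  # fixed mode, exactly at threshold: dead ("drops below" read as <=)
  out2 <- classifyViability(inst, f, mode = "fixed", fixedThreshold = 0.5)
  expect_equal(out2$viability, "dead")
  out3 <- classifyViability(inst, f, mode = "fixed", fixedThreshold = 0.499)
  expect_equal(out3$viability, "alive")
})

test_that("viability is monotone in opacity", {
  dark <- matrix(0.2, 60, 60)
  px <- rectPixels(26:35, 21:40)
  f0 <- frameFromDarkness(dark)
  thr <- classifyViability(instanceFromPixels(px), {
    d <- dark; d[px] <- 0.35; frameFromDarkness(d)
  }, mode = "fixed", fixedThreshold = 0.4)
  expect_equal(thr$viability, "dead")
  # darker worm, same fixed threshold: can only move dead -> alive
  thr2 <- classifyViability(instanceFromPixels(px), {
    d <- dark; d[px] <- 0.6; frameFromDarkness(d)
  }, mode = "fixed", fixedThreshold = 0.4)
  expect_equal(thr2$viability, "alive")
})

test_that("neighboring worms are excluded from the background ring", {
  dark <- matrix(0.1, 60, 80)
  a <- rectPixels(26:35, 11:40)
  b <- rectPixels(38:47, 11:40)  # dark neighbor right below the ring
  dark[a] <- 0.5; dark[b] <- 0.9
  f <- frameFromDarkness(dark)
  wormMask <- nemasurv:::pxToMask(rbind(a, b), dim(dark))
  withMask <- classifyViability(instanceFromPixels(a), f, wormMask = wormMask)
  without <- classifyViability(instanceFromPixels(a), f)
  expect_lt(withMask$threshold, without$threshold)
})

test_that("a synthetic worm is alive before death and dead 5 h after", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 3L,
                    seed = 61L)
  for (hrs in c(0, 5)) {
    state <- list(alive = c(hrs == 0, TRUE, TRUE),
                  hoursSinceDeath = c(hrs, 0, 0),
                  shiftPx = matrix(0L, 3L, 2L))
    sc <- renderScene(spec, state = state)
    lab <- labelImage(sc$truth)
    inst <- instanceFromPixels(nemasurv:::maskToPx(lab == 1L))
    out <- classifyViability(inst, sc$brightfield,
                             wormMask = lab > 0L)
    expect_equal(out$viability, if (hrs == 0) "alive" else "dead")
  }
})

test_that("time of death follows the persistence rule", {
  expect_equal(estimateTimeOfDeath(1:4, c("alive", "alive", "dead", "dead")), 3,
               ignore_attr = TRUE)
  expect_equal(estimateTimeOfDeath(1:4, rep("alive", 4)), Inf,
               ignore_attr = TRUE)
  expect_equal(estimateTimeOfDeath(1:2, c("dead", "dead")), 1,
               ignore_attr = TRUE)
  # re-emergence: anomaly logged, last alive->dead transition used
  expect_message(
    tod <- estimateTimeOfDeath(1:5, c("alive", "dead", "alive", "dead", "dead")),
    "re-emergence")
  expect_equal(as.numeric(tod), 4)
  expect_true(attr(tod, "anomaly"))
  expect_error(estimateTimeOfDeath(1, "dead"), "2 time points")
})

test_that("fluorescence is the background-subtracted sum and is additive", {
  px <- matrix(0.1, 50, 50)
  worm <- rectPixels(21:30, 21:30)  # 100 px at 0.5
  px[worm] <- 0.5
  f <- new("WormFrame", pixels = px, channel = "fluorescence",
           chamberId = "t", timeH = 0, pairIndex = 0L, path = "x")
  tot <- measureFluorescence(instanceFromPixels(worm), f)
  expect_equal(tot, 100 * (0.5 - 0.1), tolerance = 1e-12)
  # dark worm on dark background: zero
  f0 <- new("WormFrame", pixels = matrix(0.1, 50, 50),
            channel = "fluorescence", chamberId = "t", timeH = 0,
            pairIndex = 0L, path = "x")
  expect_equal(measureFluorescence(instanceFromPixels(worm), f0), 0)
  # additivity over a split of the pixel set
  half1 <- worm[1:50, ]; half2 <- worm[51:100, ]
  wm <- nemasurv:::pxToMask(worm, dim(px))
  expect_equal(
    measureFluorescence(instanceFromPixels(half1), f, wormMask = wm) +
      measureFluorescence(instanceFromPixels(half2), f, wormMask = wm),
    measureFluorescence(instanceFromPixels(worm), f, wormMask = wm))
})

test_that("deposited per-worm fluorescence is recovered within 5%", {
  spec <- sceneSpec(imageHeightPx = 420L, imageWidthPx = 420L, nWorms = 4L,
                    seed = 71L, fluorPerWorm = c(150, 200, 250, 300))
  sc <- renderScene(spec)
  lab <- labelImage(sc$truth)
  truth <- wormTable(sc$truth)
  for (w in 1:4) {
    inst <- instanceFromPixels(nemasurv:::maskToPx(lab == w))
    got <- measureFluorescence(inst, sc$fluorescence, wormMask = lab > 0L)
    expect_lt(abs(got - truth$fluorescence_total[w]) /
                truth$fluorescence_total[w], 0.05)
  }
})

test_that("motility is the newly covered pixel fraction", {
  worm <- rectPixels(11:20, 11:110)  # 1000 px
  dims <- c(40L, 130L)
  inst <- instanceFromPixels(worm)
  same <- nemasurv:::pxToMask(worm, dims)
  expect_equal(measureMotility(inst, same), 0)
  empty <- matrix(FALSE, dims[1L], dims[2L])
  expect_equal(measureMotility(inst, empty), 1)
  # 100-px worm translated so exactly 40 px are newly covered
  worm100 <- rectPixels(11:20, 11:20)
  shifted <- worm100
  shifted[, 2L] <- shifted[, 2L] + 4L  # 4 of 10 columns newly covered
  earlier <- nemasurv:::pxToMask(worm100, dims)
  expect_equal(measureMotility(instanceFromPixels(shifted), earlier), 0.40)
  # no earlier frame: absent, never zero
  expect_true(is.na(measureMotility(inst, NULL)))
})

test_that("population summaries give step CDFs, moments and KS comparisons", {
  tab <- data.frame(time_h = rep(c(0, 12), each = 1), worm_id = 1:2,
                    opacity = c(0.7, 0.5))
  out <- populationSummaries(tab, quantities = "opacity")
  cdf0 <- out$cdfs$opacity[["0"]]
  expect_equal(cdf0(0.69), 0)   # single value: a step at v
  expect_equal(cdf0(0.7), 1)
  expect_true(all(out$stats$low_n))
  # identical samples at two times: KS statistic 0
  tab2 <- data.frame(time_h = rep(c(0, 12), each = 5), worm_id = 1:10,
                     opacity = rep(c(0.7, 0.6, 0.5, 0.4, 0.3), 2))
  ks <- populationSummaries(tab2, quantities = "opacity")$ks
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p_value, 1)
})

test_that("a declining opacity cohort separates by KS for non-consecutive times", {
  set.seed(9)
  times <- c(0, 12, 24, 36)
  shift <- 0.08  # opacity drop per 12 h
  tab <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(time_h = times[i], worm_id = 1:30,
               opacity = rnorm(30, 0.7 - (i - 1) * shift, 0.04))
  }))
  ks <- populationSummaries(tab, quantities = "opacity")$ks
  nonconsec <- ks[abs(ks$time_a - ks$time_b) > 12, ]
  expect_true(all(nonconsec$p_value < 0.01))
})

test_that("measureWorms produces one schema-complete row per worm", {
  spec <- sceneSpec(imageHeightPx = 360L, imageWidthPx = 360L, nWorms = 3L,
                    seed = 81L)
  sc <- renderScene(spec)
  lab <- labelImage(sc$truth)
  instances <- lapply(1:3, function(w)
    instanceFromPixels(nemasurv:::maskToPx(lab == w), id = w))
  tab <- measureWorms(instances, sc$brightfield,
                      fluorescence = sc$fluorescence)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("chamber_id", "time_h", "worm_id", "area_px",
                    "fluorescence_total", "opacity", "motility",
                    "viability") %in% names(tab)))
  expect_true(all(tab$viability == "alive"))
  expect_true(all(is.na(tab$motility)))  # no earlier frame given
})
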