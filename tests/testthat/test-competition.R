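test_that("growth simulation hits its decoupled and symmetric limits", {
  p0 <- growth_params(rate_winner = 1.1, rate_loser = 0.9, coupling = 0,
                      mix_fraction_winner = 0.5)
  cts <- simulate_growth(p0)
  sep <- cts[cts$condition == "separate", ]
  co <- cts[cts$condition == "coculture", ]
  for (s in c("winner", "loser"))
    expect_equal(co$count[co$subline == s],
                 0.5 * sep$count[sep$subline == s])
  # equal rates, no coupling: co-culture ratio constant over time
  psym <- growth_params(rate_winner = 1, rate_loser = 1, coupling = 0)
  rsym <- competition_ratio(simulate_growth(psym))
  expect_equal(unique(rsym$ratio[rsym$condition == "coculture"]), 1)
})

test_that("coupled losers fall below their uncoupled counterpart and the ODE oracle agrees", {
  skip_if_not_installed("deSolve")
  p <- growth_params(coupling = 3e-6)
  cts <- simulate_growth(p)
  p0 <- growth_params(coupling = 0)
  cts0 <- simulate_growth(p0)
  co_l <- function(d, x) x$count[x$condition == "coculture" &
                                   x$subline == "loser" & x$day == d]
  expect_lt(co_l(3, cts), co_l(3, cts0))
  # independent fine-step numerical integration of the coupled system
  rhs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      dW <- rw * W
      dL <- (rl - cpl * W) * L
      list(c(dW, dL))
    })
  }
  out <- deSolve::ode(
    y = c(W = 2.2e4, L = 2.2e4), times = 0:3, func = rhs,
    parms = c(rw = 1.1, rl = 0.9, cpl = 3e-6),
    method = "ode45", atol = 1e-10, rtol = 1e-10)
  for (d in 0:3)
    expect_equal(co_l(d, cts), unname(out[out[, "time"] == d, "L"]),
                 tolerance = 1e-6)
})

test_that("growth curves return exact doubling times and recover rates", {
  cts <- data.frame(day = rep(0:3, 2),
                    condition = "separate",
                    subline = rep(c("winner", "loser"), each = 4),
                    count = c(100 * 2^(0:3), rep(50, 4)),
                    replicate = 1L)
  gc <- growth_curves(cts)
  tw <- gc$rates[gc$rates$subline == "winner", ]
  expect_equal(tw$doubling_time, 1.0, tolerance = 1e-12)
  tl <- gc$rates[gc$rates$subline == "loser", ]
  expect_true(is.na(tl$doubling_time)) # flat counts: undefined growth
  # synthetic trajectories give back the generator rates
  p <- growth_params(rate_winner = 1.1, rate_loser = 0.9, coupling = 0)
  gr <- growth_curves(simulate_growth(p))
  sep <- gr$rates[gr$rates$condition == "separate", ]
  expect_equal(sep$rate[sep$subline == "winner"], 1.1, tolerance = 0.02)
  expect_equal(sep$rate[sep$subline == "loser"], 0.9, tolerance = 0.02)
  # single replicate reports SD as NA, not zero
  expect_true(all(is.na(gr$curves$sd)))
})

test_that("ratio conventions agree through r/(1+r) and guard zero denominators", {
  p <- growth_params(coupling = 2e-6)
  cts <- simulate_growth(p)
  r1 <- competition_ratio(cts, "variant_over_wt")
  r2 <- competition_ratio(cts, "subline_over_total")
  merged <- merge(r1, r2[r2$subline == "winner", ],
                  by = c("day", "condition", "replicate"))
  expect_equal(merged$ratio.y, merged$ratio.x / (1 + merged$ratio.x),
               tolerance = 1e-12)
  # equal counts: 1.0 and 0.5
  eq <- data.frame(day = 0, condition = "coculture",
                   subline = c("winner", "loser"), count = c(5, 5),
                   replicate = 1L)
  expect_equal(competition_ratio(eq, "variant_over_wt")$ratio, 1)
  expect_equal(competition_ratio(eq, "subline_over_total")$ratio,
               c(0.5, 0.5))
  # eliminated wild-type: undefined flagged ratio, share 1.0
  gone <- data.frame(day = 3, condition = "coculture",
                     subline = c("winner", "loser"), count = c(8, 0),
                     replicate = 1L)
  v <- competition_ratio(gone, "variant_over_wt")
  expect_true(v$undefined)
  expect_true(is.na(v$ratio))
  s <- competition_ratio(gone, "subline_over_total")
  expect_equal(s$ratio[s$subline == "winner"], 1)
  expect_error(competition_ratio(eq[eq$subline == "winner", ]),
               "winner.*loser")
})

test_that("coupling raises the co-culture winner ratio above separate culture", {
  cts <- simulate_growth(growth_params(coupling = 3e-6))
  r <- competition_ratio(cts)
  at3 <- r[r$day == 3, ]
  expect_gt(at3$ratio[at3$condition == "coculture"],
            at3$ratio[at3$condition == "separate"])
})

test_that("caspase fractions carry exact Clopper-Pearson intervals", {
  res <- caspase_fraction(c(0, 30), c(100, 100))
  expect_equal(res$fraction, c(0, 0.3))
  expect_equal(res$ci_lo[1], 0)
  # CI endpoints satisfy the defining binomial tail equations
  x <- 30; n <- 100; a <- 0.025
  expect_equal(sum(dbinom(x:n, n, res$ci_lo[2])), a, tolerance = 1e-9)
  expect_equal(sum(dbinom(0:x, n, res$ci_hi[2])), a, tolerance = 1e-9)
  expect_true(res$ci_lo[2] < 0.3 && res$ci_hi[2] > 0.3)
  expect_error(caspase_fraction(1, 0), "positive")
  # doubled loser positivity is recovered as a fold change ~ 2
  set.seed(7)
  loser_pos <- rbinom(6, 500, 0.2)
  winner_pos <- rbinom(6, 500, 0.1)
  f <- caspase_fraction(c(loser_pos, winner_pos), rep(500, 12),
                        condition = rep(c("loser", "winner"), each = 6))
  sm <- attr(f, "summary")
  fold <- sm$mean[sm$condition == "loser"] /
    sm$mean[sm$condition == "winner"]
  expect_lt(abs(fold - 2), 0.35)
})

test_that("density titration detects coupling-dependent suppression only", {
  run_titration <- function(coupling) {
    dens <- c(3750, 7500, 15000, 30000, 45000)
    do.call(rbind, lapply(dens, function(d) {
      cts <- simulate_growth(growth_params(plating_density = d,
                                           coupling = coupling))
      cts$plating_density <- d
      cts
    }))
  }
  null <- density_titration(run_titration(0))
  expect_equal(null$rho_loser, 0)
  coupled <- density_titration(run_titration(3e-6))
  expect_lt(coupled$rho_loser, -0.9)
  expect_true(all(diff(coupled$table$loser_rel_growth) < 0))
  one <- run_titration(0)
  expect_error(density_titration(one[one$plating_density == 3750, ]),
               "3 plating-density")
})

test_that("counts conserve subline totals and round-trip as CSV", {
  cts <- simulate_growth(growth_params())
  tot <- aggregate(count ~ day + condition, cts, sum)
  tot <- tot[order(tot$condition, tot$day), ]
  by_sub <- merge(cts[cts$subline == "winner", ],
                  cts[cts$subline == "loser", ],
                  by = c("day", "condition", "replicate"))
  by_sub <- by_sub[order(by_sub$condition, by_sub$day), ]
  expect_equal(by_sub$count.x + by_sub$count.y, tot$count)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(cts, path)
  expect_equal(read_counts(path)$count, cts$count, tolerance = 1e-12)
})

test_that("2^-ddCq hits the closed-form calibration points", {
  # identical to calibrator: RQ 1, diploid
  id <- copy_number_2ddcq(rep(25, 3), rep(26, 3), rep(25, 3), rep(26, 3))
  expect_equal(id$RQ, 1)
  expect_equal(id$copy_number_estimate, 2)
  # ddCq = -1: RQ 2, 4 copies
  up <- copy_number_2ddcq(rep(24, 3), rep(26, 3), rep(25, 3), rep(26, 3))
  expect_equal(up$ddCq, -1)
  expect_equal(up$RQ, 2)
  expect_equal(up$copy_number_estimate, 4)
  # ddCq = -0.585: RQ 1.5 (heterozygous gain, 3 copies)
  het <- copy_number_2ddcq(rep(25 - 0.585, 3), rep(26, 3),
                           rep(25, 3), rep(26, 3))
  expect_equal(het$RQ, 1.5, tolerance = 1e-3)
  expect_equal(het$copy_number_estimate, 3, tolerance = 1e-3)
  # monotone decreasing in ddCq
  dd <- seq(-2, 2, by = 0.25)
  rq <- vapply(dd, function(d)
    copy_number_2ddcq(rep(25 + d, 3), rep(26, 3), rep(25, 3),
                      rep(26, 3))$RQ, numeric(1))
  expect_true(all(diff(rq) < 0))
  # noisy triplicates flagged above 0.5 cycles but still computed
  expect_warning(
    fl <- copy_number_2ddcq(c(24, 25.5, 25), rep(26, 3), rep(25, 3),
                            rep(26, 3)),
    "high replicate SD")
  expect_true(fl$flagged_high_sd)
  expect_error(copy_number_2ddcq(c(25, NA, NA), rep(26, 3), rep(25, 3),
                                 rep(26, 3)), "usable")
  expect_error(copy_number_2ddcq(rep(45, 3), rep(26, 3), rep(25, 3),
                                 rep(26, 3)), "outside")
})
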