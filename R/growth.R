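#' Parameters for the coupled co-culture growth model
#'
#' Two sublines grow exponentially; in co-culture the loser's per-capita
#' growth rate is reduced by `coupling` times the current winner density,
#' the simplest density-dependent model of contact-mediated competition.
#'
#' @param rate_winner,rate_loser Intrinsic per-capita growth rates,
#'   per day.
#' @param plating_density Cells/cm^2 plated per subline in separate
#'   culture; co-cultures split the same total between the sublines. The
#'   default 4.4e4 cells/cm^2 is the standard growth-curve plating.
#' @param mix_fraction_winner Winner fraction of the co-culture at
#'   plating (default 0.5, a 50:50 mix).
#' @param coupling Loser death-rate increment per unit winner density
#'   (cm^2/cell/day); 0 decouples the sublines.
#' @param days Number of days simulated (daily timepoints 0..days).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(rate_winner = 1.1, rate_loser = 0.9,
                          plating_density = 4.4e4,
                          mix_fraction_winner = 0.5,
                          coupling = 3e-6, days = 3L) {
  check_prob(mix_fraction_winner, "mix_fraction_winner")
  check_positive(plating_density, "plating_density")
  if (coupling < 0) stopf("`coupling` must be >= 0")
  if (days < 1) stopf("`days` must be >= 1")
  structure(list(rate_winner = rate_winner, rate_loser = rate_loser,
                 plating_density = plating_density,
                 mix_fraction_winner = mix_fraction_winner,
                 coupling = coupling, days = as.integer(days)),
            class = "growth_params")
}

#' Simulate separate- and co-culture growth trajectories
#'
#' Deterministic closed-form integration of the coupled model. In
#' separate culture each subline is plated at `plating_density` and grows
#' as `N0 * exp(r t)`. In co-culture the winner is plated at
#' `mix_fraction_winner * plating_density` and grows exponentially, and
#' the loser (plated at the complement) obeys
#' `dL/dt = (r_L - c * W(t)) L`, which integrates to
#' `L(t) = L0 * exp(r_L t - (c * W0 / r_W) (exp(r_W t) - 1))`.
#'
#' @param params A [growth_params()].
#' @return Data frame `day`, `condition` (`separate`/`coculture`),
#'   `subline` (`winner`/`loser`), `count` (cells/cm^2), `replicate`.
#' @examples
#' head(simulate_growth(growth_params()))
#' @export
simulate_growth <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  t <- 0:params$days
  rw <- params$rate_winner; rl <- params$rate_loser
  P <- params$plating_density; mf <- params$mix_fraction_winner
  cpl <- params$coupling
  sep_w <- P * exp(rw * t)
  sep_l <- P * exp(rl * t)
  W0 <- mf * P; L0 <- (1 - mf) * P
  co_w <- W0 * exp(rw * t)
  supp <- if (rw != 0) (cpl * W0 / rw) * (exp(rw * t) - 1) else cpl * W0 * t
  co_l <- L0 * exp(rl * t - supp)
  data.frame(
    day = rep(t, 4),
    condition = rep(c("separate", "separate", "coculture", "coculture"),
                    each = length(t)),
    subline = rep(c("winner", "loser", "winner", "loser"),
                  each = length(t)),
    count = c(sep_w, sep_l, co_w, co_l),
    replicate = 1L)
}

#' Growth curves and doubling times from competition counts
#'
#' Summarises per-day counts (mean and SD across replicates; SD is `NA`
#' with a single replicate) and fits a log-linear growth rate per
#' subline/condition over a chosen day window.
#'
#' @param counts Data frame `day`, `condition`, `subline`, `count`,
#'   `replicate` (see [simulate_growth()]).
#' @param window Optional `c(first_day, last_day)` for the rate fit.
#' @return List: `curves` (day/condition/subline mean, sd, n) and `rates`
#'   (condition/subline `rate` per day and `doubling_time` in days, `NA`
#'   when growth is absent or negative).
#' @export
growth_curves <- function(counts, window = NULL) {
  need <- c("day", "condition", "subline", "count")
  if (!all(need %in% names(counts)))
    stopf("`counts` must have columns %s", paste(need, collapse = ", "))
  if (length(unique(counts$day)) < 2)
    stopf("growth curves need at least 2 timepoints")
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  mu <- aggregate(count ~ day + condition + subline, counts, mean)
  names(mu)[names(mu) == "count"] <- "mean"
  s <- aggregate(count ~ day + condition + subline, counts,
                 function(v) if (length(v) > 1) sd(v) else NA_real_)
  names(s)[names(s) == "count"] <- "sd"
  n <- aggregate(cbind(n = count) ~ day + condition + subline, counts,
                 length)
  curves <- Reduce(function(a, b)
    merge(a, b, by = c("day", "condition", "subline")), list(mu, s, n))
  if (!is.null(window))
    counts <- counts[counts$day >= window[1] & counts$day <= window[2], ]
  groups <- unique(counts[c("condition", "subline")])
  rates <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- counts[counts$condition == groups$condition[i] &
                  counts$subline == groups$subline[i] &
                  counts$count > 0, ]
    slope <- if (length(unique(g$day)) >= 2)
      unname(coef(lm(log(count) ~ day, g))[2]) else NA_real_
    data.frame(condition = groups$condition[i],
               subline = groups$subline[i], rate = slope,
               doubling_time = ifelse(is.na(slope) || slope <= 1e-12,
                                      NA_real_, log(2) / slope))
  }))
  list(curves = curves[order(curves$condition, curves$subline,
                             curves$day), ],
       rates = rates)
}

#' Subline ratios per day and condition
#'
#' Two published ratio conventions are supported and always labelled:
#' `variant_over_wt` divides the winner (variant) count by the loser
#' (wild-type) count; `subline_over_total` divides each subline by the
#' total. They are related by `s = r / (1 + r)` for the winner share.
#'
#' @param counts Data frame as in [growth_curves()]; sublines must be
#'   `winner` and `loser`.
#' @param definition Ratio convention.
#' @return Data frame with `day`, `condition`, `replicate`,
#'   (`subline` for `subline_over_total`), `ratio`, `definition`,
#'   `undefined` (TRUE where the denominator was zero).
#' @export
competition_ratio <- function(counts,
                              definition = c("variant_over_wt",
                                             "subline_over_total")) {
  definition <- match.arg(definition)
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  if (!all(c("winner", "loser") %in% counts$subline))
    stopf("`counts` must contain both 'winner' and 'loser' sublines")
  wide <- merge(
    counts[counts$subline == "winner",
           c("day", "condition", "replicate", "count")],
    counts[counts$subline == "loser",
           c("day", "condition", "replicate", "count")],
    by = c("day", "condition", "replicate"),
    suffixes = c("_winner", "_loser"))
  if (definition == "variant_over_wt") {
    undef <- wide$count_loser == 0
    out <- data.frame(
      day = wide$day, condition = wide$condition,
      replicate = wide$replicate,
      ratio = ifelse(undef, NA_real_,
                     wide$count_winner / wide$count_loser),
      definition = definition, undefined = undef)
  } else {
    tot <- wide$count_winner + wide$count_loser
    undef <- tot == 0
    out <- rbind(
      data.frame(day = wide$day, condition = wide$condition,
                 replicate = wide$replicate, subline = "winner",
                 ratio = ifelse(undef, NA_real_, wide$count_winner / tot),
                 definition = definition, undefined = undef),
      data.frame(day = wide$day, condition = wide$condition,
                 replicate = wide$replicate, subline = "loser",
                 ratio = ifelse(undef, NA_real_, wide$count_loser / tot),
                 definition = definition, undefined = undef))
  }
  out[order(out$condition, out$day, out$replicate), ]
}

#' Apoptotic (caspase-positive) fraction with exact binomial CI
#'
#' Fraction of positive cells with a Clopper-Pearson confidence interval;
#' when `condition` labels are supplied, replicate-level means and SDs per
#' condition are attached as attribute `"summary"`.
#'
#' @param n_pos,n_total Positive and total cell counts (vectorised).
#' @param condition Optional condition label per entry.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame `n_pos`, `n_total`, `fraction`, `ci_lo`, `ci_hi`
#'   (plus `condition`).
#' @export
caspase_fraction <- function(n_pos, n_total, condition = NULL,
                             conf_level = 0.95) {
  if (any(n_total <= 0)) stopf("`n_total` must be positive")
  if (any(n_pos < 0 | n_pos > n_total))
    stopf("`n_pos` must lie in [0, n_total]")
  a <- (1 - conf_level) / 2
  ci_lo <- ifelse(n_pos == 0, 0, qbeta(a, n_pos, n_total - n_pos + 1))
  ci_hi <- ifelse(n_pos == n_total, 1,
                  qbeta(1 - a, n_pos + 1, n_total - n_pos))
  out <- data.frame(n_pos = n_pos, n_total = n_total,
                    fraction = n_pos / n_total,
                    ci_lo = ci_lo, ci_hi = ci_hi)
  if (!is.null(condition)) {
    out$condition <- condition
    smry <- aggregate(fraction ~ condition, out, function(v)
      c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_))
    attr(out, "summary") <- do.call(
      data.frame, c(list(condition = smry$condition), as.data.frame(smry$fraction)))
  }
  out
}

#' Density-titration response of the loser subline
#'
#' Across plating densities, reports the endpoint loser count and
#' winner/loser ratio in co-culture and a Spearman rank correlation
#' between plating density and the endpoint loser count relative to its
#' plating (negative correlation = density-dependent suppression).
#'
#' @param counts Data frame as in [growth_curves()] with an extra
#'   `plating_density` column; needs >= 3 density levels.
#' @param day Endpoint day (default: last).
#' @return List: `table` (per density: loser count, relative growth,
#'   winner/loser ratio) and `rho_loser`, the rank correlation.
#' @export
density_titration <- function(counts, day = NULL) {
  if (!"plating_density" %in% names(counts))
    stopf("`counts` must carry a `plating_density` column")
  dens <- sort(unique(counts$plating_density))
  if (length(dens) < 3) stopf("need at least 3 plating-density levels")
  day <- day %||% max(counts$day)
  end <- counts[counts$day == day & counts$condition == "coculture", ]
  d0 <- counts[counts$day == 0 & counts$condition == "coculture", ]
  tab <- do.call(rbind, lapply(dens, function(d) {
    l <- mean(end$count[end$plating_density == d & end$subline == "loser"])
    w <- mean(end$count[end$plating_density == d & end$subline == "winner"])
    l0 <- mean(d0$count[d0$plating_density == d & d0$subline == "loser"])
    data.frame(plating_density = d, loser_count = l,
               loser_rel_growth = l / l0,
               winner_over_loser = ifelse(l > 0, w / l, NA_real_))
  }))
  # a flat response (no density dependence) has zero association, not NA
  rel <- tab$loser_rel_growth
  rho <- if (diff(range(rel)) <= 1e-12 * max(abs(rel), 1)) 0 else
    cor(tab$plating_density, rel, method = "spearman")
  list(table = tab, rho_loser = rho)
}

#' Relative copy number by the 2^-ddCq method
#'
#' From Cq triplicates of a target and a reference assay, in a test
#' sample and a diploid calibrator:
#' `dCq = mean(Cq_target) - mean(Cq_reference)` per sample,
#' `ddCq = dCq_sample - dCq_calibrator`, `RQ = 2^-ddCq`, and the copy
#' number estimate is `2 * RQ` (calibrator assumed diploid at the target
#' locus). Triplicates with SD above `sd_threshold` cycles are flagged
#' but still computed.
#'
#' @param target_sample,ref_sample,target_cal,ref_cal Numeric Cq
#'   replicate vectors (>= 2 usable values each, Cq in (0, 40)).
#' @param sd_threshold Replicate-SD flag threshold in cycles.
#' @return List: `dCq_sample`, `dCq_calibrator`, `ddCq`, `RQ`,
#'   `copy_number_estimate`, `flagged_high_sd`.
#' @examples
#' copy_number_2ddcq(c(24.0, 24.1, 23.9), c(25.0, 25.1, 24.9),
#'                   c(25.0, 25.0, 25.0), c(25.0, 25.0, 25.0))
#' @export
copy_number_2ddcq <- function(target_sample, ref_sample, target_cal,
                              ref_cal, sd_threshold = 0.5) {
  trip <- list(target_sample = target_sample, ref_sample = ref_sample,
               target_cal = target_cal, ref_cal = ref_cal)
  for (nm in names(trip)) {
    v <- trip[[nm]][!is.na(trip[[nm]])]
    if (length(v) < 2) stopf("`%s` needs >= 2 usable Cq values", nm)
    if (any(v <= 0 | v >= 40))
      stopf("`%s` contains Cq values outside (0, 40)", nm)
    trip[[nm]] <- v
  }
  high_sd <- vapply(trip, function(v) sd(v) > sd_threshold, logical(1))
  if (any(high_sd))
    warnf("high replicate SD (> %g cycles) in: %s", sd_threshold,
          paste(names(trip)[high_sd], collapse = ", "))
  dcq_s <- mean(trip$target_sample) - mean(trip$ref_sample)
  dcq_c <- mean(trip$target_cal) - mean(trip$ref_cal)
  ddcq <- dcq_s - dcq_c
  rq <- 2^(-ddcq)
  list(dCq_sample = dcq_s, dCq_calibrator = dcq_c, ddCq = ddcq, RQ = rq,
       copy_number_estimate = 2 * rq, flagged_high_sd = any(high_sd))
}
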