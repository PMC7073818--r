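# RIA/NLI k_loss estimation: ratio arithmetic, profile filters, parameter
# recovery against closed forms and a grid-search oracle, aggregation rules.

# build a long precursor table for given peptides/rates, noiseless
make_precursors <- function(peptides, k, T0 = 1000, times = c(0, 1, 4.5, 11),
                            sample_id = "S1", replicate = 1L, charge = 2L) {
  rows <- list()
  for (i in seq_along(peptides)) {
    L <- T0 * exp(-k[i] * times)
    H <- T0 - L
    rows[[i]] <- data.frame(
      sample_id = sample_id, replicate = replicate, time_h = rep(times, 2),
      peptide = peptides[i], charge = charge,
      channel = rep(c("light", "heavy"), each = length(times)),
      intensity = c(L, ifelse(H == 0, NA, H)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("relative isotopic abundance follows L/(L+H)", {
  expect_equal(compute_ria(100, 100), 0.5)
  expect_equal(compute_ria(0, 50), 0)
  expect_equal(compute_ria(30, 10), 0.75)
  # one missing channel counts as below detection
  expect_equal(compute_ria(500, NA), 1)
  expect_true(is.na(compute_ria(NA, NA)))
  expect_true(is.na(compute_ria(0, 0)))
})

test_that("profile filters drop single-time-point and non-decaying profiles", {
  prof <- data.frame(
    sample_id = "S1",
    peptide = c("AAAAAAK", rep("CCCCCCK", 3), rep("DDDDDDK", 2)),
    charge = 2L, replicate = 1L,
    time_h = c(1, 1, 4.5, 11, 1, 11),
    ria = c(0.5, 0.90, 0.95, 0.97, 0.9, 0.3),
    total = 1000, stringsAsFactors = FALSE)
  res <- filter_profiles(prof)
  expect_equal(res$exclusions$reason[res$exclusions$peptide == "AAAAAAK"],
               "single_time_point")
  expect_equal(res$exclusions$reason[res$exclusions$peptide == "CCCCCCK"],
               "non_increasing_labeling")
  expect_setequal(unique(res$profiles$peptide), "DDDDDDK")
})

test_that("the decay model honors its boundary identities", {
  expect_equal(ria_model(0, 0.3), 1)
  expect_equal(ria_model(1, log(2)), 0.5)   # half-life identity
  expect_lt(ria_model(1e4, 0.02), 1e-6)     # decays to 0
})

test_that("RIA fit recovers the true rate and matches a grid-search oracle", {
  times <- c(1, 4.5, 11)
  for (k in c(0.05, 0.2, 0.45)) {
    prof <- data.frame(time_h = times, ria = exp(-k * times))
    fit <- fit_kloss_ria(prof)
    expect_equal(fit$k_loss, k, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
    expect_equal(fit$n_points, 3)
    # independent grid search over k in (0, 5]
    expect_equal(fit$k_loss, oracle_grid_k(times, exp(-k * times)),
                 tolerance = 1e-4)
  }
  # t = 0 rows are the assumption, not data
  prof0 <- data.frame(time_h = c(0, times), ria = c(0.8, exp(-0.2 * times)))
  expect_equal(fit_kloss_ria(prof0)$k_loss, 0.2, tolerance = 1e-6)
  expect_equal(fit_kloss_ria(prof0)$n_points, 3)
})

test_that("RIA fits are scale-equivariant and order-preserving", {
  cfg <- turnover_config()
  times <- c(1, 4.5, 11)
  base <- make_precursors("AAAAAAK", 0.1, T0 = 1000, times = c(0, times))
  scaled <- base; scaled$intensity <- scaled$intensity * 7.3
  f1 <- fit_kloss(base, cfg)$estimates
  f2 <- fit_kloss(scaled, cfg)$estimates
  expect_equal(f1$k_loss, f2$k_loss, tolerance = 1e-9)

  two <- make_precursors(c("AAAAAAK", "CCCCCCK"), c(0.1, 0.3))
  ft <- fit_kloss(two, cfg)$estimates
  expect_lt(ft$k_loss[ft$peptide == "AAAAAAK"],
            ft$k_loss[ft$peptide == "CCCCCCK"])
})

test_that("NLI normalization equalizes run totals and the fit recovers k", {
  # two runs, one with double the total signal: scaled by the median ratio
  prec <- make_precursors("AAAAAAK", 0.3)
  boosted <- prec[prec$time_h == 1, ]
  prec$intensity[prec$time_h == 1] <- prec$intensity[prec$time_h == 1] * 2
  fit <- fit_kloss(prec, method = "NLI")
  expect_equal(nrow(fit$estimates), 1)
  # noiseless decay at 0.3/h (normalization is a no-op when totals are equal)
  clean <- make_precursors("AAAAAAK", 0.3)
  fitc <- fit_kloss(clean, method = "NLI")
  expect_equal(fitc$estimates$k_loss, 0.3, tolerance = 1e-6)
  expect_equal(fitc$estimates$L0, 1000, tolerance = 1e-3)
})

test_that("NLI and RIA agree on noiseless steady-state data", {
  set.seed(4)
  ks <- stats::runif(30, 0.02, 0.6)
  prec <- make_precursors(sprintf("PEPTIDEN%02dK", seq_along(ks)), ks)
  ria <- fit_kloss(prec, method = "RIA")$estimates
  nli <- fit_kloss(prec, method = "NLI")$estimates
  m <- merge(ria, nli, by = "peptide")
  expect_equal(nrow(m), 30)
  expect_lt(max(abs(m$k_loss.x - m$k_loss.y)), 1e-4)
  expect_equal(m$k_loss.x[order(m$peptide)],
               ks[order(sprintf("PEPTIDEN%02dK", seq_along(ks)))],
               tolerance = 1e-5)
})

test_that("aggregation applies weighted means, medians and the full-profile rule", {
  est <- data.frame(
    sample_id = "S1", peptide = "AAAAAAK", charge = c(2L, 3L),
    k_loss = c(0.1, 0.3), n_points = 3L, rss = 0,
    weight = c(1, 3), converged = TRUE, method = "RIA",
    stringsAsFactors = FALSE)
  gm <- data.frame(peptide = "AAAAAAK", group_id = "T1", gene_id = "G1",
                   class = "UQ", stringsAsFactors = FALSE)
  agg <- aggregate_kloss(est, gm,
                         turnover_config(min_peptides_per_group = 1))
  expect_equal(agg$peptide$k_loss, 0.25)  # weighted mean

  # group summary: median of log2 peptide values
  est3 <- data.frame(
    sample_id = "S1", peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK"),
    charge = 2L, k_loss = 2^c(-3, -2, -1), n_points = 3L, rss = 0,
    weight = 1, converged = TRUE, method = "RIA", stringsAsFactors = FALSE)
  gm3 <- data.frame(peptide = est3$peptide, group_id = "T1", gene_id = "G1",
                    class = "UQ", stringsAsFactors = FALSE)
  agg3 <- aggregate_kloss(est3, gm3, turnover_config())
  expect_equal(agg3$group$log2_kloss, -2)

  # a peptide absent from one of the samples is no full profile
  est_part <- rbind(
    transform(est3, sample_id = "S1"),
    transform(est3[1:2, ], sample_id = "S2"))
  agg_part <- aggregate_kloss(est_part, gm3, turnover_config())
  expect_false("DDDDDDK" %in% agg_part$full_peptides)
  expect_true("DDDDDDK" %in%
                agg_part$exclusions$peptide[agg_part$exclusions$reason ==
                                              "not_full_profile"])

  # groups need two peptides
  agg_small <- aggregate_kloss(est, gm, turnover_config())
  expect_equal(nrow(agg_small$group), 0)
  expect_true("T1" %in%
                agg_small$exclusions$peptide[agg_small$exclusions$reason ==
                                               "insufficient_peptides"])
})

test_that("parameter recovery holds for noiseless and noisy simulations", {
  set.seed(21)
  n <- 120
  ks <- exp(stats::runif(n, log(0.02), log(0.6)))
  times <- c(1, 4.5, 11)
  rel_err <- function(noise_cv) {
    fits <- vapply(seq_len(n), function(i) {
      y <- exp(-ks[i] * times)
      if (noise_cv > 0)
        y <- pmin(y * stats::rlnorm(3, -log(1 + noise_cv^2) / 2,
                                    sqrt(log(1 + noise_cv^2))), 1)
      fit_kloss_ria(data.frame(time_h = times, ria = y))$k_loss
    }, 0)
    abs(fits - ks) / ks
  }
  expect_lt(median(rel_err(0)), 0.001)
  expect_lt(median(rel_err(0.1)), 0.10)
})

test_that("k_deg arithmetic and the doubling-time helper are exact", {
  r <- kdeg_from_kloss(0.5, 0.03)
  expect_equal(r$k_deg, 0.47)
  expect_false(r$flagged_negative)
  expect_equal(kdeg_from_kloss(0.2, 0)$k_deg, 0.2)
  flag <- kdeg_from_kloss(0.02, 0.03)
  expect_true(flag$flagged_negative)
  expect_equal(flag$k_deg, -0.01)
  expect_equal(kcd_from_doubling_time(23.1), log(2) / 23.1)
  expect_equal(kcd_from_doubling_time(23.1), 0.03, tolerance = 0.01)
})
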