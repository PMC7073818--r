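# Degradation-rate (k_loss) estimation from pulsed-SILAC quantities.
#
# Under steady-state labeling the fraction of pre-existing (light) signal,
# the relative isotopic abundance RIA_t = L/(L+H), decays exponentially:
# RIA_t = RIA_0 * exp(-k_loss * t) with RIA_0 = 1 (no heavy isotope at t = 0).
# The RIA method fits k by nonlinear least squares with the intercept fixed
# at 1; the NLI method instead fits L_t = L0 * exp(-k * t) on run-normalized
# light-channel intensities with L0 free. k_loss absorbs both true
# degradation (k_deg) and dilution by cell division (k_cd):
# k_loss = k_deg + k_cd.

#' Turnover estimation configuration
#'
#' @param ria0 Fixed initial relative isotopic abundance (default 1; the
#'   model assumption that no heavy label is present at t = 0).
#' @param k_bounds Optimization bounds for k_loss in per hour
#'   (default `c(1e-6, 100)`).
#' @param tol Convergence tolerance passed to the optimizer.
#' @param max_iter Maximum optimizer iterations.
#' @param weighting Precursor-to-peptide averaging weights:
#'   `"total_intensity"` (summed L+H over the profile; intensity proxies
#'   measurement precision) or `"equal"`.
#' @param group_summary Peptide-to-group summary of log2 k_loss: `"median"`
#'   (default) or `"mean"`.
#' @param min_peptides_per_group Minimum peptides per AS group (default 2).
#' @param strict_monotonic If `TRUE`, require the per-time mean RIA to
#'   decrease strictly at every step instead of only endpoint-wise.
#' @param k_cd Optional named numeric vector of per-sample cell-division
#'   rates (per hour) for [kdeg_from_kloss()].
#' @return A list of class `turnover_config`.
#' @export
turnover_config <- function(ria0 = 1, k_bounds = c(1e-6, 100), tol = 1e-12,
                            max_iter = 200L,
                            weighting = c("total_intensity", "equal"),
                            group_summary = c("median", "mean"),
                            min_peptides_per_group = 2L,
                            strict_monotonic = FALSE, k_cd = NULL) {
  structure(list(ria0 = ria0, k_bounds = k_bounds, tol = tol,
                 max_iter = as.integer(max_iter),
                 weighting = match.arg(weighting),
                 group_summary = match.arg(group_summary),
                 min_peptides_per_group = as.integer(min_peptides_per_group),
                 strict_monotonic = strict_monotonic, k_cd = k_cd),
            class = "turnover_config")
}

#' Exponential label-loss model
#'
#' @param t Labeling time(s) in hours.
#' @param k k_loss in per hour.
#' @param ria0 Initial relative isotopic abundance (default 1).
#' @return `ria0 * exp(-k * t)`.
#' @export
ria_model <- function(t, k, ria0 = 1) ria0 * exp(-k * t)

#' Relative isotopic abundance of a light/heavy pair
#'
#' A missing channel is treated as signal below detection (0); a point where
#' both channels are missing, or where L + H = 0, is undefined (`NA`).
#'
#' @param L,H Light and heavy intensities (vectors; `NA` = missing).
#' @return `L / (L + H)`, with `NA` where undefined.
#' @export
compute_ria <- function(L, H) {
  both_missing <- is.na(L) & is.na(H)
  l <- ifelse(is.na(L), 0, L)
  h <- ifelse(is.na(H), 0, H)
  tot <- l + h
  out <- ifelse(tot > 0, l / tot, NA_real_)
  out[both_missing] <- NA_real_
  out
}

#' Build per-precursor RIA time-course profiles
#'
#' Pairs the light and heavy channel per (sample, replicate, time, peptide,
#' charge), computes RIA, and drops undefined points.
#'
#' @param precursors Precursor table (see [read_precursor_table()]).
#' @return `data.frame` with columns `sample_id`, `peptide`, `charge`,
#'   `replicate`, `time_h`, `ria`, `total` (L+H with missing as 0).
#' @export
build_ria_profiles <- function(precursors) {
  dt <- data.table::as.data.table(precursors)
  wide <- data.table::dcast(dt,
    sample_id + peptide + charge + replicate + time_h ~ channel,
    value.var = "intensity", fun.aggregate = sum, fill = NA_real_)
  if (!"light" %in% names(wide)) wide[, light := NA_real_]
  if (!"heavy" %in% names(wide)) wide[, heavy := NA_real_]
  wide[, ria := compute_ria(light, heavy)]
  wide[, total := ifelse(is.na(light), 0, light) + ifelse(is.na(heavy), 0, heavy)]
  out <- wide[!is.na(ria),
              c("sample_id", "peptide", "charge", "replicate", "time_h",
                "ria", "total")]
  data.table::setorder(out, sample_id, peptide, charge, time_h, replicate)
  as.data.frame(out)
}

#' Filter RIA profiles before fitting
#'
#' Excludes profiles quantified at fewer than two distinct positive labeling
#' times (`single_time_point`) and profiles whose labeling does not progress,
#' i.e. whose mean RIA at the last observed time is not below the mean RIA at
#' the first observed time (`non_increasing_labeling`). With
#' `config$strict_monotonic`, the per-time mean RIA must fall at every step.
#'
#' @param profiles Output of [build_ria_profiles()].
#' @param config A [turnover_config()].
#' @return A list with `profiles` (retained rows) and `exclusions`
#'   (`data.frame`: sample_id, peptide, charge, reason).
#' @export
filter_profiles <- function(profiles, config = turnover_config()) {
  dt <- data.table::as.data.table(profiles)
  info <- dt[, {
    tm <- sort(unique(time_h))
    per_time <- vapply(tm, function(x) mean(ria[time_h == x]), 0)
    decaying <- if (config$strict_monotonic && length(tm) > 1)
      all(diff(per_time) < 0)
    else per_time[length(per_time)] < per_time[1]
    list(n_pos_times = length(unique(time_h[time_h > 0])),
         decaying = decaying)
  }, by = c("sample_id", "peptide", "charge")]
  info[, reason := data.table::fifelse(
    n_pos_times < 2, "single_time_point",
    data.table::fifelse(!decaying, "non_increasing_labeling", NA_character_))]
  excl <- info[!is.na(reason),
               c("sample_id", "peptide", "charge", "reason")]
  keep <- info[is.na(reason), c("sample_id", "peptide", "charge")]
  retained <- merge(dt, keep, by = c("sample_id", "peptide", "charge"),
                    sort = FALSE)
  list(profiles = as.data.frame(retained), exclusions = as.data.frame(excl))
}

#' @noRd
#' One-parameter bounded NLS of y ~ exp(-k t) (RIA path, intercept fixed).
fit_decay_fixed <- function(t, y, config) {
  obj <- function(k) sum((y - exp(-k * t))^2)
  grad <- function(k) {
    e <- exp(-k * t)
    sum(2 * (y - e) * t * e)
  }
  t_last <- max(t)
  y_last <- mean(y[t == t_last])
  k0 <- min(max(-log(max(y_last, 1e-6)) / t_last, config$k_bounds[1]),
            config$k_bounds[2])
  fit <- stats::nlminb(k0, obj, gradient = grad,
                       lower = config$k_bounds[1], upper = config$k_bounds[2],
                       control = list(iter.max = config$max_iter,
                                      abs.tol = 0, rel.tol = config$tol,
                                      x.tol = 1e-12))
  list(k = fit$par, rss = fit$objective,
       converged = fit$convergence %in% c(0L, 1L) ||
         grepl("convergence", fit$message %||% "", ignore.case = TRUE))
}

#' @noRd
#' Two-parameter decay y ~ L0 exp(-k t) with L0 profiled out (NLI path).
fit_decay_free <- function(t, y, config) {
  L0_of <- function(k) {
    e <- exp(-k * t)
    sum(y * e) / sum(e^2)
  }
  obj <- function(k) {
    e <- exp(-k * t)
    L0 <- sum(y * e) / sum(e^2)
    sum((y - L0 * e)^2)
  }
  # init from log-linear regression
  pos <- y > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::cov(t[pos], log(y[pos])) / stats::var(t[pos])
    -sl
  } else 0.1
  k0 <- min(max(k0, config$k_bounds[1]), config$k_bounds[2])
  fit <- stats::nlminb(k0, obj, lower = config$k_bounds[1],
                       upper = config$k_bounds[2],
                       control = list(iter.max = config$max_iter,
                                      abs.tol = 0, rel.tol = config$tol,
                                      x.tol = 1e-12))
  list(k = fit$par, rss = fit$objective, L0 = L0_of(fit$par),
       converged = TRUE)
}

#' Fit k_loss for one RIA profile
#'
#' Minimizes `sum_t (RIA_t - exp(-k t))^2` over k with the intercept fixed at
#' `config$ria0 = 1`. Points at t = 0 are not used as data: the initial
#' condition is an assumption, not an observation. Initialization uses
#' `k0 = -log(max(RIA_last, 1e-6)) / t_last`.
#'
#' @param profile `data.frame` with columns `time_h` and `ria` (one
#'   precursor in one sample; replicate points at the same time are allowed).
#' @param config A [turnover_config()].
#' @return A list: `k_loss`, `rss`, `n_points` (positive-time points used),
#'   `converged`.
#' @export
fit_kloss_ria <- function(profile, config = turnover_config()) {
  use <- profile$time_h > 0
  t <- profile$time_h[use]
  y <- profile$ria[use] / config$ria0
  if (length(t) < 2) stop_format("profile has fewer than 2 positive-time points")
  fit <- fit_decay_fixed(t, y, config)
  list(k_loss = fit$k, rss = fit$rss, n_points = length(t),
       converged = fit$converged)
}

#' Fit k_loss for every precursor profile (RIA method)
#'
#' Builds RIA profiles, applies [filter_profiles()], and fits each retained
#' (sample, peptide, charge) profile.
#'
#' @param precursors Precursor table.
#' @param config A [turnover_config()].
#' @return A list with `estimates` (`data.frame`: sample_id, peptide, charge,
#'   k_loss, n_points, rss, weight, converged, method) and `exclusions`.
#' @export
fit_kloss_ria_all <- function(precursors, config = turnover_config()) {
  prof <- build_ria_profiles(precursors)
  flt <- filter_profiles(prof, config)
  dt <- data.table::as.data.table(flt$profiles)
  if (nrow(dt) == 0) {
    est <- data.frame(sample_id = character(), peptide = character(),
                      charge = integer(), k_loss = numeric(),
                      n_points = integer(), rss = numeric(),
                      weight = numeric(), converged = logical(),
                      method = character(), stringsAsFactors = FALSE)
    return(list(estimates = est, exclusions = flt$exclusions))
  }
  est <- dt[, {
    use <- time_h > 0
    fit <- fit_decay_fixed(time_h[use], ria[use] / config$ria0, config)
    list(k_loss = fit$k, n_points = sum(use), rss = fit$rss,
         weight = sum(total), converged = fit$converged)
  }, by = c("sample_id", "peptide", "charge")]
  est[, method := "RIA"]
  excl <- flt$exclusions
  bad <- est[converged == FALSE]
  if (nrow(bad) > 0) {
    excl <- rbind(excl, data.frame(sample_id = bad$sample_id,
                                   peptide = bad$peptide, charge = bad$charge,
                                   reason = "non_convergence"))
    est <- est[converged == TRUE]
  }
  list(estimates = as.data.frame(est), exclusions = excl)
}

#' Fit k_loss from normalized light-channel intensities (NLI method)
#'
#' Each run (a sample, time point, replicate combination) is rescaled so its
#' grand total heavy+light signal equals the median run total within the
#' sample; the light-channel decay `L_t = L0 * exp(-k t)` is then fitted per
#' precursor with L0 free, under the same profile filters as the RIA path
#' (at least two distinct positive times; endpoint light signal must fall).
#'
#' @param precursors Precursor table.
#' @param config A [turnover_config()].
#' @return As [fit_kloss_ria_all()], with `method = "NLI"` and an `L0`
#'   column.
#' @export
fit_kloss_nli_all <- function(precursors, config = turnover_config()) {
  dt <- data.table::as.data.table(precursors)
  dt <- dt[!is.na(intensity)]
  runs <- dt[, list(run_sum = sum(intensity)),
             by = c("sample_id", "time_h", "replicate")]
  runs[, run_factor := stats::median(run_sum) / run_sum, by = "sample_id"]
  dt <- merge(dt, runs, by = c("sample_id", "time_h", "replicate"),
              sort = FALSE)
  dt[, intensity := intensity * run_factor]
  light <- dt[channel == "light"]
  info <- light[, {
    tm <- sort(unique(time_h))
    per_time <- vapply(tm, function(x) mean(intensity[time_h == x]), 0)
    list(n_pos_times = length(unique(time_h[time_h > 0])),
         decaying = per_time[length(per_time)] < per_time[1])
  }, by = c("sample_id", "peptide", "charge")]
  info[, reason := data.table::fifelse(
    n_pos_times < 2, "single_time_point",
    data.table::fifelse(!decaying, "non_increasing_labeling", NA_character_))]
  excl <- as.data.frame(info[!is.na(reason),
                             c("sample_id", "peptide", "charge", "reason")])
  keep <- info[is.na(reason), c("sample_id", "peptide", "charge")]
  light <- merge(light, keep, by = c("sample_id", "peptide", "charge"),
                 sort = FALSE)
  if (nrow(light) == 0) {
    est <- data.frame(sample_id = character(), peptide = character(),
                      charge = integer(), k_loss = numeric(), L0 = numeric(),
                      n_points = integer(), rss = numeric(),
                      weight = numeric(), converged = logical(),
                      method = character(), stringsAsFactors = FALSE)
    return(list(estimates = est, exclusions = excl))
  }
  weights <- dt[, list(weight = sum(intensity)),
                by = c("sample_id", "peptide", "charge")]
  est <- light[, {
    fit <- fit_decay_free(time_h, intensity, config)
    list(k_loss = fit$k, L0 = fit$L0, n_points = length(time_h),
         rss = fit$rss, converged = fit$converged)
  }, by = c("sample_id", "peptide", "charge")]
  est <- merge(est, weights, by = c("sample_id", "peptide", "charge"),
               sort = FALSE)
  est[, method := "NLI"]
  list(estimates = as.data.frame(est), exclusions = excl)
}

#' Fit k_loss per precursor by the RIA or NLI method
#'
#' @param precursors Precursor table.
#' @param config A [turnover_config()].
#' @param method `"RIA"` (isotope-ratio fit, intercept fixed at 1) or
#'   `"NLI"` (normalized light-intensity fit, intercept free).
#' @return A list with `estimates` and `exclusions` (see
#'   [fit_kloss_ria_all()]).
#' @export
fit_kloss <- function(precursors, config = turnover_config(),
                      method = c("RIA", "NLI")) {
  method <- match.arg(method)
  if (method == "RIA") fit_kloss_ria_all(precursors, config)
  else fit_kloss_nli_all(precursors, config)
}

#' Aggregate precursor k_loss to peptide and AS-group level
#'
#' Precursor estimates are averaged to peptide level by a weighted mean
#' (weights per `config$weighting`). Only peptides with a k_loss in every
#' sample ("full profiles") enter cross-sample work. Peptide log2 k_loss is
#' summarized per group and sample by `config$group_summary` (median by
#' default); groups need at least `config$min_peptides_per_group` peptides.
#'
#' @param estimates Precursor estimates from [fit_kloss()].
#' @param group_map Peptide-to-group map from [peptide_group_map()]
#'   (multi-gene peptides must already be absent, as
#'   [assemble_as_groups()] guarantees).
#' @param config A [turnover_config()].
#' @param samples Character vector of samples a full profile must cover
#'   (default: every sample present in `estimates`).
#' @return A list with `peptide` (sample_id, peptide, k_loss, n_precursors),
#'   `full_peptides` (character vector), `group` (group_id, sample_id,
#'   log2_kloss, n_peptides), and `exclusions`.
#' @export
aggregate_kloss <- function(estimates, group_map,
                            config = turnover_config(),
                            samples = NULL) {
  dt <- data.table::as.data.table(estimates)
  samples <- samples %||% sort(unique(dt$sample_id))
  if (config$weighting == "equal") dt[, weight := 1]
  pep <- dt[, list(k_loss = sum(k_loss * weight) / sum(weight),
                   n_precursors = .N),
            by = c("sample_id", "peptide")]
  cover <- pep[, list(n_samples = sum(unique(sample_id) %in% samples)),
               by = "peptide"]
  full <- cover$peptide[cover$n_samples == length(samples)]
  not_full <- setdiff(cover$peptide, full)
  excl <- data.frame(sample_id = rep(NA_character_, length(not_full)),
                     peptide = not_full,
                     charge = rep(NA_integer_, length(not_full)),
                     reason = rep("not_full_profile", length(not_full)),
                     stringsAsFactors = FALSE)
  gm <- data.table::as.data.table(group_map)
  pep_full <- merge(pep[peptide %in% full], gm[, c("peptide", "group_id")],
                    by = "peptide")
  summ <- if (config$group_summary == "median") stats::median else mean
  grp <- pep_full[, list(log2_kloss = summ(log2(k_loss)),
                         n_peptides = length(unique(peptide))),
                  by = c("group_id", "sample_id")]
  n_pep <- grp[, list(n = max(n_peptides)), by = "group_id"]
  small <- n_pep$group_id[n_pep$n < config$min_peptides_per_group]
  if (length(small) > 0) {
    excl <- rbind(excl,
                  data.frame(sample_id = rep(NA_character_, length(small)),
                             peptide = small,
                             charge = rep(NA_integer_, length(small)),
                             reason = rep("insufficient_peptides", length(small)),
                             stringsAsFactors = FALSE))
    grp <- grp[!group_id %in% small]
  }
  data.table::setorder(grp, group_id, sample_id)
  list(peptide = as.data.frame(pep), full_peptides = sort(full),
       group = as.data.frame(grp), exclusions = excl)
}

#' Degradation rate from loss rate and cell-division rate
#'
#' `k_deg = k_loss - k_cd`. Negative results (label recycling or measurement
#' artifacts) are returned but flagged.
#'
#' @param k_loss Numeric vector of loss rates (per hour).
#' @param k_cd Cell-division rate(s), recycled against `k_loss`.
#' @return `data.frame` with `k_deg` and logical `flagged_negative`.
#' @export
kdeg_from_kloss <- function(k_loss, k_cd) {
  stopifnot(all(k_cd >= 0))
  k_deg <- k_loss - k_cd
  data.frame(k_deg = k_deg, flagged_negative = k_deg < 0)
}

#' Cell-division rate from culture doubling time
#'
#' @param doubling_time_h Doubling time in hours.
#' @return `k_cd = ln(2) / doubling_time_h`, in per hour.
#' @export
kcd_from_doubling_time <- function(doubling_time_h) {
  stopifnot(all(doubling_time_h > 0))
  log(2) / doubling_time_h
}
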