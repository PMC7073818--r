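# Correlation and differential statistics on the joined omics matrix:
# absolute (across-gene, sample-averaged) and relative (fold-change)
# Spearman correlations, per-group correlations with a t-approximation
# p-value and the matching critical-rho significance cut, CV quintile
# summaries, and the two-group / multi-isoform differential tests.

OMICS_PAIRS <- c("mRNA_kloss", "mRNA_protein", "protein_kloss")

#' @noRd
layers_for_pair <- function(pair) {
  lut <- c(mRNA = "log2_fpkm", protein = "log2_protein", kloss = "log2_kloss")
  parts <- strsplit(pair, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% names(lut)))
    stop_config("pair must be one of: ", paste(OMICS_PAIRS, collapse = ", "))
  unname(lut[parts])
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of the average-tie ranks; the two-sided
#' p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom (the convention behind the printed critical value 0.576 at
#' n = 12). An exact permutation p-value is available for small n.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @param exact If `TRUE`, compute the p-value by full enumeration of
#'   permutations (only feasible for n <= 8).
#' @return A list: `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_config("spearman_test needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 8) stop_config("exact permutation p only supported for n <= 8")
    perms <- permn_all(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(ix) stats::cor(rank(x), ry[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' @noRd
permn_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permn_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Critical Spearman rho for a two-sided test
#'
#' The smallest |rho| significant at level `alpha` for `n` pairs under the
#' t-approximation: `rho_c = sqrt(t_c^2 / (n - 2 + t_c^2))` with `t_c` the
#' two-sided critical t on n - 2 degrees of freedom. At n = 12,
#' alpha = 0.05 this is 0.576.
#'
#' @param n Number of pairs.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |rho|.
#' @export
critical_rho <- function(n, alpha = 0.05) {
  stopifnot(n > 2, alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  sqrt(tc^2 / (n - 2 + tc^2))
}

#' Absolute (across-gene) correlation
#'
#' Each layer is averaged across samples per AS group; the Spearman
#' correlation is then computed across groups.
#'
#' @param om An `omics_matrix` (complete rows are used; see
#'   [correlation_ready()]).
#' @param pair One of `"mRNA_kloss"`, `"mRNA_protein"`, `"protein_kloss"`.
#' @return A list: `rho`, `p`, `n` (groups used).
#' @export
absolute_correlation <- function(om, pair = "mRNA_kloss") {
  ly <- layers_for_pair(pair)
  cr <- correlation_ready(om)
  if (nrow(cr$rows) < 3) stop_config("need at least 3 complete AS groups")
  spearman_test(rowMeans(cr[[ly[1]]]), rowMeans(cr[[ly[2]]]))
}

#' Relative (fold-change) correlation between two conditions
#'
#' Per AS group and layer, the log2 fold change is the mean over condition-A
#' samples minus the mean over condition-B samples; the Spearman correlation
#' is computed across groups on the fold-change pairs.
#'
#' @param om An `omics_matrix`.
#' @param condition_labels Named character vector mapping sample id to
#'   condition; exactly two conditions.
#' @param pair See [absolute_correlation()].
#' @return A list: `rho`, `p`, `n`, and the per-group fold changes (`fc`).
#' @export
relative_correlation <- function(om, condition_labels, pair = "mRNA_kloss") {
  ly <- layers_for_pair(pair)
  cr <- correlation_ready(om)
  samples <- colnames(cr$log2_protein)
  cl <- condition_labels[samples]
  conds <- sort(unique(cl))
  if (length(conds) != 2)
    stop_config("relative_correlation needs exactly two conditions")
  fc_of <- function(mat) {
    rowMeans(mat[, cl == conds[1], drop = FALSE]) -
      rowMeans(mat[, cl == conds[2], drop = FALSE])
  }
  fx <- fc_of(cr[[ly[1]]]); fy <- fc_of(cr[[ly[2]]])
  if (length(fx) < 3) stop_config("need at least 3 complete AS groups")
  c(spearman_test(fx, fy),
    list(fc = data.frame(group_id = rownames(cr$log2_protein),
                         fc_x = fx, fc_y = fy, stringsAsFactors = FALSE)))
}

#' Per-AS-group correlation across samples
#'
#' For each AS group the per-sample (x, y) pairs of the chosen layers give a
#' group-specific Spearman rho with a two-sided t-approximation p-value.
#' Groups with a constant layer are flagged (`rho = NA`).
#'
#' @param om An `omics_matrix`.
#' @param pair See [absolute_correlation()].
#' @return `data.frame`: `group_id`, `pair`, `rho`, `p`, `n`.
#' @export
per_group_correlation <- function(om, pair = "mRNA_kloss") {
  ly <- layers_for_pair(pair)
  cr <- correlation_ready(om)
  x <- cr[[ly[1]]]; y <- cr[[ly[2]]]
  res <- lapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(y[i, ]) == 0)
      return(list(rho = NA_real_, p = NA_real_, n = ncol(x)))
    spearman_test(x[i, ], y[i, ])
  })
  data.frame(group_id = rownames(x), pair = pair,
             rho = vapply(res, `[[`, 0, "rho"),
             p = vapply(res, `[[`, 0, "p"),
             n = vapply(res, function(r) as.integer(r$n), 0L),
             stringsAsFactors = FALSE)
}

#' CV quintile analysis of protein variability against correlation strength
#'
#' AS groups are ordered by their per-group rho (ties broken by group id) and
#' split into five equal-count segments Q1..Q5. Per group the coefficient of
#' variation of the linear-scale protein intensities across samples is
#' computed; segments are compared by a Kruskal-Wallis omnibus test and
#' BH-corrected pairwise Wilcoxon tests.
#'
#' @param om An `omics_matrix`.
#' @param correlations Output of [per_group_correlation()].
#' @return A list: `groups` (group_id, rho, cv, quintile), `summary`
#'   (per-quintile n and median CV), `kruskal_p`, `pairwise_p` (matrix).
#' @export
cv_quintile_analysis <- function(om, correlations) {
  cr <- correlation_ready(om)
  dat <- merge(data.frame(group_id = rownames(cr$log2_protein),
                          stringsAsFactors = FALSE),
               correlations[!is.na(correlations$rho),
                            c("group_id", "rho")], by = "group_id")
  if (nrow(dat) < 5) stop_config("need at least 5 groups with correlations")
  lin <- 2^cr$log2_protein[dat$group_id, , drop = FALSE]
  dat$cv <- apply(lin, 1, function(v) stats::sd(v) / mean(v))
  ord <- order(dat$rho, dat$group_id)   # stable tie-break on group id
  dat <- dat[ord, ]
  dat$quintile <- paste0("Q", ceiling(seq_len(nrow(dat)) * 5 / nrow(dat)))
  kw <- stats::kruskal.test(dat$cv, factor(dat$quintile))
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(dat$cv, factor(dat$quintile),
                                p.adjust.method = "BH"))
  agg <- stats::aggregate(cv ~ quintile, dat,
                          function(v) c(n = length(v), median = stats::median(v)))
  summary <- data.frame(quintile = agg$quintile,
                        n = as.integer(agg$cv[, "n"]),
                        median_cv = agg$cv[, "median"],
                        stringsAsFactors = FALSE)
  list(groups = dat, summary = summary,
       kruskal_p = unname(kw$p.value), pairwise_p = pw$p.value)
}

#' Two-group differential test with BH correction
#'
#' Per key, a two-sided two-sample t-test on log2 values between the two
#' conditions; p-values are Benjamini-Hochberg corrected across keys. The
#' log2 fold change is mean(A) - mean(B) with conditions in sorted order.
#'
#' @param values `data.frame` with columns `key`, `condition`, `value`
#'   (log2 scale), at least two values per condition per key.
#' @return `data.frame`: `key`, `log2_fc`, `p`, `q`, `test`, `flagged`.
#' @export
differential_test <- function(values) {
  conds <- sort(unique(values$condition))
  if (length(conds) != 2) stop_config("differential_test needs two conditions")
  dt <- data.table::as.data.table(values)
  res <- dt[, {
    a <- value[condition == conds[1]]
    b <- value[condition == conds[2]]
    if (length(a) < 2 || length(b) < 2)
      stop_config("key '", key[1], "' has fewer than 2 values per condition")
    flag <- stats::var(a) == 0 && stats::var(b) == 0
    p <- if (flag) NA_real_ else stats::t.test(a, b)$p.value
    list(log2_fc = mean(a) - mean(b), p = p, flagged = flag)
  }, by = "key"]
  res[, q := stats::p.adjust(p, method = "BH")]
  res[, test := "t_test"]
  as.data.frame(res[, c("key", "log2_fc", "p", "q", "test", "flagged")])
}

#' Differential degradation/expression between isoform groups of one gene
#'
#' For each gene with at least two detected AS groups (each contributing at
#' least `min_per_group` peptide-level values): two groups are compared by a
#' two-sided t-test; more than two by one-way ANOVA followed by Tukey HSD
#' pairwise comparisons. A gene is called differential only if some pairwise
#' comparison has p < `alpha` and |mean log2 difference| >= `lfc`.
#'
#' @param values `data.frame` with columns `gene_id`, `group_id`, `value`
#'   (one peptide-level log2 value per row).
#' @param min_per_group Minimum values per isoform group (default 2);
#'   singleton groups are dropped and logged.
#' @param alpha Pairwise significance level (default 0.05).
#' @param lfc Minimum |log2 difference| (default 0.32).
#' @return A list with `genes` (`gene_id`, `n_groups`, `p`, `max_abs_diff`,
#'   `called`, `test`), `pairs` (per pairwise comparison), and `excluded`
#'   (dropped singleton groups).
#' @export
isoform_differential <- function(values, min_per_group = 2L, alpha = 0.05,
                                 lfc = 0.32) {
  dt <- data.table::as.data.table(values)
  sizes <- dt[, list(n = .N), by = c("gene_id", "group_id")]
  drop <- sizes[n < min_per_group]
  dt <- dt[!paste(gene_id, group_id) %in% paste(drop$gene_id, drop$group_id)]
  genes <- list(); pairs <- list()
  for (g in unique(dt$gene_id)) {
    sub <- dt[gene_id == g]
    grps <- unique(sub$group_id)
    if (length(grps) < 2) next
    if (length(grps) == 2) {
      a <- sub$value[sub$group_id == grps[1]]
      b <- sub$value[sub$group_id == grps[2]]
      p <- stats::t.test(a, b)$p.value
      d <- mean(a) - mean(b)
      pr <- data.frame(gene_id = g,
                       comparison = paste(grps[1], grps[2], sep = " vs "),
                       diff = d, p = p, stringsAsFactors = FALSE)
      omni <- p; test <- "t_test"
    } else {
      fit <- stats::aov(value ~ group_id, data = sub)
      omni <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$group_id
      pr <- data.frame(gene_id = g, comparison = rownames(tk),
                       diff = tk[, "diff"], p = tk[, "p adj"],
                       stringsAsFactors = FALSE)
      test <- "anova_tukey"
    }
    called <- any(pr$p < alpha & abs(pr$diff) >= lfc)
    genes[[g]] <- data.frame(gene_id = g, n_groups = length(grps), p = omni,
                             max_abs_diff = max(abs(pr$diff)),
                             called = called, test = test,
                             stringsAsFactors = FALSE)
    pairs[[g]] <- pr
  }
  empty_genes <- data.frame(gene_id = character(), n_groups = integer(),
                            p = numeric(), max_abs_diff = numeric(),
                            called = logical(), test = character(),
                            stringsAsFactors = FALSE)
  empty_pairs <- data.frame(gene_id = character(), comparison = character(),
                            diff = numeric(), p = numeric(),
                            stringsAsFactors = FALSE)
  g_out <- if (length(genes)) do.call(rbind, genes) else empty_genes
  p_out <- if (length(pairs)) do.call(rbind, pairs) else empty_pairs
  rownames(g_out) <- rownames(p_out) <- NULL
  list(genes = g_out, pairs = p_out, excluded = as.data.frame(drop))
}
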