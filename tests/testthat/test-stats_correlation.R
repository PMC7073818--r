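# Correlation machinery, CV quintiles, differential tests.

make_om <- function(prot, kl, fpkm, class = "UQ") {
  gids <- rownames(prot)
  structure(list(
    log2_protein = prot, log2_kloss = kl, log2_fpkm = fpkm,
    rows = data.frame(group_id = gids, gene_id = gids, class = class,
                      representative_transcript = gids,
                      stringsAsFactors = FALSE)),
    class = "omics_matrix")
}

test_that("spearman_test matches the rank-then-Pearson oracle incl. ties", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- sample(round(rnorm(n), 1))  # rounding induces ties
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # exact permutation p: only identity and reversal reach |rho| = 1
  r <- spearman_test(1:6, 2 * (1:6), exact = TRUE)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 2 / factorial(6))
  r2 <- spearman_test(1:6, c(2, 1, 4, 3, 6, 5), exact = TRUE)
  expect_equal(r2$rho, oracle_spearman(1:6, c(2, 1, 4, 3, 6, 5)))
  expect_lt(r2$p, 0.1)
})

test_that("the critical rho reproduces the printed n = 12 threshold", {
  expect_equal(critical_rho(12), 0.576, tolerance = 1e-3)
  # derived threshold at n = 10 via rho = sqrt(t^2 / (n - 2 + t^2)), df = 8
  tc <- qt(0.975, 8)
  expect_equal(critical_rho(10), sqrt(tc^2 / (8 + tc^2)))
  expect_equal(critical_rho(10), 0.632, tolerance = 1e-3)
  # decreasing in n, increasing as alpha shrinks
  ns <- 5:50
  expect_true(all(diff(vapply(ns, critical_rho, 0)) < 0))
  expect_gt(critical_rho(12, 0.01), critical_rho(12, 0.05))
})

test_that("absolute correlation hits +/-1 on monotone layers and a hand-ranked table", {
  prot <- matrix(c(1, 2, 3, 4, 5, 1.1, 2.1, 3.1, 4.1, 5.1), 5, 2,
                 dimnames = list(paste0("T", 1:5), c("S1", "S2")))
  mono <- exp(prot)          # strictly monotone transform
  rev_ <- -prot              # reversed ranks
  om1 <- make_om(prot, mono, prot)
  expect_equal(absolute_correlation(om1, "protein_kloss")$rho, 1)
  om2 <- make_om(prot, rev_, prot)
  expect_equal(absolute_correlation(om2, "protein_kloss")$rho, -1)

  # 5-row worked table with a tie: hand-computed average-rank arithmetic
  x <- c(3.2, 1.1, 4.8, 1.1, 2.0)   # ranks 4, 1.5, 5, 1.5, 3
  y <- c(10, 30, 20, 50, 40)        # ranks 1, 3, 2, 5, 4
  rx <- c(4, 1.5, 5, 1.5, 3); ry <- c(1, 3, 2, 5, 4)
  hand <- sum((rx - 3) * (ry - 3)) / sqrt(sum((rx - 3)^2) * sum((ry - 3)^2))
  as_col <- function(v) matrix(v, ncol = 1,
                               dimnames = list(paste0("T", seq_along(v)), "S1"))
  om3 <- make_om(as_col(x), as_col(y), as_col(x))
  expect_equal(absolute_correlation(om3, "protein_kloss")$rho, hand)
})

test_that("relative correlation works on fold changes and a permuted null is centered", {
  set.seed(42)
  n <- 60
  a <- matrix(rnorm(n * 3, 10), n, 3)
  fc <- rnorm(n, 0, 1)
  b <- a - fc                      # planted identical FC in both layers
  prot <- cbind(a, b)
  colnames(prot) <- c(paste0("A", 1:3), paste0("B", 1:3))
  rownames(prot) <- paste0("T", 1:n)
  kl <- prot + rnorm(n * 6, 0, 1e-9)
  om <- make_om(prot, kl, prot)
  cond <- setNames(rep(c("A", "B"), each = 3), colnames(prot))
  r <- relative_correlation(om, cond, "protein_kloss")
  expect_equal(r$rho, 1, tolerance = 1e-6)
  expect_equal(r$n, n)

  # permuting one layer's rows gives a null centered at 0
  rhos <- replicate(50, {
    perm <- sample(n)
    om_p <- make_om(prot, kl[perm, , drop = FALSE] |>
                      `rownames<-`(rownames(prot)), prot)
    relative_correlation(om_p, cond, "protein_kloss")$rho
  })
  expect_lt(abs(median(rhos)), 0.15)
})

test_that("per-group correlation flags constant rows and finds monotone ones", {
  prot <- rbind(T1 = 1:6, T2 = rep(2, 6), T3 = c(2, 1, 4, 3, 6, 5))
  colnames(prot) <- paste0("S", 1:6)
  kl <- rbind(T1 = 2 * (1:6), T2 = 1:6, T3 = 1:6)
  colnames(kl) <- paste0("S", 1:6)
  om <- make_om(prot, kl, prot)
  pg <- per_group_correlation(om, "protein_kloss")
  expect_equal(pg$rho[pg$group_id == "T1"], 1)
  expect_lt(pg$p[pg$group_id == "T1"], 1e-6)
  expect_true(is.na(pg$rho[pg$group_id == "T2"]))
  expect_equal(pg$n, rep(6L, 3))
})

test_that("CV quintiles partition evenly and detect planted noise structure", {
  set.seed(5)
  n <- 10
  prot <- matrix(rnorm(n * 4, 10, 0.1), n, 4,
                 dimnames = list(paste0("T", 1:n), paste0("S", 1:4)))
  om <- make_om(prot, prot, prot)
  corr <- data.frame(group_id = paste0("T", 1:n), pair = "mRNA_kloss",
                     rho = seq(-1, 1, length.out = n), p = 0.5, n = 4L,
                     stringsAsFactors = FALSE)
  res <- cv_quintile_analysis(om, corr)
  expect_equal(res$summary$n, rep(2L, 5))  # 10 groups -> 2 per quintile
  expect_true(all(res$groups$cv >= 0))

  # constant profile -> CV 0
  prot0 <- matrix(10, 5, 4, dimnames = list(paste0("T", 1:5), paste0("S", 1:4)))
  om0 <- make_om(prot0, prot0, prot0)
  corr0 <- data.frame(group_id = paste0("T", 1:5), pair = "mRNA_kloss",
                      rho = seq(-1, 1, length.out = 5), p = 0.5, n = 4L)
  res0 <- cv_quintile_analysis(om0, corr0)
  expect_true(all(res0$groups$cv == 0))

  # high-|rho| groups built with half the noise SD end up with lower CV
  set.seed(11)
  n2 <- 200
  rho2 <- seq(-0.99, 0.99, length.out = n2)
  noise_sd <- ifelse(rho2 > 0.6, 0.05, 0.1)  # strong positive rho: half the noise
  lin <- t(vapply(noise_sd, function(s) rlnorm(12, log(1000), s),
                  numeric(12)))
  prot2 <- log2(lin)
  dimnames(prot2) <- list(paste0("T", 1:n2), paste0("S", 1:12))
  om2 <- make_om(prot2, prot2, prot2)
  corr2 <- data.frame(group_id = paste0("T", 1:n2), pair = "mRNA_kloss",
                      rho = rho2, p = 0.5, n = 12L)
  res2 <- cv_quintile_analysis(om2, corr2)
  s <- res2$summary
  expect_lt(s$median_cv[s$quintile == "Q5"], s$median_cv[s$quintile == "Q1"])
  expect_lt(res2$kruskal_p, 0.05)
})

test_that("the two-group t-test pipeline reports fold changes and BH q-values", {
  vals <- data.frame(
    key = rep(c("P1", "P2"), each = 6),
    condition = rep(rep(c("A", "B"), each = 3), 2),
    value = c(1, 1.1, 0.9, 1, 1.1, 0.9,        # identical groups
              5, 5.1, 4.9, 4, 4.1, 3.9),       # planted 1 log2 unit shift
    stringsAsFactors = FALSE)
  res <- differential_test(vals)
  expect_equal(res$log2_fc[res$key == "P1"], 0)
  expect_equal(res$log2_fc[res$key == "P2"], 1)
  expect_lt(res$q[res$key == "P2"], 0.05)
  expect_true(all(res$q >= res$p))

  # planted 2-fold shift, n = 6 vs 6, low noise -> q < 0.01
  set.seed(9)
  many <- do.call(rbind, lapply(1:20, function(i) {
    shift <- if (i <= 5) 1 else 0
    data.frame(key = sprintf("K%02d", i),
               condition = rep(c("A", "B"), each = 6),
               value = c(rnorm(6, 10 + shift, 0.1), rnorm(6, 10, 0.1)),
               stringsAsFactors = FALSE)
  }))
  res2 <- differential_test(many)
  expect_true(all(res2$q[res2$key %in% sprintf("K%02d", 1:5)] < 0.01))

  # zero variance in both groups is flagged, not crashed
  flat <- data.frame(key = "P", condition = rep(c("A", "B"), each = 2),
                     value = c(1, 1, 2, 2), stringsAsFactors = FALSE)
  resf <- differential_test(flat)
  expect_true(resf$flagged)
  expect_true(is.na(resf$p))
})

test_that("BH correction reproduces the worked step-up example", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  q <- differential_test(data.frame(
    key = rep(paste0("P", 1:2), each = 4),
    condition = rep(rep(c("A", "B"), each = 2), 2),
    value = c(1, 1.2, 3, 3.1, 2, 2.2, 2.1, 2.3)))$q
  expect_true(all(q >= 0 & q <= 1))
})

test_that("isoform differential calls require both p and fold-change gates", {
  # two isoforms with identical peptide values: never called
  same <- data.frame(gene_id = "G1",
                     group_id = rep(c("T1", "T2"), each = 3),
                     value = rep(c(1, 1.01, 0.99), 2))
  expect_false(isoform_differential(same)$genes$called)

  # |log2 difference| 0.30 with tiny p: blocked by the 0.32 gate
  gated <- data.frame(gene_id = "G1",
                      group_id = rep(c("T1", "T2"), each = 4),
                      value = c(rnorm(4, 1, 0.001), rnorm(4, 1.30, 0.001)))
  res <- isoform_differential(gated)
  expect_lt(res$genes$p, 0.001)
  expect_false(res$genes$called)

  # planted 1.5-fold split (0.585 log2) with tight noise: called
  set.seed(2)
  called <- data.frame(gene_id = "G1",
                       group_id = rep(c("T1", "T2"), each = 4),
                       value = c(rnorm(4, 1, 0.02), rnorm(4, 1 + log2(1.5), 0.02)))
  expect_true(isoform_differential(called)$genes$called)

  # three isoform groups go through ANOVA + Tukey
  set.seed(3)
  tri <- data.frame(gene_id = "G1",
                    group_id = rep(c("T1", "T2", "T3"), each = 4),
                    value = c(rnorm(4, 1, 0.02), rnorm(4, 1, 0.02),
                              rnorm(4, 2, 0.02)))
  res3 <- isoform_differential(tri)
  expect_equal(res3$genes$test, "anova_tukey")
  expect_true(res3$genes$called)
  expect_equal(nrow(res3$pairs), 3)

  # singleton isoform groups are excluded and logged
  single <- data.frame(gene_id = "G1",
                       group_id = c("T1", "T1", "T2"),
                       value = c(1, 1.1, 5))
  resx <- isoform_differential(single)
  expect_equal(nrow(resx$genes), 0)
  expect_equal(resx$excluded$group_id, "T2")
})
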