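# Protein matrix assembly and the three-layer join.

test_that("replicate medians require two quantified injections", {
  pint <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S1", "S1", "S2"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L, 1L),
    peptide = c(rep("AAAAAAK", 4), rep("CCCCCCK", 3)),
    intensity = c(1000, 1200, 900, 1000, 1000, 1200, 500),
    stringsAsFactors = FALSE)
  gm <- data.frame(peptide = c("AAAAAAK", "CCCCCCK"),
                   group_id = c("T1", "T2"), gene_id = "G1",
                   class = "UQ", stringsAsFactors = FALSE)
  res <- assemble_protein_matrix(pint, gm,
                                 assembly_config(min_peptides_per_group = 1))
  # {1000, 1200, missing third injection}: median of the two observed values
  expect_equal(res$peptide_matrix["AAAAAAK", "S1"], log2(1100))
  # one replicate only in S2: the value is dropped, so no full profile
  expect_true("CCCCCCK@S2" %in%
                res$exclusions$key[res$exclusions$reason ==
                                     "insufficient_replicates"])
  expect_true("CCCCCCK" %in%
                res$exclusions$key[res$exclusions$reason == "not_full_profile"])
  expect_equal(rownames(res$matrix), "T1")
})

test_that("groups sum member peptides in linear space then log2", {
  pint <- expand.grid(sample_id = "S1", replicate = 1:2,
                      peptide = c("AAAAAAK", "CCCCCCK"),
                      stringsAsFactors = FALSE)
  pint$replicate <- as.integer(pint$replicate)
  pint$intensity <- c(100, 100, 300, 300)
  gm <- data.frame(peptide = c("AAAAAAK", "CCCCCCK"), group_id = "T1",
                   gene_id = "G1", class = "UQ", stringsAsFactors = FALSE)
  res <- assemble_protein_matrix(pint, gm)
  expect_equal(res$matrix["T1", "S1"], log2(400))
  # literal sum-of-logs convention behind the config switch
  res2 <- assemble_protein_matrix(pint, gm, assembly_config(collapse = "sum_log"))
  expect_equal(res2$matrix["T1", "S1"], log2(100) + log2(300))
})

omics_fixture <- function() {
  samples <- c("S1", "S2")
  prot <- matrix(c(10, 11, 12, 13), 2, 2,
                 dimnames = list(c("T7", "T1+T2"), samples))
  kl <- data.frame(group_id = rep(c("T7", "T1+T2"), each = 2),
                   sample_id = rep(samples, 2),
                   log2_kloss = c(-3, -2.5, -4, -4.4),
                   n_peptides = 2L, stringsAsFactors = FALSE)
  vals <- rbind(T7 = c(8, 8), T1 = c(16, 12), T2 = c(2, 2))
  colnames(vals) <- samples
  groups <- data.frame(
    group_id = c("T7", "T1+T2"), gene_id = c("G7", "G1"),
    class = c("UQ", "SM"),
    representative_transcript = c("T7", "T1"),
    member_transcripts = c("T7", "T1;T2"),
    n_peptides = 2L, peptides = "X", stringsAsFactors = FALSE)
  list(prot = prot, kl = kl, ex = make_expr(vals), groups = groups)
}

test_that("the join maps UQ and SM rows to the right transcript FPKM", {
  f <- omics_fixture()
  om <- join_omics(f$prot, f$kl, f$ex, f$groups)
  # UQ group of T7, FPKM 8 -> log2 = 3
  expect_equal(om$log2_fpkm["T7", "S1"], 3)
  # SM group uses the major transcript T1 (16), not T2 (2)
  expect_equal(om$log2_fpkm["T1+T2", "S1"], 4)
  expect_equal(om$log2_kloss["T7", "S2"], -2.5)
  expect_equal(nrow(correlation_ready(om)$rows), 2)

  # a row missing k_loss in one sample drops from the correlation-ready view
  f2 <- omics_fixture()
  f2$kl <- f2$kl[-2, ]
  om2 <- join_omics(f2$prot, f2$kl, f2$ex, f2$groups)
  expect_equal(rownames(correlation_ready(om2)$log2_protein), "T1+T2")

  # unknown representative transcript is an error
  f3 <- omics_fixture()
  f3$groups$representative_transcript[1] <- "TX"
  expect_error(join_omics(f3$prot, f3$kl, f3$ex, f3$groups), "TX",
               class = "pk_format_error")
})

test_that("complete-row count matches a brute-force recount and columns permute", {
  set.seed(8)
  samples <- paste0("S", 1:4)
  gids <- paste0("T", 1:12)
  prot <- matrix(rnorm(48, 10), 12, 4, dimnames = list(gids, samples))
  kl <- expand.grid(group_id = gids, sample_id = samples,
                    stringsAsFactors = FALSE)
  kl$log2_kloss <- rnorm(48, -3)
  kl$n_peptides <- 2L
  kl <- kl[-sample(48, 5), ]  # knock out some k_loss cells
  vals <- matrix(rlnorm(48, 2), 12, 4, dimnames = list(gids, samples))
  groups <- data.frame(group_id = gids, gene_id = gids, class = "UQ",
                       representative_transcript = gids,
                       member_transcripts = gids, n_peptides = 2L,
                       peptides = "X", stringsAsFactors = FALSE)
  om <- join_omics(prot, kl, make_expr(vals), groups)
  cr <- correlation_ready(om)
  # brute-force recount of rows complete in all three layers
  want <- sum(vapply(gids, function(g) {
    all(!is.na(om$log2_protein[g, ])) && all(!is.na(om$log2_kloss[g, ])) &&
      all(!is.na(om$log2_fpkm[g, ]))
  }, TRUE))
  expect_equal(nrow(cr$rows), want)
  # independent recount from the knocked-out k_loss table itself
  expect_equal(want, sum(tapply(kl$sample_id, kl$group_id, length)[gids] == 4,
                         na.rm = TRUE))

  # permuting sample columns permutes the output identically
  perm <- c("S3", "S1", "S4", "S2")
  om_p <- join_omics(prot[, perm], kl, make_expr(vals[, perm]), groups)
  expect_equal(om_p$log2_protein, om$log2_protein[, perm])
  expect_equal(om_p$log2_kloss, om$log2_kloss[, perm])
  expect_equal(om_p$log2_fpkm, om$log2_fpkm[, perm])
})

test_that("peptide intensities average total signal over times and charges", {
  prec <- data.frame(
    sample_id = "S1", replicate = 1L,
    time_h = c(0, 0, 1, 1),
    peptide = "AAAAAAK", charge = 2L,
    channel = c("light", "heavy", "light", "heavy"),
    intensity = c(1000, NA, 600, 400), stringsAsFactors = FALSE)
  pint <- peptide_intensity_table(prec)
  expect_equal(pint$intensity, 1000)  # (1000 + 1000)/2
})
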