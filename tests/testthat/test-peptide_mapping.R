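# Digestion, peptide classification, AS-group assembly.

test_that("tryptic digestion matches the cleavage rule", {
  # worked example: cleave after K2 and R6; "MK" dropped by min_length
  expect_setequal(digest("MKAAARCCCK",
                         digest_config(missed_cleavages = 0, min_length = 3,
                                       max_length = 30)),
                  c("AAAR", "CCCK"))
  # no cleavage before proline
  expect_equal(digest("AKPR", digest_config(0, 1, 30)), "AKPR")
  # missed cleavages are nested supersets
  seqs <- vapply(1:20, function(i) {
    set.seed(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                 replace = TRUE), collapse = "")
  }, "")
  for (s in seqs) {
    d0 <- digest(s, digest_config(0, 5, 30))
    d2 <- digest(s, digest_config(2, 5, 30))
    expect_true(all(d0 %in% d2))
  }
  expect_error(digest("MKXXB"), class = "pk_format_error")
})

test_that("digestion agrees with a brute-force substring oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                      replace = TRUE,
                      prob = c(rep(1, 8), 2, rep(1, 5), 2, rep(1, 5))),
               collapse = "")
    mc <- sample(0:2, 1)
    expect_setequal(digest(s, digest_config(mc, 5, 25)),
                    oracle_digest(s, mc, 5, 25))
  }
})

test_that("peptides classify as unique / shared / multi-gene", {
  tx <- data.frame(gene_id = c("G1", "G1", "G2"),
                   transcript_id = c("G1.T1", "G1.T2", "G2.T5"),
                   biotype = "protein_coding",
                   protein_sequence = "M",
                   stringsAsFactors = FALSE)
  pmap <- data.frame(
    peptide = c("AAAAAAK", "CCCCCCK", "CCCCCCK", "DDDDDDK", "DDDDDDK"),
    transcript_id = c("G1.T1", "G1.T1", "G1.T2", "G1.T1", "G2.T5"),
    stringsAsFactors = FALSE)
  cls <- classify_peptides(pmap, tx)
  expect_equal(cls$class[cls$peptide == "AAAAAAK"], "unique")
  expect_equal(cls$class[cls$peptide == "CCCCCCK"], "shared")
  expect_equal(cls$class[cls$peptide == "DDDDDDK"], "multi_gene")
  # multi-gene peptides never reach a group
  vals <- matrix(c(10, 3, 1), 3, 1,
                 dimnames = list(c("G1.T1", "G1.T2", "G2.T5"), "S1"))
  groups <- assemble_as_groups(cls, make_expr(vals))
  expect_false("DDDDDDK" %in% unlist(strsplit(groups$peptides, ";")))
})

test_that("group representative is the mRNA-major transcript with lexicographic ties", {
  cls <- data.frame(
    peptide = c("AAAAAAK", "CCCCCCK"),
    transcript_ids = c("T1;T2", "T5;T6"),
    gene_ids = c("G1", "G2"),
    class = "shared", stringsAsFactors = FALSE)
  vals <- rbind(T1 = c(12, 8), T2 = c(2, 4), T5 = c(5, 5), T6 = c(5, 5))
  colnames(vals) <- c("S1", "S2")
  groups <- assemble_as_groups(cls, make_expr(vals))
  expect_equal(groups$representative_transcript[groups$group_id == "T1+T2"],
               "T1")   # mean 10 beats mean 3
  expect_equal(groups$representative_transcript[groups$group_id == "T5+T6"],
               "T5")   # exact tie -> lexicographically smallest
  expect_true(all(groups$class == "SM"))
})

test_that("UQ groups carry their single transcript as representative", {
  cls <- data.frame(peptide = c("AAAAAAK", "CCCCCCK"),
                    transcript_ids = "T9", gene_ids = "G9",
                    class = "unique", stringsAsFactors = FALSE)
  vals <- matrix(4, 1, 1, dimnames = list("T9", "S1"))
  groups <- assemble_as_groups(cls, make_expr(vals))
  expect_equal(nrow(groups), 1)
  expect_equal(groups$class, "UQ")
  expect_equal(groups$representative_transcript, "T9")
  expect_equal(groups$n_peptides, 2L)
})

test_that("classification and majors match the brute-force oracle on toy transcriptomes", {
  for (seed in 1:40) {
    tx <- make_toy_transcriptome(seed)
    set.seed(seed + 1000)
    vals <- matrix(stats::rlnorm(nrow(tx) * 3, log(10), 1), ncol = 3,
                   dimnames = list(tx$transcript_id, paste0("S", 1:3)))
    ex <- make_expr(vals)
    got <- classify_peptides(digest_db(tx), tx)
    want <- oracle_classify(tx, tx)
    want <- want[order(want$peptide), ]
    rownames(want) <- NULL
    expect_equal(got, want)

    groups <- assemble_as_groups(got, ex)
    for (i in seq_len(nrow(groups))) {
      members <- strsplit(groups$member_transcripts[i], ";")[[1]]
      expect_equal(groups$representative_transcript[i],
                   oracle_major(members, ex))
      if (groups$class[i] == "UQ") expect_length(members, 1)
    }
  }
})

test_that("every non-multi-gene peptide lands in exactly one group; row order irrelevant", {
  tx <- make_toy_transcriptome(7)
  set.seed(7)
  vals <- matrix(stats::rlnorm(nrow(tx) * 2, log(10), 1), ncol = 2,
                 dimnames = list(tx$transcript_id, c("S1", "S2")))
  ex <- make_expr(vals)
  pmap <- digest_db(tx)
  cls <- classify_peptides(pmap, tx)
  groups <- assemble_as_groups(cls, ex)
  gm <- peptide_group_map(groups)
  keep <- cls$peptide[cls$class != "multi_gene"]
  expect_setequal(gm$peptide, keep)
  expect_equal(anyDuplicated(gm$peptide), 0L)

  # permuting input rows changes nothing
  set.seed(1)
  pmap2 <- pmap[sample(nrow(pmap)), ]
  groups2 <- assemble_as_groups(classify_peptides(pmap2, tx), ex)
  expect_equal(groups, groups2)
})
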