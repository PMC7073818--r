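# Synthetic-data generator: transcriptomes with multi-isoform genes (shared
# constitutive and isoform-specific protein segments), FPKM expression
# matrices for a two-condition multi-sample design, and pulsed-SILAC
# precursor quantity tables generated from steady-state label-incorporation
# kinetics with known ground-truth k_loss. Everything downstream is testable
# against the returned truth records.

#' Simulation configuration
#'
#' Defines the "stated world" of the generator: sample sizes, the label
#' time course, noise, missingness, and the buffering model that couples
#' per-sample degradation-rate variation to mRNA variation for a subset of
#' genes.
#'
#' @param n_genes Number of genes.
#' @param isoform_count_distribution Probabilities of a gene having 1..4
#'   isoforms (numeric vector of length 4, sums to 1).
#' @param ri_fraction Probability a non-primary isoform has biotype
#'   `retained_intron` (RI isoforms carry no protein sequence).
#' @param n_samples_per_condition Samples per condition; conditions are
#'   labeled `"A"` and `"B"` (default 6 each, mirroring a 12-cell-line panel).
#' @param n_replicates Replicate injections per sample (default 3).
#' @param time_points_h Labeling time points in hours, strictly increasing
#'   (default 0, 1, 4.5, 11).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on precursor intensities (default 0.1).
#' @param rna_noise_cv CV of the lognormal noise on replicate FPKM values
#'   (default 0.05).
#' @param missing_rate Probability an intensity observation is dropped
#'   (default 0.05).
#' @param buffered_fraction Fraction of genes whose per-sample log2 k_loss is
#'   coupled to their per-sample log2 mRNA deviation (default 0; see
#'   [plant_buffering()]).
#' @param buffering_alpha Coupling slope for buffered genes (default 0.8).
#' @param buffering_noise_sd SD (log2 units) of the residual per-sample
#'   k_loss variation (default 0.2), used for buffered and unbuffered genes.
#' @param sample_log2_sd SD (log2 units) of the gene-level per-sample mRNA
#'   deviation (default 0.5).
#' @param condition_log2fc_sd SD (log2 units) of the gene-level mRNA fold
#'   change between conditions (default 1).
#' @param kloss_range Range of true gene-level k_loss in per hour; base rates
#'   are log-uniform on this interval (default 0.02 to 0.6, spanning
#'   half-lives of roughly 1 to 35 h).
#' @param gene_fpkm_meanlog,gene_fpkm_sdlog Lognormal parameters of gene base
#'   FPKM (defaults log(20) and 1).
#' @param max_detected_peptides Maximum number of detected peptides sampled
#'   per isoform in the pSILAC table (default 4; DIA detects a subset of the
#'   theoretical digest).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       isoform_count_distribution = c(0.45, 0.30, 0.15, 0.10),
                       ri_fraction = 0.2,
                       n_samples_per_condition = 6,
                       n_replicates = 3,
                       time_points_h = c(0, 1, 4.5, 11),
                       noise_cv = 0.1,
                       rna_noise_cv = 0.05,
                       missing_rate = 0.05,
                       buffered_fraction = 0,
                       buffering_alpha = 0.8,
                       buffering_noise_sd = 0.2,
                       sample_log2_sd = 0.5,
                       condition_log2fc_sd = 1,
                       kloss_range = c(0.02, 0.6),
                       gene_fpkm_meanlog = log(20),
                       gene_fpkm_sdlog = 1,
                       max_detected_peptides = 4,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes,
    isoform_count_distribution = isoform_count_distribution,
    ri_fraction = ri_fraction,
    n_samples_per_condition = n_samples_per_condition,
    n_replicates = n_replicates,
    time_points_h = time_points_h,
    noise_cv = noise_cv,
    rna_noise_cv = rna_noise_cv,
    missing_rate = missing_rate,
    buffered_fraction = buffered_fraction,
    buffering_alpha = buffering_alpha,
    buffering_noise_sd = buffering_noise_sd,
    sample_log2_sd = sample_log2_sd,
    condition_log2fc_sd = condition_log2fc_sd,
    kloss_range = kloss_range,
    gene_fpkm_meanlog = gene_fpkm_meanlog,
    gene_fpkm_sdlog = gene_fpkm_sdlog,
    max_detected_peptides = max_detected_peptides,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  p <- cfg$isoform_count_distribution
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_config("isoform_count_distribution must be 4 non-negative ",
                "probabilities summing to 1")
  if (!is_count(cfg$n_genes)) stop_config("n_genes must be a non-negative count")
  if (!is_count(cfg$n_samples_per_condition, 1L) || !is_count(cfg$n_replicates, 1L))
    stop_config("n_samples_per_condition and n_replicates must be counts >= 1")
  if (any(diff(cfg$time_points_h) <= 0) || any(cfg$time_points_h < 0))
    stop_config("time_points_h must be non-negative and strictly increasing")
  for (f in c("ri_fraction", "missing_rate", "buffered_fraction"))
    if (!is_prob(cfg[[f]])) stop_config(f, " must be a probability in [0,1]")
  if (cfg$noise_cv < 0 || cfg$rna_noise_cv < 0)
    stop_config("noise CVs must be non-negative")
  if (length(cfg$kloss_range) != 2 || any(cfg$kloss_range <= 0) ||
      diff(cfg$kloss_range) < 0)
    stop_config("kloss_range must be positive and increasing")
  cfg
}

#' @noRd
#' Random amino-acid string; K/R boosted to ~11% combined so tryptic
#' peptides have realistic lengths.
random_protein_segment <- function(n) {
  w <- rep(1, length(AA_ALPHABET))
  names(w) <- AA_ALPHABET
  w[c("K", "R")] <- 1.17  # ~11% combined among 20 residues
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

#' Simulate a multi-isoform transcriptome with expression and turnover truth
#'
#' Generates per-gene isoform sets whose protein sequences share constitutive
#' segments (so shared peptides arise) and carry isoform-specific segments
#' (so unique peptides arise); non-primary isoforms are `retained_intron`
#' with probability `ri_fraction`. The first isoform of each gene is always
#' protein-coding and dominant in FPKM. Samples split into two conditions
#' "A"/"B"; gene-level mRNA varies across samples (lognormal around a gene
#' base FPKM) and between conditions. Gene-level k_loss is drawn log-uniform
#' from `kloss_range` with independent per-sample variation (see
#' [plant_buffering()] for coupling a fraction of genes to mRNA).
#'
#' @param config A [sim_config()].
#' @return A list with `transcripts` (annotation `data.frame`), `expression`
#'   (measured [expression_table()] with replicate noise), and `truth` (a list
#'   holding true per-sample FPKM, per-(gene, sample) k_loss, per-gene mRNA
#'   deviations, condition labels, and the config).
#' @export
simulate_transcriptome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  ns <- config$n_samples_per_condition
  samples <- c(sprintf("A%d", seq_len(ns)), sprintf("B%d", seq_len(ns)))
  condition <- stats::setNames(rep(c("A", "B"), each = ns), samples)

  if (config$n_genes == 0) {
    transcripts <- data.frame(gene_id = character(), transcript_id = character(),
                              biotype = character(), protein_sequence = character(),
                              stringsAsFactors = FALSE)
    vals <- matrix(numeric(), nrow = 0,
                   ncol = length(samples) * config$n_replicates,
                   dimnames = list(character(), NULL))
    expr <- expression_table(vals,
                             sample_id = rep(samples, each = config$n_replicates),
                             replicate = rep(seq_len(config$n_replicates),
                                             times = length(samples)))
    truth <- list(transcripts = transcripts,
                  fpkm_true = vals, mrna_dev = vals[0, , drop = FALSE],
                  kloss = vals[0, , drop = FALSE], kloss_base = numeric(),
                  condition = condition, samples = samples,
                  buffered_genes = character(), config = config)
    return(list(transcripts = transcripts, expression = expr, truth = truth))
  }

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_iso <- sample(1:4, config$n_genes, replace = TRUE,
                  prob = config$isoform_count_distribution)

  rec <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    c1 <- random_protein_segment(sample(40:80, 1))
    c2 <- random_protein_segment(sample(40:80, 1))
    tid <- sprintf("%s.T%d", genes[g], seq_len(n_iso[g]))
    biotype <- c("protein_coding",
                 ifelse(stats::runif(max(n_iso[g] - 1, 0)) < config$ri_fraction,
                        "retained_intron", "protein_coding"))[seq_len(n_iso[g])]
    seqs <- vapply(seq_len(n_iso[g]), function(j) {
      if (biotype[j] != "protein_coding") return("")
      paste0(c1, random_protein_segment(sample(20:40, 1)), c2)
    }, "")
    rec[[g]] <- data.frame(gene_id = genes[g], transcript_id = tid,
                           biotype = biotype, protein_sequence = seqs,
                           stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, rec)
  rownames(transcripts) <- NULL

  # gene-level expression: base FPKM, per-sample deviation, condition shift
  base_fpkm <- stats::rlnorm(config$n_genes, config$gene_fpkm_meanlog,
                             config$gene_fpkm_sdlog)
  cond_fc <- stats::rnorm(config$n_genes, 0, config$condition_log2fc_sd)
  mrna_dev <- matrix(stats::rnorm(config$n_genes * length(samples), 0,
                                  config$sample_log2_sd),
                     nrow = config$n_genes,
                     dimnames = list(genes, samples))
  mrna_dev[, condition[samples] == "B"] <-
    mrna_dev[, condition[samples] == "B"] + cond_fc

  # isoform weights: first isoform dominant
  iso_weight <- unlist(lapply(seq_len(config$n_genes), function(g) {
    k <- n_iso[g]
    if (k == 1) return(1)
    w1 <- stats::runif(1, 0.5, 0.85)
    rest <- stats::runif(k - 1)
    c(w1, (1 - w1) * rest / sum(rest))
  }))
  gene_of_t <- match(transcripts$gene_id, genes)
  fpkm_true <- base_fpkm[gene_of_t] * iso_weight *
    2^mrna_dev[gene_of_t, , drop = FALSE]
  rownames(fpkm_true) <- transcripts$transcript_id

  # measured FPKM: replicate columns with lognormal noise
  nrep <- config$n_replicates
  rep_sample <- rep(samples, each = nrep)
  rep_rep <- rep(seq_len(nrep), times = length(samples))
  vals <- fpkm_true[, rep_sample, drop = FALSE] *
    matrix(rlnorm_cv(nrow(fpkm_true) * length(rep_sample), config$rna_noise_cv),
           nrow = nrow(fpkm_true))
  rownames(vals) <- transcripts$transcript_id
  expr <- expression_table(vals, sample_id = rep_sample, replicate = rep_rep)

  # turnover truth: gene-level base rate, independent per-sample variation
  kloss_base <- stats::setNames(
    exp(stats::runif(config$n_genes, log(config$kloss_range[1]),
                     log(config$kloss_range[2]))), genes)
  kloss <- 2^(log2(kloss_base) +
              matrix(stats::rnorm(config$n_genes * length(samples), 0,
                                  config$buffering_noise_sd),
                     nrow = config$n_genes)) |>
    matrix(nrow = config$n_genes, dimnames = list(genes, samples))

  truth <- list(transcripts = transcripts, fpkm_true = fpkm_true,
                mrna_dev = mrna_dev, kloss = kloss, kloss_base = kloss_base,
                condition = condition, samples = samples,
                buffered_genes = character(), config = config)
  list(transcripts = transcripts, expression = expr, truth = truth)
}

#' Couple k_loss variation to mRNA variation for a fraction of genes
#'
#' For `buffered_fraction` of the genes, per-sample log2 k_loss is redrawn as
#' `alpha * (per-sample log2 mRNA deviation) + noise`, modelling degradation
#' that tracks (and thereby buffers) mRNA regulation attempts; the remaining
#' genes keep k_loss independent of mRNA.
#'
#' @param truth Truth list from [simulate_transcriptome()].
#' @param config The same [sim_config()] (uses `buffered_fraction`,
#'   `buffering_alpha`, `buffering_noise_sd`, `seed`).
#' @return The updated truth list; buffered gene ids are recorded in
#'   `truth$buffered_genes`.
#' @export
plant_buffering <- function(truth, config) {
  config <- validate_sim_config(config)
  if (length(unique(truth$condition)) < 2)
    stop_config("plant_buffering requires a two-condition design")
  genes <- names(truth$kloss_base)
  if (length(genes) == 0 || config$buffered_fraction == 0) {
    truth$buffered_genes <- character()
    return(truth)
  }
  set.seed(derive_seed(config$seed, 17L), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n_buf <- round(config$buffered_fraction * length(genes))
  buffered <- sort(sample(genes, n_buf))
  dev <- truth$mrna_dev[buffered, , drop = FALSE]
  noise <- matrix(stats::rnorm(length(dev), 0, config$buffering_noise_sd),
                  nrow = nrow(dev))
  truth$kloss[buffered, ] <- 2^(log2(truth$kloss_base[buffered]) +
                                config$buffering_alpha * dev + noise)
  truth$buffered_genes <- buffered
  truth
}

#' Simulate a pulsed-SILAC precursor quantity table
#'
#' Detected peptides are sampled from the tryptic digest of each coding
#' isoform; a peptide's total steady-state intensity in a sample sums the
#' abundances of all isoforms containing it. For a precursor with total
#' intensity T and true rate k, the noiseless channels at labeling time t are
#' `L(t) = T * exp(-k * t)` and `H(t) = T * (1 - exp(-k * t))` (steady-state
#' incorporation); at t = 0 the heavy channel is 0, stored as missing.
#' Multiplicative lognormal noise with CV `noise_cv` is applied independently
#' per channel per time point per replicate, and observations are dropped
#' with probability `missing_rate`.
#'
#' @param truth Truth list from [simulate_transcriptome()] (optionally after
#'   [plant_buffering()]).
#' @param config The same [sim_config()].
#' @return A list with `precursors` (a long `data.frame` in
#'   [read_precursor_table()] layout) and `peptides` (truth mapping:
#'   peptide, gene_id, semicolon-collapsed transcript_ids, true base k_loss).
#' @export
simulate_psilac <- function(truth, config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, 29L), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  tx <- truth$transcripts
  coding <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  empty <- data.frame(sample_id = character(), replicate = integer(),
                      time_h = numeric(), peptide = character(),
                      charge = integer(), channel = character(),
                      intensity = numeric(), stringsAsFactors = FALSE)
  if (nrow(coding) == 0)
    return(list(precursors = empty,
                peptides = data.frame(peptide = character(),
                                      gene_id = character(),
                                      transcript_ids = character(),
                                      stringsAsFactors = FALSE)))

  dcfg <- digest_config(missed_cleavages = 0)
  digests <- lapply(coding$protein_sequence, digest, config = dcfg)
  names(digests) <- coding$transcript_id

  # detected peptides: subsample per isoform, then map each detected peptide
  # to every isoform whose digest contains it
  detected <- unique(unlist(lapply(digests, function(p) {
    if (length(p) <= config$max_detected_peptides) p
    else sample(p, config$max_detected_peptides)
  })))
  pep2t <- data.table::rbindlist(lapply(seq_along(digests), function(i) {
    hit <- intersect(digests[[i]], detected)
    if (length(hit) == 0) return(NULL)
    data.table::data.table(peptide = hit,
                           transcript_id = coding$transcript_id[i],
                           gene_id = coding$gene_id[i])
  }))
  # peptides hitting several genes are kept: the classifier must see them
  pep_genes <- pep2t[, list(n_genes = length(unique(gene_id)),
                            gene_id = gene_id[1],
                            transcript_ids = paste(sort(unique(transcript_id)),
                                                   collapse = ";")),
                     by = "peptide"]

  samples <- truth$samples
  # protein abundance per isoform per sample; gene-level MS response scale
  genes <- names(truth$kloss_base)
  scale_g <- stats::setNames(stats::rlnorm(length(genes), log(500), 0.5), genes)
  fpkm <- truth$fpkm_true[pep2t$transcript_id, , drop = FALSE]
  abund <- fpkm * scale_g[pep2t$gene_id]
  # total peptide intensity per sample: sum over isoforms containing it
  eff <- stats::setNames(stats::rlnorm(nrow(pep_genes), 0, 0.8),
                         pep_genes$peptide)
  T_mat <- rowsum(abund, group = pep2t$peptide)  # peptide x sample
  T_mat <- T_mat * eff[rownames(T_mat)]

  # precursor charges: 2 or 3; some peptides seen in both
  z1 <- sample(2:3, nrow(pep_genes), replace = TRUE)
  both <- stats::runif(nrow(pep_genes)) < 0.25
  prec <- data.table::data.table(
    peptide = c(pep_genes$peptide, pep_genes$peptide[both]),
    gene_id = c(pep_genes$gene_id, pep_genes$gene_id[both]),
    charge = c(z1, 5L - z1[both])
  )
  # split total peptide signal across its charge states
  prec[, nz := .N, by = "peptide"]

  nrep <- config$n_replicates
  tp <- config$time_points_h
  grid <- data.table::CJ(prec_idx = seq_len(nrow(prec)),
                         sample_id = samples,
                         replicate = seq_len(nrep),
                         time_h = tp, sorted = FALSE)
  grid[, `:=`(peptide = prec$peptide[prec_idx],
              charge = prec$charge[prec_idx],
              gene_id = prec$gene_id[prec_idx],
              nz = prec$nz[prec_idx])]
  grid[, T_tot := T_mat[cbind(peptide, sample_id)] / nz]
  grid[, k := truth$kloss[cbind(gene_id, sample_id)]]
  grid[, L := T_tot * exp(-k * time_h)]
  grid[, H := T_tot * (1 - exp(-k * time_h))]

  long <- data.table::melt(
    grid[, c("sample_id", "replicate", "time_h", "peptide", "charge", "L", "H")],
    measure.vars = c("L", "H"), variable.name = "channel",
    value.name = "intensity")
  long[, channel := ifelse(channel == "L", "light", "heavy")]
  long[, intensity := intensity * rlnorm_cv(.N, config$noise_cv)]
  if (config$missing_rate > 0)
    long <- long[stats::runif(nrow(long)) >= config$missing_rate]
  long[intensity == 0, intensity := NA_real_]  # heavy at t = 0
  data.table::setorder(long, sample_id, replicate, time_h, peptide, charge,
                       channel)
  list(precursors = as.data.frame(long),
       peptides = as.data.frame(pep_genes[, c("peptide", "gene_id",
                                              "transcript_ids", "n_genes")]))
}

#' Simulate a clean two-condition dataset with planted isoform switches
#'
#' Builds a transcript annotation and replicate-level FPKM matrix where a
#' chosen number of two-isoform genes change their major isoform between
#' conditions (half retained-intron-to-coding, half coding-to-retained-intron)
#' while the remaining genes keep the same major isoform. Expression levels
#' are chosen to pass the default switch-caller prefilters, so the planted
#' events are exactly the callable ones.
#'
#' @param n_genes Total genes (default 60).
#' @param n_switch Number of genes with a planted major-isoform switch
#'   (default 20).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_cv CV of lognormal replicate noise (default 0.02; keep small
#'   for a clean truth set).
#' @param seed Integer seed.
#' @return A list with `transcripts`, `expression` (an [expression_table()]
#'   with columns `A:1..n` and `B:1..n`), `condition` (named vector), and
#'   `events` (the planted truth: gene_id, major_A, major_B, class).
#' @export
simulate_switch_dataset <- function(n_genes = 60, n_switch = 20,
                                    n_replicates = 3, noise_cv = 0.02,
                                    seed = 1L) {
  if (n_switch > n_genes) stop_config("n_switch cannot exceed n_genes")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  genes <- sprintf("SG%03d", seq_len(n_genes))
  is_switch <- seq_len(n_genes) <= n_switch
  to_coding <- is_switch & (seq_len(n_genes) %% 2 == 1)  # RI -> coding

  rec <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  fpkm_A <- fpkm_B <- list()
  for (g in seq_len(n_genes)) {
    t_cod <- sprintf("%s.T1", genes[g])
    t_ri <- sprintf("%s.T2", genes[g])
    rec[[g]] <- data.frame(
      gene_id = genes[g],
      transcript_id = c(t_cod, t_ri),
      biotype = c("protein_coding", "retained_intron"),
      protein_sequence = c(random_protein_segment(60), ""),
      stringsAsFactors = FALSE)
    hi <- stats::runif(1, 8, 15); lo <- stats::runif(1, 2, 4)
    if (!is_switch[g]) {          # coding major in both conditions
      a <- c(hi, lo); b <- c(hi, lo); cls <- NA_character_
      major_a <- major_b <- t_cod
    } else if (to_coding[g]) {    # RI major in A, coding major in B
      a <- c(lo, hi); b <- c(hi, lo); cls <- "RI_to_coding"
      major_a <- t_ri; major_b <- t_cod
    } else {                      # coding major in A, RI major in B
      a <- c(hi, lo); b <- c(lo, hi); cls <- "coding_to_RI"
      major_a <- t_cod; major_b <- t_ri
    }
    fpkm_A[[g]] <- a; fpkm_B[[g]] <- b
    truth[[g]] <- data.frame(gene_id = genes[g], major_A = major_a,
                             major_B = major_b, class = cls,
                             stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, rec)
  base <- cbind(matrix(rep(unlist(fpkm_A), n_replicates), ncol = n_replicates),
                matrix(rep(unlist(fpkm_B), n_replicates), ncol = n_replicates))
  vals <- base * matrix(rlnorm_cv(length(base), noise_cv), nrow = nrow(base))
  rownames(vals) <- transcripts$transcript_id
  expr <- expression_table(
    vals,
    sample_id = rep(c("A", "B"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = 2))
  events <- do.call(rbind, truth)
  list(transcripts = transcripts, expression = expr,
       condition = c(A = "A", B = "B"),
       events = events[!is.na(events$class), , drop = FALSE])
}
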