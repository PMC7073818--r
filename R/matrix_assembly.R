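# Assembly of the joined per-(AS group, sample) matrices: log2 protein
# intensity (peptides collapsed to groups), log2 k_loss (from the turnover
# module), and log2 FPKM of each group's representative transcript.

#' Matrix assembly configuration
#'
#' @param min_replicates Minimum quantified replicates for a peptide-sample
#'   intensity (default 2; otherwise the value is missing).
#' @param min_peptides_per_group Minimum peptides per AS group (default 2).
#' @param collapse Peptide-to-group collapse: `"sum_linear"` (default; sum
#'   linear intensities then log2) or `"sum_log"` (sum the log2 values, the
#'   literal reading of summing after log transformation).
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(min_replicates = 2L, min_peptides_per_group = 2L,
                            collapse = c("sum_linear", "sum_log")) {
  structure(list(min_replicates = as.integer(min_replicates),
                 min_peptides_per_group = as.integer(min_peptides_per_group),
                 collapse = match.arg(collapse)),
            class = "assembly_config")
}

#' Per-(sample, replicate) peptide intensities from a precursor table
#'
#' The steady-state total signal of a peptide in one injection: the mean over
#' time points and charge states of the summed light+heavy intensity.
#'
#' @param precursors Precursor table.
#' @return `data.frame` with `sample_id`, `replicate`, `peptide`,
#'   `intensity` (linear scale).
#' @export
peptide_intensity_table <- function(precursors) {
  dt <- data.table::as.data.table(precursors)
  tot <- dt[, list(total = if (all(is.na(intensity))) NA_real_
                   else sum(intensity, na.rm = TRUE)),
            by = c("sample_id", "replicate", "peptide", "charge", "time_h")]
  out <- tot[!is.na(total),
             list(intensity = mean(total)),
             by = c("sample_id", "replicate", "peptide")]
  data.table::setorder(out, sample_id, replicate, peptide)
  as.data.frame(out)
}

#' Assemble the group x sample protein intensity matrix
#'
#' Peptide intensities are log2-transformed; replicate injections are
#' summarized per sample by the median, requiring at least
#' `config$min_replicates` quantified replicates. Only peptide full profiles
#' (quantified in every sample) are kept. Member-peptide linear intensities
#' are then summed per group and log2-transformed (see
#' [assembly_config()] for the collapse convention); groups need at least
#' `config$min_peptides_per_group` peptides.
#'
#' @param peptide_intensities Output of [peptide_intensity_table()] (linear
#'   scale).
#' @param group_map Peptide-to-group map from [peptide_group_map()].
#' @param config An [assembly_config()].
#' @param samples Samples a full profile must cover (default: all present).
#' @return A list with `matrix` (groups x samples, log2 intensity),
#'   `peptide_matrix` (full-profile peptides x samples, log2),
#'   and `exclusions` (key, reason).
#' @export
assemble_protein_matrix <- function(peptide_intensities, group_map,
                                    config = assembly_config(),
                                    samples = NULL) {
  dt <- data.table::as.data.table(peptide_intensities)
  samples <- samples %||% sort(unique(dt$sample_id))
  # median over replicates in linear intensity space, then log2 (for an even
  # number of observed replicates the linear median is the natural reading)
  per <- dt[!is.na(intensity),
            list(n_rep = .N, log2_int = log2(stats::median(intensity))),
            by = c("sample_id", "peptide")]
  low_rep <- per[n_rep < config$min_replicates]
  excl <- data.frame(key = paste(low_rep$peptide, low_rep$sample_id, sep = "@"),
                     reason = rep("insufficient_replicates", nrow(low_rep)),
                     stringsAsFactors = FALSE)
  per <- per[n_rep >= config$min_replicates]
  cover <- per[, list(n_samples = sum(unique(sample_id) %in% samples)),
               by = "peptide"]
  full <- cover$peptide[cover$n_samples == length(samples)]
  not_full <- setdiff(cover$peptide, full)
  excl <- rbind(excl, data.frame(key = not_full,
                                 reason = rep("not_full_profile",
                                              length(not_full)),
                                 stringsAsFactors = FALSE))
  per <- per[peptide %in% full]
  pep_mat <- if (nrow(per) > 0)
    as.matrix(data.table::dcast(per, peptide ~ sample_id,
                                value.var = "log2_int"), rownames = "peptide")
  else matrix(numeric(), 0, length(samples), dimnames = list(NULL, samples))

  gm <- data.table::as.data.table(group_map)
  per_g <- merge(per, gm[, c("peptide", "group_id")], by = "peptide")
  grp <- per_g[, list(
    n_peptides = length(unique(peptide)),
    log2_int = if (config$collapse == "sum_linear") log2(sum(2^log2_int))
    else sum(log2_int)
  ), by = c("group_id", "sample_id")]
  n_pep <- grp[, list(n = max(n_peptides)), by = "group_id"]
  small <- n_pep$group_id[n_pep$n < config$min_peptides_per_group]
  excl <- rbind(excl, data.frame(key = small,
                                 reason = rep("insufficient_peptides",
                                              length(small)),
                                 stringsAsFactors = FALSE))
  grp <- grp[!group_id %in% small]
  mat <- if (nrow(grp) > 0)
    as.matrix(data.table::dcast(grp, group_id ~ sample_id,
                                value.var = "log2_int"), rownames = "group_id")
  else matrix(numeric(), 0, length(samples), dimnames = list(NULL, samples))
  list(matrix = mat, peptide_matrix = pep_mat, exclusions = excl)
}

#' Join protein, k_loss and mRNA layers per AS group
#'
#' UQ rows take the FPKM of their single transcript; SM rows take the FPKM
#' of their representative (major) transcript. Per-sample FPKM is the mean
#' over that sample's replicates, log2-transformed with no pseudocount
#' (FPKM 0 maps to missing).
#'
#' @param protein_matrix Group x sample log2 intensity matrix from
#'   [assemble_protein_matrix()].
#' @param kloss_group Group-level k_loss table from [aggregate_kloss()]
#'   (`group_id`, `sample_id`, `log2_kloss`).
#' @param expression An [expression_table()].
#' @param groups AS groups from [assemble_as_groups()].
#' @return An object of class `omics_matrix`: a list of three aligned
#'   group x sample matrices (`log2_protein`, `log2_kloss`, `log2_fpkm`) and
#'   a `rows` data.frame (group_id, gene_id, class,
#'   representative_transcript).
#' @export
join_omics <- function(protein_matrix, kloss_group, expression, groups) {
  kdt <- data.table::as.data.table(kloss_group)
  common <- intersect(rownames(protein_matrix), unique(kdt$group_id))
  common <- intersect(common, groups$group_id)
  samples <- colnames(protein_matrix)
  rows <- groups[match(common, groups$group_id),
                 c("group_id", "gene_id", "class", "representative_transcript")]
  rownames(rows) <- NULL
  unknown <- setdiff(rows$representative_transcript, rownames(expression))
  if (length(unknown) > 0)
    stop_format("group representative transcript(s) missing from the ",
                "expression matrix: ", paste(utils::head(unknown, 5),
                                             collapse = ", "))
  kmat <- matrix(NA_real_, length(common), length(samples),
                 dimnames = list(common, samples))
  kdt <- kdt[group_id %in% common & sample_id %in% samples]
  kmat[cbind(kdt$group_id, kdt$sample_id)] <- kdt$log2_kloss

  means <- expr_sample_means(expression)
  fmat <- means[rows$representative_transcript, samples, drop = FALSE]
  fmat[fmat == 0] <- NA_real_
  fmat <- log2(fmat)
  rownames(fmat) <- common

  structure(list(log2_protein = protein_matrix[common, samples, drop = FALSE],
                 log2_kloss = kmat, log2_fpkm = fmat, rows = rows),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d AS groups x %d samples (%d complete rows)\n",
              nrow(x$rows), ncol(x$log2_protein),
              nrow(correlation_ready(x)$rows)))
  invisible(x)
}

#' Correlation-ready view of an omics matrix
#'
#' Keeps only rows with complete protein, k_loss and mRNA profiles in every
#' sample.
#'
#' @param om An `omics_matrix` from [join_omics()].
#' @return An `omics_matrix` restricted to complete rows.
#' @export
correlation_ready <- function(om) {
  ok <- stats::complete.cases(om$log2_protein) &
    stats::complete.cases(om$log2_kloss) &
    stats::complete.cases(om$log2_fpkm)
  structure(list(log2_protein = om$log2_protein[ok, , drop = FALSE],
                 log2_kloss = om$log2_kloss[ok, , drop = FALSE],
                 log2_fpkm = om$log2_fpkm[ok, , drop = FALSE],
                 rows = om$rows[ok, , drop = FALSE]),
            class = "omics_matrix")
}

#' Long-format export of an omics matrix
#'
#' @param om An `omics_matrix`.
#' @return A long `data.frame` (group_id, sample_id, log2_protein,
#'   log2_kloss, log2_fpkm).
#' @export
omics_long <- function(om) {
  samples <- colnames(om$log2_protein)
  out <- expand.grid(group_id = rownames(om$log2_protein),
                     sample_id = samples, stringsAsFactors = FALSE)
  out$log2_protein <- om$log2_protein[cbind(out$group_id, out$sample_id)]
  out$log2_kloss <- om$log2_kloss[cbind(out$group_id, out$sample_id)]
  out$log2_fpkm <- om$log2_fpkm[cbind(out$group_id, out$sample_id)]
  out
}
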