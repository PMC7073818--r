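# Sample-specific, expression-filtered protein sequence database: only
# protein-coding transcripts expressed above an FPKM threshold in enough
# samples enter the search space, mirroring the observation that MS cannot
# detect proteins translated from very low-abundance transcripts.

#' Database filter configuration
#'
#' @param fpkm_threshold Transcripts must exceed this FPKM (strictly) to
#'   count as expressed in a sample (default 1).
#' @param min_samples Minimum number of distinct samples in which the
#'   transcript must be expressed (default 3).
#' @param required_biotype Only transcripts of this biotype are eligible
#'   (default `"protein_coding"`).
#' @return A list of class `db_filter_config`.
#' @export
db_filter_config <- function(fpkm_threshold = 1, min_samples = 3,
                             required_biotype = "protein_coding") {
  if (!is.numeric(fpkm_threshold) || length(fpkm_threshold) != 1)
    stop_config("fpkm_threshold must be a single number")
  if (!is_count(min_samples, 1L)) stop_config("min_samples must be a count >= 1")
  structure(list(fpkm_threshold = fpkm_threshold,
                 min_samples = as.integer(min_samples),
                 required_biotype = required_biotype),
            class = "db_filter_config")
}

#' Build the expression-filtered protein database
#'
#' A transcript is included iff its biotype matches
#' `config$required_biotype` and its per-sample mean FPKM (replicates
#' averaged first) exceeds `config$fpkm_threshold` strictly in at least
#' `config$min_samples` distinct samples.
#'
#' @param transcripts Transcript annotation `data.frame`
#'   (see [read_transcripts()]).
#' @param expression An [expression_table()]; every row must resolve against
#'   `transcripts`. Transcripts absent from the expression table count as
#'   unexpressed everywhere.
#' @param config A [db_filter_config()].
#' @return A list with `db` (the included transcript records, FASTA-ready)
#'   and `report` (per transcript: biotype, number of samples passing the
#'   FPKM cut, inclusion verdict and reason).
#' @export
build_filtered_db <- function(transcripts, expression,
                              config = db_filter_config()) {
  orphans <- setdiff(rownames(expression), transcripts$transcript_id)
  if (length(orphans) > 0)
    stop_format("expression matrix contains transcript(s) absent from the ",
                "annotation: ", paste(utils::head(orphans, 5), collapse = ", "),
                if (length(orphans) > 5) ", ..." else "")
  means <- expr_sample_means(expression)
  pass_n <- stats::setNames(rep(0L, nrow(transcripts)),
                            transcripts$transcript_id)
  present <- intersect(transcripts$transcript_id, rownames(means))
  if (length(present) > 0)
    pass_n[present] <- rowSums(means[present, , drop = FALSE] >
                                 config$fpkm_threshold)
  biotype_ok <- transcripts$biotype == config$required_biotype
  expressed <- pass_n[transcripts$transcript_id] >= config$min_samples
  included <- biotype_ok & expressed
  reason <- ifelse(included, "included",
                   ifelse(!biotype_ok, "wrong_biotype", "below_expression_cut"))
  report <- data.frame(transcript_id = transcripts$transcript_id,
                       gene_id = transcripts$gene_id,
                       biotype = transcripts$biotype,
                       n_samples_pass = unname(pass_n[transcripts$transcript_id]),
                       included = included,
                       reason = reason,
                       stringsAsFactors = FALSE)
  list(db = transcripts[included, , drop = FALSE], report = report)
}
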