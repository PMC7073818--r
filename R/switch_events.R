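# Alternative-splicing switch caller: detects genes whose major (most
# mRNA-abundant) isoform changes between two conditions and classifies the
# event by the biotype pair of the two majors (retained-intron vs coding).
# This is a simplified dominance-based re-specification of switch detection,
# not a port of any existing caller.

#' Switch-caller configuration
#'
#' @param gene_expression_threshold Gene-summed FPKM a gene must exceed
#'   (default 1).
#' @param expression_breadth Percent of samples (replicate columns pooled) in
#'   which the gene-summed FPKM must exceed the threshold (default 50).
#' @param dominance Minimum ratio of the major isoform's mean FPKM to the
#'   second most abundant isoform's, required in both conditions (default 1;
#'   single-isoform genes have infinite dominance but can never switch).
#' @param prefilter If `TRUE` (default), transcripts must have non-zero FPKM
#'   in all replicate columns and FPKM > 1 in at least `prefilter_min`
#'   columns.
#' @param prefilter_min Columns required above FPKM 1 by the prefilter
#'   (default 3).
#' @return A list of class `switch_config`.
#' @export
switch_config <- function(gene_expression_threshold = 1,
                          expression_breadth = 50,
                          dominance = 1,
                          prefilter = TRUE,
                          prefilter_min = 3L) {
  stopifnot(gene_expression_threshold >= 0, expression_breadth >= 0,
            expression_breadth <= 100, dominance >= 0)
  structure(list(gene_expression_threshold = gene_expression_threshold,
                 expression_breadth = expression_breadth,
                 dominance = dominance, prefilter = prefilter,
                 prefilter_min = as.integer(prefilter_min)),
            class = "switch_config")
}

#' @noRd
biotype_switch_class <- function(bt_a, bt_b) {
  if (bt_a == "retained_intron" && bt_b == "protein_coding") "RI_to_coding"
  else if (bt_a == "protein_coding" && bt_b == "retained_intron") "coding_to_RI"
  else if (bt_a == "protein_coding" && bt_b == "protein_coding") "coding_to_coding"
  else "other"
}

#' Call alternative-splicing switch events between two conditions
#'
#' Applies the transcript prefilter, determines per gene and condition the
#' major isoform (highest mean FPKM over the condition's columns; ties break
#' to the lexicographically smallest transcript id) and its dominance ratio,
#' checks gene-level eligibility (summed expression above
#' `gene_expression_threshold` in at least `expression_breadth` percent of
#' columns; dominance at least `config$dominance` in both conditions), and
#' emits an event for every eligible gene whose major isoform differs between
#' conditions.
#'
#' @param expression An [expression_table()].
#' @param transcripts Transcript annotation resolving ids to gene and
#'   biotype.
#' @param condition_labels Named character vector sample_id -> condition;
#'   exactly two conditions (sorted order defines A and B).
#' @param config A [switch_config()].
#' @return `data.frame` of events: `gene_id`, `major_A`, `major_B`,
#'   `dominance_A`, `dominance_B`, `class`.
#' @export
call_switches <- function(expression, transcripts, condition_labels,
                          config = switch_config()) {
  s <- expr_samples(expression)
  cl <- condition_labels[s$sample_id]
  if (any(is.na(cl)))
    stop_config("condition_labels must cover every sample in the expression table")
  conds <- sort(unique(cl))
  if (length(conds) != 2) stop_config("call_switches needs exactly two conditions")
  vals <- unclass(expression)
  attr(vals, "samples") <- NULL

  if (config$prefilter) {
    keep <- rowSums(vals > 0) == ncol(vals) &
      rowSums(vals > 1) >= config$prefilter_min
    vals <- vals[keep, , drop = FALSE]
  }
  if (nrow(vals) == 0) return(empty_switch_events())
  tx <- transcripts[match(rownames(vals), transcripts$transcript_id), ]
  if (any(is.na(tx$transcript_id)))
    stop_format("expression rows missing from the transcript annotation")

  gene_sum <- rowsum(vals, group = tx$gene_id)
  breadth <- rowMeans(gene_sum > config$gene_expression_threshold) * 100
  eligible_expr <- names(breadth)[breadth >= config$expression_breadth]

  mean_a <- rowMeans(vals[, cl == conds[1], drop = FALSE])
  mean_b <- rowMeans(vals[, cl == conds[2], drop = FALSE])
  events <- list()
  for (g in intersect(unique(tx$gene_id), eligible_expr)) {
    ix <- which(tx$gene_id == g)
    if (length(ix) < 2) next
    tids <- tx$transcript_id[ix]
    major <- function(means) {
      o <- order(-means, tids)
      dom <- if (means[o[2]] > 0) means[o[1]] / means[o[2]] else Inf
      list(id = tids[o[1]], dom = dom)
    }
    ma <- major(mean_a[ix]); mb <- major(mean_b[ix])
    if (ma$dom < config$dominance || mb$dom < config$dominance) next
    if (ma$id == mb$id) next
    bt <- function(id) tx$biotype[tx$transcript_id == id]
    events[[g]] <- data.frame(
      gene_id = g, major_A = ma$id, major_B = mb$id,
      dominance_A = ma$dom, dominance_B = mb$dom,
      class = biotype_switch_class(bt(ma$id), bt(mb$id)),
      stringsAsFactors = FALSE)
  }
  if (length(events) == 0) return(empty_switch_events())
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' @noRd
empty_switch_events <- function() {
  data.frame(gene_id = character(), major_A = character(),
             major_B = character(), dominance_A = numeric(),
             dominance_B = numeric(), class = character(),
             stringsAsFactors = FALSE)
}

#' Protein-level consequences of switch events
#'
#' Collects the matched protein and k_loss log2 fold changes per switch
#' class and tests each class against the coding-to-coding control class
#' with a two-sided rank-sum test.
#'
#' @param events Output of [call_switches()].
#' @param protein_fc Named numeric vector: gene_id -> log2 protein fold
#'   change between the two conditions.
#' @param kloss_fc Named numeric vector: gene_id -> log2 k_loss fold change
#'   (optional, `NULL` to skip).
#' @param control Control class (default `"coding_to_coding"`).
#' @param min_n Minimum matched values for a class to be tested (default 3).
#' @return A list with `distributions` (long `data.frame`: class, layer,
#'   gene_id, log2_fc) and `tests` (class, layer, n, median_fc, p vs
#'   control; `NA` p where skipped).
#' @export
switch_consequences <- function(events, protein_fc, kloss_fc = NULL,
                                control = "coding_to_coding", min_n = 3L) {
  layers <- list(protein = protein_fc)
  if (!is.null(kloss_fc)) layers$kloss <- kloss_fc
  dist <- list(); tests <- list()
  for (layer in names(layers)) {
    fc <- layers[[layer]]
    matched <- events[events$gene_id %in% names(fc), , drop = FALSE]
    if (nrow(matched) > 0)
      dist[[layer]] <- data.frame(class = matched$class, layer = layer,
                                  gene_id = matched$gene_id,
                                  log2_fc = unname(fc[matched$gene_id]),
                                  stringsAsFactors = FALSE)
    ctrl_vals <- fc[matched$gene_id[matched$class == control]]
    for (cls in unique(matched$class)) {
      vals <- fc[matched$gene_id[matched$class == cls]]
      p <- if (length(vals) >= min_n && length(ctrl_vals) >= min_n)
        suppressWarnings(stats::wilcox.test(vals, ctrl_vals)$p.value)
      else NA_real_
      tests[[paste(layer, cls)]] <- data.frame(
        class = cls, layer = layer, n = length(vals),
        median_fc = stats::median(vals), p_vs_control = p,
        stringsAsFactors = FALSE)
    }
  }
  empty_dist <- data.frame(class = character(), layer = character(),
                           gene_id = character(), log2_fc = numeric(),
                           stringsAsFactors = FALSE)
  empty_tests <- data.frame(class = character(), layer = character(),
                            n = integer(), median_fc = numeric(),
                            p_vs_control = numeric(), stringsAsFactors = FALSE)
  d_out <- if (length(dist)) do.call(rbind, dist) else empty_dist
  t_out <- if (length(tests)) do.call(rbind, tests) else empty_tests
  rownames(d_out) <- rownames(t_out) <- NULL
  list(distributions = d_out, tests = t_out)
}
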