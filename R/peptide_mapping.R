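# In-silico tryptic digestion, peptide-to-isoform classification and
# AS-group assembly. Peptides either resolve a single isoform (unique, UQ
# groups) or a set of isoforms of one gene (shared, SM groups represented by
# the most mRNA-abundant member); peptides hitting several genes are
# excluded from all quantification.

#' Digestion configuration
#'
#' @param missed_cleavages Maximum internal missed cleavage sites (default 2).
#' @param min_length,max_length Peptide length bounds (defaults 7 and 30,
#'   common DIA practice).
#' @return A list of class `digest_config`.
#' @export
digest_config <- function(missed_cleavages = 2, min_length = 7,
                          max_length = 30) {
  if (!is_count(missed_cleavages)) stop_config("missed_cleavages must be a count")
  if (!is_count(min_length, 1L) || !is_count(max_length, 1L) ||
      min_length > max_length)
    stop_config("need 1 <= min_length <= max_length")
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_config")
}

#' Tryptic in-silico digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' returns every fully tryptic fragment with at most
#' `config$missed_cleavages` internal cleavage sites and length within the
#' configured bounds.
#'
#' @param protein_sequence A single amino-acid string.
#' @param config A [digest_config()].
#' @return Character vector of distinct peptides.
#' @export
digest <- function(protein_sequence, config = digest_config()) {
  if (length(protein_sequence) != 1 || is.na(protein_sequence) ||
      nchar(protein_sequence) == 0)
    stop_format("digest needs one non-empty sequence")
  if (!grepl(AA_REGEX, protein_sequence))
    stop_format("illegal residue in protein sequence")
  chars <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  bounds <- c(0L, cuts, n)
  m <- length(bounds)
  out <- character(0)
  for (a in seq_len(m - 1)) {
    bmax <- min(a + 1L + config$missed_cleavages, m)
    for (b in (a + 1):bmax) {
      len <- bounds[b] - bounds[a]
      if (len >= config$min_length && len <= config$max_length)
        out <- c(out, substr(protein_sequence, bounds[a] + 1L, bounds[b]))
    }
  }
  unique(out)
}

#' Build the peptide -> transcript map of a protein database
#'
#' Digests every database entry and records which transcripts each peptide
#' can originate from.
#'
#' @param db Transcript records with non-empty `protein_sequence`.
#' @param config A [digest_config()].
#' @return `data.frame` with one row per (peptide, transcript_id) pair.
#' @export
digest_db <- function(db, config = digest_config()) {
  stopifnot(all(db$protein_sequence != ""))
  peps <- lapply(db$protein_sequence, digest, config = config)
  data.frame(
    peptide = unlist(peps),
    transcript_id = rep(db$transcript_id, lengths(peps)),
    stringsAsFactors = FALSE
  )
}

#' Classify peptides as unique, shared or multi-gene
#'
#' A peptide mapping to exactly one transcript is `unique`; to several
#' transcripts of one gene, `shared`; to transcripts of several genes,
#' `multi_gene` (excluded from all downstream quantification).
#'
#' @param peptide_map `data.frame` of (peptide, transcript_id) pairs, e.g.
#'   from [digest_db()].
#' @param transcripts Transcript annotation resolving `transcript_id` to
#'   `gene_id`.
#' @return `data.frame` with columns `peptide`, `transcript_ids`
#'   (semicolon-collapsed, sorted), `gene_ids` (likewise), `class`.
#' @export
classify_peptides <- function(peptide_map, transcripts) {
  unknown <- setdiff(peptide_map$transcript_id, transcripts$transcript_id)
  if (length(unknown) > 0)
    stop_format("peptide map references unknown transcript(s): ",
                paste(utils::head(unknown, 5), collapse = ", "))
  dt <- data.table::as.data.table(peptide_map)
  dt[, gene_id := transcripts$gene_id[match(transcript_id,
                                            transcripts$transcript_id)]]
  res <- dt[, list(
    transcript_ids = paste(sort(unique(transcript_id)), collapse = ";"),
    gene_ids = paste(sort(unique(gene_id)), collapse = ";"),
    n_t = length(unique(transcript_id)),
    n_g = length(unique(gene_id))
  ), by = "peptide"]
  res[, class := ifelse(n_g > 1, "multi_gene",
                        ifelse(n_t == 1, "unique", "shared"))]
  data.table::setorder(res, peptide)
  as.data.frame(res[, c("peptide", "transcript_ids", "gene_ids", "class")])
}

#' Assemble protein AS groups from classified peptides
#'
#' Unique peptides form one UQ group per transcript. Shared peptides with an
#' identical transcript-id set form one SM group whose representative is the
#' member transcript with the highest FPKM averaged over all samples
#' (replicates averaged per sample first); ties break to the
#' lexicographically smallest transcript id. Multi-gene peptides are
#' discarded.
#'
#' @param assignments Output of [classify_peptides()].
#' @param expression An [expression_table()]; member transcripts absent from
#'   it count as FPKM 0.
#' @return `data.frame` with columns `group_id`, `gene_id`, `class`
#'   (`"UQ"`/`"SM"`), `representative_transcript`, `member_transcripts`
#'   (semicolon-collapsed), `n_peptides`, `peptides` (semicolon-collapsed).
#' @export
assemble_as_groups <- function(assignments, expression) {
  keep <- assignments[assignments$class != "multi_gene", , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(group_id = character(), gene_id = character(),
                      class = character(), representative_transcript = character(),
                      member_transcripts = character(), n_peptides = integer(),
                      peptides = character(), stringsAsFactors = FALSE))
  means <- expr_sample_means(expression)
  overall_mean <- rowMeans(means)
  mean_fpkm <- function(tid) {
    v <- overall_mean[tid]
    v[is.na(v)] <- 0
    v
  }
  dt <- data.table::as.data.table(keep)
  groups <- dt[, list(
    n_peptides = .N,
    peptides = paste(sort(peptide), collapse = ";"),
    class = ifelse(class[1] == "unique", "UQ", "SM"),
    gene_id = gene_ids[1]
  ), by = "transcript_ids"]
  members <- strsplit(groups$transcript_ids, ";", fixed = TRUE)
  groups[, representative_transcript := vapply(members, function(tt) {
    f <- mean_fpkm(tt)
    cand <- tt[f == max(f)]
    sort(cand)[1]
  }, "")]
  groups[, group_id := ifelse(class == "UQ", representative_transcript,
                              gsub(";", "+", transcript_ids, fixed = TRUE))]
  data.table::setorder(groups, group_id)
  data.table::setnames(groups, "transcript_ids", "member_transcripts")
  as.data.frame(groups[, c("group_id", "gene_id", "class",
                           "representative_transcript", "member_transcripts",
                           "n_peptides", "peptides")])
}

#' Peptide -> group lookup
#'
#' @param groups Output of [assemble_as_groups()].
#' @return `data.frame` with columns `peptide`, `group_id`, `gene_id`,
#'   `class`.
#' @export
peptide_group_map <- function(groups) {
  peps <- strsplit(groups$peptides, ";", fixed = TRUE)
  data.frame(peptide = unlist(peps),
             group_id = rep(groups$group_id, lengths(peps)),
             gene_id = rep(groups$gene_id, lengths(peps)),
             class = rep(groups$class, lengths(peps)),
             stringsAsFactors = FALSE)
}
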