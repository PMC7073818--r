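# Readers and writers for the external formats the pipeline touches:
# long-format precursor quantity tables, transcript annotation tables,
# FPKM expression matrices (all TSV) and protein FASTA. All readers validate
# strictly and fail with the offending column/line rather than coercing.

PRECURSOR_COLUMNS <- c("sample_id", "replicate", "time_h", "peptide",
                       "charge", "channel", "intensity")

#' Read a long-format precursor quantity table
#'
#' Reads a tab-separated DIA-software-style export with one row per
#' (sample, replicate, labeling time, stripped peptide, charge, channel)
#' intensity observation. Intensities of exactly 0 are stored as missing
#' (`NA`): DIA exports use 0 and blank interchangeably for "below detection".
#'
#' @param path Path to a TSV file with a header row. Lines starting with `#`
#'   are ignored.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`sample_id`, `replicate`, `time_h`, `peptide`, `charge`,
#'   `channel`, `intensity`) to the column names used in the file, so real
#'   exports can be adapted without code changes.
#' @return A `data.frame` with the canonical columns; `intensity` is numeric
#'   with `NA` for missing, `channel` is `"light"`/`"heavy"`.
#' @export
read_precursor_table <- function(path, schema = NULL) {
  raw <- read_pk_tsv(path)
  schema <- schema %||% stats::setNames(PRECURSOR_COLUMNS, PRECURSOR_COLUMNS)
  missing_cols <- setdiff(PRECURSOR_COLUMNS, names(schema))
  if (length(missing_cols) > 0)
    stop_format("schema does not map required column(s): ",
                paste(missing_cols, collapse = ", "))
  absent <- setdiff(unname(schema[PRECURSOR_COLUMNS]), names(raw))
  if (length(absent) > 0)
    stop_format("precursor table ", path, " is missing required column(s): ",
                paste(absent, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(raw[[schema[["sample_id"]]]]),
    replicate = as.integer(raw[[schema[["replicate"]]]]),
    time_h    = as.numeric(raw[[schema[["time_h"]]]]),
    peptide   = as.character(raw[[schema[["peptide"]]]]),
    charge    = as.integer(raw[[schema[["charge"]]]]),
    channel   = as.character(raw[[schema[["channel"]]]]),
    intensity = suppressWarnings(as.numeric(raw[[schema[["intensity"]]]])),
    stringsAsFactors = FALSE
  )
  validate_precursor_table(out, path)
}

#' @noRd
validate_precursor_table <- function(x, origin = "precursor table") {
  bad_pep <- which(!grepl(AA_REGEX, x$peptide))
  if (length(bad_pep) > 0)
    stop_format(origin, ": illegal peptide sequence at data line ",
                bad_pep[1], " ('", x$peptide[bad_pep[1]], "')")
  if (!all(x$channel %in% c("light", "heavy")))
    stop_format(origin, ": channel must be 'light' or 'heavy' (first offender ",
                "at data line ", which(!x$channel %in% c("light", "heavy"))[1], ")")
  if (any(!is.na(x$time_h) & x$time_h < 0))
    stop_format(origin, ": negative labeling time")
  neg <- which(!is.na(x$intensity) & x$intensity < 0)
  if (length(neg) > 0)
    stop_format(origin, ": negative intensity at data line ", neg[1])
  # 0 = below detection, by convention stored as missing
  x$intensity[!is.na(x$intensity) & x$intensity == 0] <- NA_real_
  key <- paste(x$sample_id, x$replicate, x$time_h, x$peptide, x$charge,
               x$channel, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop_format(origin, ": duplicate (sample, replicate, time, peptide, ",
                "charge, channel) key at data line ", dup[1], ": ",
                gsub("\r", "/", key[dup[1]]))
  x
}

#' Write a precursor quantity table
#'
#' @param x A precursor `data.frame` as returned by [read_precursor_table()]
#'   or [simulate_psilac()].
#' @param path Output TSV path.
#' @param seed Seed recorded in the provenance comment line, if any.
#' @return The path, invisibly.
#' @export
write_precursor_table <- function(x, path, seed = NA) {
  write_pk_tsv(x[, PRECURSOR_COLUMNS], path, command = "precursors", seed = seed)
}

# ---- expression matrices ----------------------------------------------------

#' Construct an expression table
#'
#' An expression table holds transcript-level abundances (FPKM) for a set of
#' (sample, replicate) columns. It is a numeric matrix (rows = transcripts)
#' with a `samples` attribute describing each column.
#'
#' @param values Numeric matrix, rows named by transcript id.
#' @param sample_id Character vector, one entry per column of `values`.
#' @param replicate Integer vector, one entry per column of `values`.
#' @return An object of class `expr_table`.
#' @export
expression_table <- function(values, sample_id, replicate) {
  stopifnot(is.matrix(values), length(sample_id) == ncol(values),
            length(replicate) == ncol(values))
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop_format("expression matrix must have transcript ids as row names")
  if (any(values < 0, na.rm = TRUE))
    stop_format("expression matrix contains negative FPKM")
  colnames(values) <- paste0(sample_id, ":", replicate)
  structure(values,
            samples = data.frame(column = colnames(values),
                                 sample_id = as.character(sample_id),
                                 replicate = as.integer(replicate),
                                 stringsAsFactors = FALSE),
            class = c("expr_table", "matrix", "array"))
}

#' @export
print.expr_table <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("expr_table: %d transcripts x %d columns (%d samples)\n",
              nrow(x), ncol(x), length(unique(s$sample_id))))
  invisible(x)
}

#' Column metadata of an expression table
#'
#' @param x An `expr_table`.
#' @return A `data.frame` with `column`, `sample_id`, `replicate`.
#' @export
expr_samples <- function(x) attr(x, "samples")

#' Per-sample mean expression (replicates averaged)
#'
#' @param x An `expr_table`.
#' @return Numeric matrix, transcripts x samples, replicate columns averaged.
#' @export
expr_sample_means <- function(x) {
  s <- expr_samples(x)
  samples <- unique(s$sample_id)
  out <- matrix(NA_real_, nrow(x), length(samples),
                dimnames = list(rownames(x), samples))
  for (sm in samples)
    out[, sm] <- rowMeans(x[, s$column[s$sample_id == sm], drop = FALSE],
                          na.rm = TRUE)
  out
}

#' Read a transcript expression matrix (FPKM)
#'
#' The file is a TSV whose first column is `transcript_id` and whose
#' remaining columns are named `<sample_id>:<replicate>`.
#'
#' @param path Path to the TSV file.
#' @return An `expr_table`.
#' @export
read_expression_matrix <- function(path) {
  raw <- read_pk_tsv(path)
  if (names(raw)[1] != "transcript_id")
    stop_format("expression matrix ", path,
                ": first column must be 'transcript_id'")
  ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_format("expression matrix ", path, ": negative FPKM at data line ",
                neg[1, 1], ", column '", colnames(vals)[neg[1, 2]], "'")
  parts <- regmatches(colnames(vals), regexec("^(.*):(\\d+)$", colnames(vals)))
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0)
    stop_format("expression matrix ", path, ": column '",
                colnames(vals)[bad[1]], "' is not of the form sample:replicate")
  expression_table(vals,
                   sample_id = vapply(parts, `[`, "", 2L),
                   replicate = as.integer(vapply(parts, `[`, "", 3L)))
}

#' Write a transcript expression matrix
#'
#' @param x An `expr_table`.
#' @param path Output TSV path.
#' @param seed Seed recorded in the provenance line, if any.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(x, path, seed = NA) {
  df <- data.frame(transcript_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_pk_tsv(df, path, command = "expression", seed = seed)
}

# ---- transcript annotations -------------------------------------------------

TRANSCRIPT_BIOTYPES <- c("protein_coding", "retained_intron", "other")

#' Read a transcript annotation table
#'
#' TSV with columns `gene_id`, `transcript_id`, `biotype`,
#' `protein_sequence`. Only `protein_coding` transcripts may (and must)
#' carry a protein sequence.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of transcript records.
#' @export
read_transcripts <- function(path) {
  raw <- read_pk_tsv(path, colClasses = "character")
  need <- c("gene_id", "transcript_id", "biotype", "protein_sequence")
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0)
    stop_format("transcript table ", path, " is missing column(s): ",
                paste(absent, collapse = ", "))
  out <- raw[, need]
  out$protein_sequence[is.na(out$protein_sequence)] <- ""
  validate_transcripts(out, path)
}

#' @noRd
validate_transcripts <- function(x, origin = "transcript table") {
  dup <- which(duplicated(x$transcript_id))
  if (length(dup) > 0)
    stop_format(origin, ": duplicate transcript_id '", x$transcript_id[dup[1]],
                "' at data line ", dup[1])
  bad_bt <- which(!x$biotype %in% TRANSCRIPT_BIOTYPES)
  if (length(bad_bt) > 0)
    stop_format(origin, ": unknown biotype '", x$biotype[bad_bt[1]],
                "' at data line ", bad_bt[1])
  coding <- x$biotype == "protein_coding"
  if (any(coding & x$protein_sequence == ""))
    stop_format(origin, ": protein_coding transcript without protein ",
                "sequence: ", x$transcript_id[which(coding & x$protein_sequence == "")[1]])
  seqs <- x$protein_sequence[x$protein_sequence != ""]
  bad <- which(!grepl(AA_REGEX, seqs))
  if (length(bad) > 0)
    stop_format(origin, ": illegal residue in protein sequence of record ",
                x$transcript_id[x$protein_sequence != ""][bad[1]])
  x
}

#' Write a transcript annotation table
#'
#' @param x Transcript `data.frame` (see [read_transcripts()]).
#' @param path Output TSV path.
#' @param seed Seed recorded in the provenance line, if any.
#' @return The path, invisibly.
#' @export
write_transcripts <- function(x, path, seed = NA) {
  write_pk_tsv(x[, c("gene_id", "transcript_id", "biotype", "protein_sequence")],
               path, command = "transcripts", seed = seed)
}

# ---- FASTA ------------------------------------------------------------------

#' Write protein records to FASTA
#'
#' Headers carry `>transcript_id|gene_id|biotype` so a database entry can be
#' traced back to its transcript.
#'
#' @param records Transcript `data.frame` with non-empty `protein_sequence`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (any(records$protein_sequence == ""))
    stop_format("cannot write FASTA: record without protein sequence (",
                records$transcript_id[records$protein_sequence == ""][1], ")")
  seqs <- Biostrings::AAStringSet(records$protein_sequence)
  names(seqs) <- paste(records$transcript_id, records$gene_id,
                       records$biotype, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Read protein records from FASTA
#'
#' @param path FASTA path with `>transcript_id|gene_id|biotype` headers.
#' @return A transcript `data.frame` (see [read_transcripts()]).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0)
    stop_format("FASTA ", path, ": header '", names(seqs)[bad[1]],
                "' is not of the form transcript_id|gene_id|biotype")
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 2L),
    transcript_id = vapply(parts, `[`, "", 1L),
    biotype = vapply(parts, `[`, "", 3L),
    protein_sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  validate_transcripts(out, origin = paste0("FASTA ", path))
}

# ---- annotation terms -------------------------------------------------------

#' Read an annotation term file
#'
#' Two-column TSV `term<TAB>key` mapping annotation terms (e.g. GO
#' categories) to protein-group keys.
#'
#' @param path Path to the TSV file.
#' @return A named list: term -> character vector of member keys.
#' @export
read_annotations <- function(path) {
  raw <- read_pk_tsv(path, colClasses = "character")
  if (!all(c("term", "key") %in% names(raw)))
    stop_format("annotation file ", path, " must have columns 'term' and 'key'")
  split(raw$key, raw$term)
}
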