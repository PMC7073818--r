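# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 20 standard residues; B/J/O/U/X/Z deliberately absent.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

AA_REGEX <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")

pk_version <- function() {
  as.character(utils::packageVersion("pulsekin"))
}

#' @noRd
#' sdlog of a lognormal multiplier with mean 1 and coefficient of variation cv
lognormal_sigma <- function(cv) {
  stopifnot(cv >= 0)
  sqrt(log(1 + cv^2))
}

#' @noRd
#' multiplicative lognormal noise factors with mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lognormal_sigma(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == trunc(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pk_config_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("pk_format_error", "error")))
}

#' @noRd
#' Write a TSV with the pulsekin provenance comment line.
write_pk_tsv <- function(x, path, command = "write", seed = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pulsekin %s %s %s", pk_version(), command,
                     ifelse(is.na(seed), "-", as.character(seed))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' @noRd
#' Read a TSV written by write_pk_tsv (or any headered TSV; '#' lines skipped).
read_pk_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' @noRd
#' Derive a per-stage seed from the global seed (kept below 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 77761 * as.numeric(index)) %% 2147483647)
}
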