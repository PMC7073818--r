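# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Enumerate every substring of a protein that is a valid fully tryptic
# peptide: starts at the N-terminus or right after a cleavage site, ends at
# the C-terminus or at a cleavage site, has at most `mc` internal cleavage
# sites, and length within bounds. A cleavage site is a K/R not followed
# by P.
oracle_digest <- function(seq, mc = 2, min_len = 7, max_len = 30) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  is_site <- ch %in% c("K", "R") & c(ch[-1] != "P", FALSE)
  out <- character(0)
  for (i in seq_len(n)) {
    if (i != 1 && !is_site[i - 1]) next
    for (j in i:n) {
      if (j != n && !is_site[j]) next
      len <- j - i + 1
      if (len < min_len || len > max_len) next
      # sites strictly inside the peptide: cleavage after residues i..j-1
      internal <- if (j > i) sum(is_site[i:(j - 1)]) else 0
      if (internal <= mc) out <- c(out, substr(seq, i, j))
    }
  }
  unique(out)
}

# Peptide -> transcript sets via oracle digestion; classification by direct
# counting.
oracle_classify <- function(db, transcripts, mc = 2, min_len = 7,
                            max_len = 30) {
  maps <- lapply(seq_len(nrow(db)), function(i) {
    peps <- oracle_digest(db$protein_sequence[i], mc, min_len, max_len)
    if (length(peps) == 0) return(NULL)
    data.frame(peptide = peps, transcript_id = db$transcript_id[i],
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, maps)
  m$gene_id <- transcripts$gene_id[match(m$transcript_id,
                                         transcripts$transcript_id)]
  sp <- split(m, m$peptide)
  do.call(rbind, lapply(sp, function(d) {
    tids <- sort(unique(d$transcript_id))
    gids <- sort(unique(d$gene_id))
    data.frame(peptide = d$peptide[1],
               transcript_ids = paste(tids, collapse = ";"),
               gene_ids = paste(gids, collapse = ";"),
               class = if (length(gids) > 1) "multi_gene"
               else if (length(tids) == 1) "unique" else "shared",
               stringsAsFactors = FALSE)
  }))
}

# Major transcript of a member set: highest FPKM averaged over samples
# (replicates averaged per sample first), lexicographic tie-break.
oracle_major <- function(tids, expression) {
  s <- expr_samples(expression)
  per_sample <- sapply(unique(s$sample_id), function(sm) {
    cols <- s$column[s$sample_id == sm]
    rowMeans(unclass(expression)[, cols, drop = FALSE])
  })
  avg <- rowMeans(per_sample)
  v <- ifelse(tids %in% names(avg), avg[tids], 0)
  names(v) <- tids
  cand <- sort(names(v)[v == max(v)])
  cand[1]
}

# Rank-then-Pearson Spearman oracle (average ranks for ties).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Grid search for the decay rate minimizing sum((y - exp(-k t))^2) over
# k in (0, 5]: coarse grid then local refinement.
oracle_grid_k <- function(t, y, lo = 1e-4, hi = 5) {
  for (pass in 1:3) {
    ks <- seq(lo, hi, length.out = 4001)
    sse <- vapply(ks, function(k) sum((y - exp(-k * t))^2), 0)
    best <- ks[which.min(sse)]
    step <- ks[2] - ks[1]
    lo <- max(1e-6, best - 2 * step); hi <- best + 2 * step
  }
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of member subsets
# (no ties, n <= 10): doubles the smaller tail of the exact U distribution.
oracle_mw_exact <- function(x_in, x_out) {
  scores <- c(x_in, x_out)
  n <- length(scores); m <- length(x_in)
  r <- rank(scores)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(n, m)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# A tiny random transcriptome with shared/unique protein segments, for
# mapping-correctness checks.
make_toy_transcriptome <- function(seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seg <- function(n) paste(sample(aa, n, replace = TRUE,
                                  prob = ifelse(aa %in% c("K", "R"), 2, 1)),
                           collapse = "")
  rec <- list()
  for (g in 1:3) {
    n_iso <- sample(1:3, 1)
    pre <- seg(sample(15:25, 1)); post <- seg(sample(15:25, 1))
    for (j in seq_len(n_iso)) {
      rec[[length(rec) + 1]] <- data.frame(
        gene_id = sprintf("TG%d", g),
        transcript_id = sprintf("TG%d.T%d", g, j),
        biotype = "protein_coding",
        protein_sequence = paste0(pre, seg(sample(8:15, 1)), post),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rec)
}

# Expression table fixture: given a matrix of per-sample values and a
# replicate count, expand to replicate columns (identical values).
make_expr <- function(values, n_replicates = 1) {
  stopifnot(is.matrix(values))
  samples <- colnames(values)
  vals <- values[, rep(samples, each = n_replicates), drop = FALSE]
  expression_table(vals,
                   sample_id = rep(samples, each = n_replicates),
                   replicate = rep(seq_len(n_replicates), times = length(samples)))
}
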