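# Rank-based 1D and 2D annotation enrichment. For each annotation term the
# member scores are compared to the non-member scores with a two-sided
# Mann-Whitney U test, and located by the bounded rank score
# s = 2 * (mean rank in - mean rank out) / n, which lies in [-1, 1] and is
# invariant under monotone transforms of the scores.

#' @noRd
rank_score <- function(ranks, is_member) {
  n <- length(ranks)
  2 * (mean(ranks[is_member]) - mean(ranks[!is_member])) / n
}

#' One-dimensional rank-based annotation enrichment
#'
#' @param scores Named numeric vector: key -> score (e.g. per-group rho or
#'   log2 fold change).
#' @param annotations Named list (term -> character vector of member keys) or
#'   a `data.frame` with columns `term` and `key`.
#' @param min_members Minimum annotated keys present in `scores` for a term
#'   to be tested (default 10).
#' @return `data.frame` sorted by q: `term`, `n_members`, `s` (rank score in
#'   [-1, 1]), `p` (two-sided Mann-Whitney), `q` (BH).
#' @export
enrich_1d <- function(scores, annotations, min_members = 10L) {
  annotations <- as_annotation_list(annotations)
  scores <- scores[!is.na(scores)]
  keys <- names(scores)
  if (is.null(keys)) stop_config("scores must be a named vector")
  ranks <- rank(scores)
  n <- length(scores)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(annotations[[term]], keys)
    m <- length(members)
    if (m < min_members || m == n) return(NULL)
    is_mem <- keys %in% members
    p <- suppressWarnings(
      stats::wilcox.test(scores[is_mem], scores[!is_mem])$p.value)
    data.frame(term = term, n_members = m,
               s = rank_score(ranks, is_mem), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), n_members = integer(),
                      s = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$term), , drop = FALSE]
}

#' Two-dimensional rank-based annotation enrichment
#'
#' Computes the two 1D rank scores independently on the keys present in both
#' score maps. The joint p-value is the larger of the two per-dimension
#' Mann-Whitney p-values (conservative); the quadrant label locates the term
#' (e.g. `"upper right"`: both scores positive — for mRNA-x / k_loss-y axes
#' the buffering quadrant).
#'
#' @param scores_x,scores_y Named numeric vectors sharing a key space.
#' @param annotations See [enrich_1d()].
#' @param min_members See [enrich_1d()].
#' @return `data.frame` sorted by q: `term`, `n_members`, `s_x`, `s_y`,
#'   `p`, `q`, `quadrant`.
#' @export
enrich_2d <- function(scores_x, scores_y, annotations, min_members = 10L) {
  annotations <- as_annotation_list(annotations)
  shared <- intersect(names(scores_x)[!is.na(scores_x)],
                      names(scores_y)[!is.na(scores_y)])
  x <- scores_x[shared]; y <- scores_y[shared]
  rx <- rank(x); ry <- rank(y)
  n <- length(shared)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(annotations[[term]], shared)
    m <- length(members)
    if (m < min_members || m == n) return(NULL)
    is_mem <- shared %in% members
    px <- suppressWarnings(stats::wilcox.test(x[is_mem], x[!is_mem])$p.value)
    py <- suppressWarnings(stats::wilcox.test(y[is_mem], y[!is_mem])$p.value)
    sx <- rank_score(rx, is_mem); sy <- rank_score(ry, is_mem)
    data.frame(term = term, n_members = m, s_x = sx, s_y = sy,
               p = max(px, py),
               quadrant = paste(ifelse(sy >= 0, "upper", "lower"),
                                ifelse(sx >= 0, "right", "left")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), n_members = integer(),
                      s_x = numeric(), s_y = numeric(), p = numeric(),
                      q = numeric(), quadrant = character(),
                      stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term),
             c("term", "n_members", "s_x", "s_y", "p", "q", "quadrant")]
  rownames(out) <- NULL
  out
}

#' @noRd
as_annotation_list <- function(annotations) {
  if (is.data.frame(annotations)) {
    if (!all(c("term", "key") %in% names(annotations)))
      stop_config("annotation data.frame needs columns 'term' and 'key'")
    return(split(annotations$key, annotations$term))
  }
  if (!is.list(annotations) || is.null(names(annotations)))
    stop_config("annotations must be a named list or a term/key data.frame")
  annotations
}
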