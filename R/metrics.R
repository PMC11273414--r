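# Retrieval evaluation: average precision per query, MAP and MAP@k, and the
# rank-1 (MAP@1) confusion matrix. Relevance is defined as sharing the
# query's class label.

#' Average precision of one ranked result list
#'
#' `AP = (1/n_gt) * sum_k P(k) * r(k)` where `P(k)` is the precision among
#' the top k results and `r(k)` indicates a relevant result at rank k.
#'
#' @param relevance binary (0/1 or logical) vector down the ranking.
#' @param n_gt number of ground-truth relevant items for this query; must be
#'   >= 1 and >= `sum(relevance)`.
#' @return scalar in `[0, 1]`.
#' @export
average_precision <- function(relevance, n_gt) {
  relevance <- as.numeric(relevance)
  if (n_gt < 1) stop("average precision undefined for n_gt = 0")
  if (sum(relevance) > n_gt)
    stop("more relevant results than ground-truth relevants")
  if (length(relevance) == 0) return(0)
  prec <- cumsum(relevance) / seq_along(relevance)
  sum(prec * relevance) / n_gt
}

#' Mean average precision over queries, optionally truncated at depth k
#'
#' Each relevance list is truncated to its top `k` entries, AP is computed
#' per query and averaged. For the truncated metric the AP denominator is
#' `min(n_gt, k)` by default, so a perfect top-k list scores 1 and MAP@1
#' coincides with top-1 accuracy; `normalize = "gt"` keeps the full `n_gt`
#' denominator instead.
#'
#' @param relevances list of binary relevance vectors, one per query, ranked
#'   best-first.
#' @param n_gts integer vector of ground-truth relevant counts per query.
#' @param k truncation depth; `Inf` evaluates the full ranking.
#' @param normalize `"clamped"` (denominator `min(n_gt, k)`) or `"gt"`
#'   (raw `n_gt`).
#' @return scalar MAP in `[0, 1]`.
#' @export
mean_average_precision <- function(relevances, n_gts, k = Inf,
                                   normalize = c("clamped", "gt")) {
  normalize <- match.arg(normalize)
  if (length(relevances) == 0) stop("empty query set")
  stopifnot(length(n_gts) == length(relevances))
  aps <- vapply(seq_along(relevances), function(q) {
    rel <- as.numeric(relevances[[q]])
    if (is.finite(k)) rel <- head(rel, k)
    denom <- if (normalize == "clamped" && is.finite(k))
      min(n_gts[q], k) else n_gts[q]
    average_precision(rel, max(denom, sum(rel)))
  }, numeric(1))
  mean(aps)
}

#' Rank-1 retrieval confusion matrix
#'
#' Entry (i, j) is the fraction of class-i queries whose top-ranked retrieved
#' item has class j. Rows of represented classes sum to 1; the label-weighted
#' mean of the diagonal equals MAP@1.
#'
#' @param query_labels integer class ids of the queries.
#' @param top1_labels integer class ids of each query's rank-1 result.
#' @param n_classes number of classes C.
#' @return `C x C` row-normalized matrix.
#' @export
map1_confusion <- function(query_labels, top1_labels, n_classes) {
  M <- matrix(0, n_classes, n_classes)
  for (q in seq_along(query_labels))
    M[query_labels[q] + 1L, top1_labels[q] + 1L] <-
      M[query_labels[q] + 1L, top1_labels[q] + 1L] + 1
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  dimnames(M) <- list(query = 0:(n_classes - 1L),
                      retrieved = 0:(n_classes - 1L))
  M
}

#' Evaluate retrieval of query codes against a database index
#'
#' Runs every query through the index, scores rankings by class-label
#' relevance, and assembles the full evaluation report.
#'
#' @param index a [retrieval_index()] over the database set.
#' @param query_codes `(Nq, L)` matrix of query codes in \{-1,+1\}.
#' @param query_labels integer class ids of the queries.
#' @param k report MAP@k at this depth (clamped to the database size).
#' @param query_ids optional query source ids; when given, a database entry
#'   with an identical id is excluded from that query's candidates.
#' @param normalize MAP@k normalization, see [mean_average_precision()].
#' @return list with `ap_per_query`, `map`, `map_at_k`, `map_at_1`, `k`,
#'   `confusion_map1`.
#' @export
evaluate_retrieval <- function(index, query_codes, query_labels, k = 10L,
                               query_ids = NULL,
                               normalize = c("clamped", "gt")) {
  normalize <- match.arg(normalize)
  if (is.null(dim(query_codes))) query_codes <- matrix(query_codes, nrow = 1L)
  Nq <- nrow(query_codes)
  if (Nq == 0 || index$N == 0) stop("empty query or database set")
  stopifnot(length(query_labels) == Nq)
  relevances <- vector("list", Nq)
  n_gts <- integer(Nq)
  top1 <- integer(Nq)
  for (q in seq_len(Nq)) {
    res <- query_index(index, query_codes[q, ], k = index$N,
                       exclude_id = if (is.null(query_ids)) NULL else query_ids[q])
    rel <- as.numeric(res$labels == query_labels[q])
    n_gt <- sum(rel)
    if (n_gt == 0) n_gt <- 1L   # no same-class item reachable: AP is 0
    relevances[[q]] <- rel
    n_gts[q] <- n_gt
    top1[q] <- res$labels[1L]
  }
  C <- max(c(index$labels, query_labels)) + 1L
  kk <- min(as.integer(k), index$N)
  list(ap_per_query = vapply(seq_len(Nq), function(q)
         average_precision(relevances[[q]], n_gts[q]), numeric(1)),
       map = mean_average_precision(relevances, n_gts, Inf),
       map_at_k = mean_average_precision(relevances, n_gts, kk, normalize),
       map_at_1 = mean_average_precision(relevances, n_gts, 1L, normalize),
       k = kk,
       confusion_map1 = map1_confusion(query_labels, top1, C))
}
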