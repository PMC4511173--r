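# Maximum-weight one-to-one pairing on a weight matrix (rows = reference
# items, columns = predicted items). Entries <= 0 are not pairable. Backed
# by igraph's maximum-weight bipartite matching; a tiny epsilon is added to
# every eligible edge so that, at equal total weight, pairings covering
# more eligible pairs are preferred (an overlapping pair with similarity 0
# still counts as a substitution rather than a deletion + insertion).
max_weight_pairing <- function(w, eligible = w > 0) {
  n <- nrow(w)
  m <- ncol(w)
  empty <- data.frame(i = integer(), j = integer(), weight = numeric())
  if (n == 0L || m == 0L || !any(eligible)) return(empty)
  idx <- which(eligible, arr.ind = TRUE)
  edges <- as.vector(rbind(idx[, 1L], n + idx[, 2L]))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n), rep(TRUE, m)), edges)
  eps <- 1e-9
  mt <- igraph::max_bipartite_match(g, weights = w[idx] + eps)$matching
  i <- which(!is.na(mt[seq_len(n)]))
  if (length(i) == 0L) return(empty)
  j <- mt[i] - n
  data.frame(i = i, j = j, weight = w[cbind(i, j)])
}

#' Optimal one-to-one pairing of reference and predicted entities
#'
#' Because boundaries and categories are approximate, several matchings
#' between reference and predicted entities are usually possible; the score
#' assumes each predicted entity matches a single reference entity and vice
#' versa. This operation returns the one-to-one matching over *overlapping*
#' pairs that maximizes the total similarity (the participant's score).
#' Entities that overlap no counterpart are never matched: leftover
#' reference entities are deletions, leftover predictions insertions.
#'
#' @param refs,preds lists of [entity()] objects.
#' @param similarity function `(ref, pred) -> numeric similarity in [0, 1]`;
#'   defaults to [segment_similarity()].
#' @return An object of class `bt_pairing`: a list with `pairs` (data.frame
#'   of `ref`, `pred` indices and `similarity`), `unmatched_ref` and
#'   `unmatched_pred` index vectors.
#' @export
pair_entities <- function(refs, preds, similarity = segment_similarity) {
  n <- length(refs)
  m <- length(preds)
  w <- matrix(0, n, m)
  eligible <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (entities_overlap(refs[[i]], preds[[j]])) {
        eligible[i, j] <- TRUE
        w[i, j] <- similarity(refs[[i]], preds[[j]])
      }
    }
  }
  pairing <- max_weight_pairing(w, eligible)
  structure(list(
    pairs = data.frame(ref = pairing$i, pred = pairing$j,
                       similarity = pairing$weight),
    unmatched_ref = setdiff(seq_len(n), pairing$i),
    unmatched_pred = setdiff(seq_len(m), pairing$j)
  ), class = "bt_pairing")
}

#' @export
print.bt_pairing <- function(x, ...) {
  cat(sprintf("<bt_pairing: %d pair(s), %d unmatched ref, %d unmatched pred>\n",
              nrow(x$pairs), length(x$unmatched_ref),
              length(x$unmatched_pred)))
  invisible(x)
}
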