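#' Boundary similarity between two text-bound entities
#'
#' Jaccard index applied to segments, extended to discontinuous spans: the
#' ratio between the number of character offsets covered by both entities
#' and the number covered by either, across all fragments. Equal spans give
#' 1; barely overlapping spans tend to 0; disjoint spans give 0.
#'
#' @param a,b [entity()] objects from the same document.
#' @return Similarity `Se` in `[0, 1]`.
#' @examples
#' segment_similarity(entity("T1", "Habitat", "0 10"),
#'                    entity("T2", "Habitat", "5 15"))  # 1/3
#' @export
segment_similarity <- function(a, b) {
  oa <- covered_offsets(a$fragments)
  ob <- covered_offsets(b$fragments)
  length(intersect(oa, ob)) / length(union(oa, ob))
}

entities_overlap <- function(a, b) {
  length(intersect(covered_offsets(a$fragments),
                   covered_offsets(b$fragments))) > 0L
}

entities_same_span <- function(a, b) {
  identical(a$fragments$start, b$fragments$start) &&
    identical(a$fragments$end, b$fragments$end)
}

#' Category similarity between concept assignments
#'
#' Wang-similarity-based credit for approximate categorization: an ancestor
#' prediction is favored over a sibling, and credit decays with hierarchy
#' distance. For singleton sets this is plain [wang_similarity()]. For
#' multi-label sets the default aggregation is the mean over reference
#' concepts of the best similarity to any predicted concept
#' (`"mean_max"`); `"max_matching"` instead averages an optimal one-to-one
#' concept matching over the reference set size.
#'
#' An empty reference set means no categorization is required (`Sc = 1`);
#' a non-empty reference with an empty prediction scores 0.
#'
#' @param onto a [ontology()].
#' @param ref_concepts,pred_concepts character vectors of concept ids.
#' @param cfg a [wang_config()].
#' @param aggregate `"mean_max"` or `"max_matching"`.
#' @return Similarity `Sc` in `[0, 1]`.
#' @export
category_similarity <- function(onto, ref_concepts, pred_concepts,
                                cfg = wang_config(),
                                aggregate = c("mean_max", "max_matching")) {
  aggregate <- match.arg(aggregate)
  ref_concepts <- unique(as.character(ref_concepts))
  pred_concepts <- unique(as.character(pred_concepts))
  if (length(ref_concepts) == 0L) return(1)
  if (length(pred_concepts) == 0L) return(0)
  w <- outer(ref_concepts, pred_concepts,
             Vectorize(function(r, p) wang_similarity(onto, r, p, cfg)))
  if (aggregate == "mean_max") {
    return(mean(apply(w, 1L, max)))
  }
  pairs <- max_weight_pairing(w)
  sum(w[as.matrix(pairs[, c("i", "j")])]) / length(ref_concepts)
}
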