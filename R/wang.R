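#' Wang similarity configuration
#'
#' Each hierarchical relation contributes a semantic factor in (0, 1): the
#' S-value of a concept decays by this factor per edge on the way to an
#' ancestor. The canonical factor for `is_a` in the Wang method is 0.8;
#' other relations fall back to `default_weight` unless named in `weights`.
#'
#' @param weights named numeric vector, relation name -> factor in (0, 1).
#' @param default_weight factor for relations not named in `weights`.
#' @return An object of class `wang_config`.
#' @export
wang_config <- function(weights = c(is_a = 0.8), default_weight = 0.8) {
  w <- c(as.numeric(weights), default_weight)
  if (any(w <= 0 | w >= 1)) {
    bt_stop("wang_config: all weights must lie in (0, 1)",
            class = "bteval_config_error")
  }
  structure(list(weights = weights, default_weight = default_weight),
            class = "wang_config")
}

relation_weight <- function(cfg, relation) {
  w <- cfg$weights[relation]
  ifelse(is.na(w), cfg$default_weight, w)
}

# S-values of a concept over its ancestor closure: S_X(X) = 1 and, walking
# upward, S_X(t) = max over children c of t inside the closure of
# w(c -> t) * S_X(c). Propagated in topological order (children first),
# which terminates because the ontology is a DAG.
wang_svalues <- function(onto, id, cfg) {
  closure <- ancestor_closure(onto, id)
  # Kahn topological order on the closure subgraph, child-before-parent
  pending <- sapply(closure, function(t) {
    sum(vapply(closure, function(c)
      sum(onto$concepts[[c]]$parents$parent == t), 0L))
  })
  names(pending) <- closure
  s <- stats::setNames(rep(-Inf, length(closure)), closure)
  s[[id]] <- 1
  queue <- closure[pending == 0L] # starts at id (no in-closure children)
  while (length(queue)) {
    c <- queue[[1L]]
    queue <- queue[-1L]
    par <- onto$concepts[[c]]$parents
    for (i in seq_len(nrow(par))) {
      p <- par$parent[[i]]
      if (!p %in% closure) next
      w <- relation_weight(cfg, par$relation[[i]])
      s[[p]] <- max(s[[p]], w * s[[c]])
      pending[[p]] <- pending[[p]] - 1L
      if (pending[[p]] == 0L) queue <- c(queue, p)
    }
  }
  s
}

#' Wang semantic similarity between two ontology concepts
#'
#' Aggregates the weighted contributions (S-values) of the ancestors that
#' two concepts share, relative to each concept's total semantic value:
#' \deqn{sim(a, b) = \frac{\sum_{t \in T_a \cap T_b} S_a(t) + S_b(t)}
#'                        {SV(a) + SV(b)}}
#' where \eqn{T_x} is the ancestor closure of \eqn{x}, \eqn{S_x} its
#' S-values and \eqn{SV(x) = \sum_t S_x(t)}. The measure is symmetric, 1 on
#' identical concepts, and favors ancestor predictions over sibling
#' predictions: an over-general category is still partially right, while
#' the credit decays faster than the number of edges on the path.
#'
#' @param onto a [ontology()].
#' @param a,b concept ids.
#' @param cfg a [wang_config()].
#' @return Similarity in (0, 1] when the concepts share a root, 0 otherwise.
#' @examples
#' onto <- load_obo(c("[Term]", "id: A", "name: a", "is_a: B",
#'                    "", "[Term]", "id: B", "name: b", "is_a: C",
#'                    "", "[Term]", "id: C", "name: c"))
#' wang_similarity(onto, "A", "C")  # 1.64 / 3.44
#' @export
wang_similarity <- function(onto, a, b, cfg = wang_config()) {
  sa <- wang_svalues(onto, a, cfg)
  sb <- wang_svalues(onto, b, cfg)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0L) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}
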