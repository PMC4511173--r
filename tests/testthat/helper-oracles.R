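# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Recursive Wang S-value oracle: S_X(X) = 1, S_X(t) = max over children c of
# t inside X's ancestor closure of w * S_X(c). Plain recursion, no memoing.
oracle_wang <- function(onto, a, b, w = 0.8) {
  parents_of <- function(id) onto$concepts[[id]]$parents$parent
  closure <- function(id) {
    out <- id
    for (p in parents_of(id)) out <- union(out, closure(p))
    out
  }
  svalue <- function(x, t, cl) {
    if (t == x) return(1)
    kids <- Filter(function(c) t %in% parents_of(c), cl)
    max(vapply(kids, function(c) w * svalue(x, c, cl), 0))
  }
  ca <- closure(a)
  cb <- closure(b)
  sa <- vapply(ca, function(t) svalue(a, t, ca), 0)
  sb <- vapply(cb, function(t) svalue(b, t, cb), 0)
  common <- intersect(ca, cb)
  if (length(common) == 0) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# Exhaustive maximum-total-similarity one-to-one matching over an
# eligibility/weight matrix (rows = refs, cols = preds).
oracle_best_matching <- function(w, eligible = w > 0) {
  n <- nrow(w)
  m <- ncol(w)
  best <- 0
  recurse <- function(i, used, total) {
    if (i > n) {
      best <<- max(best, total)
      return(invisible())
    }
    recurse(i + 1L, used, total) # leave ref i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && eligible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, total + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}

# Small deterministic is_a chain ontology C <- B <- A (A most specific),
# with one sibling A2 of A, used across Wang tests.
chain_ontology <- function() {
  load_obo(c(
    "[Term]", "id: C", "name: root", "",
    "[Term]", "id: B", "name: mid", "is_a: C", "",
    "[Term]", "id: A", "name: leaf", "is_a: B", "",
    "[Term]", "id: A2", "name: sibling leaf", "is_a: B"
  ))
}

# Random entity set over a short text span: single- or two-fragment spans.
random_entities <- function(n, text_len = 40L, prefix = "T") {
  lapply(seq_len(n), function(i) {
    s <- sample.int(text_len - 4L, 1L) - 1L
    e <- s + sample.int(6L, 1L) + 1L
    e <- min(e, text_len)
    frags <- if (runif(1) < 0.2 && e + 4L <= text_len - 2L) {
      s2 <- e + 2L
      fragments(c(s, s2), c(e, min(s2 + 3L, text_len)))
    } else {
      fragments(s, e)
    }
    entity(paste0(prefix, i), "Habitat", frags)
  })
}

# Reference BB document plus a prediction with every habitat boundary
# nudged by one character (events kept), for relaxation-dominance checks.
jittered_event_prediction <- function(doc) {
  pred <- doc
  for (id in names(pred$entities)) {
    en <- pred$entities[[id]]
    if (en$type != "Habitat") next
    f <- en$fragments
    if (f$end[1L] - f$start[1L] >= 2L) {
      f$start[1L] <- f$start[1L] + 1L
    } else {
      f$end[1L] <- f$end[1L] + 1L
    }
    pred$entities[[id]]$fragments <- f
  }
  pred
}
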