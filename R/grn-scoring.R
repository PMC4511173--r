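#' Compare two regulation networks arc by arc
#'
#' Errors are counted per ordered gene pair and summed over pairs. On a
#' pair, arcs carrying the same label in both networks are matches; leftover
#' reference and predicted labels on the same pair align into substitutions
#' (right arc, wrong label); reference arcs with no counterpart are
#' deletions, predicted arcs with no counterpart insertions. An *inversion*
#' (the agent and target roles confused, so the predicted arc runs the other
#' way) is reported separately; the counting policy is configurable:
#' \describe{
#'   \item{`"del-ins"`}{(default) the inverted arc stays a deletion on the
#'     reference pair plus an insertion on the reversed pair — the plain
#'     graph-diff reading;}
#'   \item{`"substitution"`}{each inversion is folded into a single
#'     substitution, removing one deletion and one insertion.}
#' }
#' Either way `M + S + D = N` holds.
#'
#' @param ref,pred [grn_network()] objects over the same gene-name space.
#' @param inversion_policy `"del-ins"` or `"substitution"`.
#' @return An object of class `arc_diff` with counts `M`, `S`, `D`, `I`,
#'   `N`, `P`, `inversions`, and a `substitution` data.frame listing
#'   (agent, target, ref label, pred label) for each label mismatch.
#' @export
diff_networks <- function(ref, pred,
                          inversion_policy = c("del-ins", "substitution")) {
  inversion_policy <- match.arg(inversion_policy)
  pair_key <- function(a, t) paste(a, t, sep = "\r")
  rp <- pair_key(ref$arcs$agent, ref$arcs$target)
  pp <- pair_key(pred$arcs$agent, pred$arcs$target)

  M <- 0L; S <- 0L; D <- 0L; I <- 0L
  subst <- data.frame(agent = character(), target = character(),
                      ref_label = character(), pred_label = character(),
                      stringsAsFactors = FALSE)
  del_arcs <- ins_arcs <- data.frame(agent = character(), label = character(),
                                     target = character(),
                                     stringsAsFactors = FALSE)
  for (key in union(rp, pp)) {
    ra <- ref$arcs[rp == key, , drop = FALSE]
    pa <- pred$arcs[pp == key, , drop = FALSE]
    common <- intersect(ra$label, pa$label)
    M <- M + length(common)
    ref_left <- ra[!ra$label %in% common, , drop = FALSE]
    pred_left <- pa[!pa$label %in% common, , drop = FALSE]
    ns <- min(nrow(ref_left), nrow(pred_left))
    S <- S + ns
    if (ns > 0L) {
      subst <- rbind(subst, data.frame(
        agent = ref_left$agent[seq_len(ns)],
        target = ref_left$target[seq_len(ns)],
        ref_label = ref_left$label[seq_len(ns)],
        pred_label = pred_left$label[seq_len(ns)],
        stringsAsFactors = FALSE))
    }
    if (nrow(ref_left) > ns) {
      del_arcs <- rbind(del_arcs, ref_left[(ns + 1L):nrow(ref_left), ,
                                           drop = FALSE])
    }
    if (nrow(pred_left) > ns) {
      ins_arcs <- rbind(ins_arcs, pred_left[(ns + 1L):nrow(pred_left), ,
                                            drop = FALSE])
    }
  }
  D <- nrow(del_arcs)
  I <- nrow(ins_arcs)

  # Inversions: a deleted reference arc whose reversed (target, agent, label)
  # appears among the leftover insertions. Greedy one-to-one pairing.
  inversions <- 0L
  if (D > 0L && I > 0L) {
    ins_used <- rep(FALSE, I)
    ins_key <- paste(ins_arcs$agent, ins_arcs$label, ins_arcs$target,
                     sep = "\r")
    for (i in seq_len(D)) {
      rev_key <- paste(del_arcs$target[i], del_arcs$label[i],
                       del_arcs$agent[i], sep = "\r")
      j <- which(!ins_used & ins_key == rev_key)
      if (length(j)) {
        ins_used[j[1L]] <- TRUE
        inversions <- inversions + 1L
      }
    }
  }
  if (inversion_policy == "substitution" && inversions > 0L) {
    D <- D - inversions
    I <- I - inversions
    S <- S + inversions
  }

  structure(list(M = M, S = S, D = D, I = I,
                 N = nrow(ref$arcs), P = nrow(pred$arcs),
                 inversions = inversions, substitution = subst,
                 inversion_policy = inversion_policy),
            class = "arc_diff")
}

#' @export
print.arc_diff <- function(x, ...) {
  cat(sprintf("<arc_diff: N=%d P=%d | M=%d S=%d D=%d I=%d (inversions: %d, policy %s)>\n",
              x$N, x$P, x$M, x$S, x$D, x$I, x$inversions,
              x$inversion_policy))
  invisible(x)
}

#' Slot Error Rate and companion measures from an arc diff
#'
#' `SER = (S + D + I) / N`: the proportion of substitution, deletion and
#' insertion errors relative to the reference size. Zero means a perfect
#' prediction; the measure is unbounded above because insertions are
#' unbounded. Recall `M/N`, precision `M/P` and their harmonic mean F1 are
#' reported for convenience; unlike the SER they count each substitution
#' twice (once against recall, once against precision).
#'
#' @param diff an `arc_diff` from [diff_networks()], or a reference and a
#'   predicted network to diff first.
#' @param ... passed on to [diff_networks()] when `diff` is a network.
#' @param mode evaluation mode tag carried into the report (`"official"`,
#'   `"shape"`, `"effect"`).
#' @return An object of class `network_score` with fields `SER`, `recall`,
#'   `precision`, `f1`, `diff`, `mode`.
#' @export
score_network <- function(diff, ..., mode = "official") {
  if (inherits(diff, "grn_network")) {
    diff <- diff_networks(diff, ...)
  }
  if (diff$N == 0L) {
    bt_stop("score_network: empty reference network (N = 0)",
            class = "bteval_undefined_reference")
  }
  recall <- diff$M / diff$N
  precision <- if (diff$P > 0L) diff$M / diff$P else 0
  structure(list(SER = (diff$S + diff$D + diff$I) / diff$N,
                 recall = recall, precision = precision,
                 f1 = harmonic_f1(recall, precision),
                 diff = diff, mode = mode),
            class = "network_score")
}

#' @export
print.network_score <- function(x, ...) {
  cat(sprintf("<network_score [%s]: SER=%.4f recall=%.4f precision=%.4f F1=%.4f>\n",
              x$mode, x$SER, x$recall, x$precision, x$f1))
  print(x$diff)
  invisible(x)
}

#' Shape transform: drop regulation types
#'
#' For topology-only evaluation the regulation types are removed from both
#' networks and multiple arcs between a gene pair are reduced to one, so no
#' substitution error can remain. Direction is kept by default (one arc per
#' ordered pair); `undirected = TRUE` also merges the two directions.
#'
#' @param net a [grn_network()].
#' @param undirected merge opposite directions into one arc.
#' @return A [grn_network()] whose arcs all carry the neutral label `"Arc"`.
#' @export
shape_transform <- function(net, undirected = FALSE) {
  arcs <- net$arcs
  if (nrow(arcs)) {
    arcs$label <- "Arc"
    if (undirected) {
      swap <- arcs$agent > arcs$target
      tmp <- arcs$agent[swap]
      arcs$agent[swap] <- arcs$target[swap]
      arcs$target[swap] <- tmp
    }
    arcs <- unique(arcs)
  }
  grn_network(arcs, nodes = net$nodes, check = FALSE)
}

GRN_EFFECT_LABELS <- c("Activation", "Inhibition", "Requirement", "Regulation")
GRN_MECHANISM_LABELS <- c("Binding", "Transcription")

#' Effect transform: drop mechanism types
#'
#' For effect-focused evaluation the mechanism types (`Binding`,
#' `Transcription`) are removed: a mechanism arc between two genes is
#' relabeled as a generic `Regulation` arc, and dropped outright when one
#' or two effect-type arcs already connect the pair (the relabeled arc
#' would be redundant with them). Effect arcs are untouched.
#'
#' @param net a [grn_network()].
#' @return A [grn_network()] with effect-type labels only.
#' @export
effect_transform <- function(net) {
  arcs <- net$arcs
  if (nrow(arcs)) {
    key <- paste(arcs$agent, arcs$target, sep = "\r")
    keep <- rep(TRUE, nrow(arcs))
    for (k in unique(key)) {
      sel <- key == k
      mech <- sel & arcs$label %in% GRN_MECHANISM_LABELS
      if (!any(mech)) next
      if (any(sel & arcs$label %in% GRN_EFFECT_LABELS)) {
        keep[mech] <- FALSE # redundant with the effect arcs
      } else {
        arcs$label[mech] <- "Regulation" # duplicates collapse in grn_network
      }
    }
    arcs <- arcs[keep, , drop = FALSE]
  }
  grn_network(arcs, nodes = net$nodes)
}

#' Score a prediction in one of the three evaluation modes
#'
#' Convenience wrapper applying the mode's transform to both networks and
#' scoring the result: `"official"` compares the labeled networks as they
#' are, `"shape"` compares topology only, `"effect"` compares effect-type
#' regulations only.
#'
#' @param ref,pred [grn_network()] objects.
#' @param mode `"official"`, `"shape"` or `"effect"`.
#' @param inversion_policy see [diff_networks()].
#' @param undirected_shape undirected reading of the shape transform.
#' @return A `network_score`.
#' @export
evaluate_network <- function(ref, pred,
                             mode = c("official", "shape", "effect"),
                             inversion_policy = "del-ins",
                             undirected_shape = FALSE) {
  mode <- match.arg(mode)
  if (mode == "shape") {
    ref <- shape_transform(ref, undirected = undirected_shape)
    pred <- shape_transform(pred, undirected = undirected_shape)
  } else if (mode == "effect") {
    ref <- effect_transform(ref)
    pred <- effect_transform(pred)
  }
  score_network(diff_networks(ref, pred, inversion_policy = inversion_policy),
                mode = mode)
}
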