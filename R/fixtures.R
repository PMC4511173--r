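#' Error-injection specification
#'
#' Describes exactly which errors a perturbation introduces into a
#' reference network or entity set, so downstream scorers can be checked
#' against known ground truth.
#'
#' @param n_delete reference items removed (false negatives).
#' @param n_insert spurious items added (false positives).
#' @param n_substitute items kept in place with a wrong label (networks) or
#'   perturbed boundaries/concepts (entities).
#' @param n_invert network arcs re-emitted with agent and target swapped.
#' @param boundary_jitter entities only: maximum offset shift applied to a
#'   substituted entity's boundary; 0 means concepts are substituted
#'   instead.
#' @param seed RNG seed; identical seeds give identical perturbations.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(n_delete = 0, n_insert = 0, n_substitute = 0,
                       n_invert = 0, boundary_jitter = 0, seed = NULL) {
  spec <- list(n_delete = as.integer(n_delete),
               n_insert = as.integer(n_insert),
               n_substitute = as.integer(n_substitute),
               n_invert = as.integer(n_invert),
               boundary_jitter = as.integer(boundary_jitter), seed = seed)
  if (any(unlist(spec[1:5]) < 0L)) {
    bt_stop("error_spec: counts must be non-negative",
            class = "bteval_config_error")
  }
  structure(spec, class = "error_spec")
}

#' Generate a synthetic ontology
#'
#' Builds a rooted `is_a` tree with `branching` children per concept over
#' `depth` levels (so a pure tree has `sum(branching^(0:(depth-1)))`
#' concepts), optionally DAG-ified by random cross-links to shallower
#' concepts. Ids and names are deterministic given the seed.
#'
#' @param depth number of levels including the root (>= 1).
#' @param branching children per internal concept (>= 1).
#' @param seed RNG seed.
#' @param cross_link_rate probability that a non-root concept receives one
#'   extra `is_a` parent at a strictly shallower level (keeps the DAG
#'   acyclic).
#' @return A [ontology()] object.
#' @export
generate_ontology <- function(depth, branching, seed = 1L,
                              cross_link_rate = 0) {
  stopifnot(depth >= 1, branching >= 1)
  with_local_seed(seed, {
    concepts <- list()
    levels <- list()
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("SYN:%07d", counter)
    }
    root <- new_id()
    concepts[[root]] <- list(id = root, name = "root concept",
                             synonyms = character(),
                             parents = data.frame(relation = character(),
                                                  parent = character()))
    levels[[1L]] <- root
    if (depth > 1L) {
      for (lvl in 2:depth) {
        levels[[lvl]] <- character()
        for (parent in levels[[lvl - 1L]]) {
          for (b in seq_len(branching)) {
            id <- new_id()
            parents <- data.frame(relation = "is_a", parent = parent)
            if (cross_link_rate > 0 && lvl > 2L &&
                runif(1) < cross_link_rate) {
              extra_lvl <- sample.int(lvl - 1L, 1L)
              extra <- sample_one(setdiff(levels[[extra_lvl]], parent))
              if (length(extra)) {
                parents <- rbind(parents,
                                 data.frame(relation = "is_a", parent = extra))
              }
            }
            concepts[[id]] <- list(
              id = id,
              name = sprintf("habitat %d", counter),
              synonyms = character(), parents = parents)
            levels[[lvl]] <- c(levels[[lvl]], id)
          }
        }
      }
    }
    ontology(concepts)
  })
}

#' Generate a synthetic regulation network
#'
#' Distinct ordered gene pairs with one random label each (the one-arc-per-
#' pair layout keeps injected substitution counts exactly recoverable).
#'
#' @param n_genes number of gene nodes.
#' @param n_arcs number of arcs (at most `n_genes * (n_genes - 1)`).
#' @param seed RNG seed.
#' @return A [grn_network()].
#' @export
generate_network <- function(n_genes, n_arcs, seed = 1L) {
  if (n_arcs > n_genes * (n_genes - 1L)) {
    bt_stop("generate_network: %d arcs do not fit on %d genes", n_arcs,
            n_genes, class = "bteval_config_error")
  }
  with_local_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    pairs <- expand.grid(agent = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$agent != pairs$target, , drop = FALSE]
    pick <- pairs[sample.int(nrow(pairs), n_arcs), , drop = FALSE]
    grn_network(data.frame(
      agent = pick$agent,
      label = sample(GRN_INTERACTION_LABELS, n_arcs, replace = TRUE),
      target = pick$target, stringsAsFactors = FALSE))
  })
}

#' Inject errors into a reference network
#'
#' Applies exactly the requested deletions, insertions, label substitutions
#' and inversions to disjoint arc subsets, under placement constraints that
#' make every injected error identifiable by [diff_networks()]:
#' substituted labels differ from every reference label on the pair,
#' inserted arcs land on ordered pairs free in both directions, and
#' inverted arcs land on reverse pairs free in the reference.
#'
#' @param net reference [grn_network()].
#' @param spec an [error_spec()].
#' @return A list of class `bt_perturbation`: `prediction` (the perturbed
#'   network), `truth` (the expected `M`, `S`, `D`, `I`, `inversions`
#'   under the `del-ins` inversion policy) and `spec`.
#' @export
perturb_network <- function(net, spec) {
  N <- nrow(net$arcs)
  touched <- spec$n_delete + spec$n_substitute + spec$n_invert
  if (touched > N) {
    bt_stop("error_spec infeasible: %d arcs to perturb but only %d in reference",
            touched, N, class = "bteval_config_error")
  }
  with_local_seed(spec$seed, {
    arcs <- net$arcs
    pair_of <- function(a) paste(a$agent, a$target, sep = "\r")
    ref_pairs <- unique(c(pair_of(arcs),
                          paste(arcs$target, arcs$agent, sep = "\r")))
    idx <- sample.int(N, touched)
    del_idx <- idx[seq_len(spec$n_delete)]
    sub_idx <- idx[spec$n_delete + seq_len(spec$n_substitute)]
    inv_idx <- idx[spec$n_delete + spec$n_substitute + seq_len(spec$n_invert)]

    pred <- arcs
    # substitutions: relabel with a label absent from the pair in the reference
    for (i in sub_idx) {
      here <- pair_of(arcs)[i] == pair_of(arcs)
      pred$label[i] <- sample_one(setdiff(GRN_INTERACTION_LABELS,
                                          arcs$label[here]))
    }
    # inversions: need the reverse pair free in the reference and unused so far
    inv_ok <- vapply(inv_idx, function(i) {
      !paste(arcs$target[i], arcs$agent[i], sep = "\r") %in% pair_of(arcs)
    }, TRUE)
    if (!all(inv_ok)) {
      pool <- setdiff(which(vapply(seq_len(N), function(i)
        !paste(arcs$target[i], arcs$agent[i], sep = "\r") %in% pair_of(arcs),
        TRUE)), idx[seq_len(spec$n_delete + spec$n_substitute)])
      if (length(pool) < spec$n_invert) {
        bt_stop("error_spec infeasible: not enough invertible arcs",
                class = "bteval_config_error")
      }
      inv_idx <- sample_k(pool, spec$n_invert)
    }
    for (i in inv_idx) {
      tmp <- pred$agent[i]
      pred$agent[i] <- pred$target[i]
      pred$target[i] <- tmp
    }
    pred <- pred[setdiff(seq_len(N), del_idx), , drop = FALSE]

    # insertions: ordered pairs free in both directions in the reference
    if (spec$n_insert > 0L) {
      genes <- net$nodes
      if (length(genes) < 2L) {
        bt_stop("error_spec infeasible: need >= 2 genes for insertions",
                class = "bteval_config_error")
      }
      free <- expand.grid(agent = genes, target = genes,
                          stringsAsFactors = FALSE)
      free <- free[free$agent != free$target, , drop = FALSE]
      used <- unique(c(ref_pairs, pair_of(pred)))
      free <- free[!pair_of(free) %in% used, , drop = FALSE]
      # also keep inserted pairs mutually non-reverse
      if (nrow(free) < spec$n_insert) {
        bt_stop("error_spec infeasible: not enough free gene pairs to insert",
                class = "bteval_config_error")
      }
      chosen <- NULL
      for (k in sample.int(nrow(free))) {
        cand <- free[k, , drop = FALSE]
        if (!is.null(chosen) &&
            paste(cand$target, cand$agent, sep = "\r") %in% pair_of(chosen)) {
          next
        }
        chosen <- rbind(chosen, cand)
        if (nrow(chosen) == spec$n_insert) break
      }
      if (is.null(chosen) || nrow(chosen) < spec$n_insert) {
        bt_stop("error_spec infeasible: not enough free gene pairs to insert",
                class = "bteval_config_error")
      }
      pred <- rbind(pred, data.frame(
        agent = chosen$agent,
        label = sample(GRN_INTERACTION_LABELS, spec$n_insert, replace = TRUE),
        target = chosen$target, stringsAsFactors = FALSE))
    }
    structure(list(
      prediction = grn_network(pred, nodes = net$nodes),
      truth = list(M = N - touched, S = spec$n_substitute,
                   D = spec$n_delete + spec$n_invert,
                   I = spec$n_insert + spec$n_invert,
                   inversions = spec$n_invert, N = N,
                   P = N - spec$n_delete + spec$n_insert),
      spec = spec), class = "bt_perturbation")
  })
}

# ---- Bacteria-biotope document generation ---------------------------------

#' Fixture profile for synthetic bacteria-biotope documents
#'
#' Defaults mirror the published corpus statistics: about 1.8% of entity
#' annotations discontinuous, 54% of Localization and 63% of PartOf events
#' intra-sentence, and three quarters of events Localization.
#'
#' @param n_docs number of documents (used by corpus-level helpers).
#' @param entities_per_doc approximate entity count per document.
#' @param events_per_doc number of events per document.
#' @param discontinuity_rate fraction of entities that are discontinuous.
#' @param intra_sentence_rate probability that a Localization event's
#'   arguments share a sentence.
#' @param partof_intra_rate same for PartOf events.
#' @param localization_fraction fraction of events that are Localization.
#' @param equivalence_rate probability that a repeated bacterium name gets
#'   an equivalence set over its mentions.
#' @param multi_concept_rate probability that a habitat normalization
#'   carries two concepts rather than one.
#' @return An object of class `bb_profile`.
#' @export
bb_profile <- function(n_docs = 1L, entities_per_doc = 12L,
                       events_per_doc = 6L, discontinuity_rate = 0.018,
                       intra_sentence_rate = 0.54, partof_intra_rate = 0.63,
                       localization_fraction = 0.75,
                       equivalence_rate = 0.1, multi_concept_rate = 0.05) {
  rates <- c(discontinuity_rate, intra_sentence_rate, partof_intra_rate,
             localization_fraction, equivalence_rate, multi_concept_rate)
  if (any(rates < 0 | rates > 1)) {
    bt_stop("bb_profile: rates must lie in [0, 1]",
            class = "bteval_config_error")
  }
  structure(list(n_docs = n_docs, entities_per_doc = entities_per_doc,
                 events_per_doc = events_per_doc,
                 discontinuity_rate = discontinuity_rate,
                 intra_sentence_rate = intra_sentence_rate,
                 partof_intra_rate = partof_intra_rate,
                 localization_fraction = localization_fraction,
                 equivalence_rate = equivalence_rate,
                 multi_concept_rate = multi_concept_rate),
            class = "bb_profile")
}

# Incremental text builder tracking 0-based offsets.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$text <- ""
  env$entities <- list()
  env$counter <- 0L
  env
}

bld_append <- function(b, s) {
  start <- nchar(b$text)
  b$text <- paste0(b$text, s)
  c(start, start + nchar(s))
}

bld_entity <- function(b, type, frag_list) {
  b$counter <- b$counter + 1L
  id <- paste0("T", b$counter)
  frags <- fragments(vapply(frag_list, `[`, 0, 1L),
                     vapply(frag_list, `[`, 0, 2L))
  b$entities[[id]] <- entity(id, type, frags)
  id
}

#' Generate a synthetic bacteria-biotope document
#'
#' Synthesizes English-like filler text with `Bacteria`, `Habitat` and
#' `Geographical` entities (discontinuous habitats arise from shared-head
#' coordinations like "X and Y Z"), `Localization` and `PartOf` events at
#' the profile's intra-sentence rates, equivalence sets over repeated
#' bacterium mentions, and habitat normalizations drawn from the supplied
#' ontology. The result validates against the `"bb"` schema; linguistic
#' realism is a non-goal — only offsets, types and structure matter to the
#' scorers.
#'
#' @param profile a [bb_profile()].
#' @param onto a [ontology()] providing habitat concepts.
#' @param seed RNG seed.
#' @param doc_id document identifier.
#' @return A [standoff_document()] with sentence spans attached.
#' @export
generate_bb_document <- function(profile, onto, seed = 1L, doc_id = "synth") {
  if (length(onto$concepts) == 0L) {
    bt_stop("generate_bb_document: empty ontology",
            class = "bteval_config_error")
  }
  with_local_seed(seed, {
    n_sent <- max(2L, ceiling(profile$entities_per_doc / 3))
    bacteria_pool <- sprintf("Bacillus strain%02d",
                             seq_len(max(2L, ceiling(n_sent / 2))))
    habitat_words <- c("soil", "water", "milk", "intestine", "sediment",
                       "plant", "cheese", "sludge", "mucosa", "rhizosphere")
    habitat_mods <- c("animal", "human", "bovine", "marine", "forest",
                      "dairy", "acidic", "thermal", "coastal", "alpine")
    geo_pool <- c("Norway", "Japan", "Provence", "Yellowstone", "Atacama")
    coord_p <- min(1, 3 * profile$discontinuity_rate)

    b <- new_builder()
    sentence_spans <- list()
    sent_entities <- list() # per sentence: list(bacteria=ids, habitats=ids)
    for (s in seq_len(n_sent)) {
      sent_start <- nchar(b$text)
      info <- list(bacteria = character(), habitats = character(),
                   geo = character())
      bname <- sample_one(bacteria_pool)
      frag <- bld_append(b, bname)
      info$bacteria <- bld_entity(b, "Bacteria", list(frag))
      bld_append(b, " was isolated from ")
      n_hab <- sample(1:2, 1L)
      for (h in seq_len(n_hab)) {
        if (h > 1L) bld_append(b, " and from ")
        if (runif(1) < coord_p) {
          # coordination with shared head: "<m1> and <m2> <head>"
          m1 <- sample_one(habitat_mods)
          m2 <- sample_one(setdiff(habitat_mods, m1))
          head_w <- sample_one(habitat_words)
          f1 <- bld_append(b, m1)
          bld_append(b, " and ")
          f2a <- bld_append(b, m2)
          bld_append(b, " ")
          fh <- bld_append(b, head_w)
          # discontinuous entity: modifier 1 + head
          info$habitats <- c(info$habitats,
                             bld_entity(b, "Habitat", list(f1, fh)),
                             bld_entity(b, "Habitat", list(c(f2a[1], fh[2]))))
        } else {
          phrase <- paste(sample_one(habitat_mods), sample_one(habitat_words))
          frag <- bld_append(b, phrase)
          info$habitats <- c(info$habitats,
                             bld_entity(b, "Habitat", list(frag)))
        }
      }
      if (runif(1) < 0.25) {
        bld_append(b, " in ")
        frag <- bld_append(b, sample_one(geo_pool))
        info$geo <- bld_entity(b, "Geographical", list(frag))
      }
      bld_append(b, ". ")
      sentence_spans[[s]] <- c(sent_start, nchar(b$text) - 1L)
      sent_entities[[s]] <- info
    }

    # events
    events <- list()
    ecount <- 0L
    add_event <- function(type, args) {
      ecount <<- ecount + 1L
      events[[length(events) + 1L]] <<- event(paste0("E", ecount), type, args)
    }
    for (k in seq_len(profile$events_per_doc)) {
      is_loc <- runif(1) < profile$localization_fraction
      s <- sample.int(n_sent, 1L)
      info <- sent_entities[[s]]
      if (is_loc) {
        targets <- c(info$habitats, info$geo)
        if (length(targets) == 0L) next
        target <- sample_one(targets)
        intra <- runif(1) < profile$intra_sentence_rate
        bac <- if (intra) {
          info$bacteria
        } else {
          others <- setdiff(seq_len(n_sent), s)
          sample_one(vapply(sent_entities[others], function(i)
            i$bacteria, ""))
        }
        add_event("Localization", c(Bacterium = bac, Localization = target))
      } else {
        intra <- runif(1) < profile$partof_intra_rate
        if (intra) {
          if (length(info$habitats) < 2L) next
          pick <- sample_k(info$habitats, 2L)
        } else {
          s2 <- sample_one(setdiff(seq_len(n_sent), s))
          h1 <- sent_entities[[s]]$habitats
          h2 <- sent_entities[[s2]]$habitats
          if (length(h1) == 0L || length(h2) == 0L) next
          pick <- c(sample_one(h1), sample_one(h2))
        }
        add_event("PartOf", c(Host = pick[1L], Part = pick[2L]))
      }
    }
    # drop duplicate events (same type + args)
    if (length(events)) {
      sig <- vapply(events, function(e)
        paste(e$type, paste(e$args, collapse = " ")), "")
      events <- events[!duplicated(sig)]
    }

    # equivalence sets over repeated bacterium names
    equivalences <- list()
    bac_ids <- unlist(lapply(sent_entities, `[[`, "bacteria"))
    bac_names <- vapply(bac_ids, function(id)
      fragment_surface(b$text, b$entities[[id]]$fragments), "")
    for (nm in unique(bac_names)) {
      ids <- bac_ids[bac_names == nm]
      if (length(ids) >= 2L && runif(1) < profile$equivalence_rate) {
        equivalences[[length(equivalences) + 1L]] <- ids
      }
    }

    # habitat normalizations
    normalizations <- list()
    ncount <- 0L
    concept_ids <- names(onto$concepts)
    for (id in names(b$entities)) {
      if (b$entities[[id]]$type != "Habitat") next
      ncount <- ncount + 1L
      k <- if (length(concept_ids) > 1L &&
               runif(1) < profile$multi_concept_rate) 2L else 1L
      normalizations[[ncount]] <-
        normalization(paste0("N", ncount), id, sample_k(concept_ids, k))
    }

    spans <- fragments(vapply(sentence_spans, `[`, 0, 1L),
                       vapply(sentence_spans, `[`, 0, 2L))
    standoff_document(doc_id, b$text, b$entities, events, normalizations,
                      equivalences, sentence_spans = spans)
  })
}

#' Inject errors into a document's entity annotations
#'
#' Builds a prediction document over the same text: the scored entities are
#' copied, then exactly `n_delete` are removed, `n_insert` spurious
#' entities are placed on text stretches overlapping no reference entity,
#' and `n_substitute` are perturbed — boundary shifts of up to
#' `boundary_jitter` characters (still overlapping the original, touching
#' no other reference entity) when `boundary_jitter > 0`, otherwise
#' concept substitutions. Events and equivalence sets are not carried into
#' the prediction (entity scoring ignores them).
#'
#' @param doc reference [standoff_document()].
#' @param spec an [error_spec()].
#' @param onto [ontology()] used to draw substitute concepts.
#' @param entity_types which entity types are perturbed/copied.
#' @return A list of class `bt_perturbation`: `prediction` (document),
#'   `truth` (`D`, `I`, `n_substituted`), `spec`.
#' @export
perturb_entities <- function(doc, spec, onto, entity_types = "Habitat") {
  ents <- Filter(function(e) e$type %in% entity_types, doc$entities)
  N <- length(ents)
  if (spec$n_delete + spec$n_substitute > N) {
    bt_stop("error_spec infeasible: %d entities to perturb but only %d present",
            spec$n_delete + spec$n_substitute, N,
            class = "bteval_config_error")
  }
  with_local_seed(spec$seed, {
    idx <- sample.int(N, spec$n_delete + spec$n_substitute)
    del_ids <- names(ents)[idx[seq_len(spec$n_delete)]]
    sub_ids <- names(ents)[idx[spec$n_delete + seq_len(spec$n_substitute)]]

    all_ref_offsets <- sort(unique(unlist(lapply(doc$entities, function(e)
      covered_offsets(e$fragments)))))
    pred_entities <- list()
    pred_norms <- list()
    ncount <- 0L
    copy_norm <- function(pid, concepts) {
      ncount <<- ncount + 1L
      pred_norms[[ncount]] <<- normalization(paste0("N", ncount), pid,
                                             concepts)
    }
    pcount <- 0L
    for (id in names(ents)) {
      if (id %in% del_ids) next
      en <- ents[[id]]
      pcount <- pcount + 1L
      pid <- paste0("T", pcount)
      concepts <- entity_concepts(doc, id)
      if (id %in% sub_ids) {
        if (spec$boundary_jitter > 0L) {
          en$fragments <- jitter_fragments(en$fragments, doc, id,
                                           spec$boundary_jitter,
                                           nchar(doc$text))
        } else {
          if (length(names(onto$concepts)) < 2L) {
            bt_stop("concept substitution needs an ontology with >= 2 concepts",
                    class = "bteval_config_error")
          }
          concepts <- sample_one(setdiff(names(onto$concepts), concepts))
        }
      }
      pred_entities[[pid]] <- entity(pid, en$type, en$fragments)
      if (length(concepts)) copy_norm(pid, concepts)
    }
    # insertions on free text stretches
    if (spec$n_insert > 0L) {
      free <- setdiff(seq.int(0L, nchar(doc$text) - 1L), all_ref_offsets)
      runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
      runs <- Filter(function(r) length(r) >= 3L, runs)
      if (length(runs) < spec$n_insert) {
        bt_stop("error_spec infeasible: not enough free text to insert %d entities",
                spec$n_insert, class = "bteval_config_error")
      }
      for (r in sample_k(runs, spec$n_insert)) {
        pcount <- pcount + 1L
        pid <- paste0("T", pcount)
        pred_entities[[pid]] <- entity(pid, entity_types[[1L]],
                                       fragments(r[[1L]],
                                                 r[[1L]] + min(3L, length(r))))
        copy_norm(pid, sample_one(names(onto$concepts)))
      }
    }
    structure(list(
      prediction = standoff_document(doc$doc_id, doc$text, pred_entities,
                                     normalizations = pred_norms,
                                     sentence_spans = doc$sentence_spans),
      truth = list(N = N, P = N - spec$n_delete + spec$n_insert,
                   D = spec$n_delete, I = spec$n_insert,
                   n_substituted = spec$n_substitute),
      spec = spec), class = "bt_perturbation")
  })
}

# Shift one boundary of a single-fragment entity by up to `jitter`
# characters while keeping overlap with the original and touching no other
# reference entity; falls back to shrinking within the original span.
jitter_fragments <- function(frags, doc, self_id, jitter, text_len) {
  others <- unlist(lapply(setdiff(names(doc$entities), self_id), function(i)
    covered_offsets(doc$entities[[i]]$fragments)))
  f <- frags[1L, ]
  for (try in seq_len(50L)) {
    ds <- sample.int(2L * jitter + 1L, 1L) - jitter - 1L
    de <- sample.int(2L * jitter + 1L, 1L) - jitter - 1L
    s <- max(0L, f$start + ds)
    e <- min(text_len, f$end + de)
    if (s >= e) next
    if (s == f$start && e == f$end) next
    if (s >= f$end || e <= f$start) next # must still overlap the original
    offs <- seq.int(s, e - 1L)
    extra <- setdiff(offs, seq.int(f$start, f$end - 1L))
    if (length(intersect(extra, others))) next
    out <- frags
    out$start[1L] <- s
    out$end[1L] <- e
    if (nrow(out) > 1L && out$end[1L] > out$start[2L]) next
    return(fragments(out$start, out$end))
  }
  # guaranteed-safe shrink: drop the first character if possible
  if (f$end - f$start >= 2L) {
    out <- frags
    out$start[1L] <- f$start + 1L
    return(fragments(out$start, out$end))
  }
  bt_stop("could not jitter entity %s", self_id,
          class = "bteval_config_error")
}

#' Generate a flat GRN document from a network
#'
#' Writes one sentence per arc ("geneA regulates geneB.") with `Gene`
#' entities and a flat `Interaction:<label>` event, so that
#' [infer_network()] on the result reproduces the network exactly
#' (direct-submission equivalence).
#'
#' @param net a [grn_network()].
#' @param doc_id document identifier.
#' @return A [standoff_document()] in the `"grn"` schema.
#' @export
network_to_document <- function(net, doc_id = "grn-synth") {
  b <- new_builder()
  events <- list()
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs$agent[[i]]
    t <- net$arcs$target[[i]]
    fa <- bld_append(b, a)
    bld_append(b, " regulates ")
    ft <- bld_append(b, t)
    bld_append(b, ". ")
    ida <- bld_entity(b, "Gene", list(fa))
    idt <- bld_entity(b, "Gene", list(ft))
    events[[i]] <- event(paste0("E", i),
                         paste0("Interaction:", net$arcs$label[[i]]),
                         c(Agent = ida, Target = idt))
  }
  standoff_document(doc_id, b$text, b$entities, events)
}
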