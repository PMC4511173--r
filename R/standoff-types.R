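#' Fragment tables
#'
#' A fragment is a half-open character interval `[start, end)` in 0-based
#' code-point offsets, following the BioNLP-ST convention. An entity span is
#' an ordered list of disjoint fragments; most entities have one fragment,
#' but coordination and range structures in text ("animal and human
#' intestine") produce discontinuous spans.
#'
#' @param start,end integer vectors of equal length; `0 <= start < end`.
#' @return A data.frame with columns `start` and `end`, sorted by `start`.
#' @examples
#' fragments(c(0, 17), c(6, 26))
#' @export
fragments <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end) || length(start) == 0L) {
    bt_stop("fragments: start/end must be non-empty and of equal length",
            class = "bteval_fragment_error")
  }
  if (any(start < 0L) || any(end <= start)) {
    bt_stop("fragments: require 0 <= start < end", class = "bteval_fragment_error")
  }
  ord <- order(start)
  start <- start[ord]
  end <- end[ord]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    bt_stop("fragments: fragments must be pairwise non-overlapping",
            class = "bteval_fragment_error")
  }
  data.frame(start = start, end = end)
}

# "0 6;17 26" -> fragment data.frame
parse_fragments <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  se <- vapply(parts, function(p) {
    xs <- strsplit(trimws(p), "[[:space:]]+")[[1L]]
    if (length(xs) != 2L || anyNA(suppressWarnings(as.integer(xs)))) {
      bt_stop("malformed fragment '%s'", p, class = "bteval_parse_error")
    }
    as.integer(xs)
  }, integer(2))
  fragments(se[1L, ], se[2L, ])
}

format_fragments <- function(frags) {
  paste(paste(frags$start, frags$end), collapse = ";")
}

# Set of covered 0-based offsets, across all fragments
covered_offsets <- function(frags) {
  unlist(mapply(function(s, e) seq.int(s, e - 1L), frags$start, frags$end,
                SIMPLIFY = FALSE), use.names = FALSE)
}

# Extract the surface form of a (possibly discontinuous) span. Fragments are
# joined with a single space; the joined surface is informational only and
# never used by any scorer (scoring works on offsets).
fragment_surface <- function(text, frags, sep = " ") {
  paste(substring(text, frags$start + 1L, frags$end), collapse = sep)
}

#' Text-bound entity
#'
#' @param id annotation identifier (conventionally `T`-prefixed).
#' @param type entity type label, e.g. `"Habitat"`, `"Bacteria"`, `"Gene"`.
#' @param frags fragment data.frame from [fragments()], or a string
#'   `"START END[;START END]*"`.
#' @param surface covered text; recomputed from the document text when the
#'   entity is attached to a document.
#' @return An object of class `bt_entity`.
#' @export
entity <- function(id, type, frags, surface = NA_character_) {
  if (is.character(frags)) frags <- parse_fragments(frags)
  structure(list(id = id, type = type, fragments = frags, surface = surface),
            class = "bt_entity")
}

#' Event annotation
#'
#' Events map role names to argument ids; arguments may be entities or, in
#' the gene-regulation schema, other events (nested events). Role names may
#' repeat.
#'
#' @param id annotation identifier (conventionally `E`- or `R`-prefixed).
#' @param type event type label, e.g. `"Localization"`,
#'   `"Interaction:Regulation"`, `"Promoter_of"`.
#' @param args named character vector: role name -> argument id.
#' @return An object of class `bt_event`.
#' @export
event <- function(id, type, args) {
  if (is.null(names(args)) || any(!nzchar(names(args)))) {
    bt_stop("event %s: all arguments must be role-named", id,
            class = "bteval_event_error")
  }
  structure(list(id = id, type = type, args = args), class = "bt_event")
}

#' Concept normalization
#'
#' Attaches one or more ontology concept identifiers to a text-bound entity
#' (habitat categorization against OntoBiotope-style ontologies).
#'
#' @param id annotation identifier (conventionally `N`-prefixed).
#' @param entity_id id of the normalized entity.
#' @param concepts non-empty character vector of concept ids.
#' @param type normalization type label written on the standoff line.
#' @export
normalization <- function(id, entity_id, concepts, type = "OntoBiotope") {
  concepts <- unique(as.character(concepts))
  if (length(concepts) == 0L) {
    bt_stop("normalization %s: concepts must be non-empty", id,
            class = "bteval_norm_error")
  }
  structure(list(id = id, type = type, entity_id = entity_id,
                 concepts = concepts),
            class = "bt_normalization")
}

#' Annotated document
#'
#' Container for a document text plus its standoff annotations: entities
#' (possibly discontinuous), events, concept normalizations, equivalence
#' sets of interchangeable entity mentions, and optional sentence spans.
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param entities list of [entity()] objects.
#' @param events list of [event()] objects.
#' @param normalizations list of [normalization()] objects.
#' @param equivalences list of character vectors of entity ids (each of
#'   length >= 2); stored transitively closed (overlapping sets are merged).
#' @param sentence_spans optional fragment data.frame of sentence extents.
#' @return An object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text, entities = list(), events = list(),
                              normalizations = list(), equivalences = list(),
                              sentence_spans = NULL) {
  names(entities) <- vapply(entities, `[[`, "", "id")
  names(events) <- vapply(events, `[[`, "", "id")
  ids <- c(names(entities), names(events))
  if (anyDuplicated(ids)) {
    bt_stop("duplicate annotation id: %s", ids[duplicated(ids)][1L],
            class = "bteval_parse_error")
  }
  n <- nchar(text)
  entities <- lapply(entities, function(en) {
    if (max(en$fragments$end) > n) {
      bt_stop("entity %s: fragment beyond text end (%d > %d)", en$id,
              max(en$fragments$end), n, class = "bteval_parse_error")
    }
    en$surface <- fragment_surface(text, en$fragments)
    en
  })
  for (ev in events) {
    missing <- setdiff(ev$args, ids)
    if (length(missing)) {
      bt_stop("event %s: dangling argument reference %s", ev$id, missing[1L],
              class = "bteval_resolution_error")
    }
  }
  for (nm in normalizations) {
    if (!nm$entity_id %in% names(entities)) {
      bt_stop("normalization %s: dangling entity reference %s", nm$id,
              nm$entity_id, class = "bteval_resolution_error")
    }
  }
  equivalences <- close_equivalences(equivalences, names(entities))
  doc <- structure(list(doc_id = doc_id, text = text, entities = entities,
                        events = events, normalizations = normalizations,
                        equivalences = equivalences,
                        sentence_spans = sentence_spans),
                   class = "standoff_document")
  assert_no_event_cycle(doc)
  doc
}

# Merge overlapping equivalence sets (symmetric, transitive closure) and
# check that every member resolves to an entity.
close_equivalences <- function(equivalences, entity_ids) {
  if (length(equivalences) == 0L) return(list())
  sets <- lapply(equivalences, function(s) {
    s <- unique(as.character(s))
    missing <- setdiff(s, entity_ids)
    if (length(missing)) {
      bt_stop("equivalence set: dangling entity reference %s", missing[1L],
              class = "bteval_resolution_error")
    }
    if (length(s) < 2L) {
      bt_stop("equivalence set must have >= 2 members",
              class = "bteval_parse_error")
    }
    s
  })
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  lapply(sets, function(s) sort(s))
}

assert_no_event_cycle <- function(doc) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack) {
      bt_stop("cyclic event nesting through %s", id,
              class = "bteval_cycle_error")
    }
    ev <- doc$events[[id]]
    if (is.null(ev)) return(invisible())
    for (a in ev$args) {
      if (a %in% names(doc$events)) visit(a, c(stack, id))
    }
  }
  for (id in names(doc$events)) visit(id, character())
  invisible(doc)
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document %s: %d chars, %d entities, %d events, %d normalizations, %d equivalence sets>\n",
              x$doc_id, nchar(x$text), length(x$entities), length(x$events),
              length(x$normalizations), length(x$equivalences)))
  invisible(x)
}

#' @export
print.bt_entity <- function(x, ...) {
  cat(sprintf("<entity %s %s %s \"%s\">\n", x$id, x$type,
              format_fragments(x$fragments), x$surface))
  invisible(x)
}

#' @export
print.bt_event <- function(x, ...) {
  cat(sprintf("<event %s %s %s>\n", x$id, x$type,
              paste(names(x$args), x$args, sep = ":", collapse = " ")))
  invisible(x)
}

# Equivalence lookup: all ids interchangeable with `id` (including itself)
equivalent_ids <- function(doc, id) {
  for (s in doc$equivalences) if (id %in% s) return(s)
  id
}

entity_concepts <- function(doc, entity_id) {
  out <- character()
  for (nm in doc$normalizations) {
    if (nm$entity_id == entity_id) out <- union(out, nm$concepts)
  }
  out
}
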