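GRN_INTERACTION_LABELS <- c("Activation", "Inhibition", "Requirement",
                            "Regulation", "Binding", "Transcription")

GRN_AGENT_TYPES <- c("Gene", "Protein", "GeneFamily", "ProteinFamily",
                     "ProteinComplex", "PolymeraseComplex", "Regulon",
                     "Operon")
GRN_DNA_TYPES <- c("Gene", "Promoter", "Site", "Operon", "GeneFamily")

# Role signature: list(kinds = subset of c("entity","event"), types = NULL
# (any entity type) or a character vector of allowed entity types,
# optional = FALSE unless stated.
role_sig <- function(kinds, types = NULL, optional = FALSE) {
  list(kinds = kinds, types = types, optional = optional)
}

#' Task schemas
#'
#' A schema names the allowed entity types and the role signatures of each
#' event type for one task. Two schemas are built in:
#' \describe{
#'   \item{`"grn"`}{gene regulation: molecular events (`Bind_to`, `Site_of`,
#'     `Promoter_of`, `Master_of_Promoter`, `Transcription_by`,
#'     `Transcription_from`, `Master_of_Regulon`, `Member_of_Regulon`) and
#'     the six `Interaction:*` event types, whose arguments may be nested
#'     events.}
#'   \item{`"bb"`}{bacteria biotopes: `Bacteria`, `Habitat` and
#'     `Geographical` entities; binary `Localization` (bacterium in a
#'     biotope) and `PartOf` (host part of a host) events with entity
#'     arguments only.}
#' }
#'
#' @param name `"grn"` or `"bb"`.
#' @return A schema object (list with `name`, `entity_types`, `event_types`).
#' @export
task_schema <- function(name = c("grn", "bb")) {
  name <- match.arg(name)
  if (name == "bb") {
    schema <- list(
      name = "bb",
      entity_types = c("Bacteria", "Habitat", "Geographical"),
      event_types = list(
        Localization = list(
          Bacterium = role_sig("entity", "Bacteria"),
          Localization = role_sig("entity", c("Habitat", "Geographical"))
        ),
        PartOf = list(
          Host = role_sig("entity", "Habitat"),
          Part = role_sig("entity", "Habitat")
        )
      )
    )
  } else {
    interaction <- list(
      Agent = role_sig(c("entity", "event"), GRN_AGENT_TYPES),
      Target = role_sig(c("entity", "event"),
                        union(GRN_AGENT_TYPES, GRN_DNA_TYPES))
    )
    schema <- list(
      name = "grn",
      entity_types = c("Gene", "Protein", "GeneFamily", "ProteinFamily",
                       "ProteinComplex", "PolymeraseComplex", "Promoter",
                       "Site", "Regulon", "Operon", "mRNA"),
      event_types = c(
        stats::setNames(rep(list(interaction), 6L),
                        paste0("Interaction:", GRN_INTERACTION_LABELS)),
        list(
          Transcription = list(Gene = role_sig("entity",
                                               c("Gene", "Operon", "GeneFamily")),
                               Promoter = role_sig("entity", "Promoter",
                                                   optional = TRUE)),
          Expression = list(Gene = role_sig("entity",
                                            c("Gene", "Operon", "GeneFamily"))),
          Bind_to = list(Agent = role_sig("entity", GRN_AGENT_TYPES),
                         Site = role_sig("entity", c("Site", "Promoter"))),
          Site_of = list(Site = role_sig("entity", c("Site", "Promoter")),
                         Target = role_sig("entity", GRN_DNA_TYPES)),
          Promoter_of = list(Promoter = role_sig("entity", "Promoter"),
                             Gene = role_sig("entity",
                                             c("Gene", "Operon", "GeneFamily"))),
          Master_of_Promoter = list(Agent = role_sig("entity", GRN_AGENT_TYPES),
                                    Promoter = role_sig("entity", "Promoter")),
          Transcription_by = list(Transcription = role_sig(c("entity", "event"),
                                                           GRN_DNA_TYPES),
                                  Agent = role_sig("entity", GRN_AGENT_TYPES)),
          Transcription_from = list(Transcription = role_sig(c("entity", "event"),
                                                             GRN_DNA_TYPES),
                                    Site = role_sig("entity",
                                                    c("Site", "Promoter"))),
          Master_of_Regulon = list(Agent = role_sig("entity", GRN_AGENT_TYPES),
                                   Regulon = role_sig("entity", "Regulon")),
          Member_of_Regulon = list(Gene = role_sig("entity",
                                                   c("Gene", "Operon")),
                                   Regulon = role_sig("entity", "Regulon"))
        )
      )
    )
  }
  structure(schema, class = "bt_schema")
}

#' Validate a document against a task schema
#'
#' Checks every annotation against the schema's type vocabulary and role
#' signatures. Returns a character vector of human-readable violations, one
#' per problem, each naming the offending annotation id; a conforming
#' document yields `character(0)`.
#'
#' @param doc a [standoff_document()].
#' @param schema a schema from [task_schema()], or its name.
#' @return Character vector of violations (empty iff the document conforms).
#' @export
validate_document <- function(doc, schema) {
  if (is.character(schema)) schema <- task_schema(schema)
  if (!inherits(schema, "bt_schema")) {
    bt_stop("unknown schema", class = "bteval_config_error")
  }
  v <- character()
  for (en in doc$entities) {
    if (!en$type %in% schema$entity_types) {
      v <- c(v, sprintf("%s: unknown entity type '%s'", en$id, en$type))
    }
  }
  for (ev in doc$events) {
    sig <- schema$event_types[[ev$type]]
    if (is.null(sig)) {
      v <- c(v, sprintf("%s: unknown event type '%s'", ev$id, ev$type))
      next
    }
    for (i in seq_along(ev$args)) {
      role <- names(ev$args)[[i]]
      arg <- ev$args[[i]]
      rs <- sig[[role]]
      if (is.null(rs)) {
        v <- c(v, sprintf("%s: role '%s' not allowed for %s", ev$id, role,
                          ev$type))
        next
      }
      if (arg %in% names(doc$entities)) {
        if (!"entity" %in% rs$kinds) {
          v <- c(v, sprintf("%s: role '%s' does not accept entities", ev$id,
                            role))
        } else if (!is.null(rs$types) &&
                   !doc$entities[[arg]]$type %in% rs$types) {
          v <- c(v, sprintf("%s: role '%s' has %s argument %s, expected one of %s",
                            ev$id, role, doc$entities[[arg]]$type, arg,
                            paste(rs$types, collapse = "/")))
        }
      } else if (arg %in% names(doc$events)) {
        if (!"event" %in% rs$kinds) {
          v <- c(v, sprintf("%s: role '%s' does not accept event arguments",
                            ev$id, role))
        }
      }
    }
    required <- names(sig)[!vapply(sig, `[[`, FALSE, "optional")]
    for (role in setdiff(required, names(ev$args))) {
      v <- c(v, sprintf("%s: missing required role '%s'", ev$id, role))
    }
  }
  for (s in doc$equivalences) {
    types <- unique(vapply(doc$entities[s], `[[`, "", "type"))
    if (length(types) > 1L) {
      v <- c(v, sprintf("equivalence set {%s}: mixed entity types %s",
                        paste(s, collapse = ","),
                        paste(types, collapse = "/")))
    }
  }
  v
}
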