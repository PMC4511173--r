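GENE_LIKE_TYPES <- c("Gene", "Protein", "GeneFamily", "ProteinFamily",
                     "ProteinComplex", "PolymeraseComplex", "Operon", "mRNA")

#' Reduce an annotation to its participating genes
#'
#' Network nodes are genes, while event arguments may be proteins, promoters,
#' binding sites or nested events. This reduction maps any argument to the
#' set of genes standing behind it:
#' \itemize{
#'   \item a gene/protein-like entity stands for its gene (a protein is
#'     reduced to the gene encoding it); the gene name is the entity's
#'     normalization when present, otherwise its surface form;
#'   \item a promoter or site entity is reduced through `Promoter_of` /
#'     `Site_of` events to the gene it is attached to;
#'   \item an event is reduced to the union over its arguments, recursively
#'     (a transcription event over `cwlH` reduces to `{cwlH}`).
#' }
#'
#' @param doc a [standoff_document()] in the GRN schema.
#' @param arg_id annotation id of an entity or event in `doc`.
#' @param .depth recursion guard; nesting deeper than 10 is an error.
#' @return Character vector of gene names (possibly empty).
#' @export
reduce_to_genes <- function(doc, arg_id, .depth = 0L) {
  if (.depth > 10L) {
    bt_stop("reduce_to_genes: nesting deeper than 10 at %s", arg_id,
            class = "bteval_reduction_error")
  }
  en <- doc$entities[[arg_id]]
  if (!is.null(en)) {
    if (en$type %in% GENE_LIKE_TYPES) {
      return(gene_name(doc, en))
    }
    if (en$type %in% c("Promoter", "Site")) {
      genes <- character()
      for (ev in doc$events) {
        if (ev$type == "Promoter_of" && identical(unname(ev$args["Promoter"]),
                                                  arg_id)) {
          genes <- union(genes, reduce_to_genes(doc, ev$args[["Gene"]],
                                                .depth + 1L))
        }
        if (ev$type == "Site_of" && identical(unname(ev$args["Site"]),
                                              arg_id)) {
          genes <- union(genes, reduce_to_genes(doc, ev$args[["Target"]],
                                                .depth + 1L))
        }
      }
      return(genes)
    }
    return(character()) # Regulon and friends carry no single gene
  }
  ev <- doc$events[[arg_id]]
  if (is.null(ev)) {
    bt_stop("reduce_to_genes: unresolvable argument %s", arg_id,
            class = "bteval_reduction_error")
  }
  genes <- character()
  for (a in ev$args) {
    genes <- union(genes, reduce_to_genes(doc, a, .depth + 1L))
  }
  genes
}

# Normalized gene name of a gene-like entity: its normalization concept when
# one is attached (proteins and their genes share one node), else the
# surface string. Matching downstream is case-sensitive exact.
gene_name <- function(doc, en) {
  concepts <- entity_concepts(doc, en$id)
  if (length(concepts)) concepts[[1L]] else en$surface
}

#' The molecular-to-biological rule registry
#'
#' Each rule is a premise pattern over event types and role-bound variables
#' together with a concluded event. The built-in set covers the deduction
#' chains from binding sites and promoters up to `Interaction:*` events:
#' \enumerate{
#'   \item `Bind_to(Agent=P, Site=S)` and `Site_of(Site=S, Target=Pr)` with
#'     `Pr` a promoter imply `Master_of_Promoter(Agent=P, Promoter=Pr)`;
#'   \item `Master_of_Promoter(Agent=P, Promoter=Pr)` and
#'     `Promoter_of(Promoter=Pr, Gene=G)` imply
#'     `Interaction:Binding(Agent=P, Target=G)`;
#'   \item `Transcription_from(Transcription=T, Site=Pr)`,
#'     `Promoter_of(Promoter=Pr, Gene=G)` and
#'     `Transcription_by(Transcription=T, Agent=P)` imply
#'     `Interaction:Transcription(Agent=P, Target=G)`;
#'   \item `Master_of_Regulon(Agent=P, Regulon=R)` and
#'     `Member_of_Regulon(Gene=G, Regulon=R)` imply
#'     `Interaction:Regulation(Agent=P, Target=G)`.
#' }
#' Rules flagged `provisional` are excluded from the default rule set so
#' that semantics not pinned down by the annotation model are never guessed
#' silently; drop-in replacement of the registry is supported through the
#' `rules` argument of [apply_molecular_rules()].
#'
#' @param include_provisional also return rules marked provisional.
#' @return List of rule objects.
#' @export
grn_rules <- function(include_provisional = FALSE) {
  rule <- function(name, premises, conclusion, provisional = FALSE) {
    list(name = name, premises = premises, conclusion = conclusion,
         provisional = provisional)
  }
  prem <- function(type, ...) list(type = type, roles = c(...))
  rules <- list(
    rule("master_of_promoter",
         list(prem("Bind_to", Agent = "P", Site = "S"),
              prem("Site_of", Site = "S", Target = "Pr")),
         list(type = "Master_of_Promoter",
              roles = c(Agent = "P", Promoter = "Pr"),
              require_type = c(Pr = "Promoter"))),
    rule("interaction_binding",
         list(prem("Master_of_Promoter", Agent = "P", Promoter = "Pr"),
              prem("Promoter_of", Promoter = "Pr", Gene = "G")),
         list(type = "Interaction:Binding",
              roles = c(Agent = "P", Target = "G"))),
    rule("interaction_transcription",
         list(prem("Transcription_from", Transcription = "T", Site = "Pr"),
              prem("Promoter_of", Promoter = "Pr", Gene = "G"),
              prem("Transcription_by", Transcription = "T", Agent = "P")),
         list(type = "Interaction:Transcription",
              roles = c(Agent = "P", Target = "G"))),
    rule("interaction_regulation_regulon",
         list(prem("Master_of_Regulon", Agent = "P", Regulon = "R"),
              prem("Member_of_Regulon", Gene = "G", Regulon = "R")),
         list(type = "Interaction:Regulation",
              roles = c(Agent = "P", Target = "G"))),
    # Transcription_by without a promoter: plausible Interaction:Transcription
    # reading, but not pinned down by the annotation model.
    rule("transcription_by_direct",
         list(prem("Transcription_by", Transcription = "T", Agent = "P")),
         list(type = "Interaction:Transcription",
              roles = c(Agent = "P", Target = "T")),
         provisional = TRUE)
  )
  if (!include_provisional) {
    rules <- Filter(function(r) !r$provisional, rules)
  }
  rules
}

# All variable bindings satisfying a rule's premises in `doc` (naive join).
match_rule <- function(doc, rule) {
  bindings <- list(stats::setNames(list(), character()))
  for (p in rule$premises) {
    nxt <- list()
    cand <- Filter(function(ev) ev$type == p$type, doc$events)
    for (b in bindings) {
      for (ev in cand) {
        b2 <- b
        ok <- TRUE
        for (role in names(p$roles)) {
          if (!role %in% names(ev$args)) { ok <- FALSE; break }
          v <- p$roles[[role]]
          val <- unname(ev$args[[role]])
          if (!is.null(b2[[v]]) && b2[[v]] != val) { ok <- FALSE; break }
          b2[[v]] <- val
        }
        if (ok) nxt[[length(nxt) + 1L]] <- b2
      }
    }
    bindings <- nxt
    if (length(bindings) == 0L) break
  }
  req <- rule$conclusion$require_type
  if (!is.null(req) && length(bindings)) {
    bindings <- Filter(function(b) {
      all(vapply(names(req), function(v) {
        en <- doc$entities[[b[[v]]]]
        !is.null(en) && en$type == req[[v]]
      }, TRUE))
    }, bindings)
  }
  bindings
}

#' Derive biological events from molecular events
#'
#' First inference step: saturates the document under the rule registry,
#' adding derived events (ids `D1`, `D2`, ...) until a fixpoint is reached.
#' An event is only added once per `(type, arguments)` signature, so the
#' operation is idempotent; unmatched premises simply yield nothing.
#'
#' @param doc a [standoff_document()] in the GRN schema.
#' @param rules rule registry, by default [grn_rules()].
#' @return The document augmented with derived events.
#' @export
apply_molecular_rules <- function(doc, rules = grn_rules()) {
  signature <- function(type, args) {
    paste(type, paste(names(args), args, sep = ":", collapse = " "))
  }
  seen <- vapply(doc$events, function(ev) signature(ev$type, ev$args), "")
  counter <- sum(grepl("^D[0-9]+$", names(doc$events)))
  repeat {
    added <- FALSE
    for (rule in rules) {
      for (b in match_rule(doc, rule)) {
        args <- vapply(rule$conclusion$roles, function(v) b[[v]], "")
        sig <- signature(rule$conclusion$type, args)
        if (sig %in% seen) next
        counter <- counter + 1L
        id <- paste0("D", counter)
        while (id %in% c(names(doc$entities), names(doc$events))) {
          counter <- counter + 1L
          id <- paste0("D", counter)
        }
        doc$events[[id]] <- event(id, rule$conclusion$type, args)
        seen <- c(seen, sig)
        added <- TRUE
      }
    }
    if (!added) break
  }
  doc
}

#' Infer a regulation network from annotated documents
#'
#' Second inference step: every `Interaction:L` event contributes arcs
#' `(a, t, L)` for each agent gene `a` and target gene `t` obtained by
#' [reduce_to_genes()] on its `Agent` and `Target` arguments. Interactions
#' repeated across the corpus collapse to a single arc.
#'
#' @param corpus a [standoff_document()] or list of them.
#' @param apply_rules run [apply_molecular_rules()] on each document first.
#' @param rules rule registry used when `apply_rules` is `TRUE`.
#' @return A [grn_network()].
#' @export
infer_network <- function(corpus, apply_rules = TRUE, rules = grn_rules()) {
  if (inherits(corpus, "standoff_document")) corpus <- list(corpus)
  agent <- label <- target <- character()
  for (doc in corpus) {
    if (apply_rules) doc <- apply_molecular_rules(doc, rules)
    for (ev in doc$events) {
      if (!startsWith(ev$type, "Interaction:")) next
      lab <- sub("^Interaction:", "", ev$type)
      agents <- reduce_to_genes(doc, ev$args[["Agent"]])
      targets <- reduce_to_genes(doc, ev$args[["Target"]])
      for (a in agents) for (t in targets) {
        agent <- c(agent, a)
        label <- c(label, lab)
        target <- c(target, t)
      }
    }
  }
  grn_network(data.frame(agent = agent, label = label, target = target,
                         stringsAsFactors = FALSE))
}
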