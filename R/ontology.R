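#' Build an ontology object
#'
#' An ontology is a rooted directed acyclic graph of concepts connected by
#' named hierarchical relations (`is_a`, optionally `part_of`, ...). Roots
#' are the concepts with no parents.
#'
#' @param concepts named list; each element a list with fields `id`, `name`,
#'   `synonyms` (character vector) and `parents` (data.frame with columns
#'   `relation`, `parent`).
#' @return An object of class `bt_ontology`.
#' @export
ontology <- function(concepts) {
  names(concepts) <- vapply(concepts, `[[`, "", "id")
  for (co in concepts) {
    missing <- setdiff(co$parents$parent, names(concepts))
    if (length(missing)) {
      bt_stop("concept %s: unresolved parent %s", co$id, missing[1L],
              class = "bteval_ontology_error")
    }
  }
  onto <- structure(list(concepts = concepts), class = "bt_ontology")
  onto$roots <- names(concepts)[vapply(concepts, function(co)
    nrow(co$parents) == 0L, TRUE)]
  check_acyclic(onto)
  onto
}

check_acyclic <- function(onto) {
  color <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  visit <- function(id, stack) {
    st <- get0(id, envir = color)
    if (identical(st, 2L)) return(invisible())
    if (identical(st, 1L)) {
      cyc <- c(stack[which(stack == id):length(stack)], id)
      bt_stop("ontology cycle: %s", paste(cyc, collapse = " -> "),
              class = "bteval_cycle_error")
    }
    assign(id, 1L, envir = color)
    for (p in onto$concepts[[id]]$parents$parent) visit(p, c(stack, id))
    assign(id, 2L, envir = color)
  }
  for (id in names(onto$concepts)) visit(id, character())
  invisible(onto)
}

#' @export
print.bt_ontology <- function(x, ...) {
  cat(sprintf("<bt_ontology: %d concepts, %d root(s)>\n",
              length(x$concepts), length(x$roots)))
  invisible(x)
}

#' Load an OBO-format ontology
#'
#' Minimal OBO 1.2 reader covering what hierarchy-based similarity needs:
#' `[Term]` stanzas with `id`, `name`, `synonym`, `is_a` and
#' `relationship` tags. Obsolete terms are excluded; a cycle in the
#' hierarchy is a structural error.
#'
#' @param path path to an `.obo` file, or a character vector of lines.
#' @return A [ontology()] object.
#' @export
load_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  lines <- sub("!.*$", "", lines) # strip comments
  concepts <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) {
      cur$obsolete <- NULL
      concepts[[length(concepts) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(id = NA_character_, name = NA_character_,
                  synonyms = character(),
                  parents = data.frame(relation = character(),
                                       parent = character()))
      next
    }
    if (grepl("^\\[", line)) { # other stanza kinds ([Typedef], ...)
      flush()
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1L]]
    if (length(m) != 3L) next
    tag <- m[[2L]]
    val <- trimws(m[[3L]])
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "synonym") {
      syn <- regmatches(val, regexec("^\"([^\"]*)\"", val))[[1L]]
      if (length(syn) == 2L) cur$synonyms <- c(cur$synonyms, syn[[2L]])
    } else if (tag == "is_a") {
      cur$parents <- rbind(cur$parents,
                           data.frame(relation = "is_a",
                                      parent = strsplit(val, "[[:space:]]+")[[1L]][1L]))
    } else if (tag == "relationship") {
      toks <- strsplit(val, "[[:space:]]+")[[1L]]
      if (length(toks) >= 2L) {
        cur$parents <- rbind(cur$parents,
                             data.frame(relation = toks[[1L]],
                                        parent = toks[[2L]]))
      }
    } else if (tag == "is_obsolete" && grepl("true", val)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  ontology(concepts)
}

#' Write an ontology as OBO
#'
#' @param onto a [ontology()] object.
#' @param path output path; if `NULL` the lines are returned instead.
#' @return The OBO lines, invisibly when written to a file.
#' @export
write_obo <- function(onto, path = NULL) {
  out <- c("format-version: 1.2", "")
  for (co in onto$concepts) {
    out <- c(out, "[Term]", paste0("id: ", co$id), paste0("name: ", co$name))
    for (s in co$synonyms) {
      out <- c(out, sprintf("synonym: \"%s\" EXACT []", s))
    }
    if (nrow(co$parents)) {
      for (i in seq_len(nrow(co$parents))) {
        rel <- co$parents$relation[[i]]
        par <- co$parents$parent[[i]]
        out <- c(out, if (rel == "is_a") {
          sprintf("is_a: %s ! %s", par, onto$concepts[[par]]$name)
        } else {
          sprintf("relationship: %s %s ! %s", rel, par,
                  onto$concepts[[par]]$name)
        })
      }
    }
    out <- c(out, "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# All ancestors of a concept including itself (the "ancestor closure").
ancestor_closure <- function(onto, id) {
  if (is.null(onto$concepts[[id]])) {
    bt_stop("unknown concept id '%s'", id, class = "bteval_lookup_error")
  }
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(onto$concepts[frontier],
                           function(co) co$parents$parent))),
      seen)
  }
  seen
}
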