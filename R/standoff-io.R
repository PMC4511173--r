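#' Parse a standoff-annotated document
#'
#' Reads the BioNLP-ST standoff dialect: tab-separated annotation lines over
#' a separate document text. Recognized line shapes:
#' \itemize{
#'   \item entities: `ID<TAB>TYPE START END[;START END]*<TAB>SURFACE`
#'     (`T`-ids; discontinuous spans as semicolon-separated fragments),
#'   \item events/relations: `ID<TAB>TYPE Role:Arg ...` (`E`/`R`-ids),
#'   \item equivalence sets: `*<TAB>Equiv ID ID ...`,
#'   \item normalizations: `ID<TAB>TYPE Role:EntityId Referent:CONCEPT`
#'     (`N`-ids; several lines with the same id, or a comma-separated
#'     concept list, accumulate into one multi-concept normalization).
#' }
#' Unrecognized lines are preserved verbatim in `$extra` and flagged with a
#' warning rather than rejected.
#'
#' @param text document text (single string).
#' @param lines character vector of annotation lines (one or several streams
#'   concatenated, e.g. `.a1` then `.a2` content).
#' @param doc_id document identifier.
#' @param sentence_spans optional fragment data.frame of sentence extents.
#' @return A [standoff_document()].
#' @export
parse_standoff <- function(text, lines, doc_id = "doc",
                           sentence_spans = NULL) {
  entities <- list()
  events <- list()
  norm_acc <- list() # id -> list(type, entity_id, concepts)
  equivalences <- list()
  extra <- character()

  for (k in seq_along(lines)) {
    line <- lines[[k]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      bt_stop("line %d: expected at least 2 tab-separated fields", k,
              class = "bteval_parse_error")
    }
    id <- fields[[1L]]
    body <- fields[[2L]]

    if (id == "*") {
      toks <- strsplit(trimws(body), "[[:space:]]+")[[1L]]
      if (toks[[1L]] != "Equiv") {
        bt_stop("line %d: '*' line must carry an Equiv set", k,
                class = "bteval_parse_error")
      }
      equivalences[[length(equivalences) + 1L]] <- toks[-1L]
    } else if (grepl("^T", id)) {
      m <- regmatches(body, regexec("^(\\S+)\\s+([0-9 ;]+)$", body))[[1L]]
      if (length(m) != 3L) {
        bt_stop("line %d: malformed entity line", k,
                class = "bteval_parse_error")
      }
      surface <- if (length(fields) >= 3L) fields[[3L]] else NA_character_
      entities[[length(entities) + 1L]] <-
        entity(id, m[[2L]], parse_fragments(m[[3L]]), surface)
    } else if (grepl("^[ER]", id)) {
      toks <- strsplit(trimws(body), "[[:space:]]+")[[1L]]
      etype <- toks[[1L]]
      argtok <- toks[-1L]
      if (length(argtok) == 0L || any(!grepl(":", argtok, fixed = TRUE))) {
        bt_stop("line %d: event arguments must be Role:Arg pairs", k,
                class = "bteval_parse_error")
      }
      roles <- sub(":.*$", "", argtok)
      args <- sub("^[^:]*:", "", argtok)
      names(args) <- roles
      events[[length(events) + 1L]] <- event(id, etype, args)
    } else if (grepl("^N", id)) {
      toks <- strsplit(trimws(body), "[[:space:]]+")[[1L]]
      ntype <- toks[[1L]]
      argtok <- toks[-1L]
      roles <- sub(":.*$", "", argtok)
      vals <- sub("^[^:]*:", "", argtok)
      concept <- vals[roles == "Referent"]
      target <- vals[roles != "Referent"][1L]
      if (is.na(target) || length(concept) == 0L) {
        bt_stop("line %d: normalization needs an entity arg and a Referent", k,
                class = "bteval_parse_error")
      }
      concepts <- unlist(strsplit(concept, ",", fixed = TRUE))
      if (is.null(norm_acc[[id]])) {
        norm_acc[[id]] <- list(type = ntype, entity_id = target,
                               concepts = concepts)
      } else {
        norm_acc[[id]]$concepts <- union(norm_acc[[id]]$concepts, concepts)
      }
    } else {
      warning(sprintf("line %d: unknown annotation kind '%s' preserved verbatim",
                      k, id), call. = FALSE)
      extra <- c(extra, line)
    }
  }

  normalizations <- lapply(names(norm_acc), function(id) {
    a <- norm_acc[[id]]
    normalization(id, a$entity_id, a$concepts, type = a$type)
  })
  doc <- standoff_document(doc_id, text, entities, events, normalizations,
                           equivalences, sentence_spans)
  if (length(extra)) doc$extra <- extra
  doc
}

#' Serialize a document back to standoff lines
#'
#' Inverse of [parse_standoff()]: `parse_standoff(text, serialize_standoff(doc))`
#' reproduces `doc`. Multi-concept normalizations are emitted as one line per
#' concept sharing the normalization id.
#'
#' @param doc a [standoff_document()].
#' @return Character vector of annotation lines.
#' @export
serialize_standoff <- function(doc) {
  out <- character()
  for (en in doc$entities) {
    out <- c(out, sprintf("%s\t%s %s\t%s", en$id, en$type,
                          format_fragments(en$fragments), en$surface))
  }
  for (ev in doc$events) {
    out <- c(out, sprintf("%s\t%s %s", ev$id, ev$type,
                          paste(names(ev$args), ev$args, sep = ":",
                                collapse = " ")))
  }
  for (nm in doc$normalizations) {
    for (concept in nm$concepts) {
      out <- c(out, sprintf("%s\t%s Annotation:%s Referent:%s", nm$id,
                            nm$type, nm$entity_id, concept))
    }
  }
  for (s in doc$equivalences) {
    out <- c(out, sprintf("*\tEquiv %s", paste(s, collapse = " ")))
  }
  c(out, doc$extra)
}

#' Read a standoff document from files
#'
#' @param txt_path path to the document text file.
#' @param ann_paths character vector of annotation file paths (`.a1`, `.a2`,
#'   ... contents are concatenated in order).
#' @param doc_id document id; defaults to the text file name without extension.
#' @param sentence_spans optional fragment data.frame.
#' @return A [standoff_document()].
#' @export
read_standoff_document <- function(txt_path, ann_paths, doc_id = NULL,
                                   sentence_spans = NULL) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  lines <- unlist(lapply(ann_paths, readLines, warn = FALSE))
  doc_id <- doc_id %||% sub("\\.[^.]*$", "", basename(txt_path))
  parse_standoff(text, lines, doc_id, sentence_spans)
}

#' Write a standoff document to files
#'
#' @param doc a [standoff_document()].
#' @param dir output directory; files `<doc_id>.txt` and `<doc_id>.ann` are
#'   written (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_standoff_document <- function(doc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt <- file.path(dir, paste0(doc$doc_id, ".txt"))
  ann <- file.path(dir, paste0(doc$doc_id, ".ann"))
  writeLines(doc$text, txt, sep = "")
  writeLines(serialize_standoff(doc), ann)
  invisible(c(txt, ann))
}

#' Read a directory of standoff documents
#'
#' Pairs every `<id>.txt` with its `<id>.a1`/`<id>.a2`/`<id>.ann` files.
#'
#' @param dir directory path.
#' @param sentence_spans optional sentence-span table from
#'   [read_sentence_spans()]; matched to documents by `doc_id`.
#' @return Named list of [standoff_document()] objects.
#' @export
read_standoff_corpus <- function(dir, sentence_spans = NULL) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(txt) {
    id <- sub("\\.txt$", "", basename(txt))
    anns <- file.path(dir, paste0(id, c(".a1", ".a2", ".ann")))
    anns <- anns[file.exists(anns)]
    spans <- NULL
    if (!is.null(sentence_spans)) {
      sel <- sentence_spans$doc_id == id
      if (any(sel)) spans <- fragments(sentence_spans$start[sel],
                                       sentence_spans$end[sel])
    }
    read_standoff_document(txt, anns, doc_id = id, sentence_spans = spans)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}

#' Read sentence spans
#'
#' TSV with columns `doc_id`, `start`, `end` (0-based half-open offsets),
#' one row per sentence.
#'
#' @param path file path.
#' @return data.frame with columns `doc_id`, `start`, `end`.
#' @export
read_sentence_spans <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("doc_id", "start", "end"),
                          stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
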