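# Corpus model: documents, sense inventories, concept graphs, gold sense
# annotations, their on-disk formats, and term matching.
#
# A corpus is a plain data.frame (doc_id, title, abstract, year); a sense
# inventory is an S3 object wrapping the term -> candidate-CUI mapping; term
# mentions and sense annotations are data.frames with one row per mention, a
# layout that keeps the whole pipeline vectorisable.

#' Normalize free text for term lookup
#'
#' Lowercases, replaces every non-alphanumeric character by a space and
#' collapses runs of whitespace. The transformation is deterministic and
#' idempotent; all term matching, mention offsets and feature extraction
#' operate on normalized text.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_text("Raynaud's Disease")  # "raynaud s disease"
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Read a dated document corpus
#'
#' The native dialect is JSON Lines: one object per document with keys
#' `doc_id`, `title`, optional `abstract`, and integer `year`. A minimal
#' PubMed/MEDLINE XML reader is provided as a convenience
#' (`PubmedArticle` records with `PMID`, `ArticleTitle`, `AbstractText` and a
#' `PubDate/Year`).
#'
#' @param path file path.
#' @param format `"jsonl"` or `"pubmed_xml"`.
#' @param year_range two integers; records outside this range are rejected.
#'   Publication year is mandatory because time-slicing partitions on it.
#' @return data.frame with columns `doc_id`, `title`, `abstract` (NA when
#'   absent) and integer `year`, in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "pubmed_xml"),
                        year_range = c(1700L, 2100L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop(sprintf(
                        "corpus record %d: malformed JSON (%s)", i,
                        conditionMessage(e)), call. = FALSE))
      parse_corpus_record(rec, i, year_range)
    })
    corpus <- do.call(rbind, recs)
  } else {
    doc <- xml2::read_xml(path)
    arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
    if (length(arts) == 0L) stop("no PubmedArticle records in ", path,
                                 call. = FALSE)
    recs <- lapply(seq_along(arts), function(i) {
      a <- arts[[i]]
      rec <- list(
        doc_id = xml2::xml_text(xml2::xml_find_first(a, ".//PMID")),
        title = xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle")),
        abstract = {
          ab <- xml2::xml_find_all(a, ".//AbstractText")
          if (length(ab)) paste(xml2::xml_text(ab), collapse = " ") else NULL
        },
        year = xml2::xml_text(xml2::xml_find_first(a, ".//PubDate/Year")))
      parse_corpus_record(rec, i, year_range)
    })
    corpus <- do.call(rbind, recs)
  }
  if (anyDuplicated(corpus$doc_id)) {
    stop("duplicate doc_id in corpus: ",
         corpus$doc_id[anyDuplicated(corpus$doc_id)], call. = FALSE)
  }
  rownames(corpus) <- NULL
  corpus
}

parse_corpus_record <- function(rec, i, year_range) {
  need <- function(field) {
    v <- rec[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(as.character(v)))
      stop(sprintf("corpus record %d: missing or empty field '%s'", i, field),
           call. = FALSE)
    as.character(v)
  }
  doc_id <- need("doc_id")
  title <- need("title")
  year_raw <- need("year")
  year <- suppressWarnings(as.integer(year_raw))
  if (is.na(year) || year != as.numeric(year_raw)) {
    stop(sprintf("corpus record %d (doc_id %s): unparseable year '%s'",
                 i, doc_id, year_raw), call. = FALSE)
  }
  if (year < year_range[[1L]] || year > year_range[[2L]]) {
    stop(sprintf("corpus record %d (doc_id %s): year %d outside [%d, %d]",
                 i, doc_id, year, year_range[[1L]], year_range[[2L]]),
         call. = FALSE)
  }
  abstract <- rec[["abstract"]]
  abstract <- if (is.null(abstract) || is.na(abstract)) NA_character_ else
    as.character(abstract)
  data.frame(doc_id = doc_id, title = title, abstract = abstract,
             year = year, stringsAsFactors = FALSE)
}

#' Write a corpus as JSON Lines
#'
#' Inverse of [read_corpus()] for the JSONL dialect: `write_corpus` followed
#' by `read_corpus` is the identity on valid corpora.
#'
#' @param corpus data.frame as returned by [read_corpus()].
#' @param path output file path.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(doc_id = corpus$doc_id[[i]], title = corpus$title[[i]],
                year = corpus$year[[i]])
    if (!is.na(corpus$abstract[[i]])) rec$abstract <- corpus$abstract[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a sense inventory
#'
#' A sense inventory maps normalized surface terms (possibly multiword) to a
#' non-empty set of candidate concepts. Terms mapping to two or more concepts
#' are "ambiguous". Surface terms are normalized at construction time and
#' duplicate rows merge their concept sets; within a term, candidate CUIs are
#' kept in lexicographic order, which is also the package-wide tie-breaking
#' order.
#'
#' @param term,cui,description character vectors of equal length, one row per
#'   (term, concept) sense pairing.
#' @return object of class `sense_inventory` with elements `terms` (named
#'   list term -> character vector of CUIs), `concepts` (data.frame `cui`,
#'   `description`) and `max_term_tokens`.
#' @export
sense_inventory <- function(term, cui, description = NULL) {
  stopifnot(length(term) == length(cui))
  if (is.null(description)) description <- rep("", length(term))
  term <- normalize_text(term)
  if (any(!nzchar(term))) stop("empty term in sense inventory", call. = FALSE)
  if (any(!nzchar(cui))) stop("empty cui in sense inventory", call. = FALSE)
  terms <- lapply(split(cui, term), function(x) sort(unique(x)))
  concepts <- data.frame(cui = cui, description = description,
                         stringsAsFactors = FALSE)
  concepts <- concepts[!duplicated(concepts$cui), , drop = FALSE]
  concepts <- concepts[order(concepts$cui), , drop = FALSE]
  rownames(concepts) <- NULL
  structure(list(
    terms = terms,
    concepts = concepts,
    max_term_tokens = max(lengths(strsplit(names(terms), " ", fixed = TRUE)))
  ), class = "sense_inventory")
}

#' @export
print.sense_inventory <- function(x, ...) {
  amb <- sum(lengths(x$terms) >= 2L)
  cat(sprintf("sense_inventory: %d terms (%d ambiguous), %d concepts\n",
              length(x$terms), amb, nrow(x$concepts)))
  invisible(x)
}

#' Candidate concepts of a normalized term
#'
#' @param inventory a [sense_inventory()].
#' @param term character vector of surface terms (normalized internally).
#' @return list of candidate CUI vectors, `NULL` for unknown terms.
#' @export
inventory_candidates <- function(inventory, term) {
  inventory$terms[normalize_text(term)]
}

#' Names of the ambiguous (>= 2 senses) terms of an inventory
#' @param inventory a [sense_inventory()].
#' @export
ambiguous_terms <- function(inventory) {
  names(inventory$terms)[lengths(inventory$terms) >= 2L]
}

#' Read a sense inventory from TSV (columns: term, cui, description)
#' @param path file path.
#' @return a [sense_inventory()].
#' @export
read_sense_inventory <- function(path) {
  df <- read_tsv_strict(path, c("term", "cui", "description"),
                        optional = "description")
  sense_inventory(df$term, df$cui, df$description)
}

#' Write a sense inventory as TSV
#' @param inventory a [sense_inventory()].
#' @param path output path.
#' @export
write_sense_inventory <- function(inventory, path) {
  term <- rep(names(inventory$terms), lengths(inventory$terms))
  cui <- unlist(inventory$terms, use.names = FALSE)
  desc <- inventory$concepts$description[match(cui, inventory$concepts$cui)]
  write_tsv(data.frame(term = term, cui = cui,
                       description = desc %||% "",
                       stringsAsFactors = FALSE), path)
}

#' Read a concept -> semantic type map from TSV (columns: cui, semantic_type)
#'
#' A concept may carry several types (one row each) or none (no rows).
#' @param path file path.
#' @return data.frame with columns `cui`, `semantic_type`.
#' @export
read_semantic_types <- function(path) {
  read_tsv_strict(path, c("cui", "semantic_type"))
}

#' Construct a concept relation graph
#'
#' An undirected graph over CUIs in the style of an MRREL edge list.
#' Duplicate edges collapse to a single edge whose weight is the multiplicity
#' (or the sum of the supplied counts); self-loops are rejected.
#'
#' @param cui1,cui2 character vectors, the edge endpoints.
#' @param weight optional numeric edge multiplicities (default 1).
#' @param nodes optional superset of node CUIs (isolated nodes allowed).
#' @return object of class `concept_graph` with elements `nodes` (sorted
#'   character) and `edges` (data.frame `cui1 < cui2`, `weight`).
#' @export
concept_graph <- function(cui1 = character(), cui2 = character(),
                          weight = NULL, nodes = NULL) {
  stopifnot(length(cui1) == length(cui2))
  if (is.null(weight)) weight <- rep(1, length(cui1))
  if (any(cui1 == cui2)) {
    stop("self-loop in concept graph: ", cui1[cui1 == cui2][[1L]],
         call. = FALSE)
  }
  a <- pmin(cui1, cui2); b <- pmax(cui1, cui2)
  key <- paste(a, b, sep = "|")
  w <- vapply(split(as.numeric(weight), key), sum, numeric(1L))
  keys <- sort(names(w))
  parts <- strsplit(keys, "|", fixed = TRUE)
  edges <- data.frame(
    cui1 = vapply(parts, `[[`, "", 1L),
    cui2 = vapply(parts, `[[`, "", 2L),
    weight = as.numeric(w[keys]), stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(edges$cui1, edges$cui2, nodes)))
  structure(list(nodes = all_nodes, edges = edges), class = "concept_graph")
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("concept_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a concept relation graph from TSV (columns: cui1, cui2[, count])
#' @param path file path.
#' @return a [concept_graph()].
#' @export
read_relations <- function(path) {
  df <- read_tsv_strict(path, c("cui1", "cui2", "count"), optional = "count")
  w <- if ("count" %in% names(df)) as.numeric(df$count) else NULL
  concept_graph(df$cui1, df$cui2, weight = w)
}

#' Write a concept relation graph as TSV
#' @param graph a [concept_graph()].
#' @param path output path.
#' @export
write_relations <- function(graph, path) {
  df <- graph$edges
  names(df)[names(df) == "weight"] <- "count"
  write_tsv(df, path)
}

#' Read gold sense annotations from TSV
#'
#' Columns: `instance_id`, `doc_id`, `start`, `end`, `term`, `gold_cui`.
#' Offsets are 0-based half-open over the normalized title text.
#' @param path file path.
#' @return data.frame with integer `start`/`end`.
#' @export
read_gold <- function(path) {
  df <- read_tsv_strict(path, c("instance_id", "doc_id", "start", "end",
                                "term", "gold_cui"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write gold sense annotations as TSV
#' @param gold data.frame as returned by [read_gold()].
#' @param path output path.
#' @export
write_gold <- function(gold, path) write_tsv(gold, path)

#' Match inventory terms in a document field
#'
#' Greedy left-to-right longest-match over the whitespace tokens of the
#' normalized field text. Matches never overlap; each mention carries the
#' full candidate concept set from the inventory (monosemous and ambiguous
#' terms alike). Character offsets are 0-based and half-open over the
#' normalized field text.
#'
#' @param doc single-row corpus data.frame (or a list with `doc_id`, `year`
#'   and the named field).
#' @param inventory a [sense_inventory()].
#' @param field `"title"` or `"abstract"`.
#' @return data.frame with columns `doc_id`, `year`, `field`, `start`, `end`,
#'   `surface` and list-column `candidates`; zero rows when nothing matches.
#' @export
match_terms <- function(doc, inventory, field = c("title", "abstract")) {
  field <- match.arg(field)
  text <- doc[[field]]
  if (is.null(text) || length(text) != 1L || is.na(text)) {
    stop("document ", doc$doc_id, " has no ", field, call. = FALSE)
  }
  norm <- normalize_text(text)
  empty <- mention_frame(integer(), integer(), character(), list(),
                         doc$doc_id, doc$year, field)
  if (!nzchar(norm)) return(empty)
  tokens <- strsplit(norm, " ", fixed = TRUE)[[1L]]
  n <- length(tokens)
  starts <- c(0L, cumsum(nchar(tokens) + 1L))[seq_len(n)]
  ends <- starts + nchar(tokens)
  maxlen <- inventory$max_term_tokens
  out_start <- integer(); out_end <- integer(); out_surf <- character()
  out_cand <- list()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      cand <- inventory$terms[[phrase]]
      if (!is.null(cand)) {
        out_start <- c(out_start, starts[[i]])
        out_end <- c(out_end, ends[[i + len - 1L]])
        out_surf <- c(out_surf, phrase)
        out_cand <- c(out_cand, list(cand))
        hit <- len
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  mention_frame(out_start, out_end, out_surf, out_cand,
                doc$doc_id, doc$year, field)
}

mention_frame <- function(start, end, surface, candidates,
                          doc_id, year, field) {
  n <- length(start)
  df <- data.frame(
    doc_id = rep(as.character(doc_id), n),
    year = rep(as.integer(year), n),
    field = rep(field, n),
    start = as.integer(start), end = as.integer(end),
    surface = as.character(surface), stringsAsFactors = FALSE)
  df$candidates <- candidates
  df
}

#' Match inventory terms across a whole corpus
#'
#' @param corpus corpus data.frame.
#' @param inventory a [sense_inventory()].
#' @param field `"title"` (the co-occurrence field) or `"abstract"`.
#' @return row-bound [match_terms()] output over all documents.
#' @export
match_corpus <- function(corpus, inventory, field = "title") {
  rows <- lapply(seq_len(nrow(corpus)), function(i)
    match_terms(corpus[i, , drop = FALSE], inventory, field))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write sense annotations as JSON Lines
#'
#' One object per document: `doc_id`, `year`, `assignments` (list of
#' `{start, end, surface, candidates, chosen}` with `chosen = null` for an
#' abstention).
#'
#' @param annotations annotation data.frame (mentions plus a `chosen`
#'   column, `NA` meaning abstain).
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  by_doc <- split(annotations, annotations$doc_id)
  by_doc <- by_doc[unique(annotations$doc_id)]
  lines <- vapply(by_doc, function(d) {
    assigns <- lapply(seq_len(nrow(d)), function(i) list(
      start = d$start[[i]], end = d$end[[i]], surface = d$surface[[i]],
      candidates = as.list(d$candidates[[i]]),
      chosen = if (is.na(d$chosen[[i]])) NULL else d$chosen[[i]]))
    jsonlite::toJSON(list(doc_id = d$doc_id[[1L]], year = d$year[[1L]],
                          assignments = assigns), auto_unbox = TRUE,
                     null = "null")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read sense annotations from JSON Lines written by [write_annotations()]
#' @param path file path.
#' @return annotation data.frame.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    n <- length(rec$assignments)
    df <- mention_frame(
      start = vapply(rec$assignments, function(a) a$start, numeric(1L)),
      end = vapply(rec$assignments, function(a) a$end, numeric(1L)),
      surface = vapply(rec$assignments, function(a) a$surface, character(1L)),
      candidates = lapply(rec$assignments, function(a)
        unlist(a$candidates, use.names = FALSE)),
      doc_id = rec$doc_id, year = rec$year, field = "title")
    df$chosen <- vapply(rec$assignments, function(a)
      if (is.null(a$chosen)) NA_character_ else a$chosen, character(1L))
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
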