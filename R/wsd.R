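# Word sense disambiguation backends.
#
# Every backend consumes a mention data.frame (see match_corpus) and returns
# the same frame with a `chosen` column: the selected candidate CUI, or NA
# for an abstention. All backends obey the candidate contract: chosen is
# always a member of the mention's candidate set or NA. Ties are broken by
# the lexicographically smallest CUI throughout.

annotate_result <- function(mentions, chosen) {
  out <- mentions
  out$chosen <- as.character(chosen)
  out
}

#' Random-sense baseline
#'
#' Selects one of the candidate concepts uniformly at random for each
#' mention. This is the floor any informed disambiguator must beat.
#'
#' @param mentions mention data.frame from [match_corpus()].
#' @param seed integer seed; the assignment is fully reproducible.
#' @return annotation data.frame (`mentions` plus `chosen`).
#' @export
disambiguate_random <- function(mentions, seed) {
  chosen <- with_seed(seed, vapply(mentions$candidates, function(cand) {
    cand[[sample.int(length(cand), 1L)]]
  }, character(1L)))
  annotate_result(mentions, chosen)
}

#' First-sense (sense-collapsing) baseline
#'
#' Assigns every mention its lexicographically first candidate, ignoring
#' context entirely. All occurrences of an ambiguous term therefore collapse
#' onto a single concept — the failure mode that lets the A-B-C model
#' manufacture spurious hidden knowledge through distinct senses of one
#' linking term.
#'
#' @param mentions mention data.frame.
#' @return annotation data.frame.
#' @export
disambiguate_first_sense <- function(mentions) {
  chosen <- vapply(mentions$candidates, function(cand) sort(cand)[[1L]],
                   character(1L))
  annotate_result(mentions, chosen)
}

#' Noisy-oracle backend with configurable accuracy
#'
#' A stand-in for a WSD system of arbitrary quality: each ambiguous mention
#' receives its gold concept with probability `target_accuracy` and otherwise
#' a uniformly chosen wrong candidate. Monosemous mentions are always
#' assigned their single candidate. This enables controlled sweeps of WSD
#' accuracy against downstream discovery performance.
#'
#' @param mentions mention data.frame.
#' @param gold gold sense annotations (see [read_gold()]); every ambiguous
#'   mention must have a gold instance aligned by `(doc_id, start, end)`.
#' @param target_accuracy real in `[0, 1]`.
#' @param seed integer seed.
#' @return annotation data.frame.
#' @export
disambiguate_oracle <- function(mentions, gold, target_accuracy, seed) {
  stopifnot(is.numeric(target_accuracy), length(target_accuracy) == 1L,
            target_accuracy >= 0, target_accuracy <= 1)
  key <- paste(mentions$doc_id, mentions$start, mentions$end)
  gkey <- paste(gold$doc_id, gold$start, gold$end)
  gold_cui <- gold$gold_cui[match(key, gkey)]
  n_cand <- lengths(mentions$candidates)
  missing <- n_cand >= 2L & is.na(gold_cui)
  if (any(missing)) {
    i <- which(missing)[[1L]]
    stop(sprintf("ambiguous mention without gold annotation: doc %s [%d,%d) '%s'",
                 mentions$doc_id[[i]], mentions$start[[i]], mentions$end[[i]],
                 mentions$surface[[i]]), call. = FALSE)
  }
  chosen <- with_seed(seed, {
    u <- stats::runif(nrow(mentions))
    vapply(seq_len(nrow(mentions)), function(i) {
      cand <- mentions$candidates[[i]]
      if (length(cand) == 1L) return(cand)
      if (u[[i]] < target_accuracy) return(gold_cui[[i]])
      wrong <- setdiff(cand, gold_cui[[i]])
      wrong[[sample.int(length(wrong), 1L)]]
    }, character(1L))
  })
  annotate_result(mentions, chosen)
}

#' Personalized PageRank over a concept graph
#'
#' Computes the stationary vector of `r = d * M %*% r + (1 - d) * p` where
#' `M` is the column-stochastic transition matrix of the undirected concept
#' graph (each undirected edge acts as two directed edges, multi-edges as
#' weights) and `p` is the teleport (personalization) distribution. Mass
#' arriving at dangling nodes (no incident edges) is redistributed to `p`,
#' so scores always sum to 1. Iteration stops when the L1 change drops below
#' `tol` or after `max_iter` sweeps.
#'
#' @param graph a [concept_graph()].
#' @param personalization named non-negative numeric vector over a subset of
#'   the graph nodes; normalized internally.
#' @param damping damping factor `d` in `[0, 1)`.
#' @param max_iter,tol iteration controls. The defaults (30 sweeps,
#'   `1e-9`) follow common knowledge-graph WSD practice; raise `max_iter`
#'   when convergence to machine precision is required.
#' @return named numeric rank vector over all graph nodes, summing to 1.
#' @export
personalized_pagerank <- function(graph, personalization, damping = 0.85,
                                  max_iter = 30L, tol = 1e-9) {
  nodes <- graph$nodes
  if (length(nodes) == 0L) stop("empty graph", call. = FALSE)
  if (length(personalization) == 0L || sum(personalization) <= 0) {
    stop("empty personalization vector", call. = FALSE)
  }
  if (!all(names(personalization) %in% nodes)) {
    stop("personalization concepts absent from graph: ",
         paste(setdiff(names(personalization), nodes), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(damping >= 0, damping < 1)
  n <- length(nodes)
  p <- numeric(n)
  names(p) <- nodes
  p[names(personalization)] <- personalization
  if (any(p < 0)) stop("negative personalization weight", call. = FALSE)
  p <- p / sum(p)

  e <- graph$edges
  if (nrow(e) > 0L) {
    i <- c(match(e$cui1, nodes), match(e$cui2, nodes))
    j <- c(match(e$cui2, nodes), match(e$cui1, nodes))
    w <- c(e$weight, e$weight)
    W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  out_w <- Matrix::colSums(W)
  dangling <- out_w == 0
  scale <- ifelse(dangling, 0, 1 / pmax(out_w, .Machine$double.eps))
  M <- W %*% Matrix::Diagonal(n, scale)

  r <- p
  for (iter in seq_len(max_iter)) {
    r_new <- as.numeric(damping * (M %*% r + sum(r[dangling]) * p) +
                          (1 - damping) * p)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  names(r) <- nodes
  r / sum(r)
}

#' Disambiguate by personalized PageRank
#'
#' Single-pass mode (default) runs one PPR per document with the teleport
#' distribution spread uniformly over all candidate concepts of all mentions
#' in the document, then assigns each mention its highest-ranked candidate;
#' this resolves every sense in the context in one pass. Per-target mode
#' runs one PPR per ambiguous mention, personalized on the candidates of the
#' other mentions only (the target's own senses are excluded from the
#' teleport set).
#'
#' A mention abstains when none of its candidates is a graph node, or when
#' the document offers no disambiguation signal at all (a lone mention whose
#' candidates have no incident edges in single-pass mode; an empty context
#' in per-target mode). Ties are broken by the lexicographically smallest
#' CUI.
#'
#' @param mentions mention data.frame.
#' @param graph a [concept_graph()].
#' @param damping,max_iter,tol passed to [personalized_pagerank()].
#' @param mode `"single_pass"` or `"per_target"`.
#' @return annotation data.frame.
#' @export
disambiguate_ppr <- function(mentions, graph, damping = 0.85,
                             max_iter = 30L, tol = 1e-9,
                             mode = c("single_pass", "per_target")) {
  mode <- match.arg(mode)
  node_deg <- numeric(length(graph$nodes))
  names(node_deg) <- graph$nodes
  tab <- table(c(graph$edges$cui1, graph$edges$cui2))
  node_deg[names(tab)] <- as.numeric(tab)

  chosen <- rep(NA_character_, nrow(mentions))
  for (doc in unique(mentions$doc_id)) {
    idx <- which(mentions$doc_id == doc)
    cands <- mentions$candidates[idx]
    present <- lapply(cands, function(cs) intersect(sort(cs), graph$nodes))
    if (mode == "single_pass") {
      seeds <- unique(unlist(present))
      if (length(seeds) == 0L) next
      lone <- length(idx) == 1L && all(node_deg[present[[1L]]] == 0)
      if (lone) next  # no context, no edges: nothing to rank on
      r <- personalized_pagerank(
        graph, setNames(rep(1, length(seeds)), seeds),
        damping = damping, max_iter = max_iter, tol = tol)
      for (k in seq_along(idx)) {
        cs <- present[[k]]
        if (length(cs) == 0L) next
        chosen[idx[[k]]] <- cs[[which.max(r[cs])]]
      }
    } else {
      for (k in seq_along(idx)) {
        cs <- present[[k]]
        if (length(cs) == 0L) next
        if (length(cands[[k]]) == 1L) {
          chosen[idx[[k]]] <- cands[[k]]
          next
        }
        context <- setdiff(unique(unlist(present[-k])), cands[[k]])
        if (length(context) == 0L) next
        r <- personalized_pagerank(
          graph, setNames(rep(1, length(context)), context),
          damping = damping, max_iter = max_iter, tol = tol)
        chosen[idx[[k]]] <- cs[[which.max(r[cs])]]
      }
    }
  }
  annotate_result(mentions, chosen)
}

#' Default stoplist of non-content words
#'
#' A small list of English function words shipped with the package, used to
#' restrict sentence features to content words.
#' @return character vector.
#' @export
default_stoplist <- function() {
  path <- system.file("extdata", "stoplist.txt", package = "abclbd")
  readLines(path, warn = FALSE)
}

#' Extract a context feature vector for a mention
#'
#' Features are the lemmas of the content words (non-stopword tokens) of the
#' sentence containing the mention, plus the lemmas of all tokens (stopwords
#' included) within a window of `window` tokens either side of the mention.
#' The mention's own tokens are excluded; counts from the two sources
#' accumulate. Sentences are delimited by periods in the raw field text;
#' all tokenization happens over normalized text.
#'
#' @param doc single-row corpus data.frame.
#' @param mention single-row mention data.frame (offsets over the normalized
#'   field text).
#' @param window integer half-width in tokens; 0 means sentence features
#'   only.
#' @param stoplist character vector of stopwords (normalized).
#' @param lemmatizer function mapping a token vector to lemmas; the default
#'   identity keeps normalized tokens as their own lemmas.
#' @return named numeric count vector (possibly empty).
#' @export
extract_features <- function(doc, mention, window = 4L,
                             stoplist = default_stoplist(),
                             lemmatizer = identity) {
  field <- mention$field %||% "title"
  if (is.data.frame(mention)) field <- mention$field[[1L]]
  raw <- doc[[field]]
  if (is.data.frame(doc)) raw <- doc[[field]][[1L]]
  norm <- normalize_text(raw)
  m_start <- mention$start[[1L]]; m_end <- mention$end[[1L]]

  tokens <- strsplit(norm, " ", fixed = TRUE)[[1L]]
  tok_start <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
  tok_end <- tok_start + nchar(tokens)
  in_mention <- tok_start >= m_start & tok_end <= m_end

  # sentence spans over normalized text: normalize() of a period-split piece
  # concatenates (space-joined) back to the normalized full text
  pieces <- normalize_text(strsplit(raw, ".", fixed = TRUE)[[1L]])
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L) pieces <- norm
  s_start <- c(0L, cumsum(nchar(pieces) + 1L))[seq_along(pieces)]
  s_end <- s_start + nchar(pieces)
  sent <- which(s_start <= m_start & m_start < s_end)[1]
  if (is.na(sent)) sent <- 1L

  in_sentence <- tok_start >= s_start[[sent]] & tok_end <= s_end[[sent]]
  sent_feats <- tokens[in_sentence & !in_mention &
                         !(tokens %in% stoplist)]

  m_tokens <- which(in_mention)
  win_feats <- character()
  if (window > 0L && length(m_tokens) > 0L) {
    lo <- max(1L, min(m_tokens) - window)
    hi <- min(length(tokens), max(m_tokens) + window)
    keep <- setdiff(seq.int(lo, hi), m_tokens)
    win_feats <- tokens[keep]
  }
  feats <- lemmatizer(c(sent_feats, win_feats))
  if (length(feats) == 0L) return(stats::setNames(numeric(), character()))
  tab <- table(feats)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Train sense centroid vectors
#'
#' The centroid of a sense is the arithmetic mean of the feature vectors of
#' its training instances.
#'
#' @param features list of named numeric feature vectors.
#' @param labels character vector of concept labels, one per instance.
#' @return object of class `sense_centroids`: named list cui -> list
#'   `(vector, support)`.
#' @export
train_centroids <- function(features, labels) {
  stopifnot(length(features) == length(labels))
  if (length(features) == 0L) stop("empty training set", call. = FALSE)
  out <- lapply(split(features, labels), function(inst) {
    all_names <- unique(unlist(lapply(inst, names)))
    acc <- stats::setNames(numeric(length(all_names)), all_names)
    for (v in inst) acc[names(v)] <- acc[names(v)] + v
    list(vector = acc / length(inst), support = length(inst))
  })
  structure(out, class = "sense_centroids")
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  shared <- intersect(names(x), names(y))
  if (length(shared) == 0L) return(0)
  sum(x[shared] * y[shared]) / (nx * ny)
}

#' Disambiguate by sense-centroid vector space model
#'
#' Each mention's context feature vector is compared by cosine similarity
#' against the centroid of every candidate sense that has one; the most
#' similar candidate wins, ties going to the lexicographically smallest CUI.
#' A mention abstains when its feature vector is empty/zero or when no
#' candidate has a trained centroid.
#'
#' @param mentions mention data.frame.
#' @param centroids a [train_centroids()] result.
#' @param corpus corpus data.frame (source of the context text).
#' @param window,stoplist,lemmatizer passed to [extract_features()].
#' @return annotation data.frame.
#' @export
disambiguate_vsm <- function(mentions, centroids, corpus, window = 4L,
                             stoplist = default_stoplist(),
                             lemmatizer = identity) {
  doc_idx <- match(mentions$doc_id, corpus$doc_id)
  chosen <- rep(NA_character_, nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    fv <- extract_features(corpus[doc_idx[[i]], , drop = FALSE],
                           mentions[i, , drop = FALSE], window = window,
                           stoplist = stoplist, lemmatizer = lemmatizer)
    if (length(fv) == 0L || all(fv == 0)) next
    cand <- sort(mentions$candidates[[i]])
    cand <- cand[cand %in% names(centroids)]
    if (length(cand) == 0L) next
    sims <- vapply(cand, function(cui)
      cosine_sim(fv, centroids[[cui]]$vector), numeric(1L))
    if (all(is.na(sims))) next
    chosen[[i]] <- cand[[which.max(sims)]]
  }
  annotate_result(mentions, chosen)
}

#' Harvest pseudo-labeled training data from monosemous relatives
#'
#' Every mention of a monosemous term whose single concept is also a
#' candidate sense of some ambiguous term yields a training instance for
#' that concept: the unambiguous occurrence stands in for an annotated
#' occurrence of the ambiguous term. Ambiguous mentions contribute nothing.
#'
#' @param corpus corpus data.frame.
#' @param inventory a [sense_inventory()].
#' @param window,stoplist,lemmatizer passed to [extract_features()].
#' @param field document field to mine.
#' @return list with `features` (list of named numeric vectors) and
#'   `labels` (character), suitable for [train_centroids()].
#' @export
generate_pseudo_labels <- function(corpus, inventory, window = 4L,
                                   stoplist = default_stoplist(),
                                   lemmatizer = identity, field = "title") {
  amb_senses <- unique(unlist(inventory$terms[ambiguous_terms(inventory)]))
  mentions <- match_corpus(corpus, inventory, field = field)
  keep <- lengths(mentions$candidates) == 1L &
    vapply(mentions$candidates, `[[`, "", 1L) %in% amb_senses
  mentions <- mentions[keep, , drop = FALSE]
  doc_idx <- match(mentions$doc_id, corpus$doc_id)
  features <- lapply(seq_len(nrow(mentions)), function(i)
    extract_features(corpus[doc_idx[[i]], , drop = FALSE],
                     mentions[i, , drop = FALSE], window = window,
                     stoplist = stoplist, lemmatizer = lemmatizer))
  labels <- vapply(mentions$candidates, `[[`, "", 1L)
  nonempty <- lengths(features) > 0L
  list(features = features[nonempty], labels = labels[nonempty])
}
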