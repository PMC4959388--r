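# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (dense algebra, triple loops, direct
# set arithmetic) and never call the code paths they check.

# small hand inventory used across corpus/wsd tests
annotate_result_for_test <- function(mentions, chosen) {
  out <- mentions
  out$chosen <- chosen
  out
}

tiny_inventory <- function() {
  sense_inventory(
    term = c("cold", "cold", "common cold", "fever", "Raynaud's Disease"),
    cui = c("C0009443", "C0024117", "C0009443", "C0015967", "C0034734"),
    description = c("common cold", "chronic obstructive lung disease",
                    "common cold", "fever", "raynaud disease"))
}

# a small fully-specified world for pipeline tests (fast to generate)
small_world <- function(seed = 11L, ...) {
  generate_world(world_config(n_docs_pre = 200L, n_docs_post = 100L,
                              seed = seed, ...))
}

# mentions frame built directly (bypasses match_terms) for backend tests
make_mentions <- function(candidates, doc_id = NULL, year = 2000L) {
  n <- length(candidates)
  if (is.null(doc_id)) doc_id <- sprintf("d%d", seq_len(n))
  df <- data.frame(doc_id = doc_id, year = year, field = "title",
                   start = 0L, end = 1L, surface = sprintf("t%d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$candidates <- candidates
  df
}

gold_for_mentions <- function(mentions, gold_cui) {
  data.frame(instance_id = sprintf("i%d", seq_len(nrow(mentions))),
             doc_id = mentions$doc_id, start = mentions$start,
             end = mentions$end, term = mentions$surface,
             gold_cui = gold_cui, stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# dense linear solve of the personalized PageRank fixed point:
# (I - d*M - d*p*t(dangling)) r = (1-d) p
ppr_dense_solve <- function(graph, personalization, damping = 0.85) {
  nodes <- graph$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges$cui1[[k]]; b <- graph$edges$cui2[[k]]
    w <- graph$edges$weight[[k]]
    W[a, b] <- W[a, b] + w
    W[b, a] <- W[b, a] + w
  }
  out_w <- colSums(W)
  M <- sweep(W, 2L, pmax(out_w, 1), "/")
  M[, out_w == 0] <- 0
  p <- numeric(n); names(p) <- nodes
  p[names(personalization)] <- personalization
  p <- p / sum(p)
  dang <- as.numeric(out_w == 0)
  A <- diag(n) - damping * M - damping * outer(p, dang)
  r <- solve(A, (1 - damping) * p)
  stats::setNames(as.numeric(r), nodes)
}

# naive dense matrix square
naive_square <- function(A) {
  M <- as.matrix(A$counts)
  n <- nrow(M)
  B <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    B[i, j] <- sum(M[i, ] * M[, j])
  }
  B
}

# entrywise hidden-knowledge definition on dense matrices
naive_hidden <- function(A) {
  M <- as.matrix(A$counts)
  B <- naive_square(A)
  cn <- A$concepts
  rows <- list()
  for (i in seq_along(cn)) for (j in seq_along(cn)) {
    if (i < j && B[i, j] > 0 && M[i, j] == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        cui_a = cn[[i]], cui_b = cn[[j]], score = B[i, j],
        link_count = sum(M[i, ] > 0 & M[, j] > 0), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(cui_a = character(), cui_b = character(),
                      score = numeric(), link_count = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cui_a, out$cui_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random annotated corpus over n_concepts concepts (for brute-force checks)
random_annotations <- function(n_docs, n_concepts, seed,
                               year = 2000L) {
  withr::with_seed(seed, {
    cuis <- sprintf("C%04d", seq_len(n_concepts))
    rows <- lapply(seq_len(n_docs), function(d) {
      k <- sample(1:4, 1L)
      chosen <- sample(cuis, k, replace = TRUE)
      data.frame(doc_id = sprintf("d%03d", d), year = year, field = "title",
                 start = seq_len(k), end = seq_len(k) + 1L,
                 surface = "x", chosen = chosen, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$candidates <- as.list(out$chosen)
    out
  })
}

# brute-force co-occurrence matrix: per-document unordered pair enumeration
naive_build_matrix <- function(annotations, year_range) {
  ann <- annotations[!is.na(annotations$chosen) &
                       annotations$year >= year_range[[1L]] &
                       annotations$year <= year_range[[2L]], , drop = FALSE]
  concepts <- sort(unique(ann$chosen))
  M <- matrix(0, length(concepts), length(concepts),
              dimnames = list(concepts, concepts))
  for (d in unique(ann$doc_id)) {
    cuis <- unique(ann$chosen[ann$doc_id == d])
    if (length(cuis) < 2L) next
    for (i in seq_along(cuis)) for (j in seq_along(cuis)) {
      if (i != j) M[cuis[[i]], cuis[[j]]] <- M[cuis[[i]], cuis[[j]]] + 1
    }
  }
  M
}

pair_keys <- function(df) paste(df$cui_a, df$cui_b)
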