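# A-B-C engine: concept co-occurrence matrix over titles, semantic-type
# filtering, matrix squaring and hidden-knowledge extraction.
#
# The co-occurrence matrix A has a_ij = number of documents whose titles
# contain both concept i and concept j (binary per document by default).
# Non-zero entries of A are direct knowledge; non-zero entries of A^2 that
# are zero in A are hidden knowledge: pairs connected only through some
# intermediate linking concept.

#' Filter concepts by semantic type
#'
#' A concept is removed iff it carries at least one semantic type and all of
#' its types are in the excluded set. Concepts with no recorded type are
#' retained: absence of typing information is not evidence of
#' uninformativeness.
#'
#' @param cuis character vector of concept identifiers.
#' @param type_map data.frame with columns `cui`, `semantic_type` (a concept
#'   may have several rows), or NULL to skip filtering.
#' @param excluded_types character vector of semantic-type labels to drop.
#' @return the retained subset of `cuis`, original order preserved.
#' @export
filter_concepts <- function(cuis, type_map = NULL,
                            excluded_types = character()) {
  if (is.null(type_map) || length(excluded_types) == 0L) return(cuis)
  types <- split(type_map$semantic_type, type_map$cui)
  drop <- vapply(cuis, function(cui) {
    t <- types[[cui]]
    length(t) > 0L && all(t %in% excluded_types)
  }, logical(1L))
  cuis[!drop]
}

#' Build the concept co-occurrence matrix from annotated titles
#'
#' Concepts failing the semantic-type filter are dropped first. For every
#' document whose year falls in `year_range`, each unordered pair of
#' distinct concepts assigned in its title increments the corresponding
#' matrix cell. Abstentions contribute nothing. By default a pair counts
#' once per document regardless of how many mention pairs realize it;
#' `counting = "mention"` instead adds the number of mention pairs.
#'
#' @param annotations annotation data.frame (mentions plus `chosen`).
#' @param type_map,excluded_types see [filter_concepts()].
#' @param year_range two integers, inclusive; only documents in this span
#'   contribute.
#' @param counting `"document"` (default) or `"mention"`.
#' @return object of class `cooc_matrix`: list with `concepts` (sorted cui
#'   index) and `counts` (sparse symmetric `dgCMatrix` with zero diagonal).
#' @export
build_matrix <- function(annotations, type_map = NULL,
                         excluded_types = character(), year_range,
                         counting = c("document", "mention")) {
  counting <- match.arg(counting)
  if (missing(year_range) || length(year_range) != 2L ||
      anyNA(year_range) || year_range[[1L]] > year_range[[2L]]) {
    stop("empty or invalid year_range", call. = FALSE)
  }
  ann <- annotations[!is.na(annotations$chosen) &
                       annotations$year >= year_range[[1L]] &
                       annotations$year <= year_range[[2L]], , drop = FALSE]
  retained <- filter_concepts(sort(unique(ann$chosen)), type_map,
                              excluded_types)
  ann <- ann[ann$chosen %in% retained, , drop = FALSE]
  concepts <- sort(unique(ann$chosen))
  n <- length(concepts)
  ii <- integer(); jj <- integer(); xx <- numeric()
  if (nrow(ann) > 0L) {
    by_doc <- split(match(ann$chosen, concepts), ann$doc_id)
    for (ids in by_doc) {
      if (counting == "document") {
        ids <- unique(ids)
        if (length(ids) < 2L) next
        prs <- utils::combn(sort(ids), 2L)
        ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
        xx <- c(xx, rep(1, ncol(prs)))
      } else {
        cnt <- table(ids)
        u <- sort(as.integer(names(cnt)))
        if (length(u) < 2L) next
        prs <- utils::combn(u, 2L)
        ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
        xx <- c(xx, as.numeric(cnt[as.character(prs[1L, ])]) *
                  as.numeric(cnt[as.character(prs[2L, ])]))
      }
    }
  }
  counts <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                                 dims = c(n, n),
                                 dimnames = list(concepts, concepts))
  structure(list(concepts = concepts,
                 counts = methods::as(counts, "CsparseMatrix")),
            class = "cooc_matrix")
}

#' Wrap an existing symmetric count matrix as a `cooc_matrix`
#'
#' Mainly useful for tests and for loading persisted matrices; enforces
#' symmetry and a zero diagonal.
#' @param counts square matrix (dense or sparse) with concept dimnames.
#' @export
as_cooc_matrix <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    stop("count matrix needs concept dimnames", call. = FALSE)
  }
  if (!Matrix::isSymmetric(counts)) stop("matrix not symmetric",
                                         call. = FALSE)
  Matrix::diag(counts) <- 0
  counts <- Matrix::drop0(counts)
  structure(list(concepts = rownames(counts), counts = counts),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("cooc_matrix: %d concepts, %d nonzero cells\n",
              length(x$concepts), Matrix::nnzero(x$counts)))
  invisible(x)
}

#' Square a co-occurrence matrix
#'
#' `B = A %*% A`; `B[i, j]` counts (with multiplicity) the length-2 paths
#' between concepts i and j, i.e. their indirect connections through any
#' single linking concept. The diagonal of A is forced to zero first so that
#' self co-occurrence cannot contaminate the path counts.
#'
#' @param A a [build_matrix()] result.
#' @return sparse matrix `B` over the same concept index; `A` is unmodified.
#' @export
square_matrix <- function(A) {
  counts <- A$counts
  Matrix::diag(counts) <- 0
  methods::as(counts %*% counts, "CsparseMatrix")
}

#' Extract hidden knowledge from A and A-squared
#'
#' Emits every unordered concept pair that is indirectly connected
#' (`B[i, j] > 0`) but never directly co-occurs (`A[i, j] == 0`). The score
#' is the path weight `B[i, j]`; `link_count` is the number of distinct
#' linking concepts k with `A[i, k] > 0` and `A[k, j] > 0`.
#'
#' @param A a [build_matrix()] result.
#' @param B its square, recomputed when not supplied.
#' @return data.frame `cui_a < cui_b`, `score`, `link_count`, sorted
#'   lexicographically.
#' @export
hidden_knowledge <- function(A, B = square_matrix(A)) {
  counts <- A$counts
  Matrix::diag(counts) <- 0
  P <- Matrix::drop0(counts)                   # boolean adjacency
  P@x[] <- 1
  L <- methods::as(P %*% P, "CsparseMatrix")   # distinct-linker counts
  Bt <- methods::as(B, "TsparseMatrix")
  keep <- Bt@i < Bt@j & Bt@x > 0
  i <- Bt@i[keep] + 1L; j <- Bt@j[keep] + 1L; x <- Bt@x[keep]
  direct <- counts[cbind(i, j)] > 0
  i <- i[!direct]; j <- j[!direct]; x <- x[!direct]
  out <- data.frame(cui_a = A$concepts[i], cui_b = A$concepts[j],
                    score = x,
                    link_count = as.numeric(L[cbind(i, j)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cui_a, out$cui_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Open discovery from a source concept
#'
#' All hidden-knowledge pairs involving `source_cui`, ranked by score
#' (descending), ties broken by the partner CUI (ascending).
#'
#' @param A a [build_matrix()] result.
#' @param source_cui the A-term to start from; must be in the concept index.
#' @param top_n truncate to this many pairs; 0 keeps all.
#' @return data.frame like [hidden_knowledge()] output.
#' @export
open_discovery <- function(A, source_cui, top_n = 0L) {
  if (!source_cui %in% A$concepts) {
    stop("unknown source concept: ", source_cui, call. = FALSE)
  }
  hk <- hidden_knowledge(A)
  hk <- hk[hk$cui_a == source_cui | hk$cui_b == source_cui, , drop = FALSE]
  partner <- ifelse(hk$cui_a == source_cui, hk$cui_b, hk$cui_a)
  hk <- hk[order(-hk$score, partner), , drop = FALSE]
  if (top_n > 0L) hk <- utils::head(hk, top_n)
  rownames(hk) <- NULL
  hk
}

#' Persist a co-occurrence matrix (MatrixMarket + concept index sidecar)
#'
#' @param A a [build_matrix()] result.
#' @param mtx_path path for the MatrixMarket coordinate file.
#' @param index_path path for the sidecar text file (row number -> cui).
#' @export
write_cooc_matrix <- function(A, mtx_path, index_path) {
  Matrix::writeMM(A$counts, mtx_path)
  writeLines(A$concepts, index_path)
  invisible(mtx_path)
}

#' Read a co-occurrence matrix written by [write_cooc_matrix()]
#' @param mtx_path,index_path paths used at write time.
#' @return a `cooc_matrix`.
#' @export
read_cooc_matrix <- function(mtx_path, index_path) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  concepts <- readLines(index_path, warn = FALSE)
  dimnames(counts) <- list(concepts, concepts)
  as_cooc_matrix(counts)
}

#' Write hidden knowledge as TSV (cui_a, cui_b, score, link_count)
#' @param hidden a [hidden_knowledge()] result.
#' @param path output path.
#' @export
write_hidden <- function(hidden, path) write_tsv(hidden, path)

#' Read hidden knowledge written by [write_hidden()]
#' @param path file path.
#' @export
read_hidden <- function(path) {
  df <- read_tsv_strict(path, c("cui_a", "cui_b", "score", "link_count"))
  df$score <- as.numeric(df$score)
  df$link_count <- as.numeric(df$link_count)
  df
}
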