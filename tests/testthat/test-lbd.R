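# A-B-C engine: matrix construction, filtering, squaring, hidden knowledge

ann_from_titles <- function(titles, years = NULL) {
  # titles: list of character vectors of concept ids, one per document
  if (is.null(years)) years <- rep(2000L, length(titles))
  rows <- lapply(seq_along(titles), function(d) {
    k <- length(titles[[d]])
    data.frame(doc_id = sprintf("d%d", d), year = years[[d]], field = "title",
               start = seq_len(k), end = seq_len(k) + 1L, surface = "x",
               chosen = titles[[d]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$candidates <- as.list(out$chosen)
  out
}

test_that("build_matrix counts documents, not mention pairs, by default", {
  ann <- ann_from_titles(list(c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  expect_identical(A$concepts, c("c1", "c2", "c3"))
  expect_equal(A$counts["c1", "c2"], 1)
  expect_equal(A$counts["c2", "c3"], 1)
  expect_equal(A$counts["c1", "c3"], 0)

  ann <- ann_from_titles(list(c("c1", "c2"), c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  expect_equal(A$counts["c1", "c2"], 2)
  expect_equal(A$counts["c2", "c3"], 1)

  # repeated mentions in one title count once per document...
  ann <- ann_from_titles(list(c("c1", "c1", "c2")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  expect_equal(A$counts["c1", "c2"], 1)
  # ...unless mention-level counting is requested
  A <- build_matrix(ann, year_range = c(2000L, 2000L), counting = "mention")
  expect_equal(A$counts["c1", "c2"], 2)

  # abstentions and out-of-range years contribute nothing
  ann <- ann_from_titles(list(c("c1", "c2", "c4"), c("c1", "c3")),
                         years = c(2000L, 2005L))
  ann$chosen[ann$chosen == "c4"] <- NA_character_  # abstention
  A <- build_matrix(ann, year_range = c(2000L, 2001L))
  expect_equal(A$counts["c1", "c2"], 1)
  expect_false("c3" %in% A$concepts)
  expect_false("c4" %in% A$concepts)

  expect_error(build_matrix(ann, year_range = c(2005L, 2000L)), "year_range")
})

test_that("build_matrix equals brute-force pair enumeration on random corpora", {
  for (seed in 1:20) {
    ann <- random_annotations(n_docs = 15L, n_concepts = 8L, seed = seed)
    A <- build_matrix(ann, year_range = c(2000L, 2000L))
    ref <- naive_build_matrix(ann, c(2000L, 2000L))
    expect_equal(as.matrix(A$counts), ref, ignore_attr = FALSE)
    # permutation invariance: shuffled document order gives the same matrix
    perm <- withr::with_seed(seed + 100L,
                             ann[sample(nrow(ann)), , drop = FALSE])
    A2 <- build_matrix(perm, year_range = c(2000L, 2000L))
    expect_equal(A$counts, A2$counts)
    # structural invariants
    expect_true(Matrix::isSymmetric(A$counts))
    expect_true(all(Matrix::diag(A$counts) == 0))
    expect_true(all(A$counts@x <= length(unique(ann$doc_id))))
  }
})

test_that("filter_concepts removes a concept only when all types are excluded", {
  type_map <- data.frame(
    cui = c("g1", "g2", "g2"),
    semantic_type = c("geographical location", "disease",
                      "geographical location"), stringsAsFactors = FALSE)
  excl <- "geographical location"
  expect_identical(filter_concepts(c("g1", "g2", "g3"), type_map, excl),
                   c("g2", "g3"))  # g2 keeps its disease type; g3 untyped
  expect_identical(filter_concepts(c("g1", "g2"), type_map, character()),
                   c("g1", "g2"))
})

test_that("square_matrix matches hand products and the naive oracle", {
  ann <- ann_from_titles(list(c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  B <- square_matrix(A)
  expect_equal(B["c1", "c3"], 1)
  expect_equal(B["c1", "c1"], 1)
  expect_equal(B["c2", "c2"], 2)

  ann <- ann_from_titles(list(c("c1", "c2"), c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  expect_equal(square_matrix(A)["c1", "c3"], 2)

  Z <- as_cooc_matrix(Matrix::Matrix(0, 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))))
  expect_equal(sum(square_matrix(Z)), 0)

  for (seed in 1:10) {
    ann <- random_annotations(12L, 7L, seed)
    A <- build_matrix(ann, year_range = c(2000L, 2000L))
    expect_equal(as.matrix(square_matrix(A)), naive_square(A))
  }
})

test_that("hidden_knowledge equals the entrywise definition", {
  ann <- ann_from_titles(list(c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  hk <- hidden_knowledge(A)
  expect_identical(hk$cui_a, "c1")
  expect_identical(hk$cui_b, "c3")
  expect_equal(hk$score, 1)
  expect_equal(hk$link_count, 1)

  # complete 3-clique: everything direct, nothing hidden
  ann <- ann_from_titles(list(c("c1", "c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  expect_identical(nrow(hidden_knowledge(A)), 0L)

  for (seed in 1:20) {
    ann <- random_annotations(20L, sample(4:12, 1L), seed + 300L)
    A <- build_matrix(ann, year_range = c(2000L, 2000L))
    hk <- hidden_knowledge(A)
    expect_equal(hk, naive_hidden(A))
    # disjointness: hidden pairs are never direct pairs
    if (nrow(hk) > 0L) {
      expect_true(all(A$counts[cbind(hk$cui_a, hk$cui_b)] == 0))
    }
  }
})

test_that("open_discovery filters and ranks consistently with hidden_knowledge", {
  ann <- ann_from_titles(list(c("c1", "c2"), c("c2", "c3")))
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  od <- open_discovery(A, "c1")
  expect_identical(od$cui_b, "c3")
  expect_identical(nrow(open_discovery(A, "c2")), 0L)
  expect_error(open_discovery(A, "nope"), "unknown source")

  ann <- random_annotations(25L, 10L, 77L)
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  hk <- hidden_knowledge(A)
  src <- A$concepts[[1L]]
  od <- open_discovery(A, src)
  ref <- hk[hk$cui_a == src | hk$cui_b == src, , drop = FALSE]
  expect_setequal(pair_keys(od), pair_keys(ref))
  expect_true(all(diff(od$score) <= 0))
  if (nrow(od) > 1L) {
    od3 <- open_discovery(A, src, top_n = 1L)
    expect_identical(nrow(od3), 1L)
    expect_equal(od3$score, max(od$score))
  }
})

test_that("co-occurrence matrices round-trip through MatrixMarket", {
  ann <- random_annotations(15L, 8L, 5L)
  A <- build_matrix(ann, year_range = c(2000L, 2000L))
  mtx <- withr::local_tempfile(fileext = ".mtx")
  idx <- withr::local_tempfile(fileext = ".txt")
  write_cooc_matrix(A, mtx, idx)
  back <- read_cooc_matrix(mtx, idx)
  expect_identical(back$concepts, A$concepts)
  expect_equal(as.matrix(back$counts), as.matrix(A$counts))
})
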