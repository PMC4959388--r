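# WSD backends: random, oracle, PPR, VSM, pseudo-labeling

test_that("random backend is uniform over candidates and reproducible", {
  m <- make_mentions(list("C1", c("C1", "C2"), c("C1", "C2", "C3")))
  a1 <- disambiguate_random(m, seed = 7L)
  a2 <- disambiguate_random(m, seed = 7L)
  expect_identical(a1$chosen, a2$chosen)
  expect_identical(a1$chosen[[1]], "C1")  # monosemous: forced
  # binomial oracle: 2,000 two-way mentions, agreement with "gold" = C1
  m2 <- make_mentions(rep(list(c("C1", "C2")), 2000L))
  acc <- mean(disambiguate_random(m2, seed = 1L)$chosen == "C1")
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("oracle backend hits its target accuracy and handles extremes", {
  m <- make_mentions(rep(list(c("C1", "C2")), 500L))
  gold <- gold_for_mentions(m, rep("C1", 500L))
  expect_identical(disambiguate_oracle(m, gold, 1.0, seed = 1L)$chosen,
                   gold$gold_cui)
  expect_true(all(disambiguate_oracle(m, gold, 0.0, seed = 1L)$chosen == "C2"))
  a <- disambiguate_oracle(m, gold, 0.7, seed = 5L)
  expect_lt(abs(mean(a$chosen == "C1") - 0.7), 3 * sqrt(0.7 * 0.3 / 500))
  # every chosen concept is a candidate
  expect_true(all(mapply(`%in%`, a$chosen, m$candidates)))
  # ambiguous mention without gold is an error
  expect_error(disambiguate_oracle(m, gold[-1L, ], 0.5, seed = 1L),
               "without gold")
})

test_that("first-sense backend collapses every term onto one concept", {
  m <- make_mentions(list(c("C2", "C1"), c("C3", "C2"), "C9"))
  expect_identical(disambiguate_first_sense(m)$chosen, c("C1", "C2", "C9"))
})

test_that("personalized_pagerank matches closed forms", {
  g2 <- concept_graph("a", "b")
  r <- personalized_pagerank(g2, c(a = 1), max_iter = 200L)
  expect_equal(unname(r["a"]), 0.15 / (1 - 0.85^2), tolerance = 1e-8)
  expect_equal(unname(r["b"]), 1 - 0.15 / (1 - 0.85^2), tolerance = 1e-8)

  tri <- concept_graph(c("a", "b", "c"), c("b", "c", "a"))
  r <- personalized_pagerank(tri, c(a = 1, b = 1, c = 1), max_iter = 200L)
  expect_equal(unname(r), rep(1 / 3, 3L), tolerance = 1e-9)

  # damping 0: rank equals the personalization for any graph
  r <- personalized_pagerank(tri, c(a = 0.7, b = 0.3), damping = 0)
  expect_equal(unname(r[c("a", "b", "c")]), c(0.7, 0.3, 0), tolerance = 1e-12)

  expect_error(personalized_pagerank(tri, numeric()), "empty personalization")
  expect_error(personalized_pagerank(tri, c(zz = 1)), "absent from graph")
})

test_that("personalized_pagerank agrees with a dense linear solve", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(3:10, 1L)
      nodes <- sprintf("n%02d", seq_len(n))
      n_edges <- sample(seq_len(n * (n - 1) / 2), 1L)
      all_pairs <- utils::combn(nodes, 2L)
      pick <- sample(ncol(all_pairs), n_edges)
      g <- concept_graph(all_pairs[1L, pick], all_pairs[2L, pick],
                         weight = sample(1:3, n_edges, replace = TRUE),
                         nodes = nodes)
      k <- sample(seq_len(n), sample(seq_len(n), 1L))
      p <- stats::setNames(stats::runif(length(k), 0.1, 1), nodes[k])
      r <- personalized_pagerank(g, p, max_iter = 5000L, tol = 1e-13)
      expect_equal(sum(r), 1, tolerance = 1e-8)
      r_ref <- ppr_dense_solve(g, p)
      expect_equal(r[names(r_ref)], r_ref, tolerance = 1e-6)
    }
  })
})

test_that("disambiguate_ppr follows context, ties and abstention rules", {
  # one ambiguous mention {s1, s2} with monosemous context m; edge m--s1
  g <- concept_graph(c("m"), c("s1"), nodes = c("m", "s1", "s2"))
  mentions <- make_mentions(list(c("s1", "s2"), "m"), doc_id = c("d1", "d1"))
  ann <- disambiguate_ppr(mentions, g)
  expect_identical(ann$chosen[[1]], "s1")
  # brute-force check on the same 3-node graph
  r <- ppr_dense_solve(g, c(s1 = 1, s2 = 1, m = 1))
  expect_gt(r["s1"], r["s2"])

  # graph-isolated tied candidates with context present: lexicographic rule
  g2 <- concept_graph("m", "x", nodes = c("m", "x", "s8", "s3"))
  mentions <- make_mentions(list(c("s8", "s3"), "m"), doc_id = c("d1", "d1"))
  expect_identical(disambiguate_ppr(mentions, g2)$chosen[[1]], "s3")

  # lone mention with edgeless candidates: abstain
  mentions <- make_mentions(list(c("s8", "s3")), doc_id = "d1")
  expect_true(is.na(disambiguate_ppr(mentions, g2)$chosen[[1]]))

  # candidates entirely absent from the graph: abstain
  mentions <- make_mentions(list(c("q1", "q2"), "m"), doc_id = c("d1", "d1"))
  expect_true(is.na(disambiguate_ppr(mentions, g2)$chosen[[1]]))

  # per-target mode excludes the target's own senses from the teleport set
  ann <- disambiguate_ppr(make_mentions(list(c("s1", "s2"), "m"),
                                        doc_id = c("d1", "d1")),
                          g, mode = "per_target")
  expect_identical(ann$chosen[[1]], "s1")
  # per-target with no context: abstain
  ann <- disambiguate_ppr(make_mentions(list(c("s1", "s2")), doc_id = "d1"),
                          g, mode = "per_target")
  expect_true(is.na(ann$chosen[[1]]))
})

test_that("every backend returns a candidate or abstains on random worlds", {
  world <- small_world(seed = 23L)
  corpus <- utils::head(world$corpus, 60L)
  mentions <- match_corpus(corpus, world$inventory)
  gold <- world$gold
  backends <- list(
    disambiguate_random(mentions, 1L),
    disambiguate_first_sense(mentions),
    disambiguate_oracle(mentions, gold, 0.5, 2L),
    disambiguate_ppr(mentions, world$graph))
  for (ann in backends) {
    ok <- mapply(function(ch, cand) is.na(ch) || ch %in% cand,
                 ann$chosen, ann$candidates)
    expect_true(all(ok))
  }
})

test_that("extract_features implements the sentence + window rule", {
  doc <- data.frame(doc_id = "d1", title = "cold causes fever", year = 2000L,
                    stringsAsFactors = FALSE)
  mention <- match_terms(doc, tiny_inventory())[1L, , drop = FALSE]
  expect_identical(mention$surface, "cold")
  fv <- extract_features(doc, mention, window = 4L, stoplist = "causes")
  expect_identical(fv[order(names(fv))], c(causes = 1, fever = 2))
  # window 0: sentence content words only
  fv0 <- extract_features(doc, mention, window = 0L, stoplist = "causes")
  expect_identical(fv0, c(fever = 1))
  # mention spanning the whole title: empty vector
  doc2 <- data.frame(doc_id = "d2", title = "common cold", year = 2000L,
                     stringsAsFactors = FALSE)
  m2 <- match_terms(doc2, tiny_inventory())
  expect_length(extract_features(doc2, m2, window = 4L), 0L)
  # sentence boundary: features from the mention's sentence only
  doc3 <- data.frame(doc_id = "d3", title = "cold hurts. fever elsewhere",
                     year = 2000L, stringsAsFactors = FALSE)
  m3 <- match_terms(doc3, tiny_inventory())[1L, , drop = FALSE]
  fv3 <- extract_features(doc3, m3, window = 0L, stoplist = character())
  expect_identical(names(fv3), "hurts")
})

test_that("train_centroids averages instance vectors", {
  ce <- train_centroids(list(c(a = 1), c(a = 3)), c("C1", "C1"))
  expect_equal(ce$C1$vector, c(a = 2))
  expect_identical(ce$C1$support, 2L)
  expect_error(train_centroids(list(), character()), "empty training")
  # brute-force mean oracle on random instances
  withr::with_seed(9, {
    feats <- lapply(1:20, function(i) {
      k <- sample(1:4, 1L)
      stats::setNames(stats::runif(k), sample(letters[1:6], k))
    })
    labels <- sample(c("C1", "C2"), 20L, replace = TRUE)
    ce <- train_centroids(feats, labels)
    for (lab in c("C1", "C2")) {
      inst <- feats[labels == lab]
      ref <- stats::setNames(numeric(6), letters[1:6])
      for (v in inst) ref[names(v)] <- ref[names(v)] + v
      ref <- ref / length(inst)
      got <- stats::setNames(numeric(6), letters[1:6])
      got[names(ce[[lab]]$vector)] <- ce[[lab]]$vector
      expect_equal(got, ref)
    }
  })
})

test_that("disambiguate_vsm ranks by cosine with stated degenerate rules", {
  corpus <- data.frame(doc_id = "d1", title = "cold f1 f1 f2", year = 2000L,
                       stringsAsFactors = FALSE)
  inv <- sense_inventory(c("cold", "cold"), c("s1", "s2"))
  mentions <- match_corpus(corpus, inv)
  # instance vector is (f1 = 2, f2 = 1); centroids on the two axes
  ce <- train_centroids(list(c(f1 = 1), c(f2 = 1)), c("s1", "s2"))
  ann <- disambiguate_vsm(mentions, ce, corpus, window = 4L,
                          stoplist = character())
  expect_identical(ann$chosen[[1]], "s1")  # cos 0.894 beats 0.447
  # identical centroids: lexicographic tie-break
  ce2 <- train_centroids(list(c(f1 = 1, f2 = 1), c(f1 = 1, f2 = 1)),
                         c("s2", "s1"))
  ann <- disambiguate_vsm(mentions, ce2, corpus, stoplist = character())
  expect_identical(ann$chosen[[1]], "s1")
  # no candidate centroid: abstain
  ce3 <- train_centroids(list(c(f1 = 1)), "other")
  ann <- disambiguate_vsm(mentions, ce3, corpus, stoplist = character())
  expect_true(is.na(ann$chosen[[1]]))
  # empty feature vector: abstain
  corpus2 <- data.frame(doc_id = "d1", title = "cold", year = 2000L,
                        stringsAsFactors = FALSE)
  ann <- disambiguate_vsm(match_corpus(corpus2, inv), ce, corpus2,
                          stoplist = character())
  expect_true(is.na(ann$chosen[[1]]))
})

test_that("pseudo-labeling mines monosemous relatives only", {
  inv <- sense_inventory(c("cold", "cold", "common cold", "flu"),
                         c("s1", "s2", "s1", "f1"))
  corpus <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    title = c("common cold with sneezing", "cold with sneezing",
              "flu season"),
    year = 2000L, stringsAsFactors = FALSE)
  out <- generate_pseudo_labels(corpus, inv, stoplist = character())
  # only the monosemous relative of an ambiguous sense contributes:
  # "common cold" (s1) yields an instance; "cold" is ambiguous; "flu"'s
  # concept is no sense of any ambiguous term
  expect_identical(out$labels, "s1")
  expect_identical(out$features[[1]][["sneezing"]], 2)
  # corpus with no monosemous terms: empty training set
  inv2 <- sense_inventory(c("cold", "cold"), c("s1", "s2"))
  out2 <- generate_pseudo_labels(corpus, inv2)
  expect_length(out2$labels, 0L)
})

test_that("pseudo-label volume matches the generator's bookkeeping", {
  world <- small_world(seed = 31L)
  corpus <- world$corpus[world$corpus$year <= world$config$cutoff_year, ]
  out <- generate_pseudo_labels(corpus, world$inventory)
  # oracle: count monosemous mentions whose concept is an ambiguous sense
  mentions <- match_corpus(corpus, world$inventory)
  amb_senses <- unique(unlist(
    world$inventory$terms[ambiguous_terms(world$inventory)]))
  mono <- lengths(mentions$candidates) == 1L
  hits <- vapply(mentions$candidates[mono], `[[`, "", 1L) %in% amb_senses
  expect_lte(length(out$labels), sum(hits))  # empty-context instances drop
  expect_gt(length(out$labels), 0L)
  expect_true(all(out$labels %in% amb_senses))
})
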