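# Synthetic toy worlds: a complete, internally consistent set of LBD inputs
# (sense inventory, semantic types, concept relation graph, dated corpus,
# gold sense annotations) with planted A-B-C discovery triples and optional
# ambiguity confounds.
#
# The generator states a world and the tests interrogate it: planted triples
# guarantee recoverable hidden knowledge, ambiguity is realized as terms
# whose senses live in disjoint topical contexts (so context carries
# disambiguation signal), "noise" concepts typed with excluded semantic
# types attach themselves to unrelated titles (the 'geographical location'
# effect), and confound structures demonstrate how collapsing the senses of
# a linking term manufactures spurious discoveries.

#' Configuration of a synthetic LBD world
#'
#' Defaults describe the shipped default world: 200 concepts, 150 surface
#' terms of which 30 % are ambiguous (up to 3 senses each), 30 planted
#' A-B-C triples, 5 ambiguity confounds, 800 pre-cutoff and 400 post-cutoff
#' documents, half of the background titles being topically incoherent
#' distractors. Half of the semantic types are marked for exclusion,
#' mirroring the roughly half of type inventory typically judged
#' uninformative for discovery.
#'
#' @param n_concepts number of concepts (CUIs).
#' @param n_terms number of surface terms in the sense inventory.
#' @param ambiguity_rate fraction of terms with >= 2 senses.
#' @param max_senses maximum senses per ambiguous term.
#' @param n_semantic_types size of the declared semantic-type set.
#' @param excluded_type_fraction fraction of types marked for removal.
#' @param n_docs_pre,n_docs_post documents before/after the cutoff
#'   (confound documents are added on top).
#' @param cutoff_year time-slice cutoff; pre years span
#'   `[cutoff_year - 5, cutoff_year]`, post years
#'   `[cutoff_year + 1, cutoff_year + 5]`.
#' @param n_planted_triples planted A-B-C discovery triples.
#' @param n_confounds ambiguity confound structures.
#' @param distractor_rate fraction of background titles drawing concepts
#'   across topics instead of within one topic.
#' @param multiword_rate fraction of terms realized as two-token surfaces.
#' @param seed integer master seed; the world is a pure function of the
#'   config.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_concepts = 200L, n_terms = 150L,
                         ambiguity_rate = 0.3, max_senses = 3L,
                         n_semantic_types = 10L,
                         excluded_type_fraction = 0.5,
                         n_docs_pre = 800L, n_docs_post = 400L,
                         cutoff_year = 2005L, n_planted_triples = 30L,
                         n_confounds = 5L, distractor_rate = 0.5,
                         multiword_rate = 0.2, seed = 42L) {
  cfg <- list(n_concepts = as.integer(n_concepts),
              n_terms = as.integer(n_terms),
              ambiguity_rate = ambiguity_rate,
              max_senses = as.integer(max_senses),
              n_semantic_types = as.integer(n_semantic_types),
              excluded_type_fraction = excluded_type_fraction,
              n_docs_pre = as.integer(n_docs_pre),
              n_docs_post = as.integer(n_docs_post),
              cutoff_year = as.integer(cutoff_year),
              n_planted_triples = as.integer(n_planted_triples),
              n_confounds = as.integer(n_confounds),
              distractor_rate = distractor_rate,
              multiword_rate = multiword_rate,
              seed = as.integer(seed))
  counts <- cfg[c("n_concepts", "n_terms", "max_senses", "n_semantic_types",
                  "n_docs_pre", "n_docs_post")]
  if (any(unlist(counts) <= 0L)) {
    stop("world_config: all counts must be positive", call. = FALSE)
  }
  rates <- unlist(cfg[c("ambiguity_rate", "excluded_type_fraction",
                        "distractor_rate", "multiword_rate")])
  if (any(rates < 0 | rates > 1)) {
    stop("world_config: rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$max_senses < 2L) stop("world_config: max_senses must be >= 2",
                                call. = FALSE)
  structure(cfg, class = "world_config")
}

#' Generate a synthetic LBD world
#'
#' Produces a sense inventory, semantic-type map, concept relation graph,
#' dated corpus, gold sense annotations and the planted discovery truth, all
#' as a pure function of the config seed. Per planted triple (A, B, C) the
#' pre-cutoff corpus contains one title realizing (A, B) and one realizing
#' (B, C) but none realizing (A, C); the post-cutoff corpus realizes (A, C).
#' Planted B concepts are (where the term budget allows) senses of ambiguous
#' terms, so WSD errors directly disturb the discoverable paths. When
#' `n_confounds > 0` the corresponding confound structures are planted via
#' [plant_ambiguity_confound()].
#'
#' @param config a [world_config()].
#' @return object of class `lbd_world`: list with `config`, `inventory`,
#'   `type_map`, `excluded_types`, `graph`, `corpus`, `gold`, `triples`,
#'   `confounds`, `spurious_pairs` and internal bookkeeping used by the
#'   confound planter.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  world <- with_seed(config$seed, generate_world_impl(config))
  if (config$n_confounds > 0L) {
    world <- plant_ambiguity_confound(world, config$n_confounds,
                                      seed = config$seed + 1000003L)
  }
  world
}

generate_world_impl <- function(cfg) {
  n_tri <- cfg$n_planted_triples
  cuis <- sprintf("C%07d", seq_len(cfg$n_concepts))
  pool <- sample(cuis)

  # concept allocation: planted triples, confound reserve, noise, background
  need_planted <- 3L * n_tri
  need_confound <- 4L * cfg$n_confounds
  n_noise <- max(2L, round(0.05 * cfg$n_concepts))
  n_bg <- cfg$n_concepts - need_planted - need_confound - n_noise
  if (n_bg < 2L * cfg$max_senses) {
    stop(sprintf(paste0(
      "infeasible config: n_concepts = %d cannot host %d planted triples, ",
      "%d confounds, %d noise concepts and a background of at least %d"),
      cfg$n_concepts, n_tri, cfg$n_confounds, n_noise, 2L * cfg$max_senses),
      call. = FALSE)
  }
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[setdiff(seq_along(pool), seq_len(k))]
    out
  }
  planted <- take(need_planted)
  tri_a <- planted[seq_len(n_tri)]
  tri_b <- planted[n_tri + seq_len(n_tri)]
  tri_c <- planted[2L * n_tri + seq_len(n_tri)]
  free_concepts <- take(need_confound)
  noise <- take(n_noise)
  bg <- pool

  # topics over all non-noise concepts (round-robin); cliques keep node
  # degrees roughly uniform so PPR ranks senses on context, not on degree
  non_noise <- c(bg, planted, free_concepts)
  n_topics <- max(2L, cfg$max_senses, length(non_noise) %/% 8L)
  topic_of <- stats::setNames(rep(seq_len(n_topics), length.out = length(non_noise)),
                              non_noise)
  topics <- split(non_noise, topic_of)
  bg_topics <- lapply(topics, intersect, x = bg)
  sense_topics <- names(bg_topics)[lengths(bg_topics) >= 1L]

  # semantic types: excluded block first, noise concepts typed from it
  all_types <- sprintf("T%03d", seq_len(cfg$n_semantic_types))
  n_excl <- min(cfg$n_semantic_types - 1L,
                ceiling(cfg$excluded_type_fraction * cfg$n_semantic_types))
  excluded_types <- all_types[seq_len(n_excl)]
  retained_types <- setdiff(all_types, excluded_types)
  type_of <- character(cfg$n_concepts)
  names(type_of) <- cuis
  type_of[noise] <- sample(excluded_types, n_noise, replace = TRUE)
  rest <- setdiff(cuis, noise)
  type_of[rest] <- sample(retained_types, length(rest), replace = TRUE)
  type_map <- data.frame(cui = cuis, semantic_type = type_of[cuis],
                         stringsAsFactors = FALSE)

  # relation graph: topical cliques, planted A-B / B-C edges, noise hubs
  e1 <- character(); e2 <- character()
  for (tp in topics) {
    if (length(tp) >= 2L) {
      prs <- utils::combn(tp, 2L)
      e1 <- c(e1, prs[1L, ]); e2 <- c(e2, prs[2L, ])
    }
  }
  e1 <- c(e1, tri_a, tri_b); e2 <- c(e2, tri_b, tri_c)
  for (nz in noise) {
    nb <- sample(bg, min(5L, n_bg))
    e1 <- c(e1, rep(nz, length(nb))); e2 <- c(e2, nb)
  }
  dup <- e1 == e2
  graph <- concept_graph(e1[!dup], e2[!dup], nodes = cuis)

  # sense inventory -------------------------------------------------------
  n_amb <- round(cfg$ambiguity_rate * cfg$n_terms)
  n_mono <- cfg$n_terms - n_amb
  n_amb_planted <- min(n_amb, n_tri)
  n_b_mono <- n_tri - n_amb_planted          # planted B lacking an ambiguous term
  if (n_mono < 2L * n_tri + n_b_mono) {
    stop(sprintf(paste0(
      "infeasible config: %d monosemous terms cannot cover %d planted ",
      "triples (need %d)"), n_mono, n_tri, 2L * n_tri + n_b_mono),
      call. = FALSE)
  }
  surface_of <- function(idx, base) {
    multi <- stats::runif(length(idx)) < cfg$multiword_rate
    ifelse(multi, sprintf("%s%03d %s%03dx", base, idx, base, idx),
           sprintf("%s%03d", base, idx))
  }
  inv_term <- character(); inv_cui <- character()
  add_entry <- function(term, cui) {
    inv_term <<- c(inv_term, rep(term, length(cui)))
    inv_cui <<- c(inv_cui, cui)
  }
  amb_surfaces <- surface_of(seq_len(n_amb), "amb")
  bg_sense_used <- character()
  for (i in seq_len(n_amb)) {
    k <- sample(2:cfg$max_senses, 1L)
    first <- if (i <= n_amb_planted) tri_b[[i]] else NULL
    k_bg <- k - length(first)
    tps <- sample(sense_topics, k_bg)
    senses <- c(first, vapply(tps, function(t)
      bg_topics[[t]][sample.int(length(bg_topics[[t]]), 1L)], ""))
    senses <- unique(senses)
    if (length(senses) < 2L) senses <- c(senses, sample(setdiff(bg, senses), 1L))
    add_entry(amb_surfaces[[i]], senses)
    bg_sense_used <- c(bg_sense_used, setdiff(senses, tri_b))
  }
  bg_sense_used <- unique(bg_sense_used)
  mono_surfaces <- surface_of(seq_len(n_mono), "mono")
  mono_concepts <- character(n_mono)
  mono_concepts[seq_len(2L * n_tri)] <- c(tri_a, tri_c)
  if (n_b_mono > 0L) {
    mono_concepts[2L * n_tri + seq_len(n_b_mono)] <-
      tri_b[n_amb_planted + seq_len(n_b_mono)]
  }
  n_spare <- n_mono - 2L * n_tri - n_b_mono
  n_noise_terms <- min(n_noise, max(0L, n_spare - 5L))
  spare_idx <- 2L * n_tri + n_b_mono + seq_len(n_spare)
  if (n_noise_terms > 0L) {
    mono_concepts[spare_idx[seq_len(n_noise_terms)]] <- noise[seq_len(n_noise_terms)]
  }
  n_bg_mono <- n_spare - n_noise_terms
  if (n_bg_mono > 0L) {
    # half monosemous relatives of ambiguous senses, half fresh coverage
    n_rel <- min(length(bg_sense_used), n_bg_mono %/% 2L)
    rel <- if (n_rel > 0L) sample(bg_sense_used, n_rel) else character()
    fresh_pool <- setdiff(bg, bg_sense_used)
    n_fresh <- n_bg_mono - n_rel
    fresh <- if (n_fresh > 0L)
      sample(fresh_pool, min(n_fresh, length(fresh_pool))) else character()
    extra <- n_bg_mono - n_rel - length(fresh)
    if (extra > 0L) fresh <- c(fresh, sample(bg, extra, replace = TRUE))
    mono_concepts[spare_idx[n_noise_terms + seq_len(n_bg_mono)]] <- c(rel, fresh)
  }
  for (i in seq_len(n_mono)) add_entry(mono_surfaces[[i]], mono_concepts[[i]])
  descriptions <- paste("synthetic concept", inv_cui)
  inventory <- sense_inventory(inv_term, inv_cui, descriptions)

  # realization map: concept -> surface terms that can express it
  concept_terms <- split(rep(names(inventory$terms),
                             lengths(inventory$terms)),
                         unlist(inventory$terms, use.names = FALSE))
  amb_set <- names(inventory$terms)[lengths(inventory$terms) >= 2L]
  pick_term <- function(cui) {
    ts <- concept_terms[[cui]]
    if (length(ts) == 1L) return(ts)
    amb <- ts[ts %in% amb_set]
    mono <- setdiff(ts, amb)
    if (length(amb) > 0L && (length(mono) == 0L || stats::runif(1L) < 0.5)) {
      return(sample(amb, 1L))
    }
    sample(mono, 1L)
  }

  covered_bg <- intersect(bg, names(concept_terms))
  covered_topics <- lapply(bg_topics, intersect, x = covered_bg)
  usable_topics <- names(covered_topics)[lengths(covered_topics) >= 2L]
  covered_noise <- intersect(noise, names(concept_terms))

  # corpus ---------------------------------------------------------------
  pre_years <- seq(cfg$cutoff_year - 5L, cfg$cutoff_year)
  post_years <- seq(cfg$cutoff_year + 1L, cfg$cutoff_year + 5L)
  titles <- character(); years <- integer()
  gold_surface <- list(); gold_cui <- list()

  emit_doc <- function(surfaces, concepts, year) {
    ord <- sample(length(surfaces))
    titles <<- c(titles, paste(surfaces[ord], collapse = " "))
    years <<- c(years, year)
    gold_surface[[length(gold_surface) + 1L]] <<- surfaces[ord]
    gold_cui[[length(gold_cui) + 1L]] <<- concepts[ord]
  }
  emit_pair <- function(c1, c2, year) {
    emit_doc(c(pick_term(c1), pick_term(c2)), c(c1, c2), year)
  }
  background_doc <- function(year) {
    k <- sample(2:4, 1L)
    if (stats::runif(1L) < cfg$distractor_rate || length(usable_topics) == 0L) {
      concepts <- sample(covered_bg, min(k, length(covered_bg)))
    } else {
      tp <- covered_topics[[sample(usable_topics, 1L)]]
      concepts <- sample(tp, min(k, length(tp)))
    }
    if (length(covered_noise) > 0L && stats::runif(1L) < 0.15) {
      concepts <- c(concepts, sample(covered_noise, 1L))
    }
    surfaces <- vapply(concepts, pick_term, "")
    keep <- !duplicated(surfaces)
    emit_doc(surfaces[keep], concepts[keep], year)
  }

  for (i in seq_len(n_tri)) {
    b_term_surface <- if (i <= n_amb_planted) amb_surfaces[[i]] else
      pick_term(tri_b[[i]])
    emit_doc(c(pick_term(tri_a[[i]]), b_term_surface),
             c(tri_a[[i]], tri_b[[i]]), sample(pre_years, 1L))
    emit_doc(c(b_term_surface, pick_term(tri_c[[i]])),
             c(tri_b[[i]], tri_c[[i]]), sample(pre_years, 1L))
  }
  n_bg_pre <- max(0L, cfg$n_docs_pre - 2L * n_tri)
  for (i in seq_len(n_bg_pre)) background_doc(sample(pre_years, 1L))
  for (i in seq_len(n_tri)) {
    emit_pair(tri_a[[i]], tri_c[[i]], sample(post_years, 1L))
  }
  n_bg_post <- max(0L, cfg$n_docs_post - n_tri)
  for (i in seq_len(n_bg_post)) background_doc(sample(post_years, 1L))

  corpus <- data.frame(doc_id = sprintf("d%05d", seq_along(titles)),
                       title = titles, abstract = NA_character_,
                       year = years, stringsAsFactors = FALSE)
  gold <- build_gold_frame(corpus$doc_id, gold_surface, gold_cui, 0L)

  structure(list(
    config = cfg, inventory = inventory, type_map = type_map,
    excluded_types = excluded_types, graph = graph, corpus = corpus,
    gold = gold,
    triples = data.frame(cui_a = tri_a, cui_b = tri_b, cui_c = tri_c,
                         realized = TRUE, stringsAsFactors = FALSE),
    confounds = data.frame(term = character(), cui_a = character(),
                           cui_b1 = character(), cui_b2 = character(),
                           cui_c = character(), stringsAsFactors = FALSE),
    spurious_pairs = data.frame(cui_a = character(), cui_b = character(),
                                stringsAsFactors = FALSE),
    # confound reserve plus never-realized background concepts: safe hosts
    # for later confound planting (they appear in no title)
    free_concepts = c(free_concepts, setdiff(bg, names(concept_terms))),
    pre_years = pre_years), class = "lbd_world")
}

# gold rows from per-doc surface/cui vectors; spans over the space-joined
# normalized title
build_gold_frame <- function(doc_ids, surfaces, cuis, id_offset) {
  rows <- lapply(seq_along(doc_ids), function(i) {
    s <- surfaces[[i]]
    n <- length(s)
    starts <- c(0L, cumsum(nchar(s) + 1L))[seq_len(n)]
    data.frame(doc_id = doc_ids[[i]], start = starts,
               end = starts + nchar(s), term = s, gold_cui = cuis[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(instance_id = sprintf("i%06d", id_offset + seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.lbd_world <- function(x, ...) {
  cat(sprintf(paste0(
    "lbd_world: %d concepts, %d terms, %d docs (%d pre / %d post cutoff %d),\n",
    "  %d planted triples, %d confounds, %d gold sense instances\n"),
    x$config$n_concepts, length(x$inventory$terms), nrow(x$corpus),
    sum(x$corpus$year <= x$config$cutoff_year),
    sum(x$corpus$year > x$config$cutoff_year), x$config$cutoff_year,
    nrow(x$triples), nrow(x$confounds), nrow(x$gold)))
  invisible(x)
}

#' Plant ambiguity confound structures into a world
#'
#' Each confound adds a fresh ambiguous term with two senses B1 and B2 and
#' two pre-cutoff titles: one connecting a fresh concept A to sense B1, one
#' connecting sense B2 to a fresh concept C. No true A-C link exists, yet
#' any annotator that collapses the two senses of the term onto one concept
#' creates a length-2 path A - B - C and with it the spurious hidden pair
#' (A, C). The spurious pairs are recorded in `world$spurious_pairs` so
#' tests can count exactly how many an annotation produced.
#'
#' @param world an [generate_world()] result.
#' @param n_confounds number of confound structures to add.
#' @param seed integer seed.
#' @return the augmented world.
#' @export
plant_ambiguity_confound <- function(world, n_confounds, seed) {
  stopifnot(inherits(world, "lbd_world"))
  n_confounds <- as.integer(n_confounds)
  if (n_confounds == 0L) return(world)
  if (length(world$free_concepts) < 4L * n_confounds) {
    stop(sprintf(paste0(
      "insufficient free concepts for %d confounds: need %d, have %d ",
      "(raise n_concepts or lower n_confounds)"), n_confounds,
      4L * n_confounds, length(world$free_concepts)), call. = FALSE)
  }
  with_seed(seed, {
    inv <- world$inventory
    inv_term <- rep(names(inv$terms), lengths(inv$terms))
    inv_cui <- unlist(inv$terms, use.names = FALSE)
    e1 <- character(); e2 <- character()
    titles <- character(); years <- integer()
    gold_surface <- list(); gold_cui <- list()
    conf_rows <- list(); spur <- list()
    pool <- world$free_concepts
    for (j in seq_len(n_confounds)) {
      ids <- pool[seq_len(4L)]; pool <- pool[-seq_len(4L)]
      a <- ids[[1L]]; b1 <- ids[[2L]]; b2 <- ids[[3L]]; cc <- ids[[4L]]
      t_amb <- sprintf("cfd%03d", j)
      t_a <- sprintf("cfd%03da", j); t_c <- sprintf("cfd%03dc", j)
      inv_term <- c(inv_term, t_amb, t_amb, t_a, t_c)
      inv_cui <- c(inv_cui, b1, b2, a, cc)
      e1 <- c(e1, a, b2); e2 <- c(e2, b1, cc)
      for (d in list(list(s = c(t_a, t_amb), g = c(a, b1)),
                     list(s = c(t_amb, t_c), g = c(b2, cc)))) {
        ord <- sample(2L)
        titles <- c(titles, paste(d$s[ord], collapse = " "))
        years <- c(years, sample(world$pre_years, 1L))
        gold_surface[[length(gold_surface) + 1L]] <- d$s[ord]
        gold_cui[[length(gold_cui) + 1L]] <- d$g[ord]
      }
      conf_rows[[j]] <- data.frame(term = t_amb, cui_a = a, cui_b1 = b1,
                                   cui_b2 = b2, cui_c = cc,
                                   stringsAsFactors = FALSE)
      spur[[j]] <- data.frame(cui_a = min(a, cc), cui_b = max(a, cc),
                              stringsAsFactors = FALSE)
    }
    desc <- paste("synthetic concept", inv_cui)
    world$inventory <- sense_inventory(inv_term, inv_cui, desc)
    world$graph <- concept_graph(c(world$graph$edges$cui1, e1),
                                 c(world$graph$edges$cui2, e2),
                                 weight = c(world$graph$edges$weight,
                                            rep(1, length(e1))),
                                 nodes = world$graph$nodes)
    ids <- sprintf("d%05d", nrow(world$corpus) + seq_along(titles))
    world$corpus <- rbind(world$corpus, data.frame(
      doc_id = ids, title = titles, abstract = NA_character_, year = years,
      stringsAsFactors = FALSE))
    world$gold <- rbind(world$gold,
                        build_gold_frame(ids, gold_surface, gold_cui,
                                         nrow(world$gold)))
    world$confounds <- rbind(world$confounds, do.call(rbind, conf_rows))
    world$spurious_pairs <- rbind(world$spurious_pairs, do.call(rbind, spur))
    world$free_concepts <- pool
    world
  })
}

#' Write a world to disk in the formats the readers consume
#'
#' Emits `corpus.jsonl`, `inventory.tsv`, `semantic_types.tsv`,
#' `relations.tsv`, `gold.tsv` and `manifest.json` (config, excluded types,
#' planted truth, spurious confound pairs and a content hash).
#'
#' @param world an [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(world$corpus, file.path(dir, "corpus.jsonl"))
  write_sense_inventory(world$inventory, file.path(dir, "inventory.tsv"))
  write_tsv(world$type_map, file.path(dir, "semantic_types.tsv"))
  write_relations(world$graph, file.path(dir, "relations.tsv"))
  write_gold(world$gold, file.path(dir, "gold.tsv"))
  manifest <- list(
    config = unclass(world$config),
    config_hash = content_hash(jsonlite::toJSON(unclass(world$config),
                                              auto_unbox = TRUE)),
    excluded_types = world$excluded_types,
    triples = world$triples,
    confounds = world$confounds,
    spurious_pairs = world$spurious_pairs,
    counts = list(n_docs = nrow(world$corpus),
                  n_gold = nrow(world$gold),
                  n_edges = nrow(world$graph$edges)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a world directory written by [write_world()]
#' @param dir directory path.
#' @return list with `corpus`, `inventory`, `type_map`, `graph`, `gold`,
#'   `manifest`.
#' @export
read_world <- function(dir) {
  list(corpus = read_corpus(file.path(dir, "corpus.jsonl")),
       inventory = read_sense_inventory(file.path(dir, "inventory.tsv")),
       type_map = read_semantic_types(file.path(dir, "semantic_types.tsv")),
       graph = read_relations(file.path(dir, "relations.tsv")),
       gold = read_gold(file.path(dir, "gold.tsv")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

# 31-bit polynomial content hash (dependency-free fingerprint for manifests;
# pure double arithmetic so no integer overflow)
content_hash <- function(x) {
  bytes <- utf8ToInt(as.character(x))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
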