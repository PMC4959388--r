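# Evaluation: precision/recall/F for WSD output, time-sliced gold standards
# for hidden knowledge, scaled F-measure across systems, and the
# WSD-accuracy sweep driver that ties the whole pipeline together.

#' Harmonic mean of precision and recall
#'
#' Works on proportions or percentages alike (the result is on the scale of
#' its inputs); returns 0 when both inputs are 0.
#' @param precision,recall numeric vectors.
#' @return F-measure vector.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Construct a precision/recall/F record
#'
#' @param correct,attempted,total counts: correct predictions, non-abstain
#'   predictions, and gold instances.
#' @return object of class `prf` with `precision`, `recall`, `f_measure`
#'   (proportions in `[0, 1]`), the three counts, and
#'   `undefined_precision = TRUE` when nothing was attempted (precision is
#'   then reported as 0).
#' @export
prf <- function(correct, attempted, total) {
  stopifnot(correct <= attempted || attempted == 0, correct <= total)
  undef <- attempted == 0
  p <- if (undef) 0 else correct / attempted
  r <- if (total > 0) correct / total else 0
  structure(list(precision = p, recall = r, f_measure = f_measure(p, r),
                 correct = correct, attempted = attempted, total = total,
                 undefined_precision = undef), class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("P = %.1f %%  R = %.1f %%  F = %.1f %%  (%d/%d attempted, %d gold)%s\n",
              100 * x$precision, 100 * x$recall, 100 * x$f_measure,
              x$correct, x$attempted, x$total,
              if (x$undefined_precision) "  [precision undefined]" else ""))
  invisible(x)
}

#' Score sense assignments against gold annotations
#'
#' Predictions are aligned to gold instances by `(doc_id, start, end)`.
#' `total` is the number of gold instances, `attempted` the number of
#' aligned non-abstain predictions, `correct` those matching the gold CUI.
#'
#' @param annotations annotation data.frame (mentions plus `chosen`).
#' @param gold gold sense annotations ([read_gold()] layout).
#' @return a [prf()] record.
#' @export
evaluate_wsd <- function(annotations, gold) {
  if (nrow(gold) == 0L) stop("empty gold standard", call. = FALSE)
  key <- paste(annotations$doc_id, annotations$start, annotations$end)
  gkey <- paste(gold$doc_id, gold$start, gold$end)
  hit <- match(gkey, key)
  aligned <- !is.na(hit)
  pred <- annotations$chosen[hit[aligned]]
  attempted <- sum(!is.na(pred))
  correct <- sum(!is.na(pred) & pred == gold$gold_cui[aligned])
  prf(correct, attempted, nrow(gold))
}

#' Build a time-sliced LBD gold standard
#'
#' Title co-occurrence pairs are extracted from documents published after
#' the cutoff year and every pair already co-occurring in or before the
#' cutoff year is eliminated: what remains is "new published knowledge",
#' the yardstick for generated hidden knowledge. The same semantic-type
#' filter applied on the discovery side can be applied here so both sides
#' share a concept vocabulary.
#'
#' @param annotations annotation data.frame spanning years on both sides of
#'   the cutoff (typically gold-sense annotations of the full timeline).
#' @param cutoff_year documents with `year <= cutoff_year` are "pre",
#'   `year > cutoff_year` are "post".
#' @param type_map,excluded_types optional concept filter, see
#'   [filter_concepts()].
#' @return object of class `timeslice_gold`: list with `cutoff_year`,
#'   `pairs` (data.frame `cui_a < cui_b`), `n_post_docs`, `n_eliminated`.
#' @export
build_timeslice_gold <- function(annotations, cutoff_year, type_map = NULL,
                                 excluded_types = character()) {
  ann <- annotations[!is.na(annotations$chosen), , drop = FALSE]
  retained <- filter_concepts(sort(unique(ann$chosen)), type_map,
                              excluded_types)
  ann <- ann[ann$chosen %in% retained, , drop = FALSE]
  post <- annotations$year > cutoff_year
  if (!any(post)) stop("no documents after cutoff year ", cutoff_year,
                       call. = FALSE)
  pairs_of <- function(a) {
    by_doc <- split(a$chosen, a$doc_id)
    ii <- character(); jj <- character()
    for (cuis in by_doc) {
      u <- sort(unique(cuis))
      if (length(u) < 2L) next
      prs <- utils::combn(u, 2L)
      ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
    }
    if (length(ii) == 0L) {
      return(data.frame(cui_a = character(), cui_b = character(),
                        stringsAsFactors = FALSE))
    }
    pair_frame(ii, jj)
  }
  post_pairs <- pairs_of(ann[ann$year > cutoff_year, , drop = FALSE])
  pre_pairs <- pairs_of(ann[ann$year <= cutoff_year, , drop = FALSE])
  in_pre <- pair_key(post_pairs$cui_a, post_pairs$cui_b) %in%
    pair_key(pre_pairs$cui_a, pre_pairs$cui_b)
  structure(list(cutoff_year = cutoff_year,
                 pairs = post_pairs[!in_pre, , drop = FALSE],
                 n_post_docs = length(unique(annotations$doc_id[post])),
                 n_eliminated = sum(in_pre)),
            class = "timeslice_gold")
}

#' @export
print.timeslice_gold <- function(x, ...) {
  cat(sprintf("timeslice_gold: cutoff %d, %d new-knowledge pairs (%d eliminated, %d post docs)\n",
              x$cutoff_year, nrow(x$pairs), x$n_eliminated, x$n_post_docs))
  invisible(x)
}

#' Score hidden knowledge against a time-sliced gold standard
#'
#' Pair identity is the unordered CUI pair. Precision is the fraction of
#' generated pairs found in the gold standard, recall the fraction of gold
#' pairs generated.
#'
#' @param hidden a [hidden_knowledge()] result (or any data.frame with
#'   `cui_a`, `cui_b`).
#' @param gold a [build_timeslice_gold()] result.
#' @return a [prf()] record.
#' @export
evaluate_lbd <- function(hidden, gold) {
  if (nrow(gold$pairs) == 0L) stop("empty timeslice gold standard",
                                   call. = FALSE)
  hk <- unique(pair_key(hidden$cui_a, hidden$cui_b))
  gk <- unique(pair_key(gold$pairs$cui_a, gold$pairs$cui_b))
  prf(correct = sum(hk %in% gk), attempted = length(hk), total = length(gk))
}

#' Scale F-measures to the best-performing system
#'
#' Divides every system's F-measure by the maximum F-measure in the report
#' set, so the reference (best) system scores exactly 1.
#'
#' @param reports data.frame with at least columns `system` and `f` (raw
#'   F-measure); typically also `n_hidden`, `precision`, `recall`.
#' @return `reports` with a `scaled_f` column added; the row with maximal
#'   `f` has `scaled_f == 1`.
#' @export
scaled_f <- function(reports) {
  stopifnot(is.data.frame(reports), "f" %in% names(reports))
  f_ref <- max(reports$f)
  if (f_ref <= 0) stop("all F-measures are zero; no reference system",
                       call. = FALSE)
  reports$scaled_f <- reports$f / f_ref
  reports$scaled_f[which.max(reports$f)] <- 1
  reports
}

#' Sweep oracle WSD accuracy against LBD performance
#'
#' For each (target accuracy, seed) combination: annotate the pre-cutoff
#' documents with the noisy-oracle backend at that accuracy, build the
#' co-occurrence matrix, extract hidden knowledge, and score it against the
#' time-sliced gold standard built from the gold sense annotations of the
#' full timeline. This is the controlled, desk-scale version of running LBD
#' behind WSD systems of decreasing quality.
#'
#' @param corpus corpus data.frame spanning the cutoff.
#' @param inventory a [sense_inventory()].
#' @param gold gold sense annotations for every mention.
#' @param accuracies numeric vector of oracle target accuracies in `[0, 1]`.
#' @param seeds integer vector; each accuracy runs once per seed.
#' @param cutoff_year time-slice cutoff.
#' @param type_map,excluded_types semantic-type filter applied on both the
#'   discovery and the gold side.
#' @return object of class `lbd_sweep`: list with `runs` (one row per
#'   accuracy x seed: `target_accuracy`, `seed`, `measured_accuracy`,
#'   `precision`, `recall`, `f`, `n_hidden`) and `summary` (per-accuracy
#'   means plus `scaled_f` relative to the best mean F).
#' @export
run_accuracy_sweep <- function(corpus, inventory, gold, accuracies, seeds,
                               cutoff_year, type_map = NULL,
                               excluded_types = character()) {
  stopifnot(all(accuracies >= 0 & accuracies <= 1), length(seeds) >= 1L)
  mentions <- match_corpus(corpus, inventory, field = "title")
  gold_ann <- annotate_with_gold(mentions, gold)
  ts_gold <- build_timeslice_gold(gold_ann, cutoff_year, type_map,
                                  excluded_types)
  pre_mentions <- mentions[mentions$year <= cutoff_year, , drop = FALSE]
  pre_gold <- gold[gold$doc_id %in% pre_mentions$doc_id, , drop = FALSE]
  year_range <- c(min(corpus$year), cutoff_year)

  grid <- expand.grid(seed = seeds, target_accuracy = accuracies)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    a <- grid$target_accuracy[[g]]; s <- grid$seed[[g]]
    ann <- disambiguate_oracle(pre_mentions, gold, a, seed = s)
    wsd <- evaluate_wsd(ann, pre_gold)
    A <- build_matrix(ann, type_map, excluded_types, year_range)
    hk <- hidden_knowledge(A)
    res <- evaluate_lbd(hk, ts_gold)
    data.frame(target_accuracy = a, seed = s,
               measured_accuracy = wsd$precision,
               precision = res$precision, recall = res$recall,
               f = res$f_measure, n_hidden = nrow(hk))
  })
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(
    runs[c("measured_accuracy", "precision", "recall", "f", "n_hidden")],
    by = list(target_accuracy = runs$target_accuracy), FUN = mean)
  agg <- agg[order(-agg$target_accuracy), , drop = FALSE]
  rownames(agg) <- NULL
  agg <- scaled_f(agg)
  structure(list(runs = runs, summary = agg), class = "lbd_sweep")
}

#' Attach gold concepts as the chosen assignment of every mention
#'
#' The "perfect WSD" annotation: each mention aligned to a gold instance is
#' assigned its gold CUI; unaligned mentions abstain.
#' @param mentions mention data.frame.
#' @param gold gold sense annotations.
#' @return annotation data.frame.
#' @export
annotate_with_gold <- function(mentions, gold) {
  key <- paste(mentions$doc_id, mentions$start, mentions$end)
  gkey <- paste(gold$doc_id, gold$start, gold$end)
  annotate_result(mentions, gold$gold_cui[match(key, gkey)])
}

#' @export
print.lbd_sweep <- function(x, ...) {
  cat("lbd_sweep over oracle accuracies:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write sweep results as TSV (one row per accuracy x seed)
#' @param sweep a [run_accuracy_sweep()] result.
#' @param path output path.
#' @export
write_sweep <- function(sweep, path) {
  runs <- sweep$runs
  runs$scaled_f <- sweep$summary$scaled_f[
    match(runs$target_accuracy, sweep$summary$target_accuracy)]
  write_tsv(runs, path)
}
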