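#' Sensitive seed-and-extend local alignment
#'
#' Aligns each query against every database sequence on both strands.  Exact
#' `word`-mer seed matches are chained by diagonal proximity and each chain is
#' extended by a full affine-gap (Gotoh) local alignment within its subject
#' window, so on small instances the best reported score equals the exact
#' Smith-Waterman optimum whenever a seed exists.  Hits shorter than
#' `min_len` aligned columns or with expect value above `max_e` are dropped;
#' two hits on the same subject whose query spans overlap by more than half of
#' the shorter span and whose subject spans also overlap (the same placement
#' re-found from adjacent seed windows) keep only the better-scoring one.
#'
#' @param queries Tibble with columns `id` and `seq` (or a named character
#'   vector of sequences).
#' @param db Named character vector (or DNAStringSet) of subject sequences.
#' @param params [align_params()].
#' @return A hit tibble sorted by ascending expect value (ties: descending
#'   score, then subject and position): `query_id`, `qstart`, `qend`, `qlen`
#'   (all on the forward query; 1-based closed), `subject`, `sstart`, `send`
#'   (`sstart` is always the smallest subject coordinate), `strand`, `score`,
#'   `matches`, `length`, `evalue`.
#' @export
local_align <- function(queries, db, params = align_params()) {
  if (is.character(queries)) {
    queries <- tibble(id = names(queries), seq = unname(queries))
  }
  stopifnot(all(c("id", "seq") %in% names(queries)))
  subj <- as_seq_vector(db, "subject database")
  if (length(subj) == 0) abort("empty subject database")
  n_db <- sum(nchar(subj))
  if (nrow(queries) == 0) return(local_hits_schema())
  raw <- as_tibble(cpp_local_align(
    toupper(queries$seq), unname(subj), params$word, params$match,
    params$mismatch, params$gap_open, params$gap_extend, params$min_len))
  if (nrow(raw) == 0) return(local_hits_schema())
  hits <- raw %>%
    mutate(query_id = queries$id[.data$query],
           qlen = nchar(queries$seq)[.data$query],
           subject = names(subj)[.data$subject],
           evalue = params$ka_k * .data$qlen * n_db *
             exp(-params$ka_lambda * .data$score)) %>%
    filter(.data$evalue <= params$max_e) %>%
    select("query_id", "qstart", "qend", "qlen", "subject", "sstart", "send",
           "strand", "score", "matches", "length", "evalue")
  hits <- mask_overlaps(hits)
  hits %>%
    select("query_id", "qstart", "qend", "qlen", "subject", "sstart", "send",
           "strand", "score", "matches", "length", "evalue") %>%
    arrange(.data$query_id, .data$evalue, dplyr::desc(.data$score),
            .data$subject, .data$sstart)
}

local_hits_schema <- function() {
  tibble(query_id = character(), qstart = integer(), qend = integer(),
         qlen = integer(), subject = character(), sstart = integer(),
         send = integer(), strand = character(), score = integer(),
         matches = integer(), length = integer(), evalue = double())
}

# same query + same subject, query-span overlap > 50% of the shorter span AND
# overlapping subject spans: keep the better-scoring hit.  This removes
# seed-ladder duplicates (the same alignment re-found from adjacent windows)
# while preserving distinct placements of a repeated query on one subject,
# which the rank/retention machinery needs to flag ambiguity.  The grouped
# scan only runs on the rare multi-hit groups.
mask_overlaps <- function(hits) {
  hits <- hits %>%
    group_by(.data$query_id, .data$subject) %>%
    mutate(.gn = dplyr::n()) %>%
    ungroup()
  singles <- filter(hits, .data$.gn == 1)
  multis <- filter(hits, .data$.gn > 1)
  if (nrow(multis) > 0) {
    multis <- multis %>%
      group_by(.data$query_id, .data$subject) %>%
      dplyr::group_modify(function(g, key) {
        g <- arrange(g, dplyr::desc(.data$score), .data$evalue, .data$sstart)
        keep <- rep(TRUE, nrow(g))
        for (i in seq_len(nrow(g))[-1]) {
          for (j in seq_len(i - 1)) {
            if (!keep[j]) next
            ov <- min(g$qend[i], g$qend[j]) - max(g$qstart[i], g$qstart[j]) + 1
            sov <- min(g$send[i], g$send[j]) - max(g$sstart[i], g$sstart[j]) + 1
            shorter <- min(g$qend[i] - g$qstart[i], g$qend[j] - g$qstart[j]) + 1
            if (ov > 0.5 * shorter && sov > 0) { keep[i] <- FALSE; break }
          }
        }
        g[keep, ]
      }) %>%
      ungroup()
  }
  bind_rows(singles, multis) %>% select(-".gn")
}

#' Rank hits of one query by expect value
#'
#' A hit has rank N when N hits in the list (itself included) have expect
#' value less than or equal to its own, so a unique best hit has rank 1 and
#' tied best hits share a rank equal to the tie size.
#'
#' @param hits Hit tibble for a single query (column `evalue`).
#' @return The tibble with a `rank` column added.
#' @export
rank_hits <- function(hits) {
  if (nrow(hits) == 0) return(mutate(hits, rank = integer(0)))
  e <- hits$evalue
  hits$rank <- vapply(e, function(x) sum(e <= x), integer(1))
  hits
}

#' Retain top hits of one query
#'
#' Keeps all hits tied at the smallest expect value; when the best hit is
#' unique, hits at the second-smallest expect value are retained alongside it
#' (the unique best may be noise, so keeping the runner-up preserves the true
#' placement).
#'
#' @param hits Hit tibble for a single query.
#' @return The retained subset.
#' @export
retain_top_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  e <- hits$evalue
  e_min <- min(e)
  if (sum(e == e_min) >= 2) return(hits[e == e_min, ])
  rest <- e[e > e_min]
  if (length(rest) == 0) return(hits[e == e_min, ])
  e2 <- min(rest)
  hits[e <= e2, ]
}

# apply rank + retention per (read, mate): each mate is a read with its own
# hit list.  Vectorized form of
# retain_top_hits(rank_hits(.)) — rank with ties.method = "max" counts the
# hits at or below each expect value, and the retention rule reduces to a
# window-function filter.  Agreement with the per-group form is a tested
# property.
rank_and_retain <- function(hits) {
  if (nrow(hits) == 0) return(mutate(hits, rank = integer(0)))
  hits %>%
    group_by(.data$read_id, .data$mate) %>%
    mutate(rank = as.integer(rank(.data$evalue, ties.method = "max")),
           .emin = min(.data$evalue),
           .nmin = sum(.data$evalue == .data$.emin),
           .e2 = min(c(.data$evalue[.data$evalue > .data$.emin], Inf))) %>%
    filter((.data$.nmin >= 2 & .data$evalue == .data$.emin) |
             (.data$.nmin == 1 & .data$evalue <= .data$.e2)) %>%
    ungroup() %>%
    select(-".emin", -".nmin", -".e2")
}
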