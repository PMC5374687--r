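#' Flatten the retained host hits of the chimeric set
#'
#' @param pairs Read-pair tibble at stage `X_chimera` (with a `host_hits`
#'   list-column).
#' @return One row per retained host hit: `read_id`, `mate`, hit fields and
#'   `rank`.
#' @export
host_hit_table <- function(pairs) {
  if (nrow(pairs) == 0 || is.null(pairs$host_hits)) {
    return(mutate(empty_mate_hits(), rank = integer(0)))
  }
  bind_rows(pairs$host_hits)
}

#' Cluster co-localized host hits
#'
#' Within each chromosome, hits are sorted by position and chained: a new
#' cluster starts whenever the gap to the previous hit start exceeds or
#' equals `d + 2*sigma`.  Every hit belongs to exactly one cluster.
#'
#' @param hits Host hit tibble (from [host_hit_table()]); positions in
#'   `subject`/`sstart`.
#' @param stats [library_stats()].
#' @return The hits with a `cluster_id` column (`<chrom>:<n>`), sorted by
#'   chromosome and position.
#' @export
cluster_hits <- function(hits, stats) {
  stopifnot(inherits(stats, "library_stats"))
  if (nrow(hits) == 0) return(mutate(hits, cluster_id = character(0)))
  thr <- stats$d + 2 * stats$sigma
  hits %>%
    arrange(.data$subject, .data$sstart, .data$send, .data$read_id, .data$mate) %>%
    group_by(.data$subject) %>%
    mutate(gap = as.numeric(.data$sstart) -
             dplyr::lag(as.numeric(.data$sstart), default = -Inf),
           cluster_id = paste0(.data$subject, ":", cumsum(.data$gap >= thr))) %>%
    ungroup() %>%
    select(-"gap")
}

#' Partition cluster members by junction orientation
#'
#' Classifies every host hit by where the virus lies relative to the host:
#' side `Cplus` (host 5' of virus) collects whole-read or prefix alignments
#' on the + strand and suffix alignments on the - strand; side `Cminus`
#' (host 3' of virus) collects the complements.  Whole-read alignments follow
#' their strand.  Hits whose aligned part is internal to the read (neither a
#' prefix nor a suffix) fit no junction geometry and are classed `noise`.
#' Prefix/suffix is judged on the forward-read query span with a small edge
#' tolerance absorbing aligner end-trimming.
#'
#' @param members Clustered host hit tibble.
#' @param edge_tol Bases of slack at the read ends (default 3).
#' @return The tibble with a `side` column (`Cplus`, `Cminus`, `noise`).
#' @export
partition_orientation <- function(members, edge_tol = 3) {
  if (nrow(members) == 0) return(mutate(members, side = character(0)))
  is_prefix <- members$qstart <= 1 + edge_tol
  is_suffix <- members$qend >= members$qlen - edge_tol
  whole <- is_prefix & is_suffix
  plus <- members$strand == "+"
  side <- rep("noise", nrow(members))
  side[whole & plus] <- "Cplus"
  side[whole & !plus] <- "Cminus"
  side[!whole & is_prefix & plus] <- "Cplus"
  side[!whole & is_suffix & !plus] <- "Cplus"
  side[!whole & is_suffix & plus] <- "Cminus"
  side[!whole & is_prefix & !plus] <- "Cminus"
  mutate(members, side = side)
}

#' Median rank of a cluster
#'
#' The lower median (for even counts, the smaller central order statistic) of
#' the member hit ranks.  Only clusters with median rank 1 — unambiguous host
#' placements — enter the main call set.
#'
#' @param members Host hit tibble of one (sub-)cluster with a `rank` column.
#' @return An integer.
#' @export
median_rank <- function(members) {
  if (nrow(members) == 0) abort("median_rank of an empty cluster")
  as.integer(lower_median(members$rank))
}
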