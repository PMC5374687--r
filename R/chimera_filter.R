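#' Confirm viral content by local alignment (stage X2)
#'
#' Every pair that survived the k-mer screen is re-examined with the sensitive
#' local aligner against the virus database; pairs with at least one hit on
#' either mate are promoted to stage `X2` with their virus hits stored in a
#' nested `virus_hits` list-column, the rest are discarded (a spurious k-mer
#' match with no alignable viral segment does not survive this stage).
#'
#' @param pairs Read-pair tibble at stage `X1`.
#' @param virus_db Named character vector (or DNAStringSet) of virus genomes.
#' @param params [align_params()].
#' @return Surviving pairs with `stage = "X2"` and a `virus_hits` list-column
#'   (per-pair tibble with a `mate` column alongside the hit fields).
#' @export
build_x2 <- function(pairs, virus_db, params = align_params()) {
  aligned <- align_mates(pairs, virus_db, params)
  attach_hits(pairs, aligned, "virus_hits", "X2")
}

#' Confirm host content by local alignment (stage X_chimera)
#'
#' Pairs at stage `X2` are aligned against the host genome; pairs with at
#' least one host hit on either mate are promoted to the chimeric set.  Host
#' hits are ranked and passed through the top-hit retention rule per mate
#' (all ties at the best expect value; plus the runner-up when the best is
#' unique), so every stored host hit carries its `rank`.
#'
#' @param pairs Read-pair tibble at stage `X2` (with `virus_hits`).
#' @param host_genome Named character vector (or DNAStringSet) of host
#'   chromosomes.
#' @param params [align_params()].
#' @return Surviving pairs with `stage = "X_chimera"` and a `host_hits`
#'   list-column of retained, ranked host hits.
#' @export
build_x_chimera <- function(pairs, host_genome, params = align_params()) {
  aligned <- align_mates(pairs, host_genome, params)
  aligned <- rank_and_retain(aligned)
  attach_hits(pairs, aligned, "host_hits", "X_chimera")
}

# align both mates of every pair against a database; long format with
# read_id + mate identifying the query
align_mates <- function(pairs, db, params) {
  if (nrow(pairs) == 0) {
    return(empty_mate_hits())
  }
  queries <- tibble(
    id = c(paste0(pairs$id, "/1"), paste0(pairs$id, "/2")),
    seq = c(pairs$seq1, pairs$seq2))
  hits <- local_align(queries, db, params)
  hits %>%
    mutate(mate = ifelse(grepl("/2$", .data$query_id), 2L, 1L),
           read_id = sub("/[12]$", "", .data$query_id)) %>%
    select("read_id", "mate", dplyr::everything(), -"query_id")
}

empty_mate_hits <- function() {
  mutate(local_hits_schema(), read_id = character(0), mate = integer(0),
         query_id = NULL)
}

attach_hits <- function(pairs, hits, column, new_stage) {
  lst <- split(hits, hits$read_id)     # read_id stays inside each table
  out <- pairs %>% filter(.data$id %in% names(lst)) %>%
    mutate(stage = new_stage)
  out[[column]] <- unname(lst[match(out$id, names(lst))])
  out
}
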