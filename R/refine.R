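# merge overlapping 1-based query spans and count the resulting segments
count_segments <- function(qstart, qend) {
  if (length(qstart) == 0) return(0L)
  o <- order(qstart, qend)
  qstart <- qstart[o]; qend <- qend[o]
  n <- 1L
  hi <- qend[1]
  for (i in seq_along(qstart)[-1]) {
    if (qstart[i] > hi + 1) n <- n + 1L
    hi <- max(hi, qend[i])
  }
  n
}

# per-pair layout summary used by the complex filter
pair_layout <- function(pairs) {
  purrr::map2(pairs$virus_hits %||% rep(list(NULL), nrow(pairs)),
              pairs$host_hits %||% rep(list(NULL), nrow(pairs)),
              function(v, h) list(virus = v, host = h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove complex and mis-oriented read pairs from clusters
#'
#' A sequenced read spanning one junction carries at most one host segment
#' and one virus segment; any mate whose merged hit spans show more than one
#' segment from either genome (for example virus-host-virus) marks the whole
#' pair as complex and it is discarded.  Pairs whose two mates are both
#' host-mapped must in addition lie on the same chromosome in forward-reverse
#' orientation, as a concordant fragment would.
#'
#' @param members Clustered host hit tibble.
#' @param pairs The stage-`X_chimera` pair tibble (provides the full per-mate
#'   hit layouts).
#' @return `members` with the rows of discarded pairs removed.
#' @export
filter_complex <- function(members, pairs) {
  if (nrow(members) == 0) return(members)
  pairs <- filter(pairs, .data$id %in% unique(members$read_id))
  bad <- vapply(seq_len(nrow(pairs)), function(i) {
    v <- pairs$virus_hits[[i]]
    h <- pairs$host_hits[[i]]
    for (m in 1:2) {
      vsel <- if (!is.null(v)) v$mate == m else logical(0)
      hsel <- if (!is.null(h)) h$mate == m else logical(0)
      if (count_segments(v$qstart[vsel], v$qend[vsel]) > 1 ||
          count_segments(h$qstart[hsel], h$qend[hsel]) > 1) return(TRUE)
    }
    # both mates host-mapped: require same chromosome + FR orientation
    if (!is.null(h) && all(1:2 %in% h$mate)) {
      i1 <- which(h$mate == 1); i1 <- i1[which.min(h$evalue[i1])]
      i2 <- which(h$mate == 2); i2 <- i2[which.min(h$evalue[i2])]
      if (h$subject[i1] != h$subject[i2]) return(TRUE)
      if (h$strand[i1] == h$strand[i2]) return(TRUE)
      ip <- if (h$strand[i1] == "+") i1 else i2
      im <- if (h$strand[i1] == "+") i2 else i1
      if (h$sstart[ip] > h$send[im]) return(TRUE)  # not facing each other
    }
    FALSE
  }, logical(1))
  filter(members, !.data$read_id %in% pairs$id[bad])
}

#' Collapse duplicate read pairs
#'
#' Identically aligned pairs are almost surely optical/PCR duplicates in a
#' whole-genome library, so when enabled only one copy — the pair with the
#' lexicographically smallest id — is kept per full alignment signature
#' (every host and virus hit tuple of both mates).
#'
#' @param members Clustered host hit tibble.
#' @param pairs The stage-`X_chimera` pair tibble.
#' @param enabled When `FALSE` the input is returned unchanged.
#' @return `members` with duplicate pairs' rows removed.
#' @export
dedupe_pairs <- function(members, pairs, enabled = TRUE) {
  if (!enabled || nrow(members) == 0) return(members)
  pairs <- filter(pairs, .data$id %in% unique(members$read_id))
  # one alignment-signature string per pair, built over the flattened hit
  # tables in a single pass
  sig_of <- function(hit_list) {
    hh <- bind_rows(hit_list)
    if (nrow(hh) == 0) return(setNames(character(0), character(0)))
    o <- order(hh$read_id, hh$mate, hh$subject, hh$sstart, hh$strand,
               hh$qstart, hh$qend)
    hh <- hh[o, ]
    row_str <- paste(hh$mate, hh$subject, hh$sstart, hh$send, hh$strand,
                     hh$qstart, hh$qend, sep = ",")
    vapply(split(row_str, hh$read_id), paste, character(1), collapse = ";")
  }
  hsig <- sig_of(pairs$host_hits)
  vsig <- sig_of(pairs$virus_hits)
  blank <- function(x) ifelse(is.na(x), "", x)
  sig <- paste(blank(hsig[pairs$id]), blank(vsig[pairs$id]), sep = "|")
  keep_ids <- tibble(id = pairs$id, sig = sig) %>%
    group_by(.data$sig) %>%
    summarise(id = min(.data$id), .groups = "drop") %>%
    pull("id")
  filter(members, .data$read_id %in% keep_ids)
}

# natural split reads: a mate carrying both a retained host hit (a cluster
# member) and a virus hit on a near-disjoint query span pinpoints the
# junction at base resolution
natural_splits <- function(members, pairs, max_span_overlap = 5) {
  if (nrow(members) == 0) return(empty_splits())
  vhits <- bind_rows(pairs$virus_hits[match(unique(members$read_id), pairs$id)])
  if (nrow(vhits) == 0) return(empty_splits())
  joined <- members %>%
    mutate(.mrow = row_number()) %>%
    dplyr::inner_join(vhits, by = c("read_id", "mate"),
                      suffix = c("", ".v"), relationship = "many-to-many") %>%
    filter(pmin(.data$qend, .data$qend.v) -
             pmax(.data$qstart, .data$qstart.v) + 1 <= max_span_overlap) %>%
    group_by(.data$.mrow) %>%
    slice_min(.data$evalue.v, n = 1, with_ties = FALSE) %>%
    ungroup()
  if (nrow(joined) == 0) return(empty_splits())
  # side of the virus segment on the read: compare span centres, robust to
  # the few bases of overlap tolerated above
  virus_right <- (joined$qstart.v + joined$qend.v) >
    (joined$qstart + joined$qend)
  joined %>%
    mutate(
      host_junction = as.integer(ifelse(virus_right,
        ifelse(.data$strand == "+", .data$send, .data$sstart),
        ifelse(.data$strand == "+", .data$sstart, .data$send))),
      virus_junction = as.integer(ifelse(virus_right,
        ifelse(.data$strand.v == "+", .data$sstart.v, .data$send.v),
        ifelse(.data$strand.v == "+", .data$send.v, .data$sstart.v))),
      query_breakpos = as.integer(ifelse(virus_right, .data$qend, .data$qstart)),
      host_chr = .data$subject, virus_id = .data$subject.v,
      virus_strand = .data$strand.v,
      # host strand x virus strand: equal strands mean the virus reads along
      # the host + strand through the junction, i.e. a + integration
      orient = ifelse(.data$strand == .data$strand.v, "+", "-"),
      origin = "blast") %>%
    select("read_id", "mate", "cluster_id", "side", "host_chr",
           "host_junction", "virus_id", "virus_junction", "virus_strand",
           "orient", "query_breakpos", "origin")
}

empty_splits <- function() {
  tibble(read_id = character(), mate = integer(), cluster_id = character(),
         side = character(), host_chr = character(), host_junction = integer(),
         virus_id = character(), virus_junction = integer(),
         virus_strand = character(), orient = character(),
         query_breakpos = integer(), origin = character())
}

#' Rescue split reads by targeted Smith-Waterman
#'
#' A mate that aligns to the virus but leaves at least `min_unaligned`
#' contiguous bases uncovered may be a split read whose short host segment
#' was below the sensitivity floor of the local aligner (or interrupted by a
#' short random insert at the junction).  When its mate is host-anchored and
#' not itself a split read, the uncovered portion is aligned by
#' Smith-Waterman against the host window of width `d + 2*sigma` flanking the
#' anchor on the junction-facing side.  An alignment with identity at least
#' `min_identity` over at least `min_span` bases promotes the read to a true
#' split read with an exact host breakpoint; otherwise the read is left as
#' paired-end support only.
#'
#' @param members Clustered, oriented host hit tibble (column `side`).
#' @param pairs Stage-`X_chimera` pair tibble.
#' @param host_genome Named character vector of host chromosomes.
#' @param stats [library_stats()].
#' @param min_unaligned Minimum uncovered run to attempt rescue (default 10).
#' @param min_identity Minimum SW identity to accept (default 0.9).
#' @param min_span Minimum SW alignment length to accept (default 10).
#' @param params [align_params()] supplying the SW scoring scheme.
#' @return A split-read tibble (`origin = "rescued"`): one row per rescued
#'   read with `host_junction`, `virus_junction`, `virus_strand`,
#'   `query_breakpos` and the sub-cluster (`cluster_id`, `side`) of its
#'   anchor mate.
#' @export
rescue_split_reads <- function(members, pairs, host_genome, stats,
                               min_unaligned = 10, min_identity = 0.9,
                               min_span = 10, params = align_params()) {
  host <- as_seq_vector(host_genome, "host genome")
  if (nrow(members) == 0) return(empty_splits())
  window <- stats$d + 2 * stats$sigma
  nat <- natural_splits(members, pairs)
  nat_keys <- paste(nat$read_id, nat$mate)
  member_split <- split(seq_len(nrow(members)), members$read_id)
  rows <- list()
  pidx <- match(unique(members$read_id), pairs$id)
  for (pi in pidx) {
    v <- pairs$virus_hits[[pi]]
    h <- pairs$host_hits[[pi]]
    if (is.null(v) || nrow(v) == 0) next
    for (m in 1:2) {
      vm <- v[v$mate == m, , drop = FALSE]
      if (nrow(vm) == 0) next
      hm <- if (is.null(h)) NULL else h[h$mate == m, , drop = FALSE]
      read_seq <- if (m == 1) pairs$seq1[pi] else pairs$seq2[pi]
      rl <- nchar(read_seq)
      covered <- rep(FALSE, rl)
      for (j in seq_len(nrow(vm))) covered[vm$qstart[j]:vm$qend[j]] <- TRUE
      if (!is.null(hm)) for (j in seq_len(nrow(hm)))
        covered[hm$qstart[j]:hm$qend[j]] <- TRUE
      runs <- rle(covered)
      if (!any(!runs$values & runs$lengths >= min_unaligned)) next
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      cand <- which(!runs$values & runs$lengths >= min_unaligned)
      ri <- cand[which.max(runs$lengths[cand])]
      u1 <- starts[ri]; u2 <- ends[ri]
      # the anchor: the other mate's member host hit, itself not a split read
      other <- 3L - m
      mi <- member_split[[pairs$id[pi]]]
      mi <- mi[members$mate[mi] == other]
      if (length(mi) == 0) next
      mi <- mi[order(members$rank[mi], members$sstart[mi])][1]
      anchor <- members[mi, ]
      if (paste(pairs$id[pi], other) %in% nat_keys) next
      chrom <- host[[anchor$subject]]
      if (anchor$strand == "+") {
        wlo <- anchor$sstart
        whi <- min(nchar(chrom), anchor$send + window)
      } else {
        wlo <- max(1, anchor$sstart - window)
        whi <- anchor$send
      }
      win <- substr(chrom, wlo, whi)
      seg <- substr(read_seq, u1, u2)
      a_f <- cpp_smith_waterman(seg, win, params$match, params$mismatch,
                                params$gap_open, params$gap_extend)
      a_r <- cpp_smith_waterman(revcomp_chr(seg), win, params$match,
                                params$mismatch, params$gap_open,
                                params$gap_extend)
      fwd <- a_f$score >= a_r$score
      a <- if (fwd) a_f else a_r
      if (a$length < min_span || a$matches < min_identity * a$length) next
      vbest <- vm[which.min(vm$evalue), ]
      seg_right_of_virus <- u1 > vbest$qend
      host_junction <- if (seg_right_of_virus) {
        if (fwd) wlo + a$sstart - 1 else wlo + a$send - 1
      } else {
        if (fwd) wlo + a$send - 1 else wlo + a$sstart - 1
      }
      virus_junction <- if (seg_right_of_virus) {
        if (vbest$strand == "+") vbest$send else vbest$sstart
      } else {
        if (vbest$strand == "+") vbest$sstart else vbest$send
      }
      rows[[length(rows) + 1]] <- tibble(
        read_id = pairs$id[pi], mate = m, cluster_id = anchor$cluster_id,
        side = anchor$side, host_chr = anchor$subject,
        host_junction = as.integer(host_junction), virus_id = vbest$subject,
        virus_junction = as.integer(virus_junction),
        virus_strand = vbest$strand,
        orient = if (fwd == (vbest$strand == "+")) "+" else "-",
        query_breakpos = as.integer(if (seg_right_of_virus) u1 else u2),
        origin = "rescued")
    }
  }
  if (length(rows) == 0) return(empty_splits())
  bind_rows(rows)
}

#' All split reads of the refined clusters
#'
#' Combines the split reads detected directly by the local aligner (a mate
#' with adjacent host and virus hits) with those recovered by Smith-Waterman
#' rescue.
#'
#' @inheritParams rescue_split_reads
#' @return A split-read tibble; column `origin` is `"blast"` or `"rescued"`.
#' @export
split_read_table <- function(members, pairs, host_genome, stats,
                             min_unaligned = 10, min_identity = 0.9,
                             min_span = 10, params = align_params()) {
  bind_rows(
    natural_splits(members, pairs),
    rescue_split_reads(members, pairs, host_genome, stats, min_unaligned,
                       min_identity, min_span, params))
}
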