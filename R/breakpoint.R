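#' Estimate the host breakpoint of one oriented sub-cluster
#'
#' Without a junction-spanning read the best estimate is the member alignment
#' end nearest the junction: the maximum aligned host end for a `Cplus`
#' cluster (host 5' of virus) and the minimum aligned host start for a
#' `Cminus` cluster.  The estimate uses host-aligned read ends, not raw read
#' lengths, so unaligned viral tails cannot push it past the junction; it can
#' undershoot by up to the maximum insert span of the library.  When split
#' reads are supplied their median junction overrides the estimate and the
#' breakpoint becomes exact.
#'
#' @param members Host hit tibble of one sub-cluster (single `side`).
#' @param splits Optional split-read tibble for the same sub-cluster.
#' @return A list with `pos` (integer) and `exact` (logical).
#' @export
host_breakpoint <- function(members, splits = NULL) {
  if (nrow(members) == 0) abort("host_breakpoint of an empty cluster")
  side <- unique(members$side)
  stopifnot(length(side) == 1, side %in% c("Cplus", "Cminus"))
  if (!is.null(splits) && nrow(splits) > 0) {
    return(list(pos = as.integer(lower_median(splits$host_junction)),
                exact = TRUE))
  }
  pos <- if (side == "Cplus") max(members$send) else min(members$sstart)
  list(pos = as.integer(pos), exact = FALSE)
}

# orientation table: host side x winning virus strand.  The vote is taken on
# raw alignment strands; mates lying deep in the virus dominate it, so a
# Cplus cluster over a forward-integrated virus is won by the minus strand
# (those mates are sequenced from the reverse fragment strand).  The
# junction-proximal extremum and the integration orientation follow:
#   Cplus  + winner V- -> orient "+", proximal = 5'-most (min sstart)
#   Cplus  + winner V+ -> orient "-", proximal = 3'-most (max send)
#   Cminus + winner V+ -> orient "+", proximal = 3'-most (max send)
#   Cminus + winner V- -> orient "-", proximal = 5'-most (min sstart)
virus_orientation <- function(side, winner) {
  if (side == "Cplus") {
    list(orient = if (winner == "-") "+" else "-",
         proximal = if (winner == "-") "min" else "max")
  } else {
    list(orient = if (winner == "+") "+" else "-",
         proximal = if (winner == "+") "max" else "min")
  }
}

#' Virus-side breakpoint by strand majority vote
#'
#' All virus hits of the sub-cluster's reads and mates (best hit per mate)
#' are partitioned by alignment strand into V+ and V-.  With accurate
#' alignments one side should be empty; the vote tolerates noise by requiring
#' the winning side to outnumber the other by at least `epsilon` reads,
#' otherwise no virus breakpoint is reported.  The winning strand combined
#' with the host side fixes the integration orientation and which extremum of
#' the winning hits is junction-proximal.
#'
#' @param members Host hit tibble of one sub-cluster.
#' @param pairs Stage-`X_chimera` pair tibble (provides `virus_hits`).
#' @param epsilon Vote margin (default 2).
#' @return `NULL` when the vote is inconclusive or no virus hits exist,
#'   otherwise a list with `virus_id`, `pos`, `orient`, `strand` and the vote
#'   counts `n_plus`, `n_minus`.
#' @export
virus_breakpoint <- function(members, pairs, epsilon = 2) {
  side <- unique(members$side)
  stopifnot(length(side) == 1, side %in% c("Cplus", "Cminus"))
  vhits <- bind_rows(pairs$virus_hits[match(unique(members$read_id), pairs$id)])
  if (nrow(vhits) == 0) return(NULL)
  vbest <- vhits %>%
    group_by(.data$read_id, .data$mate) %>%
    slice_min(.data$evalue, n = 1, with_ties = FALSE) %>%
    ungroup()
  n_plus <- sum(vbest$strand == "+")
  n_minus <- sum(vbest$strand == "-")
  if (abs(n_plus - n_minus) < epsilon) return(NULL)
  winner <- if (n_plus > n_minus) "+" else "-"
  win <- filter(vbest, .data$strand == winner)
  virus_id <- names(sort(table(win$subject), decreasing = TRUE))[1]
  win <- filter(win, .data$subject == virus_id)
  ori <- virus_orientation(side, winner)
  pos <- if (ori$proximal == "min") min(win$sstart) else max(win$send)
  list(virus_id = virus_id, pos = as.integer(pos), orient = ori$orient,
       strand = winner, n_plus = n_plus, n_minus = n_minus)
}

#' Refine a breakpoint with split-read medians
#'
#' Aligners can place the two halves of a split read off by a few bases, so
#' the exact breakpoint is taken as the median (lower median for even counts)
#' of the split-read junction coordinates, host and virus separately.  Split
#' reads are grouped by the integration orientation they witness (the product
#' of their host and virus alignment strands, which is fragment-strand
#' independent); the median is promoted to an exact breakpoint only when one
#' orientation group outnumbers the other by at least `epsilon`.
#'
#' @param splits Split-read tibble of one sub-cluster.
#' @param epsilon Margin (default 2, shared with the strand vote).
#' @return `NULL` when there is no qualifying majority, otherwise a list with
#'   `host_pos`, `virus_pos`, `orient` (winning integration orientation) and
#'   `exact = TRUE`.
#' @export
refine_with_split_reads <- function(splits, epsilon = 2) {
  if (is.null(splits) || nrow(splits) == 0) return(NULL)
  n_plus <- sum(splits$orient == "+")
  n_minus <- sum(splits$orient == "-")
  if (abs(n_plus - n_minus) < epsilon) return(NULL)
  winner <- if (n_plus > n_minus) "+" else "-"
  win <- filter(splits, .data$orient == winner)
  list(host_pos = as.integer(lower_median(win$host_junction)),
       virus_pos = as.integer(lower_median(win$virus_junction)),
       orient = winner, exact = TRUE)
}

#' Assemble cluster reads into consensus sequences
#'
#' Greedy overlap-layout: member reads (oriented to the host + strand) are
#' merged whenever they overlap by at least `min_overlap` bases with identity
#' above `min_identity`; each column of the final pile-up is called by
#' majority vote (ties go to the first-encountered base).
#'
#' @param members Host hit tibble of one sub-cluster.
#' @param pairs Stage-`X_chimera` pair tibble (provides the sequences).
#' @param min_overlap Minimum overlap in bases (default 30).
#' @param min_identity Identity that the overlap must exceed (default 0.75).
#' @return Character vector of consensus sequences (possibly length 0).
#' @export
assemble_consensus <- function(members, pairs, min_overlap = 30,
                               min_identity = 0.75) {
  if (nrow(members) == 0) return(character(0))
  mem <- members %>%
    distinct(.data$read_id, .data$mate, .keep_all = TRUE) %>%
    arrange(.data$sstart, .data$read_id, .data$mate)
  seqs <- vapply(seq_len(nrow(mem)), function(i) {
    pi <- match(mem$read_id[i], pairs$id)
    s <- if (mem$mate[i] == 1) pairs$seq1[pi] else pairs$seq2[pi]
    if (mem$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
  contigs <- list()
  cur <- list(list(seq = seqs[1], off = 0))  # reads of the open contig
  cur_start <- 1
  out <- character(0)
  finish <- function(reads) {
    lo <- min(vapply(reads, function(r) r$off, numeric(1)))
    hi <- max(vapply(reads, function(r) r$off + nchar(r$seq), numeric(1)))
    width <- hi - lo
    counts <- matrix(0L, nrow = 5, ncol = width,
                     dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    first_seen <- rep(NA_character_, width)
    for (r in reads) {
      cols <- (r$off - lo) + seq_len(nchar(r$seq))
      bases <- strsplit(r$seq, "")[[1]]
      bases[!bases %in% c("A", "C", "G", "T")] <- "N"
      for (j in seq_along(cols)) {
        counts[bases[j], cols[j]] <- counts[bases[j], cols[j]] + 1L
        if (is.na(first_seen[cols[j]])) first_seen[cols[j]] <- bases[j]
      }
    }
    cons <- vapply(seq_len(width), function(j) {
      cc <- counts[, j]
      mx <- max(cc)
      winners <- rownames(counts)[cc == mx]
      if (first_seen[j] %in% winners) first_seen[j] else winners[1]
    }, character(1))
    paste(cons, collapse = "")
  }
  for (i in seq_len(nrow(mem))[-1]) {
    merged <- FALSE
    # try against the current layout's backbone reads
    for (r in cur) {
      bo <- cpp_best_overlap(r$seq, seqs[i], min_overlap)
      if (!is.na(bo$offset) && bo$overlap >= min_overlap &&
          bo$matches > min_identity * bo$overlap) {
        cur[[length(cur) + 1]] <- list(seq = seqs[i], off = r$off + bo$offset)
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      if (length(cur) > 1) out <- c(out, finish(cur))
      cur <- list(list(seq = seqs[i], off = 0))
    }
  }
  if (length(cur) > 1) out <- c(out, finish(cur))
  out
}

#' Call an integration from a consensus sequence
#'
#' The consensus is aligned to the host genome.  With a unique smallest
#' expect value, the unaligned remainder is aligned to the virus database; a
#' hit yields one exact call at the host/virus boundary.  When several host
#' placements tie at the smallest expect value, one call per placement is
#' emitted and each is marked ambiguous.  No virus hit, no call.
#'
#' @param consensus A single consensus sequence.
#' @param host_genome,virus_db Named sequence vectors.
#' @param params [align_params()].
#' @return A call tibble (0, 1 or several rows) with columns `host_chr`,
#'   `host_pos`, `host_side`, `virus_id`, `virus_pos`, `virus_orient`,
#'   `exact`, `ambiguous`.
#' @export
call_from_consensus <- function(consensus, host_genome, virus_db,
                                params = align_params()) {
  empty <- tibble(host_chr = character(), host_pos = integer(),
                  host_side = character(), virus_id = character(),
                  virus_pos = integer(), virus_orient = character(),
                  exact = logical(), ambiguous = logical())
  if (nchar(consensus) < params$min_len) return(empty)
  hh <- local_align(c(consensus = consensus), host_genome, params)
  if (nrow(hh) == 0) return(empty)
  e_min <- min(hh$evalue)
  best <- filter(hh, .data$evalue == e_min)
  ambiguous <- nrow(best) > 1
  out <- list()
  for (i in seq_len(nrow(best))) {
    h <- best[i, ]
    # orient the consensus so its host part reads along the host + strand
    cons_f <- if (h$strand == "-") revcomp_chr(consensus) else consensus
    qs <- if (h$strand == "-") nchar(consensus) - h$qend + 1 else h$qstart
    qe <- if (h$strand == "-") nchar(consensus) - h$qstart + 1 else h$qend
    left_len <- qs - 1
    right_len <- nchar(cons_f) - qe
    take_right <- right_len >= left_len
    rem_len <- max(left_len, right_len)
    if (rem_len < params$min_len) next
    remainder <- if (take_right) substr(cons_f, qe + 1, nchar(cons_f))
                 else substr(cons_f, 1, qs - 1)
    vh <- local_align(c(rem = remainder), virus_db, params)
    if (nrow(vh) == 0) next
    v <- slice(vh, 1)
    if (take_right) {   # host 5' of virus
      host_pos <- h$send
      host_side <- "5p_host"
      virus_pos <- if (v$strand == "+") v$sstart else v$send
    } else {            # virus 5' of host
      host_pos <- h$sstart
      host_side <- "3p_host"
      virus_pos <- if (v$strand == "+") v$send else v$sstart
    }
    out[[length(out) + 1]] <- tibble(
      host_chr = h$subject, host_pos = as.integer(host_pos),
      host_side = host_side, virus_id = v$subject,
      virus_pos = as.integer(virus_pos), virus_orient = v$strand,
      exact = TRUE, ambiguous = ambiguous)
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Call integrations from refined clusters
#'
#' Runs the full per-cluster decision procedure: each oriented sub-cluster
#' gets a host breakpoint (split-read median when an `epsilon`-majority of
#' split reads agrees, estimated extremum otherwise), a virus breakpoint from
#' the strand vote, and — when split reads are absent or the host placement
#' is rank-ambiguous — a consensus-assembly fallback.  Sub-clusters whose
#' median host-hit rank exceeds 1 land in the `unreliable` table (attached as
#' an attribute and via [unreliable_calls()]) instead of the main call set.
#'
#' @param members Clustered, filtered, oriented host hit tibble.
#' @param pairs Stage-`X_chimera` pair tibble.
#' @param splits Split-read tibble from [split_read_table()].
#' @param host_genome,virus_db Named sequence vectors.
#' @param params [call_params()].
#' @param align [align_params()].
#' @return A call tibble sorted by (host_chr, host_pos, virus_id, virus_pos),
#'   filtered to `n_pairs >= params$min_support`, with attribute
#'   `unreliable` holding the median-rank > 1 calls.
#' @export
call_integrations <- function(members, pairs, splits, host_genome, virus_db,
                              params = call_params(),
                              align = align_params()) {
  members <- filter(members, .data$side %in% c("Cplus", "Cminus"))
  if (nrow(members) == 0) {
    out <- empty_calls()
    attr(out, "unreliable") <- empty_calls()
    return(out)
  }
  split_key <- paste(splits$cluster_id, splits$side)
  groups <- members %>% dplyr::group_split(.data$cluster_id, .data$side)
  rows <- list()
  for (g in groups) {
    side <- g$side[1]
    cl <- g$cluster_id[1]
    mr <- median_rank(g)
    sp <- splits[split_key == paste(cl, side), , drop = FALSE]
    n_pairs <- dplyr::n_distinct(g$read_id)
    n_split <- nrow(sp)
    est <- host_breakpoint(g)
    vb <- virus_breakpoint(g, pairs, params$epsilon)
    sref <- refine_with_split_reads(sp, params$epsilon)
    host_side <- if (side == "Cplus") "5p_host" else "3p_host"
    base_row <- tibble(
      host_chr = g$subject[1], host_pos = est$pos, host_side = host_side,
      virus_id = if (is.null(vb)) NA_character_ else vb$virus_id,
      virus_pos = if (is.null(vb)) NA_integer_ else vb$pos,
      virus_orient = if (is.null(vb)) NA_character_ else vb$orient,
      n_pairs = n_pairs, n_split = n_split, exact = FALSE, ambiguous = FALSE,
      median_rank = mr)
    if (!is.null(sref)) {
      base_row$host_pos <- sref$host_pos
      base_row$virus_pos <- sref$virus_pos
      base_row$virus_orient <- sref$orient
      if (is.null(vb)) {
        win <- filter(sp, .data$orient == sref$orient)
        base_row$virus_id <- names(sort(table(win$virus_id), decreasing = TRUE))[1]
      }
      base_row$exact <- TRUE
      rows[[length(rows) + 1]] <- base_row
      next
    }
    # no usable split reads (or no majority): consensus fallback
    cons <- assemble_consensus(g, pairs)
    cc_rows <- list()
    for (cs in cons) {
      cr <- call_from_consensus(cs, host_genome, virus_db, align)
      if (nrow(cr) > 0) cc_rows[[length(cc_rows) + 1]] <- cr
    }
    if (length(cc_rows) > 0) {
      cr <- bind_rows(cc_rows) %>%
        filter(.data$host_side == !!host_side,
               .data$host_chr == g$subject[1])
      if (nrow(cr) > 0) {
        for (i in seq_len(nrow(cr))) {
          row <- base_row
          row$host_pos <- cr$host_pos[i]
          row$virus_id <- cr$virus_id[i]
          row$virus_pos <- cr$virus_pos[i]
          row$virus_orient <- cr$virus_orient[i]
          row$exact <- TRUE
          row$ambiguous <- cr$ambiguous[i]
          rows[[length(rows) + 1]] <- row
        }
        next
      }
    }
    rows[[length(rows) + 1]] <- base_row
  }
  calls <- bind_rows(rows) %>%
    arrange(.data$host_chr, .data$host_pos, .data$virus_id, .data$virus_pos,
            .data$host_side)
  unreliable <- filter(calls, .data$median_rank > 1)
  calls <- calls %>%
    filter(.data$median_rank == 1, .data$n_pairs >= params$min_support)
  attr(calls, "unreliable") <- unreliable
  calls
}

#' Median-rank > 1 calls of a call table
#'
#' @param calls A call tibble from [call_integrations()] or a result from
#'   [detect_integrations()].
#' @return The unreliable-call tibble (clusters whose host placement is
#'   ambiguous; typically repeat regions).
#' @export
unreliable_calls <- function(calls) {
  if (inherits(calls, "vint_result")) return(calls$unreliable)
  attr(calls, "unreliable") %||% empty_calls()
}
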