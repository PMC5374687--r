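random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

str_rev <- function(x) {
  vapply(strsplit(x, ""), function(c) paste(rev(c), collapse = ""), character(1))
}

str_comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# would a local alignment anchored on one side of a junction extend past it?
# Decided by the aligner itself: Smith-Waterman of anchor+read-continuation
# against anchor+reference-continuation extends iff the optimum consumes
# subject bases beyond the anchor.  Gapped extension paths are covered, which
# a columnwise prefix-score test would miss.
alignment_extends <- function(anchor, ref_cont, read_cont) {
  if (min(nchar(ref_cont), nchar(read_cont), nchar(anchor)) == 0) return(FALSE)
  aln <- cpp_smith_waterman(paste0(anchor, read_cont), paste0(anchor, ref_cont),
                            2L, -3L, -5L, -2L)
  aln$se > nchar(anchor)
}

#' Simulate an infected genome with known integration junctions
#'
#' Generates uniform-random host chromosomes and virus strains, plants
#' non-overlapping viral integrations (each chromosome is infected by one
#' strain), and extracts every integrated region together with `flank` host
#' bases on each side — the exact material the read simulator draws from.
#' Each integration inserts an oriented virus sub-segment at a host position
#' `p`, optionally preceded by a short random insert, giving two junctions:
#' the 5' host side at `p` and the 3' host side at `p + 1`.
#'
#' Uniform-random sequence has no repeats, so host placements are unique:
#' repeat-driven false positives and rank-ambiguous clusters of real genomes
#' are under-represented by construction.
#'
#' @param params [sim_params()]; `params$seed` fixes all randomness.
#' @return An object of class `vint_sim`: a list with `host` and `viruses`
#'   (named sequence vectors), `regions` (named vector of extracted
#'   junction regions), `truth` (tibble: `host_chr`, `host_pos_5p`,
#'   `host_pos_3p`, `virus_id`, `virus_start`, `virus_end`, `virus_orient`,
#'   `random_insert_len`) and `params`.
#' @export
simulate_infected_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  per_chrom <- diff(round(seq(0, params$n_integrations,
                              length.out = params$n_chroms + 1)))
  step <- 2 * params$flank + ceiling(params$d + 4 * params$sigma) + 100
  usable <- params$host_len - 2 * params$flank
  if (any(per_chrom * step > usable)) {
    abort(sprintf(paste0("host chromosomes of %d bp cannot hold %d ",
                         "integrations with %d bp flanks and %d bp spacing"),
                  params$host_len, max(per_chrom), params$flank, step))
  }
  withr::with_seed(params$seed, {
    host <- setNames(vapply(seq_len(params$n_chroms),
                            function(i) random_dna(params$host_len),
                            character(1)),
                     paste0("chr", seq_len(params$n_chroms)))
    viruses <- setNames(vapply(seq_len(params$n_viruses),
                               function(i) random_dna(params$virus_len),
                               character(1)),
                        paste0("virus", seq_len(params$n_viruses)))
    strain_of <- rep(seq_len(params$n_viruses),
                     length.out = params$n_chroms)
    truth_rows <- list()
    regions <- character(0)
    for (ci in seq_len(params$n_chroms)) {
      n_i <- per_chrom[ci]
      if (n_i == 0) next
      slack <- usable - n_i * step
      offs <- sort(runif(n_i, 0, slack))
      pos <- as.integer(floor(params$flank + offs + (seq_len(n_i) - 1) * step +
                                step / 2))
      vseq <- viruses[[strain_of[ci]]]
      for (j in seq_len(n_i)) {
        p <- pos[j]
        # redraw the segment until no local alignment can extend across
        # either junction in either genome: such microhomology would make
        # the planted breakpoint coordinate ambiguous, so exactness would be
        # undefined rather than testable
        w <- 30
        host_right <- substr(host[[ci]], p + 1, p + w)
        host_left_rev <- str_rev(substr(host[[ci]], max(1, p - w + 1), p))
        host_tail <- substr(host[[ci]], p - w + 1, p)       # anchor before j5
        host_head_rev <- str_rev(host_right)                # anchor after j3, reversed
        for (try in 1:100) {
          L <- params$min_segment +
            sample.int(params$max_segment - params$min_segment + 1L, 1) - 1L
          vs <- sample.int(params$virus_len - L + 1L, 1)
          ve <- vs + L - 1
          orient <- sample(c("+", "-"), 1)
          ins_len <- if (runif(1) < params$insert_prob) params$insert_len else 0L
          ins <- if (ins_len > 0) random_dna(ins_len) else ""
          seg <- substr(vseq, vs, ve)
          if (orient == "-") seg <- revcomp_chr(seg)
          # reference continuations beyond the oriented segment in the virus
          virus_before_rev <- if (orient == "+") {
            str_rev(substr(vseq, max(1, vs - w), vs - 1))
          } else {
            str_comp(substr(vseq, ve + 1, min(params$virus_len, ve + w)))
          }
          virus_after <- if (orient == "+") {
            substr(vseq, ve + 1, min(params$virus_len, ve + w))
          } else {
            revcomp_chr(substr(vseq, max(1, vs - w), vs - 1))
          }
          seg_head_rev <- str_rev(substr(seg, 1, w))
          seg_tail <- substr(seg, max(1, L - w + 1), L)
          clean <-
            # 5' flank alignment extending right into insert/virus
            !alignment_extends(host_tail, host_right,
                               substr(paste0(ins, seg), 1, w)) &&
            # 3' flank alignment extending left into the virus
            !alignment_extends(host_head_rev, host_left_rev,
                               str_rev(seg_tail)) &&
            # virus alignment extending left into insert/host
            !alignment_extends(seg_head_rev, virus_before_rev,
                               substr(paste0(str_rev(ins), host_left_rev), 1, w)) &&
            # virus alignment extending right into the host
            !alignment_extends(seg_tail, virus_after, host_right)
          if (clean) break
        }
        region <- paste0(substr(host[[ci]], p - params$flank + 1, p),
                         ins, seg,
                         substr(host[[ci]], p + 1, p + params$flank))
        regions <- c(regions, setNames(region,
          sprintf("region_%s_%d", names(host)[ci], p)))
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          host_chr = names(host)[ci], host_pos_5p = p, host_pos_3p = p + 1L,
          virus_id = names(viruses)[strain_of[ci]],
          virus_start = as.integer(vs), virus_end = as.integer(vs + L - 1),
          virus_orient = orient, random_insert_len = as.integer(ins_len))
      }
    }
    structure(list(host = host, viruses = viruses, regions = regions,
                   truth = bind_rows(truth_rows), params = params),
              class = "vint_sim")
  })
}

#' @export
print.vint_sim <- function(x, ...) {
  cat(sprintf(paste0("<vint_sim> %d integrations on %d chromosome(s) ",
                     "(%d bp each), %d virus strain(s) (%d bp), flank %d bp\n"),
              nrow(x$truth), x$params$n_chroms, x$params$host_len,
              x$params$n_viruses, x$params$virus_len, x$params$flank))
  invisible(x)
}

#' Simulate paired-end reads over the extracted regions
#'
#' Draws `round(coverage * G / (2 * read_len))` fragments per region of
#' length G with insert sizes from a Gaussian `N(d, sigma)` clamped to
#' `[read_len, G]`, uniform fragment start, forward-reverse mate orientation
#' and independent per-base substitution errors.  Fully seeded.
#'
#' @param sim A `vint_sim` object (or any named character vector of regions
#'   via the `regions` argument form).
#' @param params [sim_params()] (defaults to `sim$params`).
#' @param seed Seed for the read draw (defaults to `params$seed + 1` so the
#'   genome and the reads use distinct streams).
#' @return A read-pair tibble (`id`, `seq1`, `seq2`, `qual1`, `qual2`,
#'   `source = "raw"`, `stage = "input"`).
#' @export
simulate_read_pairs <- function(sim, params = NULL, seed = NULL) {
  regions <- if (inherits(sim, "vint_sim")) sim$regions else
    as_seq_vector(sim, "regions")
  if (is.null(params)) params <- sim$params
  if (is.null(seed)) seed <- params$seed + 1L
  rl <- params$read_len
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (ri in seq_along(regions)) {
      reg <- regions[[ri]]
      G <- nchar(reg)
      if (G < rl) {
        warn(sprintf("region %s shorter than read length, skipped",
                     names(regions)[ri]))
        next
      }
      n_frag <- round(params$coverage * G / (2 * rl))
      if (n_frag == 0) next
      insert <- pmin(pmax(round(rnorm(n_frag, params$d, params$sigma)), rl), G)
      start <- 1 + floor(runif(n_frag) * (G - insert + 1))
      r1 <- substring(reg, start, start + rl - 1)
      r2 <- revcomp_chr(substring(reg, start + insert - rl, start + insert - 1))
      out[[length(out) + 1]] <- tibble(
        id = sprintf("%s_f%04d", names(regions)[ri], seq_len(n_frag)),
        seq1 = r1, seq2 = r2)
    }
    pairs <- bind_rows(out)
    if (params$subst_error_rate > 0 && nrow(pairs) > 0) {
      pairs$seq1 <- add_subst_errors(pairs$seq1, params$subst_error_rate)
      pairs$seq2 <- add_subst_errors(pairs$seq2, params$subst_error_rate)
    }
    qual <- vapply(nchar(pairs$seq1), function(n)
      paste(rep("I", n), collapse = ""), character(1))
    pairs %>% mutate(qual1 = qual, qual2 = qual, source = "raw",
                     stage = "input")
  })
}

add_subst_errors <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Randomly downsample a read-pair table
#'
#' Each pair is kept independently with probability `fraction`; a fraction of
#' 1 returns the input unchanged.
#'
#' @param pairs Read-pair tibble.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return The kept subset of `pairs`.
#' @export
downsample_pairs <- function(pairs, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(pairs)
  withr::with_seed(as.integer(seed), {
    keep <- runif(nrow(pairs)) <= fraction
    pairs[keep, ]
  })
}
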