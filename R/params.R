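#' Insert-size library statistics
#'
#' Mean and standard deviation of the sequencing library's insert size.  The
#' clustering stage links two host hits into the same cluster when they lie
#' within `d + 2 * sigma` of each other, and split-read rescue searches a host
#' window of that same width, so these two numbers control the spatial
#' resolution of the whole caller.
#'
#' @param d Mean insert size in bases (fragment length, outer distance of the
#'   mate pair).  Must be positive.
#' @param sigma Standard deviation of the insert size in bases.  Must be
#'   non-negative.
#' @return A list of class `library_stats` with elements `d` and `sigma`.
#' @seealso [estimate_library_stats()] to derive these from an alignment file.
#' @export
#' @examples
#' library_stats(300, 30)
library_stats <- function(d, sigma) {
  stopifnot(is.numeric(d), length(d) == 1, d > 0,
            is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  structure(list(d = as.numeric(d), sigma = as.numeric(sigma)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats> d = %.1f bp, sigma = %.1f bp (cluster window d + 2*sigma = %.1f bp)\n",
              x$d, x$sigma, x$d + 2 * x$sigma))
  invisible(x)
}

#' Parameters of the k-mer virus screen
#'
#' The first-pass filter slides k-mers along each mate and asks whether any of
#' them occurs in the virus database (either strand) within `r` mismatches.
#' Sampled start positions are 1, 1+s, 1+2s, ... plus the final full k-mer of
#' the mate, so read tails are always covered.
#'
#' @param k K-mer length in bases (default 18).
#' @param r Maximum Hamming mismatches allowed (default 1; at most 2).
#' @param s Shift between sampled k-mer start positions (default 5).
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(k = 18, r = 1, s = 5) {
  stopifnot(k >= 8, k <= 31, r >= 0, r <= 2, s >= 1, s <= k)
  structure(list(k = as.integer(k), r = as.integer(r), s = as.integer(s)),
            class = "screen_params")
}

#' Parameters of the sensitive local aligner
#'
#' Scoring and reporting parameters for the seed-and-extend local aligner used
#' for both the virus-database and host-genome passes.  Expect values follow
#' the Karlin-Altschul form `e = K * m * n * exp(-lambda * score)` with `m` the
#' query length and `n` the total database length; the ungapped constants are
#' applied to gapped scores, an approximation that preserves the ordering of
#' hits, which is all the downstream ranking logic consumes.
#'
#' @param match,mismatch Per-base match/mismatch scores (match > 0 > mismatch).
#' @param gap_open,gap_extend Affine gap penalties (negative); a gap of length
#'   L costs `gap_open + L * gap_extend`.
#' @param min_len Minimum alignment length in bases to report (default 25, the
#'   practical sensitivity floor of the aligner).
#' @param max_e Maximum expect value to report.
#' @param word Exact seed word length.
#' @param ka_k,ka_lambda Karlin-Altschul constants K and lambda.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2, min_len = 25, max_e = 1e-3,
                         word = 11, ka_k = 0.41, ka_lambda = 0.625) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_len >= word, word >= 4, max_e > 0, ka_k > 0, ka_lambda > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_len = as.integer(min_len), max_e = max_e,
                 word = as.integer(word), ka_k = ka_k, ka_lambda = ka_lambda),
            class = "align_params")
}

#' Parameters of integration calling
#'
#' @param epsilon Read-count margin for the virus strand vote and for
#'   promoting split-read medians to exact breakpoints (default 2): one strand
#'   cluster must contain at least `epsilon` more reads than the other to win.
#' @param min_support Minimum number of supporting read pairs for a call to be
#'   reported (default 1; use 4 for real libraries where PCR noise matters).
#' @param correctness_window Distance in bases within which a call is scored
#'   correct during evaluation (default 300).  Used only by [evaluate_calls()].
#' @return A list of class `call_params`.
#' @export
call_params <- function(epsilon = 2, min_support = 1, correctness_window = 300) {
  stopifnot(epsilon >= 1, min_support >= 1, correctness_window >= 0)
  structure(list(epsilon = as.integer(epsilon),
                 min_support = as.integer(min_support),
                 correctness_window = as.integer(correctness_window)),
            class = "call_params")
}

#' Parameters of the infected-genome simulator
#'
#' Describes a synthetic study: uniform-random host chromosomes infected by a
#' handful of virus strains, junction regions extracted with fixed host
#' flanks, and paired-end reads drawn at a target coverage with a Gaussian
#' insert-size model.  Defaults mirror a whole-genome HBV-style design:
#' four chromosomes each carrying one of four strains, 500 bp flanks, 20X
#' coverage, 100 bp reads with inserts of 300 +/- 30 bp.
#'
#' @param host_len Length of each host chromosome in bases.
#' @param n_chroms Number of host chromosomes.
#' @param n_viruses Number of virus strains (each chromosome is infected by
#'   one strain, cycling if `n_chroms > n_viruses`).
#' @param virus_len Length of each virus strain genome.
#' @param n_integrations Total number of planted integrations.
#' @param flank Host flank extracted on each side of an integration (bases).
#' @param coverage Target fold-coverage of the extracted regions.
#' @param read_len Read length in bases.
#' @param d,sigma Mean and SD of the simulated insert size.
#' @param subst_error_rate Per-base substitution error rate of the reads.
#' @param min_segment,max_segment Range of integrated virus segment lengths.
#' @param insert_prob Probability that a junction carries a short random
#'   insert between virus and the 3' host flank.
#' @param insert_len Length of that random insert when present.
#' @param seed Integer seed fixing all randomness of the simulation.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(host_len = 50000, n_chroms = 4, n_viruses = 4,
                       virus_len = 3000, n_integrations = 100, flank = 500,
                       coverage = 20, read_len = 100, d = 300, sigma = 30,
                       subst_error_rate = 0.001, min_segment = 500,
                       max_segment = 1500, insert_prob = 0, insert_len = 10,
                       seed = 1L) {
  stopifnot(flank > 0, coverage > 0, host_len > 0, n_chroms >= 1,
            n_viruses >= 1, virus_len >= max_segment, n_integrations >= 1,
            read_len > 0, d > read_len, sigma >= 0, subst_error_rate >= 0,
            min_segment <= max_segment, insert_prob >= 0, insert_prob <= 1)
  structure(list(host_len = as.integer(host_len), n_chroms = as.integer(n_chroms),
                 n_viruses = as.integer(n_viruses), virus_len = as.integer(virus_len),
                 n_integrations = as.integer(n_integrations),
                 flank = as.integer(flank), coverage = coverage,
                 read_len = as.integer(read_len), d = d, sigma = sigma,
                 subst_error_rate = subst_error_rate,
                 min_segment = as.integer(min_segment),
                 max_segment = as.integer(max_segment),
                 insert_prob = insert_prob, insert_len = as.integer(insert_len),
                 seed = as.integer(seed)),
            class = "sim_params")
}
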