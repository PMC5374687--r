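#' Build an all-hits k-mer index over a virus database
#'
#' Indexes every k-mer of every database sequence; lookups report all
#' occurrences on either strand (reverse-strand matches are resolved by
#' querying the reverse complement against the forward index, which is
#' equivalent to indexing both strands).
#'
#' @param virus_db Named character vector (or DNAStringSet) of virus genomes.
#' @param k K-mer length (matches [screen_params()]).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(virus_db, k = 18) {
  db <- as_seq_vector(virus_db, "virus database")
  short <- nchar(db) < k
  if (any(short)) {
    warn(sprintf("skipping %d database sequence(s) shorter than k = %d: %s",
                 sum(short), k, paste(names(db)[short], collapse = ", ")))
    db <- db[!short]
  }
  if (length(db) == 0) abort("no database sequence of length >= k")
  structure(list(db = db, k = as.integer(k),
                 ptr = cpp_kmer_index_build(unname(db), k)),
            class = "kmer_index")
}

# XPtr objects do not survive serialization; rebuild transparently
index_ptr <- function(index) {
  if (is.null(index$ptr) || identical(index$ptr, methods::new("externalptr")) ||
      isTRUE(tryCatch({cpp_kmer_index_lookup(index$ptr,
        substr(index$db[[1]], 1, index$k), 0); FALSE}, error = function(e) TRUE))) {
    index$ptr <- cpp_kmer_index_build(unname(index$db), index$k)
  }
  index$ptr
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d over %d sequence(s), %s bp total\n",
              x$k, length(x$db), format(sum(nchar(x$db)), big.mark = ",")))
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index A [build_kmer_index()] object.
#' @param kmer A single k-mer string (length must equal the index k).
#' @param r Maximum Hamming mismatches (0-2).
#' @return A tibble of occurrences: `virus_id`, `pos` (1-based start on the
#'   forward database strand), `strand` (`+` if the k-mer itself occurs there,
#'   `-` if its reverse complement does) and `mismatches`.
#' @export
kmer_lookup <- function(index, kmer, r = 0) {
  stopifnot(inherits(index, "kmer_index"), r >= 0, r <= 2)
  hits <- as_tibble(cpp_kmer_index_lookup(index_ptr(index), toupper(kmer), r))
  hits$virus_id <- names(index$db)[hits$seq]
  hits %>%
    select("virus_id", "pos", "strand", "mismatches") %>%
    arrange(.data$virus_id, .data$pos, .data$strand)
}

#' Screen read pairs for viral k-mer content
#'
#' First-pass filter: a pair survives when some sampled k-mer of either mate
#' (start positions 1, 1+s, 1+2s, ... plus the final full k-mer) occurs in the
#' virus database on either strand within `r` mismatches.  Surviving pairs are
#' promoted to stage `X1`.  Mates shorter than k contribute nothing.
#'
#' @param pairs Read-pair tibble (stage `input`).
#' @param index A [build_kmer_index()] object.
#' @param params [screen_params()]; its `k` must equal the index k.
#' @return The surviving pairs with `stage = "X1"`.
#' @export
screen_pairs <- function(pairs, index, params = screen_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "screen_params"))
  if (params$k != index$k) abort("screen_params k does not match index k")
  if (nrow(pairs) == 0) return(pairs)
  hit <- cpp_screen_pairs(index_ptr(index), pairs$seq1, pairs$seq2,
                          params$r, params$s)
  pairs %>% filter(hit) %>% mutate(stage = "X1")
}
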