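# shared fixture builders; everything is generated in code under fixed seeds

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# small end-to-end simulation used by several files
small_sim <- function(seed = 7L, n_integrations = 8, error = 0.001) {
  sp <- sim_params(host_len = 20000, n_chroms = 2, n_viruses = 2,
                   n_integrations = n_integrations, coverage = 20,
                   subst_error_rate = error, seed = seed)
  sim <- simulate_infected_genome(sp)
  list(sp = sp, sim = sim, pairs = simulate_read_pairs(sim),
       stats = library_stats(sp$d, sp$sigma))
}

# Smith-Waterman oracle via an independent dynamic-programming engine
sw_oracle_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend))
}

# brute-force scan of a k-mer neighbourhood over a database, both strands;
# window matrices are vectorized (and memoised per database string) so the
# oracle stays brute force in logic but affordable in time
.window_cache <- new.env(parent = emptyenv())
db_windows <- function(s, k) {
  key <- paste0(k, ":", substr(s, 1, 40), nchar(s), digest_chr(s))
  if (is.null(.window_cache[[key]])) {
    ch <- strsplit(s, "")[[1]]
    .window_cache[[key]] <- embed(ch, k)[, k:1, drop = FALSE]
  }
  .window_cache[[key]]
}
digest_chr <- function(s) sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97))

brute_kmer_scan <- function(db, kmer, r) {
  k <- nchar(kmer)
  out <- list()
  for (si in seq_along(db)) {
    m <- db_windows(db[[si]], k)
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") kmer else rc(kmer), "")[[1]]
      mm <- rowSums(m != matrix(q, nrow(m), k, byrow = TRUE))
      hit <- which(mm <= r)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- data.frame(seq = si, pos = hit,
                                             strand = strand)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq = integer(), pos = integer(), strand = character()))
  }
  do.call(rbind, out)
}

# brute-force screen of one read: sampled k-mer starts, both strands
brute_screen_read <- function(read, db, k, r, s) {
  len <- nchar(read)
  if (len < k) return(FALSE)
  starts <- unique(c(seq(1, len - k + 1, by = s), len - k + 1))
  for (p in starts) {
    kmer <- substr(read, p, p + k - 1)
    if (nrow(brute_kmer_scan(db, kmer, r)) > 0) return(TRUE)
  }
  FALSE
}

# minimal SAM writer: records is a list of character vectors of fields
write_sam <- function(records, sq = c(chrT = 2000), path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, vapply(records, paste, character(1), collapse = "\t")), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, cigar, seq, rnext = "=",
                    pnext = 1, tlen = 0, mapq = 60) {
  c(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
    paste(rep("I", nchar(seq)), collapse = ""))
}
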