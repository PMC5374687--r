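#' Read a reference genome or virus database from FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named character vector of uppercase sequences, one element per
#'   record, named by the first word of each FASTA header.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_seq_vector(x, "FASTA input")
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a paired-end FASTQ library into a read-pair table
#'
#' Mates are matched by file order; the two files must have the same number of
#' records.  Gzipped input is accepted.
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A tibble with one row per pair: `id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`, `source` (`"raw"`) and `stage` (`"input"`).
#' @export
read_pairs_fastq <- function(r1, r2) {
  a <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  b <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(a) != length(b)) {
    abort("mate FASTQ files differ in record count")
  }
  tibble(id = sub("\\s.*$", "", sub("/[12]$", "", names(a))),
         seq1 = unname(toupper(as.character(a))),
         seq2 = unname(toupper(as.character(b))),
         qual1 = unname(as.character(S4Vectors::mcols(a)$qualities)),
         qual2 = unname(as.character(S4Vectors::mcols(b)$qualities)),
         source = "raw", stage = "input")
}

#' Write a read-pair table to a pair of FASTQ files
#'
#' @param pairs A read-pair tibble as returned by [read_pairs_fastq()] or
#'   [simulate_read_pairs()].
#' @param r1,r2 Output FASTQ paths (`.gz` suffix enables compression).
#' @return `c(r1, r2)`, invisibly.
#' @export
write_pairs_fastq <- function(pairs, r1, r2) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    if (all(!is.na(quals))) {
      q <- Biostrings::BStringSet(quals)
    } else {
      q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
        paste(rep("I", n), collapse = ""), character(1)))
    }
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  write_one(pairs$seq1, pairs$qual1, pairs$id, r1)
  write_one(pairs$seq2, pairs$qual2, pairs$id, r2)
  invisible(c(r1, r2))
}

# parse the longest soft-clip run from a CIGAR string (NA-safe)
max_softclip <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("[0-9]+S", cg)[[1]]
    if (ops[1] == -1) return(0L)
    lens <- regmatches(cg, gregexpr("[0-9]+(?=S)", cg, perl = TRUE))[[1]]
    max(as.integer(lens))
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract candidate read pairs from a SAM/BAM alignment
#'
#' Pulls out the pairs worth screening for viral content: those with at least
#' one unmapped mate, or with a soft-clip run of at least `min_softclip` bases
#' on either mate.  Sequences are restored to the original forward-read
#' orientation (reverse-strand records are reverse-complemented back).
#' Only primary alignments are considered.
#'
#' @param path Path to a BAM file, or a SAM text file (converted on the fly).
#' @param min_softclip Minimum soft-clip run length that qualifies a pair.
#' @return A read-pair tibble (`source = "sam_extracted"`, `stage = "input"`).
#' @export
extract_candidate_pairs <- function(path, min_softclip = 10) {
  stopifnot(min_softclip >= 1)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual", "cigar"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(b$qname) == 0) {
    return(tibble(id = character(), seq1 = character(), seq2 = character(),
                  qual1 = character(), qual2 = character(),
                  source = character(), stage = character()))
  }
  flag <- b$flag
  rev <- bitwAnd(flag, 16L) > 0
  unmapped <- bitwAnd(flag, 4L) > 0
  first <- bitwAnd(flag, 64L) > 0
  seqs <- as.character(b$seq)
  quals <- as.character(b$qual)
  seqs[rev] <- revcomp_chr(seqs[rev])
  quals[rev] <- vapply(strsplit(quals[rev], ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  rec <- tibble(qname = b$qname, mate = ifelse(first, 1L, 2L),
                seq = toupper(seqs), qual = quals,
                unmapped = unmapped, sclip = max_softclip(b$cigar))
  wide <- rec %>%
    tidyr::pivot_wider(names_from = "mate",
                       values_from = c("seq", "qual", "unmapped", "sclip"),
                       values_fn = dplyr::first)
  needed <- c("seq_1", "seq_2", "qual_1", "qual_2",
              "unmapped_1", "unmapped_2", "sclip_1", "sclip_2")
  missing_cols <- setdiff(needed, names(wide))
  for (cn in missing_cols) wide[[cn]] <- NA
  orphan <- is.na(wide$seq_1) | is.na(wide$seq_2)
  if (any(orphan)) {
    warn(sprintf("%d unpaired record(s) without a mate skipped", sum(orphan)))
    wide <- wide[!orphan, ]
  }
  keep <- wide$unmapped_1 | wide$unmapped_2 |
    wide$sclip_1 >= min_softclip | wide$sclip_2 >= min_softclip
  out <- wide[keep, ]
  tibble(id = out$qname, seq1 = out$seq_1, seq2 = out$seq_2,
         qual1 = out$qual_1, qual2 = out$qual_2,
         source = "sam_extracted", stage = "input") %>%
    arrange(.data$id)
}

#' Estimate insert-size statistics from concordant pairs
#'
#' @param path Path to a BAM (or SAM) file with paired alignments.
#' @param max_pairs Cap on the number of proper pairs used.
#' @return A [library_stats()] object with `d` = mean and `sigma` = sample SD
#'   of the absolute template lengths of properly paired primary alignments.
#' @export
estimate_library_stats <- function(path, max_pairs = 100000) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("isize"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  tlen <- b$isize
  tlen <- tlen[!is.na(tlen) & tlen > 0]   # one record per pair
  if (length(tlen) < 100) {
    abort(paste0("only ", length(tlen), " proper pairs found (>= 100 needed); ",
                 "supply d and sigma explicitly via library_stats()"))
  }
  tlen <- head(tlen, max_pairs)
  library_stats(mean(tlen), if (length(tlen) > 1) sd(tlen) else 0)
}

call_table_cols <- c("host_chr", "host_pos", "host_side", "virus_id",
                     "virus_pos", "virus_orient", "n_pairs", "n_split",
                     "exact", "ambiguous", "median_rank")

#' Write an integration call table
#'
#' Tab-delimited, 1-based coordinates, deterministically sorted by host
#' chromosome, host position, virus id and virus position.  Calls whose virus
#' side could not be resolved carry empty virus fields.
#'
#' @param calls A call tibble as produced by [call_integrations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (nrow(calls) == 0) {
    calls <- empty_calls()
  }
  out <- calls %>%
    select(dplyr::all_of(call_table_cols)) %>%
    mutate(exact = as.integer(.data$exact),
           ambiguous = as.integer(.data$ambiguous)) %>%
    arrange(.data$host_chr, .data$host_pos, .data$virus_id, .data$virus_pos)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read an integration call table written by [write_calls()]
#' @param path Path to the TSV.
#' @return A call tibble.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    host_chr = readr::col_character(), host_pos = readr::col_integer(),
    host_side = readr::col_character(), virus_id = readr::col_character(),
    virus_pos = readr::col_integer(), virus_orient = readr::col_character(),
    n_pairs = readr::col_integer(), n_split = readr::col_integer(),
    exact = readr::col_integer(), ambiguous = readr::col_integer(),
    median_rank = readr::col_integer()), na = "")
}

#' Write / read the simulation truth table
#'
#' @param truth A truth tibble from [simulate_infected_genome()].
#' @param path Path to the TSV.
#' @return `path` (write) or the truth tibble (read).
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    host_chr = readr::col_character(), host_pos_5p = readr::col_integer(),
    host_pos_3p = readr::col_integer(), virus_id = readr::col_character(),
    virus_start = readr::col_integer(), virus_end = readr::col_integer(),
    virus_orient = readr::col_character(),
    random_insert_len = readr::col_integer()))
}
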