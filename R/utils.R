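# shared internal helpers

revcomp_chr <- function(x) cpp_revcomp(x)

# lower median: for even n, the smaller of the two central order statistics
lower_median <- function(x) {
  stopifnot(length(x) > 0)
  sort(x)[ceiling(length(x) / 2)]
}

# named character vector of uppercase sequences from a DNAStringSet or
# character input; names are required
as_seq_vector <- function(x, what = "sequence set") {
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    abort(sprintf("%s must be a named character vector or DNAStringSet", what))
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    abort(sprintf("%s must have names", what))
  }
  out
}

empty_hits <- function() {
  tibble(read_id = character(), mate = integer(), query_id = character(),
         qstart = integer(), qend = integer(), qlen = integer(),
         subject = character(), sstart = integer(), send = integer(),
         strand = character(), score = integer(), matches = integer(),
         length = integer(), evalue = double(), rank = integer())
}

empty_calls <- function() {
  tibble(host_chr = character(), host_pos = integer(), host_side = character(),
         virus_id = character(), virus_pos = integer(), virus_orient = character(),
         n_pairs = integer(), n_split = integer(), exact = integer(),
         ambiguous = integer(), median_rank = integer())
}
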