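# builders for hand-laid-out pairs: hit tables carry the columns the refine
# stage actually consumes
hit_row <- function(read_id, mate, qstart, qend, subject, sstart, send,
                    strand = "+", evalue = 1e-30, rank = 1L, qlen = 100L) {
  tibble::tibble(read_id = read_id, mate = as.integer(mate),
                 qstart = as.integer(qstart), qend = as.integer(qend),
                 qlen = qlen, subject = subject, sstart = as.integer(sstart),
                 send = as.integer(send), strand = strand, score = 100L,
                 matches = 50L, length = qend - qstart + 1L, evalue = evalue,
                 rank = rank)
}

mk_pair_tbl <- function(ids, host_hits, virus_hits, seq1 = NULL, seq2 = NULL) {
  n <- length(ids)
  tibble::tibble(id = ids,
                 seq1 = seq1 %||% replicate(n, rand_dna(100)),
                 seq2 = seq2 %||% replicate(n, rand_dna(100)),
                 qual1 = NA_character_, qual2 = NA_character_,
                 source = "raw", stage = "X_chimera",
                 virus_hits = virus_hits, host_hits = host_hits)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

members_of <- function(pairs, stats = library_stats(300, 30)) {
  cluster_hits(host_hit_table(pairs), stats)
}

test_that("reads with a host segment between viral segments are discarded", {
  hostA <- hit_row("cplx", 1, 36, 70, "chr1", 1000, 1034)
  virusA <- dplyr::bind_rows(hit_row("cplx", 1, 1, 30, "v1", 200, 229),
                             hit_row("cplx", 1, 76, 100, "v1", 500, 524))
  clean_host <- hit_row("ok", 1, 1, 100, "chr1", 1200, 1299)
  clean_virus <- hit_row("ok", 2, 1, 100, "v1", 300, 399)
  pairs <- mk_pair_tbl(c("cplx", "ok"),
                       host_hits = list(hostA, clean_host),
                       virus_hits = list(virusA, clean_virus))
  m <- members_of(pairs)
  kept <- filter_complex(m, pairs)
  expect_setequal(unique(kept$read_id), "ok")
})

test_that("host-host pairs must be same-chromosome and forward-reverse", {
  cross <- dplyr::bind_rows(hit_row("x", 1, 1, 100, "chr1", 1000, 1099),
                            hit_row("x", 2, 1, 100, "chr7", 5000, 5099))
  same_fr <- dplyr::bind_rows(
    hit_row("s", 1, 1, 100, "chr1", 1000, 1099, strand = "+"),
    hit_row("s", 2, 1, 100, "chr1", 1280, 1379, strand = "-"))
  same_ff <- dplyr::bind_rows(
    hit_row("f", 1, 1, 100, "chr1", 1500, 1599, strand = "+"),
    hit_row("f", 2, 1, 100, "chr1", 1700, 1799, strand = "+"))
  pairs <- mk_pair_tbl(c("x", "s", "f"),
                       host_hits = list(cross, same_fr, same_ff),
                       virus_hits = list(hit_row("x", 1, 1, 20, "v1", 1, 20),
                                         hit_row("s", 1, 1, 20, "v1", 1, 20),
                                         hit_row("f", 1, 1, 20, "v1", 1, 20)))
  kept <- filter_complex(members_of(pairs), pairs)
  expect_setequal(unique(kept$read_id), "s")
})

test_that("duplicate collapsing keeps one copy and is optional and idempotent", {
  h <- function(id) hit_row(id, 1, 1, 100, "chr1", 1000, 1099)
  v <- function(id) hit_row(id, 2, 1, 100, "v1", 300, 399)
  shifted <- hit_row("c", 1, 1, 100, "chr1", 1001, 1100)
  pairs <- mk_pair_tbl(c("b", "a", "c"),
                       host_hits = list(h("b"), h("a"), shifted),
                       virus_hits = list(v("b"), v("a"), v("c")))
  m <- members_of(pairs)
  dd <- dedupe_pairs(m, pairs, enabled = TRUE)
  expect_setequal(unique(dd$read_id), c("a", "c"))  # smallest id survives
  expect_equal(dedupe_pairs(dd, pairs, enabled = TRUE), dd)  # idempotent
  off <- dedupe_pairs(m, pairs, enabled = FALSE)
  expect_equal(off, m)
  expect_lte(nrow(dd), nrow(m))
})

test_that("rescue recovers a short host segment from the anchor flank", {
  host <- c(chr1 = rand_dna(3000, seed = 90))
  st <- library_stats(300, 30)
  # mate1: anchor, fully host at [1000, 1099], + strand
  # mate2: 80 bp virus + 20 bp host segment copied from position 1280..1299
  seg <- substr(host, 1281, 1300)
  virus_part <- rand_dna(80)
  anchor_hit <- hit_row("p", 1, 1, 100, "chr1", 1000, 1099)
  virus_hit <- hit_row("p", 2, 1, 80, "v1", 101, 180)
  pairs <- mk_pair_tbl("p", host_hits = list(anchor_hit),
                       virus_hits = list(virus_hit),
                       seq1 = substr(host, 1000, 1099),
                       seq2 = paste0(virus_part, seg))
  m <- partition_orientation(members_of(pairs, st))
  got <- rescue_split_reads(m, pairs, host, st)
  expect_equal(nrow(got), 1L)
  expect_equal(got$origin, "rescued")
  expect_equal(got$host_junction, 1281L)         # junction-facing end
  expect_equal(got$query_breakpos, 81L)
  # the rescued coordinate stays inside the d + 2 sigma window
  expect_lte(got$host_junction, 1099 + 360)
  expect_gte(got$host_junction, 1000)
})

test_that("rescue is not attempted below the unaligned-length floor", {
  host <- c(chr1 = rand_dna(2000, seed = 91))
  st <- library_stats(300, 30)
  seg8 <- substr(host, 1201, 1208)
  anchor_hit <- hit_row("p", 1, 1, 100, "chr1", 1000, 1099)
  virus_hit <- hit_row("p", 2, 1, 92, "v1", 101, 192)
  pairs <- mk_pair_tbl("p", host_hits = list(anchor_hit),
                       virus_hits = list(virus_hit),
                       seq1 = substr(host, 1000, 1099),
                       seq2 = paste0(rand_dna(92), seg8))
  m <- partition_orientation(members_of(pairs, st))
  expect_equal(nrow(rescue_split_reads(m, pairs, host, st)), 0L)
})

test_that("rescue decisions agree with the Smith-Waterman DP oracle", {
  set.seed(92)
  st <- library_stats(300, 30)
  for (i in 1:10) {
    host <- c(chr1 = rand_dna(2500))
    inside <- i %% 2 == 0
    reversed <- i %% 4 == 0
    seg <- if (inside) substr(host, 1300, 1329) else rand_dna(30)
    if (inside && reversed) seg <- rc(seg)
    pairs <- mk_pair_tbl("p", host_hits = list(hit_row("p", 1, 1, 100, "chr1", 1000, 1099)),
                         virus_hits = list(hit_row("p", 2, 1, 70, "v1", 101, 170)),
                         seq1 = substr(host, 1000, 1099),
                         seq2 = paste0(rand_dna(70), seg))
    m <- partition_orientation(members_of(pairs, st))
    got <- rescue_split_reads(m, pairs, host, st)
    win <- substr(host, 1000, 1099 + 360)
    oracle <- max(sw_oracle_score(seg, win), sw_oracle_score(rc(seg), win))
    if (inside) {
      # a planted exact 30-mer (either orientation) is always rescued at the
      # exact junction: full-length DP optimum, 100% identity
      expect_equal(oracle, 60)
      expect_equal(nrow(got), 1L)
      # forward segment: junction at its window-left end; reverse-complement
      # segment: the virus-adjacent base maps to the window-right end
      expect_equal(got$host_junction, if (reversed) 1329L else 1300L)
    } else if (nrow(got) == 1) {
      # a chance acceptance must still satisfy the DP thresholds inside the
      # window: >= 90% identity over >= 10 bases scores at least 15
      expect_gte(oracle, 15)
      expect_gte(got$host_junction, 1000L)
      expect_lte(got$host_junction, 1099L + 360L)
    } else {
      # rejected: no full-identity 30-mer can be present
      expect_lt(oracle, 60)
    }
  }
})
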