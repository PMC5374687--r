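side_hits <- function(sstart, send, side = "Cplus", read_id = NULL,
                      strand = "+", rank = 1L, subject = "chr1") {
  n <- length(sstart)
  tibble::tibble(
    read_id = read_id %||% paste0("r", seq_len(n)), mate = 1L,
    qstart = 1L, qend = 100L, qlen = 100L, subject = subject,
    sstart = as.integer(sstart), send = as.integer(send),
    strand = rep_len(strand, n), score = 200L, matches = 100L, length = 100L,
    evalue = 1e-30, rank = rep_len(as.integer(rank), n),
    cluster_id = paste0(subject, ":0"), side = side)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

vhit <- function(read_id, strand, sstart, send, mate = 2L, subject = "v1",
                 evalue = 1e-30) {
  tibble::tibble(read_id = read_id, mate = as.integer(mate), qstart = 1L,
                 qend = 100L, qlen = 100L, subject = subject,
                 sstart = as.integer(sstart), send = as.integer(send),
                 strand = strand, score = 100L, matches = 50L, length = 100L,
                 evalue = evalue)
}

vpair_tbl <- function(ids, vhits, seq1 = NULL, seq2 = NULL) {
  n <- length(ids)
  tibble::tibble(id = ids,
                 seq1 = seq1 %||% rep("ACGT", n),
                 seq2 = seq2 %||% rep("ACGT", n),
                 qual1 = NA_character_, qual2 = NA_character_,
                 source = "raw", stage = "X_chimera",
                 virus_hits = vhits, host_hits = vector("list", n))
}

test_that("host breakpoint is the junction-proximal alignment extremum", {
  cp <- side_hits(c(1000, 1040), c(1099, 1139), side = "Cplus")
  expect_equal(host_breakpoint(cp), list(pos = 1139L, exact = FALSE))
  cm <- side_hits(c(2000, 2050), c(2099, 2149), side = "Cminus")
  expect_equal(host_breakpoint(cm), list(pos = 2000L, exact = FALSE))
  expect_error(host_breakpoint(cp[0, ]), "empty")
})

test_that("a split read overrides the estimate with the exact position", {
  cp <- side_hits(c(1000, 1040), c(1099, 1139), side = "Cplus")
  sp <- tibble::tibble(host_junction = c(1130L, 1130L, 1131L))
  got <- host_breakpoint(cp, sp)
  expect_true(got$exact)
  expect_equal(got$pos, 1130L)   # lower median
})

test_that("the virus strand vote needs an epsilon margin", {
  mk <- function(n_plus, n_minus) {
    ids <- paste0("p", seq_len(n_plus + n_minus))
    hits <- lapply(seq_along(ids), function(i) {
      vhit(ids[i], if (i <= n_plus) "+" else "-", 500 + 10 * i, 850 + 10 * i)
    })
    list(members = side_hits(rep(1000, length(ids)), rep(1099, length(ids)),
                             side = "Cplus", read_id = ids),
         pairs = vpair_tbl(ids, hits))
  }
  x <- mk(5, 2)
  got <- virus_breakpoint(x$members, x$pairs, epsilon = 2)
  expect_equal(c(got$n_plus, got$n_minus), c(5L, 2L))
  # Cplus won by the + strand: reverse-oriented integration, 3'-most proximal
  expect_equal(got$orient, "-")
  expect_equal(got$pos, 900L)
  tie <- mk(3, 2)
  expect_null(virus_breakpoint(tie$members, tie$pairs, epsilon = 2))
  none <- mk(2, 0)
  none$pairs$virus_hits <- list(NULL, NULL)
  expect_null(virus_breakpoint(none$members, none$pairs, epsilon = 2))
})

test_that("a minus-strand winner under a Cplus cluster gives the 5'-most position", {
  ids <- paste0("p", 1:4)
  hits <- lapply(seq_along(ids), function(i)
    vhit(ids[i], "-", 500 + 50 * (i - 1), 650 + 50 * (i - 1)))
  members <- side_hits(rep(1000, 4), rep(1099, 4), side = "Cplus", read_id = ids)
  got <- virus_breakpoint(members, vpair_tbl(ids, hits), epsilon = 2)
  expect_equal(got$orient, "+")
  expect_equal(got$pos, 500L)
})

test_that("split-read refinement takes medians under an epsilon majority", {
  sp <- function(orients, host = 1000L) {
    tibble::tibble(host_junction = rep(host, length(orients)),
                   virus_junction = 2000L, orient = orients)
  }
  three <- sp(rep("+", 3))
  three$host_junction <- c(1000L, 1001L, 1000L)
  got <- refine_with_split_reads(three, epsilon = 2)
  expect_equal(got$host_pos, 1000L)
  expect_true(got$exact)
  expect_equal(got$orient, "+")
  expect_null(refine_with_split_reads(sp(c("+", "+", "-")), epsilon = 2))
  expect_null(refine_with_split_reads(sp(character(0)), epsilon = 2))
})

consensus_fixture <- function(mut_overlap = 0) {
  set.seed(100 + mut_overlap)
  backbone <- rand_dna(160)
  r1 <- substr(backbone, 1, 100)
  r2 <- substr(backbone, 61, 160)
  if (mut_overlap > 0) {
    cs <- strsplit(r2, "")[[1]]
    for (j in sample(1:40, mut_overlap))
      cs[j] <- sample(setdiff(c("A", "C", "G", "T"), cs[j]), 1)
    r2 <- paste(cs, collapse = "")
  }
  members <- tibble::tibble(
    read_id = c("a", "b"), mate = 1L, qstart = 1L, qend = 100L, qlen = 100L,
    subject = "chr1", sstart = c(1000L, 1060L), send = c(1099L, 1159L),
    strand = "+", score = 200L, matches = 100L, length = 100L,
    evalue = 1e-30, rank = 1L, cluster_id = "chr1:0", side = "Cplus")
  pairs <- tibble::tibble(
    id = c("a", "b"), seq1 = c(r1, r2), seq2 = "ACGT",
    qual1 = NA_character_, qual2 = NA_character_, source = "raw",
    stage = "X_chimera", virus_hits = list(NULL, NULL),
    host_hits = list(NULL, NULL))
  list(backbone = backbone, members = members, pairs = pairs)
}

test_that("consensus assembly merges long, similar overlaps and no others", {
  fx <- consensus_fixture()
  expect_equal(assemble_consensus(fx$members, fx$pairs), fx$backbone)
  # 40 bp overlap at 72.5% identity (11 mutations): below the >75% bar
  bad <- consensus_fixture(mut_overlap = 11)
  expect_equal(length(assemble_consensus(bad$members, bad$pairs)), 0L)
  # a 20 bp overlap is too short regardless of identity
  short <- consensus_fixture()
  short$pairs$seq1[2] <- substr(paste0(short$backbone, rand_dna(60)), 81, 180)
  short$members$sstart[2] <- 1080L
  short$members$send[2] <- 1179L
  expect_equal(length(assemble_consensus(short$members, short$pairs)), 0L)
})

test_that("a consensus with a unique host placement yields one exact call", {
  set.seed(110)
  host <- c(chr1 = rand_dna(600))
  virus <- c(v1 = rand_dna(400))
  cons <- paste0(substr(host, 101, 180), substr(virus, 201, 260))
  got <- call_from_consensus(cons, host, virus)
  expect_equal(nrow(got), 1L)
  expect_equal(got$host_chr, "chr1")
  expect_equal(got$host_pos, 180L)
  expect_equal(got$host_side, "5p_host")
  expect_equal(got$virus_pos, 201L)
  expect_equal(got$virus_orient, "+")
  expect_true(got$exact)
  expect_false(got$ambiguous)
  # all-host consensus with no viral remainder: no call
  expect_equal(nrow(call_from_consensus(substr(host, 101, 220), host, virus)), 0L)
})

test_that("tied host placements give multiple calls marked ambiguous", {
  set.seed(111)
  unit <- rand_dna(80)
  host <- c(chr1 = paste0(rand_dna(60), unit, rand_dna(100), unit, rand_dna(60)))
  virus <- c(v1 = rand_dna(400))
  cons <- paste0(unit, substr(virus, 101, 160))
  got <- call_from_consensus(cons, host, virus)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$ambiguous))
  expect_setequal(got$host_pos, c(60L + 80L, 60L + 80L + 100L + 80L))
})

test_that("median-rank filtering routes ambiguous clusters to the unreliable set", {
  ids <- paste0("p", 1:4)
  vh <- lapply(ids, function(id) vhit(id, "-", 500, 650))
  good <- side_hits(rep(1000, 4), rep(1099, 4), read_id = ids, rank = 1L)
  bad <- side_hits(rep(30000, 4), rep(30099, 4), read_id = ids, rank = 2L)
  bad$cluster_id <- "chr1:9"
  members <- dplyr::bind_rows(good, bad)
  pairs <- vpair_tbl(ids, vh)
  calls <- call_integrations(members, pairs, vintegrate:::empty_splits(),
                             c(chr1 = rand_dna(200, seed = 1)), c(v1 = rand_dna(50)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$host_pos, 1099L)
  expect_equal(calls$median_rank, 1L)
  unre <- unreliable_calls(calls)
  expect_equal(nrow(unre), 1L)
  expect_equal(unre$median_rank, 2L)
})

test_that("an inconclusive virus vote still yields a host-only call", {
  ids <- paste0("p", 1:4)
  vh <- lapply(seq_along(ids), function(i)
    vhit(ids[i], if (i %% 2 == 0) "+" else "-", 500, 650))
  members <- side_hits(rep(1000, 4), rep(1099, 4), read_id = ids)
  calls <- call_integrations(members, vpair_tbl(ids, vh),
                             vintegrate:::empty_splits(),
                             c(chr1 = rand_dna(200, seed = 2)),
                             c(v1 = rand_dna(50)))
  expect_equal(nrow(calls), 1L)
  expect_true(is.na(calls$virus_id))
  expect_true(is.na(calls$virus_orient))
  expect_equal(calls$host_pos, 1099L)
})

test_that("raising the support floor never adds calls", {
  ids <- paste0("p", 1:4)
  vh <- lapply(ids, function(id) vhit(id, "-", 500, 650))
  members <- side_hits(rep(1000, 4), rep(1099, 4), read_id = ids)
  pairs <- vpair_tbl(ids, vh)
  host <- c(chr1 = rand_dna(200, seed = 3)); virus <- c(v1 = rand_dna(50))
  sizes <- vapply(1:6, function(ms) {
    nrow(call_integrations(members, pairs, vintegrate:::empty_splits(),
                           host, virus, call_params(min_support = ms)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[5], 0L)   # only 4 supporting pairs exist
})
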