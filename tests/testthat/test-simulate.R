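test_that("extracted regions are flank + oriented segment + flank", {
  sp <- sim_params(host_len = 6000, n_chroms = 1, n_viruses = 1,
                   n_integrations = 1, flank = 500, min_segment = 700,
                   max_segment = 700, seed = 3L)
  sim <- simulate_infected_genome(sp)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(nchar(sim$regions), 500L + 700L + 500L, ignore_attr = TRUE)
  tr <- sim$truth
  host <- sim$host[[tr$host_chr]]
  seg <- substr(sim$viruses[[tr$virus_id]], tr$virus_start, tr$virus_end)
  if (tr$virus_orient == "-") seg <- rc(seg)
  want <- paste0(substr(host, tr$host_pos_5p - 499, tr$host_pos_5p), seg,
                 substr(host, tr$host_pos_3p, tr$host_pos_3p + 499))
  expect_equal(unname(sim$regions), want)
})

test_that("minus-orientation integrations carry the reverse complement", {
  # draw seeds until an orient = '-' single integration appears
  for (seed in 1:20) {
    sp <- sim_params(host_len = 6000, n_chroms = 1, n_viruses = 1,
                     n_integrations = 1, min_segment = 600, max_segment = 600,
                     seed = seed)
    sim <- simulate_infected_genome(sp)
    if (sim$truth$virus_orient == "-") break
  }
  expect_equal(sim$truth$virus_orient, "-")
  seg <- substr(sim$viruses[[1]], sim$truth$virus_start, sim$truth$virus_end)
  expect_equal(substr(sim$regions, 501, 1100), rc(seg), ignore_attr = TRUE)
})

test_that("a host too small for the requested integrations errors", {
  expect_error(simulate_infected_genome(
    sim_params(host_len = 1000, n_chroms = 1, n_integrations = 2,
               flank = 500)), "cannot hold")
})

test_that("read counts follow coverage * G / (2 * read_len)", {
  sp <- sim_params(host_len = 6000, n_chroms = 1, n_viruses = 1,
                   n_integrations = 1, flank = 500, min_segment = 700,
                   max_segment = 700, coverage = 20, read_len = 100, seed = 4L)
  sim <- simulate_infected_genome(sp)
  pairs <- simulate_read_pairs(sim)
  expect_equal(nrow(pairs), round(20 * 1700 / 200))   # 170
  expect_true(all(nchar(pairs$seq1) == 100))
  expect_true(all(nchar(pairs$seq2) == 100))
})

test_that("error-free reads are exact strand-aware substrings of their region", {
  sp <- sim_params(host_len = 6000, n_chroms = 1, n_viruses = 1,
                   n_integrations = 2, subst_error_rate = 0, seed = 5L)
  sim <- simulate_infected_genome(sp)
  pairs <- simulate_read_pairs(sim)
  region_of <- sub("_f[0-9]+$", "", pairs$id)
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    reg <- sim$regions[[region_of[i]]]
    grepl(pairs$seq1[i], reg, fixed = TRUE) &&
      grepl(rc(pairs$seq2[i]), reg, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("observed insert sizes match the Gaussian model", {
  region <- c(big = rand_dna(5000, seed = 6))
  sp <- sim_params(host_len = 6000, n_chroms = 1, n_integrations = 1,
                   coverage = 400, read_len = 100, d = 300, sigma = 30,
                   subst_error_rate = 0, seed = 6L)
  pairs <- simulate_read_pairs(region, params = sp, seed = 99L)
  expect_gte(nrow(pairs), 1e4)
  r1_start <- vapply(pairs$seq1, function(s)
    regexpr(s, region, fixed = TRUE)[1], numeric(1), USE.NAMES = FALSE)
  r2_end <- vapply(pairs$seq2, function(s)
    regexpr(rc(s), region, fixed = TRUE)[1] + 99, numeric(1), USE.NAMES = FALSE)
  insert <- r2_end - r1_start + 1
  se <- 30 / sqrt(length(insert))
  expect_lt(abs(mean(insert) - 300), 3 * se + 0.5)  # rounding slack
  expect_lt(abs(sd(insert) - 30), 2)
})

test_that("downsampling is an independent thinning with the marginal rate", {
  sp <- sim_params(seed = 8L)
  pairs <- tibble::tibble(id = paste0("p", 1:10000), seq1 = "A", seq2 = "A",
                          qual1 = NA_character_, qual2 = NA_character_,
                          source = "raw", stage = "input")
  expect_identical(downsample_pairs(pairs, 1), pairs)
  kept <- downsample_pairs(pairs, 0.5, seed = 12L)
  ci <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.5)
  expect_gte(nrow(kept), ci[1]); expect_lte(nrow(kept), ci[2])
  # seeded determinism
  expect_identical(downsample_pairs(pairs, 0.5, seed = 12L), kept)
  kept25 <- downsample_pairs(pairs, 0.25, seed = 13L)
  ci25 <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.25)
  expect_gte(nrow(kept25), ci25[1]); expect_lte(nrow(kept25), ci25[2])
})

test_that("the same seed reproduces genomes and reads byte for byte", {
  sp <- sim_params(host_len = 8000, n_chroms = 1, n_integrations = 2, seed = 9L)
  a <- simulate_infected_genome(sp); b <- simulate_infected_genome(sp)
  expect_identical(a, b)
  pa <- simulate_read_pairs(a); pb <- simulate_read_pairs(b)
  expect_identical(pa, pb)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_pairs_fastq(pa, f1, f2); write_pairs_fastq(pb, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("scoring matches calls within the window and orientation", {
  truth <- tibble::tibble(host_chr = "chr1", host_pos_5p = 5000L,
                          host_pos_3p = 5001L, virus_id = "v1",
                          virus_start = 100L, virus_end = 800L,
                          virus_orient = "+", random_insert_len = 0L)
  call_row <- function(pos, side = "5p_host", orient = "+") {
    tibble::tibble(host_chr = "chr1", host_pos = as.integer(pos),
                   host_side = side, virus_id = "v1", virus_pos = 100L,
                   virus_orient = orient, n_pairs = 5L, n_split = 1L,
                   exact = TRUE, ambiguous = FALSE, median_rank = 1L)
  }
  within <- evaluate_calls(call_row(5000 + 299), truth, window = 300)
  expect_equal(c(within$tp, within$fp), c(1L, 0L))
  beyond <- evaluate_calls(call_row(5000 + 301), truth, window = 300)
  expect_equal(c(beyond$tp, beyond$fp), c(0L, 1L))
  flipped <- evaluate_calls(call_row(5000, orient = "-"), truth, window = 300)
  expect_equal(c(flipped$tp, flipped$fp), c(0L, 1L))
  # side must match too: a 3p-side call cannot claim the 5p junction
  wrong_side <- evaluate_calls(call_row(5000, side = "3p_host"), truth,
                               window = 300)
  expect_equal(wrong_side$tp, 1L)  # but it may claim the 3p junction at 5001
  # bookkeeping identities
  both <- evaluate_calls(dplyr::bind_rows(call_row(5000),
                                          call_row(5001, "3p_host")), truth)
  expect_equal(both$tp + both$fn, 2L)
  expect_equal(both$tp + both$fp, 2L)
  expect_equal(both$sensitivity, 1)
})
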