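#' Run the full integration-detection pipeline
#'
#' Orchestrates every stage over a read-pair table: virus k-mer screen (X1),
#' virus-alignment confirmation (X2), host-alignment confirmation
#' (X_chimera), positional clustering, cluster refinement (complex-read
#' filter, optional duplicate collapse, split-read rescue) and breakpoint
#' calling.  The input can come from raw FASTQ ([read_pairs_fastq()]; every
#' pair is screened) or from a host alignment
#' ([extract_candidate_pairs()]; only soft-clipped/unmapped-mate pairs are
#' screened).  Stage cardinalities are logged in the result's `funnel` so the
#' X1 >= X2 >= X_chimera contraction is auditable.
#'
#' @param pairs Read-pair tibble.
#' @param host_genome,virus_db Named sequence vectors (or DNAStringSets, or
#'   FASTA paths).
#' @param stats [library_stats()].
#' @param screen [screen_params()].
#' @param align [align_params()].
#' @param call [call_params()].
#' @param dedupe Collapse identically aligned pairs (default `TRUE`).
#' @param min_unaligned,min_identity,min_span Split-read rescue thresholds,
#'   see [rescue_split_reads()].
#' @param verbose Log stage cardinalities with [message()].
#' @return An object of class `vint_result`: list with `calls` (the call
#'   tibble), `unreliable` (median-rank > 1 calls), `splits`, `funnel`
#'   (stage/count tibble) and the parameter objects used.
#' @export
detect_integrations <- function(pairs, host_genome, virus_db, stats,
                                screen = screen_params(),
                                align = align_params(),
                                call = call_params(), dedupe = TRUE,
                                min_unaligned = 10, min_identity = 0.9,
                                min_span = 10, verbose = FALSE) {
  host <- if (is.character(host_genome) && length(host_genome) == 1 &&
              file.exists(host_genome)) read_genome(host_genome)
          else as_seq_vector(host_genome, "host genome")
  virus <- if (is.character(virus_db) && length(virus_db) == 1 &&
               file.exists(virus_db)) read_genome(virus_db)
           else as_seq_vector(virus_db, "virus database")
  say <- function(...) if (verbose) inform(sprintf(...))
  funnel <- list()
  log_stage <- function(stage, n) {
    funnel[[length(funnel) + 1]] <<- tibble(stage = stage, n_pairs = n)
    say("%-10s %d pairs", stage, n)
  }
  log_stage("input", nrow(pairs))
  index <- build_kmer_index(virus, screen$k)
  x1 <- screen_pairs(pairs, index, screen)
  log_stage("X1", nrow(x1))
  x2 <- build_x2(x1, virus, align)
  log_stage("X2", nrow(x2))
  chim <- build_x_chimera(x2, host, align)
  log_stage("X_chimera", nrow(chim))
  members <- host_hit_table(chim) %>%
    cluster_hits(stats) %>%
    filter_complex(chim) %>%
    dedupe_pairs(chim, enabled = dedupe) %>%
    partition_orientation()
  say("clusters   %d", dplyr::n_distinct(members$cluster_id))
  splits <- split_read_table(members, chim, host, stats, min_unaligned,
                             min_identity, min_span, align)
  say("split reads %d", nrow(splits))
  calls <- call_integrations(members, chim, splits, host, virus, call, align)
  say("calls      %d (+%d unreliable)", nrow(calls),
      nrow(unreliable_calls(calls)))
  structure(list(calls = tibble::as_tibble(calls),
                 unreliable = unreliable_calls(calls),
                 splits = splits,
                 funnel = bind_rows(funnel),
                 stats = stats, screen = screen, align = align,
                 call = call),
            class = "vint_result")
}

#' @export
print.vint_result <- function(x, ...) {
  cat("<vint_result>\n")
  f <- x$funnel
  cat(paste0("  ", format(f$stage, width = 10), " ", f$n_pairs,
             collapse = "\n"), "\n")
  cat(sprintf("  calls: %d (%d exact, %d ambiguous); unreliable: %d\n",
              nrow(x$calls), sum(x$calls$exact), sum(x$calls$ambiguous),
              nrow(x$unreliable)))
  invisible(x)
}

#' @export
tidy.vint_result <- function(x, ...) x$calls

#' @export
glance.vint_result <- function(x, ...) {
  f <- setNames(as.list(x$funnel$n_pairs), paste0("n_", x$funnel$stage))
  dplyr::bind_cols(
    tibble(n_calls = nrow(x$calls), n_exact = sum(x$calls$exact),
           n_ambiguous = sum(x$calls$ambiguous),
           n_split_reads = nrow(x$splits),
           n_unreliable = nrow(x$unreliable)),
    tibble::as_tibble(f))
}

#' @export
autoplot.vint_result <- function(object, ...) {
  f <- object$funnel %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$stage, y = .data$n_pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "read pairs (log scale)",
                  title = "Chimeric-read screening funnel") +
    ggplot2::theme_minimal()
}
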