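# expand each simulated integration into its two side-specific junctions
truth_junctions <- function(truth) {
  bind_rows(
    truth %>% mutate(host_side = "5p_host", pos = .data$host_pos_5p),
    truth %>% mutate(host_side = "3p_host", pos = .data$host_pos_3p)) %>%
    mutate(junction_id = row_number()) %>%
    select("junction_id", "host_chr", "host_side", "pos",
           orient = "virus_orient")
}

#' Score integration calls against simulation truth
#'
#' Each simulated integration contributes two truth junctions (5' host side
#' and 3' host side).  A call is correct when it lies within `window` bases
#' of an unmatched truth junction on the same chromosome, with matching host
#' side and integration orientation; matching is greedy one-to-one in order
#' of increasing distance.  Calls whose virus orientation is unresolved can
#' never satisfy the orientation requirement and count as false positives.
#'
#' @param calls Call tibble.
#' @param truth Truth tibble from [simulate_infected_genome()].
#' @param window Maximum distance in bases (default 300).
#' @return An object of class `vint_eval`: list with `tp`, `fp`, `fn`,
#'   `sensitivity` (`tp / n_junctions`), `fpr_proxy` (`fp / (tp + fp)`),
#'   `deviations` (absolute distances of matched calls) and a per-call
#'   `matches` tibble.
#' @export
evaluate_calls <- function(calls, truth, window = 300) {
  tj <- truth_junctions(truth)
  n_truth <- nrow(tj)
  if (nrow(calls) == 0) {
    return(structure(list(tp = 0L, fp = 0L, fn = n_truth,
                          sensitivity = 0, fpr_proxy = NA_real_,
                          deviations = integer(0),
                          matches = tibble(call_idx = integer(),
                                           junction_id = integer(),
                                           deviation = integer()),
                          window = window), class = "vint_eval"))
  }
  calls <- mutate(calls, call_idx = row_number())
  cand <- calls %>%
    dplyr::inner_join(tj, by = c("host_chr", "host_side"),
                      relationship = "many-to-many") %>%
    filter(!is.na(.data$virus_orient), .data$virus_orient == .data$orient,
           abs(.data$host_pos - .data$pos) <= window) %>%
    mutate(deviation = abs(.data$host_pos - .data$pos)) %>%
    arrange(.data$deviation, .data$call_idx, .data$junction_id)
  used_call <- logical(nrow(calls))
  used_truth <- logical(n_truth)
  m_call <- integer(0); m_junc <- integer(0); m_dev <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ci <- cand$call_idx[i]; ji <- cand$junction_id[i]
    if (used_call[ci] || used_truth[ji]) next
    used_call[ci] <- TRUE; used_truth[ji] <- TRUE
    m_call <- c(m_call, ci); m_junc <- c(m_junc, ji)
    m_dev <- c(m_dev, cand$deviation[i])
  }
  tp <- length(m_call)
  fp <- nrow(calls) - tp
  structure(list(tp = tp, fp = fp, fn = n_truth - tp,
                 sensitivity = tp / n_truth,
                 fpr_proxy = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
                 deviations = m_dev,
                 matches = tibble(call_idx = m_call, junction_id = m_junc,
                                  deviation = m_dev),
                 window = window), class = "vint_eval")
}

#' @export
print.vint_eval <- function(x, ...) {
  cat(sprintf(paste0("<vint_eval> tp = %d, fp = %d, fn = %d | sensitivity = ",
                     "%.1f%%, fp fraction = %s (window %d bp)\n"),
              x$tp, x$fp, x$fn, 100 * x$sensitivity,
              ifelse(is.na(x$fpr_proxy), "NA",
                     sprintf("%.1f%%", 100 * x$fpr_proxy)), x$window))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.vint_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, sensitivity = x$sensitivity,
         fpr_proxy = x$fpr_proxy,
         median_deviation = if (length(x$deviations)) median(x$deviations)
                            else NA_real_,
         window = x$window)
}

#' @export
tidy.vint_eval <- function(x, ...) x$matches

#' Sensitivity / false-positive trade-off over support thresholds
#'
#' For every minimum read-pair support t = 1 .. max(n_pairs), evaluates the
#' calls with `n_pairs >= t` against truth.  Both tp(t) and fp(t) are
#' non-increasing in t, tracing the caller's operating curve.
#'
#' @param calls Call tibble (column `n_pairs`).
#' @param truth Truth tibble.
#' @param window Match window in bases (default 300).
#' @return A tibble of class `vint_roc`: `min_support`, `n_calls`, `tp`,
#'   `fp`, `sensitivity`, `fpr_proxy`.
#' @export
roc_table <- function(calls, truth, window = 300) {
  t_max <- if (nrow(calls) == 0) 1L else max(calls$n_pairs)
  rows <- purrr::map(seq_len(t_max), function(t) {
    ev <- evaluate_calls(filter(calls, .data$n_pairs >= t), truth, window)
    tibble(min_support = t, n_calls = ev$tp + ev$fp, tp = ev$tp, fp = ev$fp,
           sensitivity = ev$sensitivity, fpr_proxy = ev$fpr_proxy)
  })
  out <- bind_rows(rows)
  class(out) <- c("vint_roc", class(out))
  out
}

#' @export
autoplot.vint_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fp, y = .data$tp,
                                       label = .data$min_support)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "incorrect calls", y = "correct calls",
                  title = "Support-thresholded operating curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vint_eval <- function(object, ...) {
  ggplot2::ggplot(tibble(deviation = object$deviations),
                  ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_histogram(binwidth = 10, boundary = 0, fill = "steelblue") +
    ggplot2::labs(x = "distance from true breakpoint (bp)", y = "calls",
                  title = "Breakpoint deviation of correct calls") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
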