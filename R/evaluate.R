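#' Cumulative enrichment curve for a ranked candidate list
#'
#' At every rank r the curve records the cumulative percent of all known
#' stabilisers found among the top r entries and the running true
#' positive rate (hits among top r divided by r). Entries without a
#' truth label are skipped with a message.
#'
#' @param ranked Data frame with `position` ordered by rank (e.g. a
#'   `candidate_list`).
#' @param truth Data frame with `position` and `label` in
#'   `c("stabilising", "destabilising", "neutral")`.
#' @return Data frame with `rank`, `position`, `hit`, `cumulative_pct`,
#'   `tpr`.
#' @export
enrichment_curve <- function(ranked, truth) {
  lab <- truth$label[match(ranked$position, truth$position)]
  known <- !is.na(lab)
  if (any(!known)) {
    message(sum(!known), " ranked position(s) without truth label ",
            "skipped")
  }
  d <- ranked[known, , drop = FALSE]
  lab <- lab[known]
  total_hits <- sum(truth$label == "stabilising")
  if (total_hits == 0L) stop("truth set contains no stabilisers")
  hit <- lab == "stabilising"
  data.frame(rank = seq_len(nrow(d)), position = d$position, hit = hit,
             cumulative_pct = 100 * cumsum(hit) / total_hits,
             tpr = cumsum(hit) / seq_len(nrow(d)))
}

#' Random-selection baseline for stabiliser and destabiliser counts
#'
#' Draws repeated random position subsets (without replacement) from the
#' truth set and reports the mean and standard deviation of the
#' stabiliser and destabiliser counts per sample.
#'
#' @param truth Data frame with `position` and `label`.
#' @param n_samplings Number of random draws (default 10).
#' @param sample_size Positions per draw (default 100).
#' @param seed Optional RNG seed for reproducibility.
#' @return Data frame with one row per class: `mean` and `sd` counts per
#'   sample.
#' @export
random_baseline <- function(truth, n_samplings = 10, sample_size = 100,
                            seed = NULL) {
  if (sample_size > nrow(truth)) {
    stop("sample_size exceeds the truth set size")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- t(vapply(seq_len(n_samplings), function(i) {
    lab <- truth$label[sample.int(nrow(truth), sample_size)]
    c(stabilising = sum(lab == "stabilising"),
      destabilising = sum(lab == "destabilising"))
  }, c(stabilising = 0, destabilising = 0)))
  data.frame(class = colnames(counts),
             mean = colMeans(counts),
             sd = apply(counts, 2, stats::sd),
             n_samplings = n_samplings, sample_size = sample_size,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Campaign success rates
#'
#' Percent of tested variants confirmed stabilising (and destabilising),
#' rounded to the nearest integer percent, half away from zero.
#'
#' @param status Character vector of final statuses, one per tested
#'   variant.
#' @return Named numeric vector with `stabilising` and `destabilising`
#'   integer percents.
#' @export
success_rate <- function(status) {
  n <- length(status)
  if (n == 0L) stop("no tested variants")
  rate <- function(k) round_half_up(100 * k / n)
  c(stabilising = rate(sum(status == "stabilising")),
    destabilising = rate(sum(status == "destabilising")))
}

round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
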