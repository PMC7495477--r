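MODULE_PRIORITY <- c("data_driven", "model_based", "deep_sequence")

#' Define a selection policy
#'
#' @param top_fraction Percent of each module's ranked sites considered
#'   (in (0, 100]; e.g. 15, 40 or 10).
#' @param per_module_quota Optional count of variants to take from each
#'   module after truncation (>= 1).
#' @param overlap_rule One of `"highest_score_wins"` (one candidate per
#'   position survives), `"drop_identical_substitution_only"` (only exact
#'   (position, substitution) duplicates collapse) or `"allow_all"`.
#' @param exclusions Integer vector of excluded positions.
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(top_fraction = 100, per_module_quota = NULL,
                             overlap_rule = c("highest_score_wins",
                                              "drop_identical_substitution_only",
                                              "allow_all"),
                             exclusions = integer()) {
  overlap_rule <- match.arg(overlap_rule)
  if (top_fraction <= 0 || top_fraction > 100) {
    stop("top_fraction must be in (0, 100]")
  }
  if (!is.null(per_module_quota) && per_module_quota < 1) {
    stop("per_module_quota must be >= 1 when set")
  }
  structure(list(top_fraction = top_fraction,
                 per_module_quota = per_module_quota,
                 overlap_rule = overlap_rule,
                 exclusions = sort(unique(as.integer(exclusions)))),
            class = "selection_policy")
}

#' Drop candidates at excluded positions
#'
#' @param candidates A candidate data frame (rows from one or more
#'   `candidate_list`s).
#' @param exclusions Integer vector of excluded 1-based positions.
#' @return List with `kept` and `dropped` data frames; dropped rows carry
#'   `reason = "excluded_position"`.
#' @export
apply_exclusions <- function(candidates, exclusions) {
  hit <- candidates$position %in% exclusions
  dropped <- candidates[hit, , drop = FALSE]
  if (nrow(dropped) > 0L) dropped$reason <- "excluded_position"
  else dropped$reason <- character(0)
  message(sum(hit), " candidate(s) dropped at excluded positions")
  list(kept = candidates[!hit, , drop = FALSE], dropped = dropped)
}

#' Resolve candidates proposed at the same position by several modules
#'
#' Under `highest_score_wins` a single candidate survives per position:
#' the one with the highest normalised score (ties broken by module
#' priority data_driven > model_based > deep_sequence, then substitution
#' alphabetically). Under `drop_identical_substitution_only` only exact
#' (position, substitution) duplicates collapse to the higher-scoring
#' entry. `allow_all` likewise drops nothing beyond exact duplicate
#' (position, substitution) pairs: different substitutions at the same
#' site all survive.
#'
#' @param candidates Combined candidate data frame with `norm_score` on
#'   a shared percent scale.
#' @param rule Overlap rule (see [selection_policy()]).
#' @return List with `kept` and `dropped` (reason `"overlap"`).
#' @export
resolve_overlaps <- function(candidates,
                             rule = c("highest_score_wins",
                                      "drop_identical_substitution_only",
                                      "allow_all")) {
  rule <- match.arg(rule)
  pri <- match(candidates$module, MODULE_PRIORITY)
  if (anyNA(pri)) stop("unknown module tag(s): ",
                       paste(unique(candidates$module[is.na(pri)]),
                             collapse = ", "))
  ord <- order(-candidates$norm_score, pri, candidates$mut_aa)
  cand <- candidates[ord, , drop = FALSE]
  key <- switch(rule,
                highest_score_wins = as.character(cand$position),
                paste(cand$position, cand$mut_aa))
  dup <- duplicated(key)
  dropped <- cand[dup, , drop = FALSE]
  if (nrow(dropped) > 0L) dropped$reason <- "overlap"
  else dropped$reason <- character(0)
  list(kept = cand[!dup, , drop = FALSE], dropped = dropped)
}

#' Merge module candidate lists into the final selection
#'
#' Applies, in order: position exclusions, per-module top-fraction
#' truncation (each module ranks its own sites), cross-module overlap
#' resolution, and the per-module quota (top of each surviving list). The
#' output order sheet is sorted by (module, rank).
#'
#' @param candidate_lists List of `candidate_list` data frames (one per
#'   module).
#' @param policy A [selection_policy()].
#' @return List of class `selection_report` with `selection` (kept rows)
#'   and `dropped` (rows with a `reason` column:
#'   excluded_position / below_fraction / overlap / over_quota).
#' @export
finalise_selection <- function(candidate_lists, policy) {
  stopifnot(inherits(policy, "selection_policy"))
  dropped_all <- list()
  trimmed <- lapply(candidate_lists, function(cl) {
    cl <- as.data.frame(cl)
    ex <- apply_exclusions(cl, policy$exclusions)
    dropped_all[[length(dropped_all) + 1L]] <<- ex$dropped
    keep_n <- ceiling(nrow(cl) * policy$top_fraction / 100)
    below <- ex$kept[ex$kept$rank > keep_n, , drop = FALSE]
    if (nrow(below) > 0L) {
      below$reason <- "below_fraction"
      dropped_all[[length(dropped_all) + 1L]] <<- below
    }
    ex$kept[ex$kept$rank <= keep_n, , drop = FALSE]
  })
  pooled <- do.call(rbind, trimmed)
  ov <- resolve_overlaps(pooled, policy$overlap_rule)
  dropped_all[[length(dropped_all) + 1L]] <- ov$dropped
  kept <- ov$kept
  if (!is.null(policy$per_module_quota)) {
    q <- policy$per_module_quota
    by_mod <- split(kept, kept$module)
    kept <- do.call(rbind, lapply(by_mod, function(d) {
      d <- d[order(d$rank), , drop = FALSE]
      if (nrow(d) < q) {
        warning("module '", d$module[1], "': quota ", q,
                " exceeds surviving list (", nrow(d), "); taking all")
        return(d)
      }
      over <- d[-seq_len(q), , drop = FALSE]
      if (nrow(over) > 0L) {
        over$reason <- "over_quota"
        dropped_all[[length(dropped_all) + 1L]] <<- over
      }
      d[seq_len(q), , drop = FALSE]
    }))
  }
  kept <- kept[order(match(kept$module, MODULE_PRIORITY), kept$rank), ,
               drop = FALSE]
  rownames(kept) <- NULL
  dropped <- do.call(rbind, dropped_all)
  rownames(dropped) <- NULL
  if (anyDuplicated(paste(kept$position, kept$mut_aa))) {
    stop("internal error: duplicate (position, substitution) in the ",
         "final selection")
  }
  kept$label <- format_variant_label(kept)
  structure(list(selection = kept, dropped = dropped, policy = policy),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection:", nrow(x$selection), "variant(s) kept,",
      nrow(x$dropped), "dropped\n")
  tab <- table(x$selection$module)
  cat("  per module:", paste(names(tab), as.integer(tab),
                             collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L) {
    dt <- table(x$dropped$reason)
    cat("  drop reasons:", paste(names(dt), as.integer(dt),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}
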