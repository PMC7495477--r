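SCORING_FACTORS <- c("amino_acid", "topology", "conservation_bin",
                     "lipid_contact_bin", "helix_contact_bin",
                     "disorder_bin")

CONSERVATION_BIN_LABELS <- paste0(seq(0, 90, 10), "-", seq(10, 100, 10))
UNIT_BIN_LABELS <- paste0(format(seq(0, 0.8, 0.2), nsmall = 1), "-",
                          format(seq(0.2, 1, 0.2), nsmall = 1))

#' Bin conservation percentages into ten decade bins
#'
#' @param x Numeric vector in \[0, 100\].
#' @return Character vector of bin labels ("0-10", ..., "90-100"); 100
#'   falls in the top bin.
#' @export
bin_conservation <- function(x) {
  if (any(x < 0 | x > 100)) stop("conservation values outside [0, 100]")
  idx <- pmin(floor(x / 10) + 1, 10)
  CONSERVATION_BIN_LABELS[idx]
}

#' Bin a unit-interval score into five equal bins
#'
#' @param x Numeric vector in \[0, 1\].
#' @return Character vector of bin labels ("0.0-0.2", ..., "0.8-1.0").
#' @export
bin_unit <- function(x) {
  if (any(x < 0 | x > 1)) stop("score values outside [0, 1]")
  idx <- pmin(floor(x * 5) + 1, 5)
  UNIT_BIN_LABELS[idx]
}

feature_levels <- function(features) {
  data.frame(
    position = features$position,
    topology = features$topology,
    conservation_bin = bin_conservation(features$conservation),
    lipid_contact_bin = bin_unit(features$lipid_contact),
    helix_contact_bin = bin_unit(features$helix_contact),
    disorder_bin = bin_unit(features$disorder),
    stringsAsFactors = FALSE
  )
}

#' Classify stability records against wild-type thresholds
#'
#' Records strictly above `stab_threshold` percent of wild-type stability
#' are stabilising, strictly below `destab_threshold` destabilising,
#' anything in between (boundaries included) neutral.
#'
#' @param relative_stability Numeric vector, percent of wild-type (>= 0).
#' @param stab_threshold Stabilising threshold, percent (default 140).
#' @param destab_threshold Destabilising threshold, percent (default 80).
#' @return Character vector in
#'   `c("stabilising", "neutral", "destabilising")`.
#' @export
classify_stability <- function(relative_stability, stab_threshold = 140,
                               destab_threshold = 80) {
  if (anyNA(relative_stability)) stop("missing relative stability values")
  if (any(relative_stability < 0)) stop("negative relative stability values")
  cls <- rep("neutral", length(relative_stability))
  cls[relative_stability > stab_threshold] <- "stabilising"
  cls[relative_stability < destab_threshold] <- "destabilising"
  cls
}

#' Abundance-weighted class frequencies for one factor
#'
#' For each observed level of the factor, the stabilising (destabilising)
#' weight is the count of stabilising (destabilising) records at that
#' level divided by the total records at that level. Neutral records
#' enter the denominator only. Normalising within each level removes the
#' skew toward abundant levels (e.g. alanine vs tryptophan).
#'
#' @param level Character vector: the factor level of each record.
#' @param class Character vector from [classify_stability()], same length.
#' @return Data frame with columns `level`, `n`, `n_stab`, `n_destab`,
#'   `stab_weight`, `destab_weight`, ordered by level.
#' @export
factor_weights <- function(level, class) {
  stopifnot(length(level) == length(class))
  levs <- sort(unique(level))
  if (length(levs) < 2L) {
    stop("factor has fewer than 2 observed levels; unrankable")
  }
  n <- as.vector(table(factor(level, levels = levs)))
  n_stab <- as.vector(table(factor(level[class == "stabilising"],
                                   levels = levs)))
  n_destab <- as.vector(table(factor(level[class == "destabilising"],
                                     levels = levs)))
  data.frame(level = levs, n = n, n_stab = n_stab, n_destab = n_destab,
             stab_weight = n_stab / n, destab_weight = n_destab / n,
             stringsAsFactors = FALSE)
}

#' Convert abundance weights to rank-based scores
#'
#' With L observed levels, levels are ordered by stabilising weight
#' descending: the level at rank r receives stabilising score L + 1 - r
#' (most-associated scores highest). Levels are independently ordered by
#' destabilising weight descending: rank r receives destabilising score r
#' (least-associated scores highest). The combined score is their sum, so
#' e.g. a residue ranked 4th of 20 for stabilising association and last
#' of 20 for destabilising association scores 17 + 20 = 37. Ties in
#' weight are broken by observation count (more observations first), then
#' level name.
#'
#' @param weights Data frame from [factor_weights()].
#' @return `weights` with `stab_score`, `destab_score`, `combined_score`
#'   columns appended; each score column is a permutation of 1..L.
#' @export
weights_to_scores <- function(weights) {
  L <- nrow(weights)
  if (L < 2L) stop("need at least 2 levels to rank")
  ord_stab <- order(-weights$stab_weight, -weights$n, weights$level)
  ord_destab <- order(-weights$destab_weight, -weights$n, weights$level)
  stab_score <- integer(L)
  stab_score[ord_stab] <- L + 1L - seq_len(L)
  destab_score <- integer(L)
  destab_score[ord_destab] <- seq_len(L)
  weights$stab_score <- stab_score
  weights$destab_score <- destab_score
  weights$combined_score <- stab_score + destab_score
  weights
}

#' Derive a stability scoring matrix from a variant stability dataset
#'
#' Fits the data-driven scoring matrix: every record is classified as
#' stabilising/neutral/destabilising from its relative stability, each of
#' six bioinformatic factors (wild-type amino acid, topology class,
#' conservation decade, lipid-contact bin, helix-contact bin, disorder
#' bin) is abundance-weighted per level, and weights are converted into
#' rank-based combined scores via [weights_to_scores()].
#'
#' @param records Stability records as returned by
#'   [read_stability_records()] (or [sim_stability_dataset()]): one row
#'   per measurement with `position`, `wt_aa` and `relative_stability`.
#' @param features A `feature_table` (see [read_feature_table()]) for the
#'   source target(s); if `records` has a `target_id` column with several
#'   targets, pass a named list of feature tables.
#' @param stab_threshold,destab_threshold Percent-of-wild-type class
#'   thresholds (defaults 140 and 80).
#' @return Object of class `stability_matrix`: a list with `scores`
#'   (data frame: factor, level, n, weights, scores), `class_counts`,
#'   `thresholds`, `n_records` and the call. Supports `print()`,
#'   `summary()`, `coef()`, `predict()` and `plot()`.
#' @seealso [predict.stability_matrix()] to score a new target.
#' @export
stability_matrix <- function(records, features, stab_threshold = 140,
                             destab_threshold = 80) {
  cl <- match.call()
  if (!is.list(features) || is.data.frame(features)) {
    features <- stats::setNames(list(features),
                                unique(records$target_id)[1])
  }
  cls <- classify_stability(records$relative_stability,
                            stab_threshold, destab_threshold)
  levels_per_record <- record_factor_levels(records, features)
  scores <- do.call(rbind, lapply(SCORING_FACTORS, function(f) {
    w <- factor_weights(levels_per_record[[f]], cls)
    w <- weights_to_scores(w)
    cbind(factor = f, w, stringsAsFactors = FALSE)
  }))
  rownames(scores) <- NULL
  counts <- table(factor(cls, levels = c("stabilising", "neutral",
                                         "destabilising")))
  structure(list(scores = scores,
                 class_counts = counts,
                 thresholds = c(stabilising = stab_threshold,
                                destabilising = destab_threshold),
                 n_records = nrow(records),
                 call = cl),
            class = "stability_matrix")
}

record_factor_levels <- function(records, features) {
  if (is.null(records$target_id)) records$target_id <- names(features)[1]
  out <- data.frame(amino_acid = records$wt_aa, topology = NA_character_,
                    conservation_bin = NA_character_,
                    lipid_contact_bin = NA_character_,
                    helix_contact_bin = NA_character_,
                    disorder_bin = NA_character_,
                    stringsAsFactors = FALSE)
  for (tid in unique(records$target_id)) {
    ft <- features[[tid]]
    if (is.null(ft)) stop("no feature table supplied for target '",
                          tid, "'")
    sel <- records$target_id == tid
    pos <- records$position[sel]
    if (any(pos < 1L | pos > nrow(ft))) {
      stop("record position(s) outside feature table for target '",
           tid, "'")
    }
    lv <- feature_levels(ft)
    out$topology[sel] <- lv$topology[pos]
    out$conservation_bin[sel] <- lv$conservation_bin[pos]
    out$lipid_contact_bin[sel] <- lv$lipid_contact_bin[pos]
    out$helix_contact_bin[sel] <- lv$helix_contact_bin[pos]
    out$disorder_bin[sel] <- lv$disorder_bin[pos]
  }
  out
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat("Stability scoring matrix (abundance-weighted, rank-based)\n")
  cat("  records:", x$n_records, "->",
      paste(names(x$class_counts), as.integer(x$class_counts),
            collapse = ", "), "\n")
  cat("  class thresholds: >", x$thresholds["stabilising"],
      "% stabilising, <", x$thresholds["destabilising"],
      "% destabilising\n", sep = "")
  cat("  factors:", paste(unique(x$scores$factor), collapse = ", "), "\n")
  invisible(x)
}

#' @method summary stability_matrix
#' @export
summary.stability_matrix <- function(object, ...) {
  s <- object$scores
  top <- do.call(rbind, lapply(split(s, s$factor), function(d) {
    d <- d[order(-d$combined_score), ]
    data.frame(factor = d$factor[1], n_levels = nrow(d),
               best_level = d$level[1],
               best_combined = d$combined_score[1],
               stringsAsFactors = FALSE)
  }))
  rownames(top) <- NULL
  print(object)
  cat("\nTop-scoring level per factor:\n")
  print(top, row.names = FALSE)
  invisible(top)
}

#' @method coef stability_matrix
#' @export
coef.stability_matrix <- function(object, ...) {
  object$scores[, c("factor", "level", "stab_score", "destab_score",
                    "combined_score")]
}

#' @method plot stability_matrix
#' @export
plot.stability_matrix <- function(x, factor = "amino_acid", ...) {
  d <- x$scores[x$scores$factor == factor, ]
  d <- d[order(-d$combined_score), ]
  graphics::barplot(d$combined_score, names.arg = d$level, las = 2,
                    ylab = "combined score",
                    main = paste("Factor:", factor), ...)
  invisible(d)
}

#' Write / read a scoring matrix as TSV
#'
#' @param matrix A `stability_matrix`.
#' @param path TSV file path.
#' @return `path` invisibly (write) or a `stability_matrix` (read; the
#'   read-back object carries scores only, which is all scoring needs).
#' @export
write_scoring_matrix <- function(matrix, path) {
  write_tsv(coef(matrix), path)
}

#' @rdname write_scoring_matrix
#' @export
read_scoring_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("factor", "level", "stab_score", "destab_score",
              "combined_score")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("scoring matrix missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$level <- as.character(df$level)
  structure(list(scores = df, class_counts = NULL, thresholds = NULL,
                 n_records = NA_integer_, call = NULL),
            class = "stability_matrix")
}

combined_lookup <- function(matrix, factor, levels) {
  d <- matrix$scores[matrix$scores$factor == factor, ]
  idx <- match(levels, d$level)
  out <- d$combined_score[idx]
  if (anyNA(out)) {
    med <- stats::median(d$combined_score)
    missing_levels <- unique(levels[is.na(idx)])
    warning("factor '", factor, "': level(s) ",
            paste(missing_levels, collapse = ", "),
            " absent from training data; using median combined score ",
            med, call. = FALSE)
    out[is.na(out)] <- med
  }
  out
}

#' Score every position of a target with a scoring matrix
#'
#' The per-position final score is the product of the combined scores of
#' the wild-type amino acid, topology class, conservation decade,
#' lipid-contact bin and helix-contact bin, optionally multiplied by the
#' disorder-bin score. Scores are normalised to percent of the maximum
#' over the target, and each position is proposed the default scanning
#' substitution (alanine, or leucine for native alanine).
#'
#' @param object A `stability_matrix`.
#' @param target A [protein_target()].
#' @param features `feature_table` for the target.
#' @param include_disorder Multiply in the disorder-bin factor
#'   (default `TRUE`; set `FALSE` for the five-factor scoring mode).
#' @param ... Unused.
#' @return Data frame (one row per position, ordered by rank) with the
#'   per-factor scores, `final_score`, `norm_score` and `rank`; class
#'   `position_scores`.
#' @method predict stability_matrix
#' @export
predict.stability_matrix <- function(object, target, features,
                                     include_disorder = TRUE, ...) {
  if (nrow(features) != target$length) {
    stop("feature table has ", nrow(features), " rows but target has ",
         target$length, " residues")
  }
  wt <- strsplit(target$sequence, "")[[1]]
  lv <- feature_levels(features)
  sc <- data.frame(
    position = features$position,
    wt_aa = wt,
    mut_aa = default_substitution(wt),
    score_aa = combined_lookup(object, "amino_acid", wt),
    score_topology = combined_lookup(object, "topology", lv$topology),
    score_conservation = combined_lookup(object, "conservation_bin",
                                         lv$conservation_bin),
    score_lipid = combined_lookup(object, "lipid_contact_bin",
                                  lv$lipid_contact_bin),
    score_helix = combined_lookup(object, "helix_contact_bin",
                                  lv$helix_contact_bin),
    stringsAsFactors = FALSE
  )
  sc$final_score <- sc$score_aa * sc$score_topology *
    sc$score_conservation * sc$score_lipid * sc$score_helix
  if (include_disorder) {
    sc$score_disorder <- combined_lookup(object, "disorder_bin",
                                         lv$disorder_bin)
    sc$final_score <- sc$final_score * sc$score_disorder
  }
  sc$norm_score <- 100 * sc$final_score / max(sc$final_score)
  sc <- sc[order(-sc$final_score, sc$position), ]
  sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  class(sc) <- c("position_scores", "data.frame")
  sc
}

#' Data-driven candidate list for a target
#'
#' Thin wrapper around [predict.stability_matrix()] that emits the shared
#' candidate-list schema used by all three evidence streams.
#'
#' @inheritParams predict.stability_matrix
#' @param matrix A `stability_matrix`.
#' @return A `candidate_list` data frame (module, rank, position, wt_aa,
#'   mut_aa, score, norm_score).
#' @export
data_driven_candidates <- function(matrix, target, features,
                                   include_disorder = TRUE) {
  sc <- predict(matrix, target, features,
                include_disorder = include_disorder)
  new_candidate_list(module = "data_driven", position = sc$position,
                     wt_aa = sc$wt_aa, mut_aa = sc$mut_aa,
                     score = sc$final_score)
}

new_candidate_list <- function(module, position, wt_aa, mut_aa, score) {
  ord <- order(-score, position)
  df <- data.frame(module = rep(module, length(position)),
                   position = position[ord],
                   wt_aa = wt_aa[ord], mut_aa = mut_aa[ord],
                   score = score[ord], stringsAsFactors = FALSE)
  df$norm_score <- if (nrow(df) > 0L) 100 * df$score / df$score[1] else
    numeric()
  df$rank <- seq_len(nrow(df))
  if (anyDuplicated(paste(df$position, df$mut_aa))) {
    stop("duplicate (position, substitution) pairs in candidate list")
  }
  class(df) <- c("candidate_list", "data.frame")
  df
}

#' @export
print.candidate_list <- function(x, n = 10L, ...) {
  cat("Candidate list (", x$module[1], "): ", nrow(x),
      " ranked entries\n", sep = "")
  print(as.data.frame(utils::head(x, n)), row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}
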