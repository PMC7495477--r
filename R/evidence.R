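#' Independent-sites consensus mutation-effect table from an MSA
#'
#' Scores every substitution at every query position by the log-ratio of
#' its column frequency to the wild-type residue's column frequency:
#' `effect(pos, x) = ln((count_x + p) / (count_wt + p))` with pseudocount
#' `p`. Positive effects mean the substitution is more frequent in the
#' family than the query residue, i.e. the query residue is an
#' "odd-one-out" at that position. Alignment columns that are gaps in the
#' query are dropped; gap characters never count as residues.
#'
#' This is an independent-sites simplification: no pairwise covariance
#' terms and no sequence reweighting. Genuine effect tables from
#' covariance-model software can be ingested instead via
#' [read_effect_table()].
#'
#' @param msa Character vector of aligned sequences (equal lengths; `-`
#'   or `.` for gaps), or an `AAStringSet`.
#' @param query_index Row index of the query sequence (default 1).
#' @param pseudocount Added to both counts (default 1).
#' @return Data frame with columns `position` (1-based in the ungapped
#'   query), `wt_aa`, `mut_aa`, `effect`.
#' @export
consensus_effect_table <- function(msa, query_index = 1, pseudocount = 1) {
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  if (length(msa) < 2L) stop("alignment depth < 2")
  if (length(unique(nchar(msa))) != 1L) {
    stop("aligned sequences differ in length")
  }
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  query <- mat[query_index, ]
  keep_cols <- which(!(query %in% c("-", ".")))
  rows <- vector("list", length(keep_cols))
  for (i in seq_along(keep_cols)) {
    col <- mat[, keep_cols[i]]
    wt <- query[keep_cols[i]]
    if (!(wt %in% AA_CANONICAL)) {
      stop("query letter '", wt, "' at alignment column ", keep_cols[i],
           " is not a canonical amino acid")
    }
    counts <- table(factor(col[col %in% AA_CANONICAL],
                           levels = AA_CANONICAL))
    muts <- setdiff(AA_CANONICAL, wt)
    rows[[i]] <- data.frame(
      position = i, wt_aa = wt, mut_aa = muts,
      effect = log((as.numeric(counts[muts]) + pseudocount) /
                     (as.numeric(counts[wt]) + pseudocount)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a precomputed mutation-effect table
#'
#' Accepts TSVs from external deep-sequence software via a column map,
#' so real runs can be ingested unchanged.
#'
#' @param path TSV file.
#' @param columns Named character vector mapping the required names
#'   (`position`, `wt_aa`, `mut_aa`, `effect`) to the file's column names.
#' @return Data frame with the four standard columns.
#' @export
read_effect_table <- function(path,
                              columns = c(position = "position",
                                          wt_aa = "wt_aa",
                                          mut_aa = "mut_aa",
                                          effect = "effect")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols) > 0L) {
    stop("effect table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(position = as.integer(df[[columns["position"]]]),
                    wt_aa = df[[columns["wt_aa"]]],
                    mut_aa = df[[columns["mut_aa"]]],
                    effect = as.numeric(df[[columns["effect"]]]),
                    stringsAsFactors = FALSE)
  out[out$wt_aa != out$mut_aa, ]
}

#' Select deep-sequence candidates from a mutation-effect table
#'
#' Keeps strictly favourable effects only, takes the best substitution
#' per site, normalises to percent of the best site and retains sites
#' with normalised score strictly above the cutoff.
#'
#' @param effects Data frame from [consensus_effect_table()] or
#'   [read_effect_table()].
#' @param cutoff_percent Normalised-score cutoff (default 70).
#' @return A `candidate_list`; empty (with a warning) when no effect is
#'   positive.
#' @export
select_deep_sequence <- function(effects, cutoff_percent = 70) {
  pos_eff <- effects[effects$effect > 0, , drop = FALSE]
  if (nrow(pos_eff) == 0L) {
    warning("no strictly favourable substitutions; empty candidate list")
    return(new_candidate_list("deep_sequence", integer(), character(),
                              character(), numeric()))
  }
  best <- do.call(rbind, lapply(split(pos_eff, pos_eff$position),
                                function(d) {
    d[order(-d$effect, d$mut_aa), ][1, ]
  }))
  keep <- 100 * best$effect / max(best$effect) > cutoff_percent
  best <- best[keep, , drop = FALSE]
  new_candidate_list("deep_sequence", best$position, best$wt_aa,
                     best$mut_aa, best$effect)
}

#' Read a per-model ddG table
#'
#' Expected columns: `position`, `wt_aa`, `mut_aa`, `ddg` (kcal/mol;
#' negative = stabilising). The model's post-minimisation unfolding
#' energy is read from a `# unfolding_energy: <value>` header line if
#' present, else must be supplied.
#'
#' @param path TSV file.
#' @param model_id Identifier (defaults to the file name).
#' @param unfolding_energy Override for the header value.
#' @return List with `model_id`, `unfolding_energy` and `table`.
#' @export
read_ddg_table <- function(path, model_id = basename(path),
                           unfolding_energy = NULL) {
  header <- readLines(path, n = 5L)
  m <- regmatches(header,
                  regexec("^#\\s*unfolding_energy:\\s*(-?[0-9.]+)", header))
  vals <- vapply(m, function(g) if (length(g) == 2L) as.numeric(g[2]) else
    NA_real_, numeric(1))
  if (is.null(unfolding_energy)) {
    unfolding_energy <- vals[!is.na(vals)][1]
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("position", "wt_aa", "mut_aa", "ddg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("ddG table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(df$ddg))) stop("non-finite ddG values in ", path)
  list(model_id = model_id, unfolding_energy = unfolding_energy,
       table = df)
}

#' Aggregate alanine-scan ddG tables across models
#'
#' Computes, for every position present in all model tables, the mean
#' alanine-substitution ddG and the number of models in which the change
#' is stabilising (ddG < 0). Positions are ordered primarily by that
#' model count (descending; agreement across models ranks highest) and
#' secondarily by mean ddG ascending (most negative first). Scores are
#' normalised to percent of the most negative mean among stabilising
#' positions; positions whose normalised score strictly exceeds the
#' cutoff pass to the position-scan stage.
#'
#' @param tables List of ddG tables from [read_ddg_table()] (or the
#'   `alascan` element of [sim_ddg_tables()]).
#' @param cutoff_percent Normalised-score cutoff (default 70).
#' @return List with `positions` (data frame: position, wt_aa, mean_ddg,
#'   n_models_stab, norm_score, ordered) and `passing` (integer vector of
#'   positions above the cutoff).
#' @export
aggregate_alascan <- function(tables, cutoff_percent = 70) {
  if (length(tables) < 1L) stop("need at least one ddG table")
  dfs <- lapply(tables, function(t) {
    d <- t$table
    d[d$mut_aa %in% c("A", "L") & d$wt_aa != d$mut_aa, ]
  })
  pos_sets <- lapply(dfs, function(d) sort(unique(d$position)))
  common <- Reduce(intersect, pos_sets)
  if (length(unique(vapply(pos_sets, length, 1L))) > 1L ||
      any(vapply(pos_sets, function(p) !identical(p, common), TRUE))) {
    warning("inconsistent position sets across models; using the ",
            "intersection (", length(common), " positions)")
  }
  ddg_mat <- vapply(dfs, function(d) {
    d$ddg[match(common, d$position)]
  }, numeric(length(common)))
  ddg_mat <- matrix(ddg_mat, nrow = length(common))
  mean_ddg <- rowMeans(ddg_mat)
  n_stab <- rowSums(ddg_mat < 0)
  wt <- dfs[[1]]$wt_aa[match(common, dfs[[1]]$position)]
  res <- data.frame(position = common, wt_aa = wt, mean_ddg = mean_ddg,
                    n_models_stab = n_stab, stringsAsFactors = FALSE)
  res$norm_score <- ifelse(res$mean_ddg < 0,
                           100 * res$mean_ddg / min(res$mean_ddg), 0)
  res <- res[order(-res$n_models_stab, res$mean_ddg, res$position), ]
  rownames(res) <- NULL
  list(positions = res,
       passing = res$position[res$norm_score > cutoff_percent])
}

#' Pick the best model by unfolding energy
#'
#' @param tables List of ddG tables from [read_ddg_table()].
#' @return The element with the lowest post-minimisation unfolding
#'   energy.
#' @export
best_model <- function(tables) {
  energies <- vapply(tables, function(t) t$unfolding_energy, numeric(1))
  if (anyNA(energies)) stop("missing unfolding energy for some model(s)")
  tables[[which.min(energies)]]
}

#' Model-based candidates from a saturation position scan
#'
#' For each passing position, selects the substitution with the most
#' negative ddG in the best model's saturation scan; positions where no
#' substitution is stabilising are dropped with a warning. Candidates
#' are ranked by that ddG ascending.
#'
#' @param passing Integer vector of positions (from
#'   [aggregate_alascan()]).
#' @param scan A ddG table from [read_ddg_table()] covering the passing
#'   positions with all 19 substitutions (the best model's scan).
#' @return A `candidate_list` with module tag `model_based`.
#' @export
select_model_based <- function(passing, scan) {
  d <- scan$table
  missing_pos <- setdiff(passing, unique(d$position))
  if (length(missing_pos) > 0L) {
    stop("passing position(s) missing from the position scan: ",
         paste(missing_pos, collapse = ", "))
  }
  rows <- lapply(passing, function(p) {
    dp <- d[d$position == p & d$wt_aa != d$mut_aa, ]
    dp <- dp[order(dp$ddg, dp$mut_aa), ]
    if (nrow(dp) == 0L || dp$ddg[1] >= 0) return(NULL)
    dp[1, c("position", "wt_aa", "mut_aa", "ddg")]
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L) {
    warning(dropped, " passing position(s) had no stabilising ",
            "substitution and were dropped")
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(new_candidate_list("model_based", integer(), character(),
                              character(), numeric()))
  }
  # score = -ddg so that larger is better and rank 1 normalises to 100
  new_candidate_list("model_based", rows$position, rows$wt_aa,
                     rows$mut_aa, -rows$ddg)
}
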