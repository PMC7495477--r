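#' memstab: thermostabilising variant selection for helical membrane proteins
#'
#' Three independent evidence streams (data-driven scoring matrix,
#' deep-sequence residue frequencies, model-based unfolding ddG tables)
#' are each turned into a ranked candidate list, merged under a selection
#' policy, and carried through to mutagenic primer design and melting-curve
#' analysis of the resulting constructs.
#'
#' @keywords internal
"_PACKAGE"

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TOPOLOGY_CLASSES <- c("TM_helix", "cytosolic_helix", "cytosolic_loop",
                      "extracellular_helix", "extracellular_loop", "reentrant")

#' Construct a protein target
#'
#' A target is a canonical amino-acid sequence plus a (possibly empty) set
#' of 1-based residue positions excluded from variant selection, e.g.
#' positions known from the literature to be mechanistically critical.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid string using the 20 canonical one-letter codes.
#'   Ambiguity codes (X, B, Z, ...) are rejected.
#' @param excluded_positions Integer vector of 1-based positions to exclude.
#' @return An object of class `protein_target` with elements `id`,
#'   `sequence`, `length` and `excluded_positions`.
#' @export
protein_target <- function(id, sequence, excluded_positions = integer()) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 1L) stop("target sequence must have length >= 1")
  letters_seen <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters_seen), AA_CANONICAL)
  if (length(bad) > 0L) {
    stop("non-canonical amino-acid letter(s) in target '", id, "': ",
         paste(bad, collapse = ", "))
  }
  excluded_positions <- sort(unique(as.integer(excluded_positions)))
  if (length(excluded_positions) > 0L &&
      (min(excluded_positions) < 1L ||
       max(excluded_positions) > nchar(sequence))) {
    stop("excluded positions outside [1, ", nchar(sequence), "]")
  }
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 excluded_positions = excluded_positions),
            class = "protein_target")
}

#' @export
print.protein_target <- function(x, ...) {
  cat("Protein target '", x$id, "': ", x$length, " residues, ",
      length(x$excluded_positions), " excluded position(s)\n", sep = "")
  invisible(x)
}

target_residue <- function(target, position) {
  substr(target$sequence, position, position)
}

#' Parse a variant label such as "G130A"
#'
#' Labels follow the usual point-mutation nomenclature: wild-type letter,
#' 1-based position, substituting letter.
#'
#' @param label Character vector of labels.
#' @return A data frame with columns `position`, `wt_aa`, `mut_aa`.
#' @examples
#' parse_variant_label("G130A")
#' @export
parse_variant_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))
  out <- lapply(seq_along(label), function(i) {
    g <- m[[i]]
    if (length(g) != 4L) stop("malformed variant label: '", label[i], "'")
    wt <- toupper(g[2]); mut <- toupper(g[4]); pos <- as.integer(g[3])
    if (!(wt %in% AA_CANONICAL) || !(mut %in% AA_CANONICAL)) {
      stop("non-canonical amino acid in variant label: '", label[i], "'")
    }
    if (pos < 1L) stop("variant position must be >= 1 in label: '",
                       label[i], "'")
    if (wt == mut) stop("wild-type and substituted residues identical ",
                        "in label: '", label[i], "'")
    data.frame(position = pos, wt_aa = wt, mut_aa = mut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Format variants back into labels
#'
#' @param variant Data frame with columns `position`, `wt_aa`, `mut_aa`.
#' @return Character vector of labels; the inverse of
#'   [parse_variant_label()].
#' @export
format_variant_label <- function(variant) {
  paste0(variant$wt_aa, variant$position, variant$mut_aa)
}

#' Default scanning substitution for a wild-type residue
#'
#' Scanning campaigns substitute to alanine, or to leucine when the native
#' residue is already alanine.
#'
#' @param wt_aa Character vector of canonical one-letter codes.
#' @return Character vector of substituting residues.
#' @export
default_substitution <- function(wt_aa) {
  wt_aa <- toupper(wt_aa)
  bad <- setdiff(unique(wt_aa), AA_CANONICAL)
  if (length(bad) > 0L) {
    stop("non-canonical amino acid(s): ", paste(bad, collapse = ", "))
  }
  ifelse(wt_aa == "A", "L", "A")
}

#' Check variants against a target sequence
#'
#' @param variant Data frame with columns `position`, `wt_aa`, `mut_aa`.
#' @param target A [protein_target()].
#' @return `variant`, invisibly unchanged, if every row is consistent.
#' @export
validate_variant <- function(variant, target) {
  for (i in seq_len(nrow(variant))) {
    pos <- variant$position[i]
    if (pos < 1L || pos > target$length) {
      stop("variant position ", pos, " outside target '", target$id,
           "' (length ", target$length, ")")
    }
    actual <- target_residue(target, pos)
    if (actual != variant$wt_aa[i]) {
      stop("wild-type mismatch at position ", pos, ": label says '",
           variant$wt_aa[i], "', sequence has '", actual, "'")
    }
  }
  invisible(variant)
}

#' Read a single protein sequence from FASTA
#'
#' @param path FASTA file with at least one record; the first is used.
#' @param id Optional identifier override (defaults to the FASTA header).
#' @param excluded_positions Passed through to [protein_target()].
#' @return A [protein_target()].
#' @export
read_protein_fasta <- function(path, id = NULL, excluded_positions = integer()) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) stop("no sequences in ", path)
  protein_target(id = if (is.null(id)) names(set)[1] else id,
                 sequence = as.character(set[[1]]),
                 excluded_positions = excluded_positions)
}

#' Read a (circular) plasmid sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return A list with `id` and `sequence` (uppercase A/C/G/T string).
#' @export
read_plasmid_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("no sequences in ", path)
  list(id = names(set)[1], sequence = toupper(as.character(set[[1]])))
}

#' Read a per-residue feature table
#'
#' The table must carry one row per residue of the target, positions
#' contiguous from 1 to the target length, with columns `position`,
#' `topology`, `conservation` (percent, 0-100), `lipid_contact`,
#' `helix_contact` and `disorder` (all in \[0,1\]). Tool-specific topology
#' labels are mapped onto the six-class vocabulary via `topology_aliases`.
#' Continuous columns arriving outside their scale are min-max rescaled
#' with a message.
#'
#' @param path TSV file.
#' @param target Optional [protein_target()]; if given, row count and
#'   position range are validated against it (no silent reindexing).
#' @param topology_aliases Named character vector mapping foreign labels to
#'   the canonical classes.
#' @return Data frame of features, class `feature_table`.
#' @export
read_feature_table <- function(path, target = NULL, topology_aliases = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_feature_table(df, target = target, topology_aliases = topology_aliases)
}

#' Validate a feature data frame
#'
#' @inheritParams read_feature_table
#' @param df Data frame with the columns documented in
#'   [read_feature_table()].
#' @return The validated data frame with class `feature_table` prepended.
#' @export
as_feature_table <- function(df, target = NULL, topology_aliases = NULL) {
  needed <- c("position", "topology", "conservation", "lipid_contact",
              "helix_contact", "disorder")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$position), , drop = FALSE]
  L <- nrow(df)
  if (!identical(as.integer(df$position), seq_len(L))) {
    stop("feature table positions must be exactly 1..L with one row per ",
         "residue; got ", L, " rows spanning ", min(df$position), "..",
         max(df$position))
  }
  if (!is.null(target) && L != target$length) {
    stop("feature table has ", L, " rows but target '", target$id,
         "' has ", target$length, " residues")
  }
  if (!is.null(topology_aliases)) {
    hit <- df$topology %in% names(topology_aliases)
    df$topology[hit] <- unname(topology_aliases[df$topology[hit]])
  }
  bad_topo <- setdiff(unique(df$topology), TOPOLOGY_CLASSES)
  if (length(bad_topo) > 0L) {
    stop("unknown topology class(es): ", paste(bad_topo, collapse = ", "),
         " (expected ", paste(TOPOLOGY_CLASSES, collapse = "/"), ")")
  }
  df$conservation <- rescale_if_needed(df$conservation, 0, 100,
                                       "conservation")
  for (col in c("lipid_contact", "helix_contact", "disorder")) {
    df[[col]] <- rescale_if_needed(df[[col]], 0, 1, col)
  }
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

rescale_if_needed <- function(x, lo, hi, name) {
  if (anyNA(x)) stop("missing values in feature column '", name, "'")
  if (min(x) < lo || max(x) > hi) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      x <- rep((lo + hi) / 2, length(x))
    } else {
      x <- lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
    }
    message("feature '", name, "' outside [", lo, ",", hi,
            "]; min-max rescaled")
  }
  x
}

#' Read a variant stability dataset
#'
#' Rows are (target, variant, state, relative stability) records, one
#' per independent measurement; relative stability is expressed as percent
#' of wild-type. Expected columns: `target_id`, `variant` (label such as
#' "G130A"), `relative_stability`, optional `state` (defaults to "apo").
#'
#' @param path TSV file.
#' @return Data frame with parsed variant columns appended.
#' @export
read_stability_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("target_id", "variant", "relative_stability")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("stability table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$state)) df$state <- "apo"
  if (any(df$relative_stability < 0)) {
    stop("negative relative stability values present")
  }
  parsed <- parse_variant_label(df$variant)
  df <- cbind(df, parsed)
  key <- paste(df$target_id, df$variant, df$state)
  if (anyDuplicated(key)) {
    stop("duplicate (target, variant, state) records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df
}

#' Write a table as TSV
#'
#' Plain tab-separated output with a header, no quoting, no row names;
#' used for every table the pipeline emits so outputs are byte-stable.
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an exclusion-position file
#'
#' One position or inclusive range (`57-60`) per line; blank lines and
#' `#` comments ignored.
#'
#' @param path Text file.
#' @return Sorted integer vector of positions.
#' @export
read_exclusion_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pos <- unlist(lapply(lines, function(x) {
    if (grepl("^[0-9]+-[0-9]+$", x)) {
      ab <- as.integer(strsplit(x, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else if (grepl("^[0-9]+$", x)) {
      as.integer(x)
    } else {
      stop("malformed exclusion entry: '", x, "'")
    }
  }))
  sort(unique(pos))
}
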