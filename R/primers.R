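# SantaLucia (1998) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(K*mol); 16 stacks keyed by the 5'->3'
# top-strand dinucleotide; values are symmetric under reverse complement.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex-initiation terms per terminal base pair
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

GAS_CONSTANT <- 1.987  # cal/(K*mol)

#' Nearest-neighbour thermodynamic parameter set
#'
#' Packages the unified oligonucleotide dinucleotide-stack parameters
#' (enthalpies in kcal/mol, entropies in cal/(K*mol)), terminal
#' initiation terms, the gas constant, the primer concentration and the
#' monovalent-cation concentration used for the entropic salt
#' correction. At `na_conc = 1` no salt correction is applied and the
#' melting temperature reduces to the bare initiation-plus-stacks
#' expression; the default 50 mM reflects typical PCR buffer.
#'
#' @param c_p Primer concentration in mol/L (default 5e-7, i.e. 0.5 uM).
#' @param na_conc Monovalent cation concentration in mol/L (default
#'   0.05).
#' @param dh,ds Named stack vectors overriding the packaged set.
#' @param init_dh,init_ds Named terminal-initiation vectors.
#' @return List of class `thermo_params`.
#' @export
thermo_params <- function(c_p = 5e-7, na_conc = 0.05,
                          dh = NN_DH, ds = NN_DS,
                          init_dh = NN_INIT_DH, init_ds = NN_INIT_DS) {
  stopifnot(length(dh) == 16L, length(ds) == 16L, c_p > 0, na_conc > 0)
  structure(list(dh = dh, ds = ds, init_dh = init_dh, init_ds = init_ds,
                 R = GAS_CONSTANT, c_p = c_p, na_conc = na_conc),
            class = "thermo_params")
}

#' Reverse-complement a DNA string
#'
#' @param seq A/C/G/T string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) {
           paste(rev(strsplit(toupper(s), "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Nearest-neighbour primer melting temperature
#'
#' `Tm = (dH_init + sum(dH_stacks)) * 1000 /
#'       (dS_init + sum(dS_stacks) + R * ln(c_p)) - 273.15`,
#' in degrees Celsius, with the entropic monovalent-salt correction
#' `0.368 * n_stacks * ln(na_conc)` added to the entropy term (zero at
#' the 1 M reference). Stacks flanking a mismatched base (a base that
#' does not pair with the template) contribute no terms.
#'
#' @param primer A/C/G/T string of length >= 8.
#' @param params A [thermo_params()].
#' @param mismatch Integer positions (1-based within the primer) that
#'   are mismatched against the template; their flanking stacks are
#'   skipped.
#' @return Melting temperature in degrees C.
#' @export
nn_tm <- function(primer, params = thermo_params(),
                  mismatch = integer()) {
  primer <- toupper(primer)
  n <- nchar(primer)
  if (n < 8L) stop("primer shorter than 8 nt")
  bases <- strsplit(primer, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("ambiguous or non-DNA base in primer: ", primer)
  }
  stacks <- paste0(bases[-n], bases[-1])
  keep <- !(seq_len(n - 1L) %in% c(mismatch, mismatch - 1L))
  dh <- sum(params$init_dh[bases[c(1L, n)]]) +
    sum(params$dh[stacks[keep]])
  ds <- sum(params$init_ds[bases[c(1L, n)]]) +
    sum(params$ds[stacks[keep]]) +
    0.368 * (n - 1L) * log(params$na_conc)
  denom <- ds + params$R * log(params$c_p)
  if (denom >= 0) stop("non-physical denominator in Tm calculation")
  dh * 1000 / denom - 273.15
}

# Approximate E. coli K-12 codon usage (synonymous fraction per codon).
CODON_USAGE_ECOLI <- c(
  TTT = 0.57, TTC = 0.43, TTA = 0.13, TTG = 0.13, CTT = 0.10,
  CTC = 0.10, CTA = 0.04, CTG = 0.50, ATT = 0.51, ATC = 0.42,
  ATA = 0.07, ATG = 1.00, GTT = 0.26, GTC = 0.22, GTA = 0.15,
  GTG = 0.37, TCT = 0.15, TCC = 0.15, TCA = 0.12, TCG = 0.15,
  AGT = 0.15, AGC = 0.28, CCT = 0.16, CCC = 0.12, CCA = 0.19,
  CCG = 0.53, ACT = 0.17, ACC = 0.44, ACA = 0.13, ACG = 0.27,
  GCT = 0.16, GCC = 0.27, GCA = 0.21, GCG = 0.36, TAT = 0.57,
  TAC = 0.43, CAT = 0.57, CAC = 0.43, CAA = 0.35, CAG = 0.65,
  AAT = 0.45, AAC = 0.55, AAA = 0.77, AAG = 0.23, GAT = 0.63,
  GAC = 0.37, GAA = 0.69, GAG = 0.31, TGT = 0.45, TGC = 0.55,
  TGG = 1.00, CGT = 0.38, CGC = 0.40, CGA = 0.06, CGG = 0.10,
  AGA = 0.04, AGG = 0.02, GGT = 0.34, GGC = 0.40, GGA = 0.11,
  GGG = 0.15)

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Choose the mutant codon for a target amino acid
#'
#' Among codons encoding the target residue, picks the one with the
#' fewest nucleotide changes from the wild-type codon; ties are broken
#' by higher usage in the host codon-usage table, then alphabetically.
#'
#' @param wt_codon Wild-type codon (must encode the wild-type residue).
#' @param target_aa Target amino acid (one-letter; stops unsupported).
#' @param usage Named numeric vector of codon usage fractions.
#' @return The chosen codon string.
#' @export
choose_mutant_codon <- function(wt_codon, target_aa,
                                usage = CODON_USAGE_ECOLI) {
  wt_codon <- toupper(wt_codon)
  target_aa <- toupper(target_aa)
  if (target_aa == "*" || !(target_aa %in% AA_CANONICAL)) {
    stop("unsupported target amino acid: '", target_aa, "'")
  }
  if (translate_codon(wt_codon) == target_aa) {
    stop("target amino acid equals the wild-type translation (",
         target_aa, ")")
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc == target_aa]
  wt_b <- strsplit(wt_codon, "")[[1]]
  edits <- vapply(codons, function(c) {
    sum(strsplit(c, "")[[1]] != wt_b)
  }, integer(1))
  u <- usage[codons]
  u[is.na(u)] <- 0
  codons[order(edits, -u, codons)][1]
}

circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

circ_replace <- function(seq, start, replacement) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  rep_chars <- strsplit(replacement, "")[[1]]
  idx <- ((start - 1L + seq_along(rep_chars) - 1L) %% n) + 1L
  chars[idx] <- rep_chars
  paste(chars, collapse = "")
}

#' Design a non-overlapping inverse-PCR mutagenic primer pair
#'
#' The forward primer carries the mutant codon with at least 10 matched
#' bases on each side of the mismatched base(s); it is grown (or shrunk)
#' at its 3' end until its melting temperature lies in `tm_window`
#' (closest achievable length if the window is skipped between
#' single-base steps). The reverse primer anneals to the opposite strand
#' starting at the base immediately 5' of the forward primer's first
#' template base (so the pair is back-to-back, never overlapping) and is
#' grown at its 3' end to match the forward melting temperature. The
#' recommended annealing temperature is `min(Tm_fwd, Tm_rev) - 3`,
#' capped at `anneal_target`. Because the forward optimisation takes the
#' shortest length inside the window, the pair's annealing
#' recommendation sits as close to the target as the base steps permit.
#' Whole-plasmid amplification followed by blunt ligation of the product
#' reconstitutes the mutant plasmid exactly; this is asserted in silico.
#'
#' @param plasmid Circular plasmid as a list with `sequence` (A/C/G/T
#'   string), e.g. from [read_plasmid_fasta()] or [sim_plasmid()].
#' @param cds_start 1-based position of the first CDS base in the
#'   plasmid.
#' @param variant One-row data frame from [parse_variant_label()].
#' @param params A [thermo_params()].
#' @param usage Codon usage table for [choose_mutant_codon()].
#' @param tm_window Forward-primer melting-temperature window in degrees
#'   C (default `c(65, 70)`).
#' @param anneal_target Annealing-temperature cap in degrees C
#'   (default 62).
#' @return List of class `primer_pair` with the two sequences, their Tm
#'   values, lengths, template coordinates, the mutant codon and the
#'   annealing recommendation.
#' @export
design_primer_pair <- function(plasmid, cds_start, variant,
                               params = thermo_params(),
                               usage = CODON_USAGE_ECOLI,
                               tm_window = c(65, 70), anneal_target = 62) {
  P <- toupper(plasmid$sequence)
  n <- nchar(P)
  pos <- variant$position[1]
  codon_start <- ((cds_start - 1L + 3L * (pos - 1L)) %% n) + 1L
  wt_codon <- circ_substr(P, codon_start, 3L)
  if (translate_codon(wt_codon) != variant$wt_aa[1]) {
    stop("CDS codon ", wt_codon, " at position ", pos,
         " translates to ", translate_codon(wt_codon),
         ", not the stated wild-type ", variant$wt_aa[1])
  }
  mut_codon <- choose_mutant_codon(wt_codon, variant$mut_aa[1], usage)
  mm_in_codon <- which(strsplit(wt_codon, "")[[1]] !=
                         strsplit(mut_codon, "")[[1]])
  flank5 <- 10L
  f1 <- ((codon_start - flank5 - 1L) %% n) + 1L
  mm_in_primer <- flank5 + mm_in_codon
  # >= 10 matched bases 3' of the last mismatched base
  min_len3 <- 10L - (3L - max(mm_in_codon))
  max_len3 <- min(45L, n - (flank5 + 3L) - 18L - 1L)
  if (max_len3 < min_len3) {
    stop("plasmid too short to fit non-overlapping primers")
  }
  fwd_at <- function(len3) {
    template <- circ_substr(P, f1, flank5 + 3L + len3)
    circ_replace_linear(template, flank5 + 1L, mut_codon)
  }
  lens <- min_len3:max_len3
  tms <- vapply(lens, function(l3) {
    nn_tm(fwd_at(l3), params, mismatch = mm_in_primer)
  }, numeric(1))
  in_win <- tms >= tm_window[1] & tms <= tm_window[2]
  if (any(in_win)) {
    # shortest in-window length keeps Tm near the lower bound, which
    # keeps the common annealing temperature near the target
    pick <- which(in_win)[1]
  } else {
    dist <- pmax(tm_window[1] - tms, tms - tm_window[2], 0)
    pick <- which.min(dist)
  }
  len3 <- lens[pick]
  fwd <- fwd_at(len3)
  tm_fwd <- tms[pick]
  len_fwd <- nchar(fwd)
  # reverse primer: opposite strand, 3' end growing away from the fork
  r2 <- ((f1 - 2L) %% n) + 1L
  max_rev <- min(60L, n - len_fwd)
  rev_lens <- 18L:max_rev
  rev_at <- function(l) revcomp(circ_substr(P, ((r2 - l) %% n) + 1L, l))
  rev_tms <- vapply(rev_lens, function(l) nn_tm(rev_at(l), params),
                    numeric(1))
  rpick <- which.min(abs(rev_tms - tm_fwd))
  rev_len <- rev_lens[rpick]
  rev <- rev_at(rev_len)
  tm_rev <- rev_tms[rpick]
  anneal <- min(anneal_target, min(tm_fwd, tm_rev) - 3)
  pair <- structure(list(
    variant = format_variant_label(variant[1, ]),
    forward = fwd, reverse = rev,
    tm_forward = tm_fwd, tm_reverse = tm_rev,
    annealing = anneal,
    length_forward = len_fwd, length_reverse = rev_len,
    template_start_forward = f1,
    template_start_reverse = ((r2 - rev_len) %% n) + 1L,
    wt_codon = wt_codon, mut_codon = mut_codon,
    codon_start = codon_start,
    mismatch_positions = mm_in_primer,
    base_step = max(abs(diff(tms[seq_len(pick)])), 0)
  ), class = "primer_pair")
  check_amplicon(pair, P, n)
  pair
}

circ_replace_linear <- function(seq, at, replacement) {
  paste0(substr(seq, 1L, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

# in-silico inverse PCR + blunt ligation: the linear product runs from
# the forward primer 5' end the whole way round to the reverse primer
# 5' end; re-circularising must give the wild-type plasmid with exactly
# the mutant codon substituted.
check_amplicon <- function(pair, P, n) {
  mutant <- circ_replace(P, pair$codon_start, pair$mut_codon)
  product <- circ_substr(mutant, pair$template_start_forward, n)
  ligated <- circ_replace(paste(rep("N", n), collapse = ""), 1L, product)
  shift <- pair$template_start_forward - 1L
  rotated <- circ_substr(ligated, n - shift + 1L, n)
  if (rotated != mutant) {
    stop("in-silico ligation does not reconstruct the mutant plasmid")
  }
  if (substr(product, 1L, pair$length_forward) != pair$forward) {
    stop("forward primer does not match the amplicon 5' end")
  }
  tail_seq <- substr(product, n - pair$length_reverse + 1L, n)
  if (revcomp(tail_seq) != pair$reverse) {
    stop("reverse primer does not match the amplicon 3' end")
  }
  invisible(TRUE)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair for ", x$variant, " (", x$wt_codon, " -> ",
      x$mut_codon, ")\n", sep = "")
  cat(sprintf("  forward (%d nt, Tm %.1f C): %s\n", x$length_forward,
              x$tm_forward, x$forward))
  cat(sprintf("  reverse (%d nt, Tm %.1f C): %s\n", x$length_reverse,
              x$tm_reverse, x$reverse))
  cat(sprintf("  annealing recommendation: %.1f C\n", x$annealing))
  invisible(x)
}

#' Design primers for a whole selection table
#'
#' @param plasmid,cds_start,params,usage,tm_window,anneal_target As in
#'   [design_primer_pair()].
#' @param selection Data frame with `position`, `wt_aa`, `mut_aa` (e.g.
#'   the `selection` element of [finalise_selection()]).
#' @return Data frame, one row per variant, suitable for a 96-well
#'   ordering sheet.
#' @export
design_primers <- function(plasmid, cds_start, selection,
                           params = thermo_params(),
                           usage = CODON_USAGE_ECOLI,
                           tm_window = c(65, 70), anneal_target = 62) {
  rows <- lapply(seq_len(nrow(selection)), function(i) {
    p <- design_primer_pair(plasmid, cds_start, selection[i, ], params,
                            usage, tm_window, anneal_target)
    data.frame(variant = p$variant, forward = p$forward,
               reverse = p$reverse,
               tm_forward = round(p$tm_forward, 1),
               tm_reverse = round(p$tm_reverse, 1),
               annealing = round(p$annealing, 1),
               length_forward = p$length_forward,
               length_reverse = p$length_reverse,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
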