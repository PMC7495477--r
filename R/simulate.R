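# Synthetic fixture generators. Every input class the pipeline consumes
# can be generated with planted structure under a fixed seed, so the
# whole pipeline is testable end to end without any external data.
# Planted trends mirror the qualitative structure reported for scanning
# campaigns of helical membrane proteins: G/T/A/Q/E/H enriched among
# stabilisers, I/Y/W/D/C/V among destabilisers, transmembrane-helix
# positions stabilising and cytosolic-helix positions destabilising on
# substitution, moderate (50-60%) conservation favourable and high
# (80-90%) conservation unfavourable; base rates 7.6% stabilising and
# 48.5% destabilising per 100 positions.

SIM_STAB_AA <- c("G", "T", "A", "Q", "E", "H")
SIM_DESTAB_AA <- c("I", "Y", "W", "D", "C", "V")

sim_class_probs <- function(aa, topology, conservation, lipid, helix,
                            disorder) {
  stab_aa_mult <- stats::setNames(rep(1, 20), AA_CANONICAL)
  stab_aa_mult[SIM_STAB_AA] <- c(3.0, 2.7, 2.4, 2.1, 1.9, 1.7)
  stab_aa_mult[SIM_DESTAB_AA] <- 0.5
  destab_aa_mult <- stats::setNames(rep(1, 20), AA_CANONICAL)
  destab_aa_mult[SIM_DESTAB_AA] <- c(1.6, 1.5, 1.4, 1.3, 1.25, 1.2)
  destab_aa_mult[SIM_STAB_AA] <- 0.7
  stab_topo <- c(TM_helix = 1.6, cytosolic_helix = 0.6,
                 cytosolic_loop = 1.0, extracellular_helix = 0.9,
                 extracellular_loop = 1.0, reentrant = 1.1)
  destab_topo <- c(TM_helix = 0.9, cytosolic_helix = 1.3,
                   cytosolic_loop = 1.0, extracellular_helix = 1.05,
                   extracellular_loop = 1.0, reentrant = 1.0)
  stab_cons <- c(0.8, 0.9, 1.0, 1.1, 1.3, 1.8, 1.2, 0.9, 0.7, 0.6)
  destab_cons <- c(0.85, 0.9, 0.9, 0.95, 1.0, 1.0, 1.05, 1.1, 1.4, 1.2)
  cons_idx <- pmin(floor(conservation / 10) + 1, 10)
  lip_idx <- pmin(floor(lipid * 5) + 1, 5)
  hel_idx <- pmin(floor(helix * 5) + 1, 5)
  dis_idx <- pmin(floor(disorder * 5) + 1, 5)
  stab_lip <- c(0.9, 0.95, 1.0, 1.05, 1.15)
  stab_hel <- c(0.9, 0.95, 1.0, 1.05, 1.15)
  stab_dis <- c(1.1, 1.05, 1.0, 0.9, 0.8)
  p_stab <- 0.076 * stab_aa_mult[aa] * stab_topo[topology] *
    stab_cons[cons_idx] * stab_lip[lip_idx] * stab_hel[hel_idx] *
    stab_dis[dis_idx]
  p_destab <- 0.485 * destab_aa_mult[aa] * destab_topo[topology] *
    destab_cons[cons_idx]
  tot <- p_stab + p_destab
  over <- tot > 0.95
  p_stab[over] <- p_stab[over] * 0.95 / tot[over]
  p_destab[over] <- p_destab[over] * 0.95 / tot[over]
  data.frame(p_stab = unname(p_stab), p_destab = unname(p_destab))
}

sim_features <- function(length) {
  topo <- sample(TOPOLOGY_CLASSES, length, replace = TRUE,
                 prob = c(0.45, 0.10, 0.15, 0.05, 0.15, 0.10))
  as_feature_table(data.frame(
    position = seq_len(length),
    topology = topo,
    conservation = stats::runif(length, 0, 100),
    lipid_contact = stats::runif(length),
    helix_contact = stats::runif(length),
    disorder = stats::runif(length)
  ))
}

#' Generate a synthetic variant stability dataset with planted effects
#'
#' Builds a random target with per-residue features, then draws
#' `n_records` scanning-substitution records whose class probabilities
#' follow planted factor effects (see the generator's documentation for
#' the planted structure). Relative stabilities are drawn to respect the
#' 140%/80% class thresholds strictly. The same probability model
#' provides a per-position truth label for enrichment evaluation.
#'
#' @param seed RNG seed; fully determines the output.
#' @param n_records Number of stability records (default 2000).
#' @param target_length Residues in the synthetic target (default 300).
#' @return List with `records` (stability records), `features`
#'   (`feature_table`), `target` ([protein_target()]), `truth`
#'   (position-level labels), and `planted` (the planted
#'   stabilising/destabilising amino-acid orderings).
#' @export
sim_stability_dataset <- function(seed, n_records = 2000,
                                  target_length = 300) {
  set.seed(seed)
  wt <- sample(AA_CANONICAL, target_length, replace = TRUE)
  features <- sim_features(target_length)
  target <- protein_target("synthetic_target",
                           paste(wt, collapse = ""))
  pr <- sim_class_probs(wt, features$topology, features$conservation,
                        features$lipid_contact, features$helix_contact,
                        features$disorder)
  pos <- rep(seq_len(target_length),
             length.out = n_records)
  state <- paste0("state", (seq_len(n_records) - 1L) %/% target_length + 1L)
  u <- stats::runif(n_records)
  cls <- ifelse(u < pr$p_stab[pos], "stabilising",
                ifelse(u < pr$p_stab[pos] + pr$p_destab[pos],
                       "destabilising", "neutral"))
  rel <- numeric(n_records)
  rel[cls == "stabilising"] <- stats::runif(sum(cls == "stabilising"),
                                            145, 250)
  rel[cls == "destabilising"] <- stats::runif(sum(cls == "destabilising"),
                                              5, 75)
  rel[cls == "neutral"] <- stats::runif(sum(cls == "neutral"), 85, 135)
  records <- data.frame(
    target_id = "synthetic_target",
    position = pos, wt_aa = wt[pos],
    mut_aa = default_substitution(wt[pos]),
    state = state, relative_stability = rel,
    stringsAsFactors = FALSE)
  records$variant <- format_variant_label(records)
  u2 <- stats::runif(target_length)
  truth_label <- ifelse(u2 < pr$p_stab, "stabilising",
                        ifelse(u2 < pr$p_stab + pr$p_destab,
                               "destabilising", "neutral"))
  list(records = records, features = features, target = target,
       truth = data.frame(position = seq_len(target_length),
                          label = truth_label,
                          stringsAsFactors = FALSE),
       planted = list(stabilising = SIM_STAB_AA,
                      destabilising = SIM_DESTAB_AA))
}

#' Generate a redundant multiple sequence alignment with planted
#' odd-one-out positions
#'
#' Every column has a dominant residue (frequency about 0.7). The query
#' carries the dominant residue except at `n_odd` planted positions
#' where it carries a residue that is rare in the column.
#'
#' @param seed RNG seed.
#' @param length Query length (default 80).
#' @param depth Alignment depth (default 500).
#' @param n_odd Number of planted odd-one-out positions (default 5).
#' @return List with `msa` (character vector, query first), `query`,
#'   and `odd_positions`.
#' @export
sim_msa <- function(seed, length = 80, depth = 500, n_odd = 5) {
  set.seed(seed)
  dominant <- sample(AA_CANONICAL, length, replace = TRUE)
  odd_positions <- sort(sample.int(length, n_odd))
  cols <- vapply(seq_len(length), function(i) {
    others <- setdiff(AA_CANONICAL, dominant[i])
    probs <- c(0.7, stats::runif(19, 0, 0.05))
    probs <- probs / sum(probs)
    sample(c(dominant[i], others), depth, replace = TRUE, prob = probs)
  }, character(depth))
  query <- dominant
  for (p in odd_positions) {
    col <- cols[, p]
    rare <- names(sort(table(factor(col, levels = AA_CANONICAL))))[1]
    query[p] <- rare
  }
  cols[1, ] <- query
  msa <- apply(cols, 1, paste, collapse = "")
  list(msa = msa, query = paste(query, collapse = ""),
       odd_positions = odd_positions)
}

#' Generate per-model alanine-scan and saturation-scan ddG tables
#'
#' A set of planted sites receives a strongly negative mean ddG
#' (stabilising on substitution) in every model; remaining sites get
#' mildly positive-shifted means. Per-model Gaussian noise is added.
#' One model is assigned the lowest post-minimisation unfolding energy
#' and carries the saturation position scan.
#'
#' @param seed RNG seed.
#' @param length Number of positions (default 100).
#' @param n_models Number of models (default 3).
#' @param n_sites Number of planted stabilising sites (default 10).
#' @param noise_sd Per-model ddG noise SD in kcal/mol (default 0.5).
#' @return List with `alascan` (list of ddG-table objects as returned by
#'   [read_ddg_table()]), `scan` (saturation table for the best model),
#'   `planted_sites`, `best_model_id` and `wt` (the wild-type residues).
#' @export
sim_ddg_tables <- function(seed, length = 100, n_models = 3,
                           n_sites = 10, noise_sd = 0.5) {
  set.seed(seed)
  wt <- sample(setdiff(AA_CANONICAL, "A"), length, replace = TRUE)
  planted <- sort(sample.int(length, n_sites))
  true_mean <- stats::runif(length, -0.3, 1.5)
  true_mean[planted] <- stats::runif(n_sites, -2.5, -1.5)
  energies <- stats::runif(n_models, 90, 150)
  alascan <- lapply(seq_len(n_models), function(m) {
    list(model_id = paste0("model", m),
         unfolding_energy = energies[m],
         table = data.frame(
           position = seq_len(length), wt_aa = wt,
           mut_aa = default_substitution(wt),
           ddg = true_mean + stats::rnorm(length, 0, noise_sd),
           stringsAsFactors = FALSE))
  })
  best_id <- paste0("model", which.min(energies))
  scan_rows <- do.call(rbind, lapply(seq_len(length), function(p) {
    muts <- setdiff(AA_CANONICAL, wt[p])
    base <- if (p %in% planted) {
      c(stats::runif(1, -3.0, -2.0),
        stats::runif(18, -0.5, 1.5))
    } else {
      stats::runif(19, -0.5, 2.0)
    }
    data.frame(position = p, wt_aa = wt[p],
               mut_aa = sample(muts), ddg = base,
               stringsAsFactors = FALSE)
  }))
  scan <- list(model_id = best_id,
               unfolding_energy = min(energies),
               table = scan_rows)
  list(alascan = alascan, scan = scan, planted_sites = planted,
       best_model_id = best_id, wt = wt)
}

#' Generate noisy four-parameter logistic melt curves
#'
#' @param seed RNG seed.
#' @param true_tm True melting temperature in deg C (default 49.3).
#' @param slope Logistic slope (default 0.5).
#' @param noise_sd Gaussian noise SD on the normalised signal
#'   (default 0.03).
#' @param n_repeats Biological repeats (default 3).
#' @param temperatures Challenge grid (default the ten-temperature grid
#'   20, 30, 40, 45, 50, 55, 60, 70, 80, 90 deg C).
#' @param construct Construct name (default "WT").
#' @param top,bottom Plateau values of the underlying curve.
#' @param ice_intensity Raw intensity of the on-ice reference lane.
#' @return Data frame in the schema [melt_summary()] consumes
#'   (`construct`, `repeat_id`, `temperature`, `intensity`; on-ice rows
#'   flagged `"ice"`).
#' @export
sim_melt_curves <- function(seed, true_tm = 49.3, slope = 0.5,
                            noise_sd = 0.03, n_repeats = 3,
                            temperatures = c(20, 30, 40, 45, 50, 55,
                                             60, 70, 80, 90),
                            construct = "WT", top = 1, bottom = 0.02,
                            ice_intensity = 1000) {
  set.seed(seed)
  rows <- lapply(seq_len(n_repeats), function(r) {
    y <- bottom + (top - bottom) /
      (1 + exp(slope * (temperatures - true_tm)))
    y <- y + stats::rnorm(length(y), 0, noise_sd)
    rbind(
      data.frame(construct = construct, repeat_id = r,
                 temperature = "ice", intensity = ice_intensity,
                 stringsAsFactors = FALSE),
      data.frame(construct = construct, repeat_id = r,
                 temperature = as.character(temperatures),
                 intensity = y * ice_intensity,
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Generate a circular plasmid carrying a target's CDS
#'
#' The target sequence is reverse-translated with usage-weighted random
#' codon choices and inserted into a random backbone of configurable GC
#' content.
#'
#' @param seed RNG seed.
#' @param target A [protein_target()].
#' @param backbone_length Backbone bases outside the CDS (default 400).
#' @param gc Backbone GC fraction (default 0.5).
#' @param usage Codon usage table for reverse translation.
#' @return List with `id`, `sequence` (circular, uppercase) and
#'   `cds_start`.
#' @export
sim_plasmid <- function(seed, target, backbone_length = 400, gc = 0.5,
                        usage = CODON_USAGE_ECOLI) {
  set.seed(seed)
  gcode <- Biostrings::GENETIC_CODE
  aa_chars <- strsplit(target$sequence, "")[[1]]
  cds <- vapply(aa_chars, function(a) {
    codons <- names(gcode)[gcode == a]
    w <- usage[codons]
    w[is.na(w) | w <= 0] <- 0.01
    sample(codons, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  backbone <- sample(c("G", "C", "A", "T"), backbone_length,
                     replace = TRUE,
                     prob = c(gc / 2, gc / 2, (1 - gc) / 2,
                              (1 - gc) / 2))
  half <- backbone_length %/% 2
  seq <- paste0(paste(backbone[seq_len(half)], collapse = ""),
                paste(cds, collapse = ""),
                paste(backbone[(half + 1):backbone_length],
                      collapse = ""))
  list(id = paste0("plasmid_", target$id), sequence = seq,
       cds_start = half + 1L)
}
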