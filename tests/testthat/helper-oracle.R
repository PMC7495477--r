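# Independent brute-force nearest-neighbour oracle. The parameter table
# is written out literally here (unified oligonucleotide set) so the
# oracle shares no code or data object with the implementation.
oracle_dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
               CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
               GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
               TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
oracle_ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
               CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
               GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
               TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
oracle_init_dh <- c(A = 2.3, C = 0.1, G = 0.1, T = 2.3)
oracle_init_ds <- c(A = 4.1, C = -2.8, G = -2.8, T = 4.1)

oracle_stack_sums <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(b) - 1)) {
    st <- paste0(b[i], b[i + 1])
    dh <- dh + oracle_dh[[st]]
    ds <- ds + oracle_ds[[st]]
  }
  c(dh = dh, ds = ds)
}

oracle_tm <- function(seq, c_p = 5e-7, na_conc = 0.05) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  s <- oracle_stack_sums(seq)
  dh <- s[["dh"]] + oracle_init_dh[[b[1]]] + oracle_init_dh[[b[n]]]
  ds <- s[["ds"]] + oracle_init_ds[[b[1]]] + oracle_init_ds[[b[n]]] +
    0.368 * (n - 1) * log(na_conc)
  dh * 1000 / (ds + 1.987 * log(c_p)) - 273.15
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}

# small hand-built feature table for unit tests
tiny_features <- function(L = 6) {
  as_feature_table(data.frame(
    position = seq_len(L),
    topology = rep(c("TM_helix", "cytosolic_loop"), length.out = L),
    conservation = seq(5, 95, length.out = L),
    lipid_contact = seq(0.1, 0.9, length.out = L),
    helix_contact = seq(0.9, 0.1, length.out = L),
    disorder = rep(0.2, L)))
}
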