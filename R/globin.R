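# A synthetic stand-in for the human globin transcript reference, plus the
# erythrocyte mixture used for calibration.

#' Synthetic globin-like transcript reference
#'
#' A SYNTHETIC 12-transcript reference that mimics the paralog structure of
#' the human alpha- and beta-globin loci: two gene clusters descended from
#' unrelated ancestors, with within-cluster divergences chosen so the
#' critical near-identical pairs behave like their real counterparts
#' (HBA1/HBA2 about 99% identical, HBG1/HBG2 about 99.5%, HBB/HBD about
#' 92%), and transcript lengths in the 550-820 nt range of real globin
#' mRNAs. Gene symbols are reused as ids for readability, but the sequences
#' are simulated — none of them is a real Ensembl transcript.
#'
#' @param seed integer seed (default 1003); the default reference is fixed.
#' @return A [transcript_set()] with ids HBA1, HBA2, HBQ1, HBM, HBZP1, HBZ,
#'   HBB, HBD, HBBP1, HBG1, HBG2, HBE1.
#' @export
synthetic_globin_reference <- function(seed = 1003) {
  with_seed(seed, {
    alpha <- random_dna(700)
    beta <- random_dna(850)
    gamma <- mutate_sequence(beta, 0.08)
    trim <- function(s, n) substr(s, 1, n)
    transcript_set(
      c("HBA1", "HBA2", "HBQ1", "HBM", "HBZP1", "HBZ",
        "HBB", "HBD", "HBBP1", "HBG1", "HBG2", "HBE1"),
      c(trim(mutate_sequence(alpha, 0.005), 576),
        trim(mutate_sequence(alpha, 0.005), 575),
        trim(mutate_sequence(alpha, 0.10), 620),
        trim(mutate_sequence(alpha, 0.13), 668),
        trim(mutate_sequence(alpha, 0.16), 640),
        trim(mutate_sequence(alpha, 0.15), 650),
        trim(mutate_sequence(beta, 0.04), 628),
        trim(mutate_sequence(beta, 0.04), 729),
        trim(mutate_sequence(beta, 0.15), 700),
        trim(mutate_sequence(gamma, 0.002), 589),
        trim(mutate_sequence(gamma, 0.002), 577),
        trim(mutate_sequence(beta, 0.09), 816))
    )
  })
}

#' The erythrocyte globin mixture used for calibration
#'
#' Relative transcript weights emulating globin expression in erythrocytes:
#' HBA1 0.7, HBA2 0.7, HBM 0.01, HBB 1.00, HBD 0.04, with the two
#' gamma-globins HBG1 and HBG2 set to `gamma` (swept over 0.005-0.10 during
#' calibration to cover variable fetal-globin expression).
#'
#' @param gamma weight given to each of HBG1 and HBG2 (default 0.02).
#' @return named numeric weight vector.
#' @export
globin_mixture <- function(gamma = 0.02) {
  c(HBA1 = 0.7, HBA2 = 0.7, HBM = 0.01, HBB = 1.00, HBD = 0.04,
    HBG1 = gamma, HBG2 = gamma)
}

#' Default gamma-level sweep for globin calibration
#'
#' Five levels spanning the stated 0.005-0.10 sweep of gamma-globin weight.
#'
#' @return numeric vector of gamma levels.
#' @export
default_gamma_levels <- function() c(0.005, 0.01, 0.02, 0.05, 0.10)
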