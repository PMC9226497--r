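## Reference chemistry for unstructured backbone-amide H->D exchange in D2O,
## after Bai, Milne, Mayne & Englander (1993) Proteins 17:75-86 with the
## poly-DL-alanine low-salt reference set (the parameterization implemented
## by the SPHERE server). All factors are log10 multipliers relative to the
## poly-DL-alanine reference rates.
##
## Columns: acid lambda (side chain of the amide's own residue, acid
## catalysis), acid rho (side chain of the preceding residue), base lambda,
## base rho. Asp/Glu are taken in their deprotonated (COO-) forms and His
## neutral, appropriate to the mildly basic labeling conditions modelled
## here; no per-residue pKa modelling is attempted. Proline has no backbone
## amide proton, so it only contributes right-neighbour (rho) factors
## (trans-proline values).
englander_factors <- local({
  m <- rbind(
    A = c( 0.00,  0.00,  0.00,  0.00),
    R = c(-0.59, -0.32,  0.08,  0.22),
    N = c(-0.58, -0.13,  0.49,  0.32),
    D = c( 0.90,  0.58,  0.10, -0.18),
    C = c(-0.54, -0.46,  0.62,  0.55),
    E = c(-0.90,  0.31, -0.11, -0.15),
    Q = c(-0.47, -0.27,  0.06,  0.20),
    G = c(-0.22,  0.22,  0.27,  0.17),
    H = c( 0.00,  0.00, -0.10,  0.14),
    I = c(-0.91, -0.59, -0.73, -0.23),
    L = c(-0.57, -0.13, -0.58, -0.21),
    K = c(-0.56, -0.29, -0.04,  0.12),
    M = c(-0.64, -0.28, -0.01,  0.11),
    F = c(-0.52, -0.43, -0.24,  0.06),
    P = c(   NA, -0.19,    NA, -0.24),
    S = c(-0.44, -0.39,  0.37,  0.30),
    T = c(-0.79, -0.47, -0.07,  0.20),
    W = c(-0.40, -0.44, -0.41, -0.11),
    Y = c(-0.41, -0.37, -0.27,  0.05),
    V = c(-0.74, -0.30, -0.70, -0.14)
  )
  colnames(m) <- c("acid_lambda", "acid_rho", "base_lambda", "base_rho")
  m
})

## Chain-terminus factors (log10): the protonated N-terminal amine acts on
## the second residue's amide as an extra rho factor; the deprotonated
## C-terminal carboxylate acts on the last residue's amide as an extra
## lambda factor.
englander_termini <- c(
  nterm_acid_rho = -1.32, nterm_base_rho = 1.62,
  cterm_acid_lambda = 0.96, cterm_base_lambda = -1.80
)

## Poly-DL-alanine reference rate constants at 293.15 K (20 C), H->D
## exchange: log10 kA (M^-1 min^-1), log10 kB (M^-1 min^-1), log10 kW
## (min^-1), and per-branch Arrhenius activation energies (kcal/mol).
englander_reference <- list(
  log10_kA = 1.62, log10_kB = 10.18, log10_kW = -1.5,
  Ea_acid = 14, Ea_base = 17, Ea_water = 19,  # kcal/mol
  T_ref = 293.15,
  pKD_ref = 15.05,          # D2O autoionization at 20 C
  dH_ion_D2O = 60.2         # kJ/mol, van't Hoff slope of pKD
)

## Temperature-dependent pKD anchored at 15.05 (20 C); gives 14.87 at 25 C,
## matching the accepted D2O ion product.
pKD_at <- function(temperature_K, ref = englander_reference) {
  ref$pKD_ref + (ref$dH_ion_D2O * 1000 / (8.314 * log(10))) *
    (1 / temperature_K - 1 / ref$T_ref)
}

arrhenius_factor <- function(Ea_kcal, temperature_K, T_ref = 293.15) {
  exp(-Ea_kcal * 4184 / 8.314 * (1 / temperature_K - 1 / T_ref))
}

#' Intrinsic amide exchange rates for an unstructured sequence
#'
#' Computes per-residue intrinsic H->D exchange rates \eqn{k_{int}}
#' (min\eqn{^{-1}}) from published neighbouring-side-chain inductive
#' factors (Bai-Englander reference chemistry, poly-DL-alanine low-salt
#' parameter set), with acid-, base- and water-catalysed branches, chain
#' terminus corrections, per-branch Arrhenius temperature correction, and
#' the glass-electrode correction pD = pH(read) + 0.4. The first residue
#' and prolines carry no exchangeable backbone amide and are marked
#' non-exchanging.
#'
#' @param sequence One-letter amino-acid string.
#' @param pH_read pH-meter reading of the D2O labeling buffer.
#' @param temperature_K Labeling temperature in kelvin.
#' @param pd_correction Apply the +0.4 glass-electrode correction
#'   (default `TRUE`).
#' @param start First residue number, for bookkeeping when the sequence is
#'   a fragment of a larger protein (default 1; the first residue is always
#'   treated as the chain N terminus).
#' @return A tibble with columns `residue`, `aa`, `exchanging`,
#'   `k_int_per_min` (NA at non-exchanging positions), carrying `pD` and
#'   `temperature_K` as attributes.
#' @examples
#' intrinsic_rates("GLSDGEWQLV", pH_read = 7.9, temperature_K = 298.15)
#' @export
intrinsic_rates <- function(sequence, pH_read = 7.9, temperature_K = 298.15,
                            pd_correction = TRUE, start = 1L) {
  if (length(sequence) != 1 || !is.character(sequence) || nchar(sequence) < 2) {
    abort("sequence must be a single string of length >= 2")
  }
  if (pH_read <= 0 || pH_read >= 14) abort("pH_read outside (0, 14)")
  aa <- strsplit(sequence, "")[[1]]
  unknown <- which(!aa %in% rownames(englander_factors))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown residue letter '", aa[unknown[1]], "' at position ", unknown[1]
    ))
  }
  n <- length(aa)
  pD <- pH_read + if (pd_correction) 0.4 else 0
  ref <- englander_reference
  pKD <- pKD_at(temperature_K)
  fA <- arrhenius_factor(ref$Ea_acid, temperature_K, ref$T_ref)
  fB <- arrhenius_factor(ref$Ea_base, temperature_K, ref$T_ref)
  fW <- arrhenius_factor(ref$Ea_water, temperature_K, ref$T_ref)

  k <- rep(NA_real_, n)
  exchanging <- rep(TRUE, n)
  exchanging[1] <- FALSE
  exchanging[aa == "P"] <- FALSE
  for (i in seq_len(n)[-1]) {
    if (!exchanging[i]) next
    aL <- englander_factors[aa[i], "acid_lambda"]
    bL <- englander_factors[aa[i], "base_lambda"]
    aR <- englander_factors[aa[i - 1], "acid_rho"]
    bR <- englander_factors[aa[i - 1], "base_rho"]
    if (i == 2) {  # free amine on residue 1 acts as an extra right factor
      aR <- aR + englander_termini[["nterm_acid_rho"]]
      bR <- bR + englander_termini[["nterm_base_rho"]]
    }
    if (i == n) {  # C-terminal carboxylate on the amide's own residue
      aL <- aL + englander_termini[["cterm_acid_lambda"]]
      bL <- bL + englander_termini[["cterm_base_lambda"]]
    }
    k_acid <- fA * 10^(ref$log10_kA + aL + aR - pD)
    k_base <- fB * 10^(ref$log10_kB + bL + bR + pD - pKD)
    k_water <- fW * 10^(ref$log10_kW + bL + bR)
    k[i] <- k_acid + k_base + k_water
  }
  out <- tibble(
    residue = start + seq_len(n) - 1L,
    aa = aa,
    exchanging = exchanging,
    k_int_per_min = k
  )
  attr(out, "pD") <- pD
  attr(out, "temperature_K") <- temperature_K
  out
}
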