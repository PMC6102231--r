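# Small in-code fixtures shared across the suite.

make_peaklist <- function(residues, cs_h, cs_n, intensity = 1,
                          lw = NA_real_, label = "fix", ligand_conc = 0,
                          protein_conc = 20, ph = 7.6) {
  n <- length(residues)
  peaklist(
    tibble::tibble(
      residue = residues,
      aa = "X",
      cs_h_ppm = rep_len(cs_h, n),
      cs_n_ppm = rep_len(cs_n, n),
      intensity = rep_len(intensity, n),
      lw_n_hz = rep_len(lw, n)
    ),
    label = label, ligand_conc = ligand_conc,
    protein_conc = protein_conc, ph = ph
  )
}

random_peaklist <- function(n = 10, ligand_conc = 0, lw = FALSE) {
  make_peaklist(
    residues = seq_len(n),
    cs_h = runif(n, 7.5, 9.5),
    cs_n = runif(n, 105, 130),
    intensity = runif(n, 0.2, 2),
    lw = if (lw) runif(n, 10, 30) else NA_real_,
    ligand_conc = ligand_conc
  )
}

# Spreadsheet-style brute-force recomputation of the per-residue
# statistics, written with plain loops and scalar arithmetic so it is
# independent of the package's vectorized implementations.
brute_force_stats <- function(ref, cond, scale_n = 25) {
  out <- data.frame(residue = integer(0), csp = double(0),
                    pct = double(0))
  for (i in seq_len(nrow(ref))) {
    r <- ref$residue[i]
    j <- which(cond$residue == r)
    if (length(j) != 1) next
    dh <- cond$cs_h_ppm[j] - ref$cs_h_ppm[i]
    dn <- cond$cs_n_ppm[j] - ref$cs_n_ppm[i]
    csp <- sqrt((dh * dh + dn * dn / scale_n) / 2)
    pct <- if (ref$intensity[i] > 0) {
      abs((ref$intensity[i] - cond$intensity[j]) / ref$intensity[i]) * 100
    } else {
      NA_real_
    }
    out <- rbind(out, data.frame(residue = r, csp = csp, pct = pct))
  }
  out
}
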