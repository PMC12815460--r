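# Independent numeric oracles, kept deliberately separate from the package's
# closed-form implementations.

# bound fraction by root-finding the raw mass-action system
# (P - c)(L - c) = kd * c on the physical branch, no quadratic formula
fraction_bound_oracle <- function(p_total, l_total, kd) {
  if (l_total == 0) return(0)
  g <- function(cc) (p_total - cc) * (l_total - cc) - kd * cc
  upper <- min(p_total, l_total)
  stats::uniroot(g, c(0, upper), tol = 1e-14)$root / p_total
}

complex_conc_oracle <- function(a_total, b_total, kd) {
  fraction_bound_oracle(a_total, b_total, kd) * a_total
}

# convenience: peak list straight from a data frame of minimal columns
quick_peaklist <- function(residue_number, intensity,
                           shift_h = 8, shift_x = 120,
                           atom_group = "backbone_amide", label = "") {
  n <- length(residue_number)
  peak_list(data.frame(
    residue_number = residue_number,
    residue_type = rep("A", n),
    atom_group = rep(atom_group, length.out = n),
    shift_h_ppm = rep(shift_h, length.out = n),
    shift_x_ppm = rep(shift_x, length.out = n),
    intensity = rep(intensity, length.out = n)), label)
}
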