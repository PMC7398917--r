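# shared fixtures: contexts, table writers, quick series builders

ctx600 <- function(T_K = 298, cond = "free")
  spectrometer_context(600.03, T_K, condition = cond)

ctx800 <- function(T_K = 298, cond = "free")
  spectrometer_context(800.4, T_K, condition = cond)

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# flat series with constant R2eff and sigma on the default grid
flat_series <- function(residue_id, level, sigma = 0.3, ctx = ctx800()) {
  nu <- default_nu_grid()
  dispersion_series(residue_id, ctx, nu, rep(level, length(nu)),
                    rep(sigma, length(nu)))
}

# intensity group in the shape read_intensity_table produces
intensity_group <- function(residue_id, ctx, nu, I, I0, noise) {
  list(residue_id = residue_id, context = ctx,
       data = data.frame(residue_id = residue_id, nu_cpmg = c(0, nu),
                         intensity = c(I0, I), noise = noise))
}
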