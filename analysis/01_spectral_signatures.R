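#!/usr/bin/env Rscript
# Spectral signatures of the tracer systems.
#
# Synthesizes noise-free measurements from the packaged template presets
# (VSOP-like tracer, Endorem-like, multicore MCP/Resovist-like), runs the
# harmonic analyzer, and tabulates the amplitude/phase spectra and the
# (A5/A3, phi3) fingerprint coordinates that separate the systems.

suppressPackageStartupMessages(library(mpsquant))

config <- excitation_config()
presets <- load_presets()
dir.create("results", showWarnings = FALSE)

tracers <- c("vsop", "endorem", "mcp_resovist")
spectra <- lapply(tracers, function(nm)
  extract_harmonics(synthesize_template(config, presets[[nm]],
                                        a3_moment = 1e-10, sample_id = nm)))
names(spectra) <- tracers

tab <- spectra_table(spectra)
write.csv(tab, "results/signature_spectra.csv", row.names = FALSE)

fp <- do.call(rbind, lapply(tracers, function(nm) {
  f <- extract_features(spectra[[nm]])
  data.frame(preset = nm, r53 = f$r53, phi3_deg = f$phi3)
}))
write.csv(fp, "results/signature_fingerprints.csv", row.names = FALSE)

message("Fingerprint coordinates (A5/A3, phi3):")
for (i in seq_len(nrow(fp)))
  message(sprintf("  %-13s A5/A3 = %.0f%%  phi3 = %+.1f deg",
                  fp$preset[i], 100 * fp$r53[i], fp$phi3_deg[i]))
message("The small fast-relaxing tracer sits in the low-ratio / near-zero-",
        "lag corner; the multicore system shows a flat spectrum with a ",
        "large lag. The coordinates are concentration independent, which ",
        "is what makes them usable as a contamination fingerprint.")
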