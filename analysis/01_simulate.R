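#!/usr/bin/env Rscript

## Simulate dual-modality lesion phantoms and summarize the planted
## spectral class contrast: mean in-lesion reflectance per band for nevi
## vs melanomas. Writes results/spectral_contrast.csv and one example
## phantom directory (TIFF stacks + truth.json).

suppressMessages(library(melspect))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

base <- phantom_config(resolution_scale = 1 / 8)
cfgs <- cohort_configs(6, 6, base_config = base, seed = 1)

rows <- list()
for (id in names(cfgs)) {
  ph <- generate_phantom(cfgs[[id]])
  if (id == names(cfgs)[1])
    write_phantom(ph, file.path(out_dir, "phantom_example"))
  for (sid in names(ph$truth_reflectance)) {
    for (band in names(ph$truth_reflectance[[sid]])) {
      rows[[length(rows) + 1]] <- data.frame(
        id = id, class = ph$truth_class, system = sid,
        band_nm = as.numeric(band),
        mean_reflectance =
          mean(ph$truth_reflectance[[sid]][[band]][ph$truth_mask[[sid]]]))
    }
  }
}
spectra <- do.call(rbind, rows)
summary_tab <- aggregate(mean_reflectance ~ class + system + band_nm,
                         spectra, mean)
write.csv(summary_tab, file.path(out_dir, "spectral_contrast.csv"),
          row.names = FALSE)

wide <- reshape(summary_tab, idvar = c("system", "band_nm"),
                timevar = "class", direction = "wide")
wide$gap <- wide$mean_reflectance.nevus - wide$mean_reflectance.melanoma
wide <- wide[order(wide$band_nm), ]
cat("Mean in-lesion reflectance by band (6 nevi vs 6 melanomas):\n")
print(wide, row.names = FALSE, digits = 3)
cat(sprintf("\nLargest nevus-melanoma gap: %.3f at %g nm (inside 995-1350 nm)\n",
            max(wide$gap), wide$band_nm[which.max(wide$gap)]))
stopifnot(all(wide$gap > 0))
cat("Nevi are brighter than melanomas at every band, as planted.\n")
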