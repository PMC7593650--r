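#!/usr/bin/env Rscript
# Generate the default knee phantom: two scans (rest position; stained and
# separated femur/tibia) plus the ground truth used by every later stage.
suppressMessages(library(kneefem))

out <- "results/01_phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec()        # desk-scale murine defaults, seed 1
ph <- generate_phantom(spec)

print(ph$rest_scan)
for (nm in names(ph$truth$masks)) print(ph$truth$masks[[nm]])

write_volume(ph$rest_scan, file.path(out, "rest_scan.nii.gz"))
write_volume(ph$stained_femur_scan, file.path(out, "stained_femur.nii.gz"))
write_volume(ph$stained_tibia_scan, file.path(out, "stained_tibia.nii.gz"))
for (nm in names(ph$truth$masks))
  write_volume(ph$truth$masks[[nm]], file.path(out, paste0("truth_", nm, ".nii.gz")))
for (bone in c("femur", "tibia")) {
  lm <- ph$truth$landmarks[[bone]]
  write_landmarks(lm$fine_rest, file.path(out, paste0(bone, "_landmarks_rest.csv")))
  write_landmarks(lm$fine_stained, file.path(out, paste0(bone, "_landmarks_stained.csv")))
  write_transform(ph$truth$transforms[[bone]],
                  file.path(out, paste0(bone, "_separation_transform.json")))
}
cat("phantom written to", out, "\n")
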