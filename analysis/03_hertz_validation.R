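#!/usr/bin/env Rscript
# Solver validation: displacement-controlled contact of an elastic sphere
# against a rigid frictionless plane, compared with the Hertz closed form
# at the measured reaction force.
suppressMessages(library(kneefem))

out <- "results/03_hertz"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hz <- run_hertz_benchmark()
cat(sprintf("reaction force     %.4f N\n", hz$F))
cat(sprintf("peak pressure      %.4f MPa  (Hertz %.4f, error %.1f%%)\n",
            hz$p0_fem, hz$hertz$p0, 100 * hz$p0_rel_err))
cat(sprintf("contact radius     %.4f mm   (Hertz %.4f, error %.1f%%)\n",
            hz$a_fem, hz$hertz$a, 100 * hz$a_rel_err))
utils::write.csv(data.frame(
  quantity = c("reaction_N", "p0_fem_MPa", "p0_hertz_MPa", "a_fem_mm", "a_hertz_mm"),
  value = c(hz$F, hz$p0_fem, hz$hertz$p0, hz$a_fem, hz$hertz$a)),
  file.path(out, "hertz_validation.csv"), row.names = FALSE)
st <- hz$solution$steps[[length(hz$solution$steps)]]
pres <- numeric(nrow(hz$mesh$nodes))
pres[st$contact[[1]]$nodes] <- st$contact[[1]]$pressure
write_vtu(hz$mesh, file.path(out, "hertz_final_step.vtu"),
          point_data = list(displacement = st$u, contact_pressure = pres),
          cell_data = list(von_mises = st$von_mises))
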