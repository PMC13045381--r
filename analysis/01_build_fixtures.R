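#!/usr/bin/env Rscript
# Build the two membrane-system kinetic fixtures (pure POPC and 7:3
# POPC:POPS) whose ground truth encodes the reported macrostate populations
# and mean first-passage times, and record the exact linear-solve MFPT
# oracle for each. Populations are matched exactly; kinetics are a
# least-squares fit on log-MFPTs, so the residual is reported.

library(openmsm)

dir.create("results", showWarnings = FALSE)

for (name in c("popc", "pops")) {
  fx <- build_fixture(name)
  cat("\n====", toupper(name), "fixture ====\n")
  print(fx)
  M <- fixture_mfpt(fx)
  dimnames(M) <- list(from = fx$state_names, to = fx$state_names)
  cat("ground-truth MFPT matrix (us), exact linear solve:\n")
  print(round(M, 3))
  write_fixture_json(fx, file.path("results", paste0("fixture_", name, ".json")))
  utils::write.table(round(M, 4),
                     file.path("results", paste0("mfpt_truth_", name, ".tsv")),
                     sep = "\t", col.names = NA)
}

cat("\nThe POPC fixture holds populations 19.9/19.5/53.2/7.3 % (renormalised)\n")
cat("with ~20 us entries into the expanded-open state; the POPS fixture holds\n")
cat("0.5/0.3/39.8/59.2 % with sub-0.5 us exchange between the two open states.\n")
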