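#!/usr/bin/env Rscript
# Regenerates the packaged model fixtures under inst/extdata/.
# Run from the repository root after changing the model builders.
suppressMessages(devtools::load_all(".", quiet = TRUE))

toy <- recombination_model(
  v_segments = c("TRBV-T" = "TGTGCCAGC"),          # CAS
  j_segments = c("TRBJ-T" = "TTTTTC"),             # FF
  v_deletion_dist = 1,
  j_deletion_dist = 1,
  insertion_length_dist = c(0.4, 0.1, 0.1, 0.4),   # 0-3 nt
  insertion_base_probs = c(A = 0.5, C = 0, G = 0.5, T = 0),
  vj_usage = data.frame(v = "TRBV-T", j = "TRBJ-T", prob = 1))
write_model(toy, "inst/extdata/toy_model.json")

write_model(build_human_model(), "inst/extdata/human_model.json")
cat("fixtures written\n")
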