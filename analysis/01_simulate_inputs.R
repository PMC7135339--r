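#!/usr/bin/env Rscript
# Generate one worked set of synthetic inputs with ground truth: reporter
# and TMRE micrographs (TIFF), a lipid feature table and a single-worm Ct
# table (CSV). Downstream drivers regenerate what they need themselves;
# this script exists so every input format can be inspected on disk.

library(wormupr)

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1

# -- whole-animal reporter image ------------------------------------------
w <- gen_worm_image(seed = seed, n_worms = 5, size = 256, worm_width = 8)
write_image(w$image, file.path(out_dir, "reporter_example.tif"))
write_mask(w$truth, file.path(out_dir, "reporter_example_truth.tif"))
cat(sprintf("reporter image: %d worms, true in-worm mean %.0f\n",
            length(w$truth$areas), mean(w$object_means)))

# -- TMRE fields, both morphologies ---------------------------------------
for (m in c("tubular", "fragmented")) {
  g <- gen_mito_image(seed = seed, size = 256, morphology = m,
                      potential_scale = if (m == "fragmented") 0.37 else 1)
  write_image(g$image, file.path(out_dir, paste0("tmre_", m, ".tif")))
  write_mask(g$truth, file.path(out_dir, paste0("tmre_", m, "_truth.tif")))
  cat(sprintf("tmre %s: %d structures, true in-structure mean %.0f\n",
              m, length(g$truth$areas), g$true_mean))
}

# -- lipid feature table with planted TG landscape ------------------------
lip <- gen_lipid_table(seed = seed, n_features = 500, tg_landscape = TRUE)
write_table(data.frame(feature_id = rownames(lip$table$intensities),
                       lip$table$intensities, check.names = FALSE),
            file.path(out_dir, "lipid_features.csv"))
write_table(lip$table$sample_meta, file.path(out_dir, "lipid_samples.csv"))
write_table(lip$annotations, file.path(out_dir, "lipid_annotations.csv"))
cat(sprintf("lipid table: %d features x %d samples (%d QC)\n",
            nrow(lip$table$intensities), ncol(lip$table$intensities),
            sum(lip$table$sample_meta$is_qc)))

# -- single-worm Ct table --------------------------------------------------
ctg <- gen_ct_table(seed = seed, fail_rate = 0.02)
write_table(data.frame(gene = rownames(ctg$table$ct), ctg$table$ct,
                       check.names = FALSE),
            file.path(out_dir, "ct_values.csv"))
write_table(data.frame(gene = rownames(ctg$table$well_flags),
                       ctg$table$well_flags, check.names = FALSE),
            file.path(out_dir, "ct_flags.csv"))
cat(sprintf("ct table: %d genes x %d worms, planted CVs %s\n",
            nrow(ctg$table$ct), ncol(ctg$table$ct),
            paste(ctg$truth$planted_cv, collapse = "/")))
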