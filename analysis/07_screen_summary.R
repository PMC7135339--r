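#!/usr/bin/env Rscript
# Screen bookkeeping over the counts-faithful synthetic suppressor
# table: autophagy-regulator fraction and cross-background suppression
# percentages as printed in the screen summary.

library(wormupr)

dir.create("results", showWarnings = FALSE)
tab <- synthetic_screen_table()
write_table(tab, "results/screen_table_synthetic.csv")

cat(sprintf("suppressors: %d; flagged as autophagy regulators: %d (%d%%)\n",
            nrow(tab), sum(tab$autophagy_flag), fraction_flagged(tab)))
cat(sprintf("of the flagged set, also suppressing the fission mutant: %d%%\n",
            fraction_suppressing(tab, "drp1", among_flagged = TRUE)))
cat(sprintf("of the flagged set, also suppressing the protease mutant: %d%%\n",
            fraction_suppressing(tab, "spg7", among_flagged = TRUE)))
spg <- tab[tab$autophagy_flag & tab$grade_spg7 != "none", ]
cat(sprintf("of those, in GO Translation/Ribosome Biogenesis: %d\n",
            count_by_go(spg, c("Translation", "Ribosome Biogenesis"))))
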