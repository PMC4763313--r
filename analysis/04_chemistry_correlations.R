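#!/usr/bin/env Rscript
# Spearman screening of the classified generalist/specialist OTUs against the
# 16 geochemical parameters, per habitat (n = 6 samples each), with exact
# permutation p-values at this sample size and BH q-values reported
# alongside the raw p < 0.05 screen.

library(minecore)

ot <- read_otu_table("results/data/otu_table.tsv", "results/data/env_map.tsv")
chem <- read_chemistry("results/data/chemistry.tsv")

for (env in unique(unname(ot$environment))) {
  nc <- classify_otus(ot, env)
  focal <- nc$otu_id[nc$label != "other"]
  if (!length(focal)) {
    cat(sprintf("%s: no generalist or specialist OTUs to screen\n", env))
    next
  }
  co <- correlate(ot, chem, focal, environment = env, alpha = 0.05)
  write_table(co, sprintf("results/correlations_%s.tsv", env))
  sig <- co[co$significant, ]
  cat(sprintf("%s: screened %d OTUs x %d parameters; %d significant at p < 0.05\n",
              env, length(focal), length(unique(co$parameter)), nrow(sig)))
  if (nrow(sig)) {
    top <- sig[order(-abs(sig$rho)), ][seq_len(min(5, nrow(sig))), ]
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s ~ %s: rho = %.2f, p = %.3g\n",
                  top$otu_id[i], top$parameter[i], top$rho[i], top$p[i]))
  }
}
cat("\nWrote correlation tables to results/\n")
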