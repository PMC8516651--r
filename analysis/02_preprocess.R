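# Adjust raw hemoglobin for smoking and elevation, classify WHO severity,
# collapse to cluster binomial counts, and resample polygon records to
# population-weighted pseudo-points.
source(file.path("analysis", "00_setup.R"))

pre <- run_stage("preprocess", config, workspace)

cat(sprintf("cluster observations: %d directly located, %d pseudo-points\n",
            nrow(pre$clusters), nrow(pre$pseudo)))
cat(sprintf("crude anemia prevalence in the data: %.3f\n",
            sum(pre$clusters$C) / sum(pre$clusters$N)))
publish("cluster_observations.csv")
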