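# Spatially stratified five-fold cross-validation with bi-tree folds, scored
# as ME / RMSE / CoV / 95% coverage / correlation at admin levels 0-2.
source(file.path("analysis", "00_setup.R"))

val <- run_stage("validate", config, workspace)

cat("predictive validity (admin levels, in and out of sample):\n")
print(val$report)
publish("validation.csv")
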