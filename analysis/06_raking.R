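# Calibrate the severity draw surfaces so national aggregates match the
# external country-year series, preserving within-country variation.
source(file.path("analysis", "00_setup.R"))

rake <- run_stage("rake", config, workspace)

tab <- data.table::fread(file.path(workspace, "raking_factors.csv"))
cat("mean raking factors by country and indicator (first years):\n")
print(tab[year <= sort(unique(year))[2]])
publish("raking_factors.csv")
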