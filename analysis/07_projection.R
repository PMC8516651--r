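# Weighted annualized rates of change, logit-space projection to the target
# years, and the probability of meeting the WHO Global Nutrition Target
# (50% reduction from the baseline year).
source(file.path("analysis", "00_setup.R"))

tr <- run_stage("project", config, workspace)

cat("national trends and target attainment:\n")
print(tr[level == "admin0",
         .(unit, aroc_mean = round(aroc_mean, 4),
           proj_2030 = round(proj_2030, 3), prob_gnt_2030,
           class_gnt_2030)])
publish("trends.csv")
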