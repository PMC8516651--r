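# Mask uninhabited/barren cells, aggregate draws to admin 0/1/2, and derive
# counts, YLDs, public-health-problem classes and inequality summaries.
source(file.path("analysis", "00_setup.R"))

post <- run_stage("postest", config, workspace)

last <- max(config$scenario$years)
nat <- post$summaries[level == "admin0" & indicator == "overall" &
                        year == last]
cat("national overall anemia prevalence, final year:\n")
print(nat[, .(country = unit, mean = round(mean, 3),
              lower = round(lower, 3), upper = round(upper, 3))])
cat("\nwithin-country inequality (admin2, final year):\n")
print(post$inequality$by_country)
publish("admin_summaries.csv", "inequality.csv")
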