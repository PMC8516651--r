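# Build the synthetic study: truth surfaces, rasters, admin hierarchy,
# woman-level hemoglobin microdata, polygon-referenced counts, and the
# national calibration series.
source(file.path("analysis", "00_setup.R"))

sim <- run_stage("simulate", config, workspace)

cat(sprintf("scenario: %d x %d cells, years %d-%d, %d countries\n",
            sim$scenario$grid$n_rows, sim$scenario$grid$n_cols,
            min(sim$scenario$grid$years), max(sim$scenario$grid$years),
            length(sim$scenario$country_effects)))
cat(sprintf("mean overall anemia truth: %.3f\n",
            mean(sim$scenario$stage_truths$overall)))
cat(sprintf("microdata: %d women in %d cluster-years; %d areal records\n",
            nrow(sim$microdata), length(unique(sim$microdata$cluster_id)),
            nrow(sim$areal)))
publish("areal.csv", "national_series.csv", "admin2_polygons.geojson")
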