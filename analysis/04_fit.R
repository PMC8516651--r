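# Fit the three continuation-ratio geostatistical stages (binomial logit,
# constrained stacker weights, country effects, nugget, Matern x AR1 knot
# field) and compose draw-level marginal severity surfaces.
source(file.path("analysis", "00_setup.R"))

fit <- run_stage("fit", config, workspace)

for (s in 1:3) print(fit$stages[[s]])
sim <- readRDS(file.path(workspace, "simulate.rds"))
pm <- apply(fit$draws$overall, c(1, 2), mean)
cat(sprintf("correlation of posterior mean overall surface with truth: %.3f\n",
            cor(as.vector(pm),
                as.vector(sim$scenario$stage_truths$overall))))
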