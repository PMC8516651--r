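# Fit the three child learners (additive smooths, boosted trees, lasso) per
# continuation-ratio stage; their out-of-fold predictions become the parent
# model's covariates.
source(file.path("analysis", "00_setup.R"))

stk <- run_stage("stack", config, workspace)

for (s in 1:3) {
  po <- stk$stacks[[s]]$pred_obs
  cat(sprintf("stage %d stacker predictions: %d obs, logit range %.2f..%.2f\n",
              s, sum(stats::complete.cases(po)), min(po, na.rm = TRUE),
              max(po, na.rm = TRUE)))
}
publish("stacker_obs_stage1.csv", "stacker_obs_stage2.csv",
        "stacker_obs_stage3.csv")
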