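# Shared preamble for the numbered analysis drivers.
#
# The pipeline runs over a workspace of artifacts under scratch/ (heavyweight,
# re-creatable) and copies the tables a reader cares about into results/.
# Run the drivers in order, or source this file and call run_stage("all", ...).

library(anemomap)

config_path <- file.path("analysis", "config.yaml")
config <- if (file.exists(config_path)) read_config(config_path) else
  default_config()
workspace <- file.path("scratch", "workspace")
dir.create("results", showWarnings = FALSE)
dir.create(workspace, recursive = TRUE, showWarnings = FALSE)

publish <- function(...) {
  for (f in c(...)) {
    src <- file.path(workspace, f)
    if (file.exists(src)) file.copy(src, file.path("results", f),
                                    overwrite = TRUE)
  }
}
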