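# Shared desk-scale synthetic survey (11 sites x 30 images, 128 px),
# generated and featurised once per test run and reused by the
# model-level checks.
.shared_data <- new.env(parent = emptyenv())

shared_survey_features <- function() {
  if (!exists("fm", envir = .shared_data)) {
    ds <- simulate_reef_survey(seed = 1)
    fm <- extract_feature_matrix(ds$images,
                                 site_id = ds$manifest$site_id,
                                 site_score = ds$manifest$site_score)
    assign("fm", fm, envir = .shared_data)
  }
  get("fm", envir = .shared_data)
}
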