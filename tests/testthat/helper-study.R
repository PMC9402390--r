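# The trained end-to-end study is expensive, so it is run at most once per
# test session and shared by every test that needs trained models.
.study_cache <- new.env(parent = emptyenv())

get_phantom_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- phantom_study(seed = 1L)
  .study_cache$study
}
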