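# Heavy shared campaigns, computed once per test run and reused across
# acceptance blocks.

.shared <- new.env(parent = emptyenv())

shared <- function(key, expr) {
  if (!exists(key, envir = .shared)) assign(key, force(expr), envir = .shared)
  get(key, envir = .shared)
}

shared_beis_campaign <- function() {
  shared("beis100", run_one_year(beis_params(), replicates = 100,
                                 base_seed = 1000))
}

shared_neutral_campaign <- function() {
  shared("neutral100", run_one_year(model_params(), replicates = 100,
                                    base_seed = 2000))
}
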