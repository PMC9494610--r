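# A moderately trained classifier shared across test files. Built lazily
# once per session: training-set assembly, fit, plus the generator objects
# it came from, so TRRS tests can reuse the pool and motif configuration.

.test_model_cache <- new.env(parent = emptyenv())

test_model_bundle <- function() {
  if (!is.null(.test_model_cache$bundle)) return(.test_model_cache$bundle)
  cfg <- repertoire_sim_config(n_clones = 3000L, shared_fraction = 0.5,
                               seed = 101L)
  pr <- gen_paired_repertoires(cfg)
  asg <- assign_compartments(pr$pbmc, pr$til)
  tats <- extract_tats(asg, pr$pbmc)
  pool <- gen_healthy_pool(cfg, size = 6000L,
                           exclude = pr$truth$shared_sequences)
  ts <- build_training_set(list(tats), pool, seed = 102L)
  fit <- tat_cnn(ts, epochs = 25L, seed = 103L)
  .test_model_cache$bundle <- list(cfg = cfg, pool = pool, ts = ts,
                                   fit = fit)
  .test_model_cache$bundle
}
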