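# Seeded synthetic-SAR benchmark runs shared by the acceptance criteria.
# Six seed-replicate networks on the standard-descriptor block per noise
# level; cached for the session because LOO training dominates runtime.

benchmark_runs <- function(noise_sd, n_models = 6, generator_seed = 1) {
  key <- sprintf("bench_%s_%d_%d", noise_sd, n_models, generator_seed)
  cache_get(key, function() {
    sar <- generate_sar_dataset(63, noise_sd = noise_sd, seed = generator_seed)
    fb <- featurize(sar, "standard")
    per_model <- tibble::tibble(id = sar$id, observed = sar$mgs_percent)
    for (k in seq_len(n_models)) {
      cfg <- model_config("regression",
                         seed = iriscreen:::derive_seed(generator_seed, k))
      per_model[[sprintf("model%d", k)]] <- loo_cv(sar, fb, cfg)$prediction
    }
    attr(per_model, "task") <- "regression"
    class(per_model) <- c("iri_loo_multi", class(per_model))
    list(sar = sar, per_model = per_model)
  })
}

# Analytic noise ceiling sqrt(Var_signal / (Var_signal + sigma^2)).
noise_ceiling <- function(sar, noise_sd) {
  vs <- stats::var(sar$true_mgs)
  sqrt(vs / (vs + noise_sd^2))
}
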