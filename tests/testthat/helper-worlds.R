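# shared fixtures, all generated in code

tiny_world <- function(seed = 3, ...) {
  simulate_cdr_world(sim_config(n_compounds = 12, n_diseases = 8,
                                d_compound = 16, d_disease = 10,
                                seed = seed, ...))
}

# a small trained classifier, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

tiny_model <- function() {
  if (is.null(.fixture_cache$model)) {
    w <- tiny_world()
    enc <- encode_world(w)
    .fixture_cache$world <- w
    .fixture_cache$enc <- enc
    .fixture_cache$model <- cdr_cnn(
      enc$images, enc$labels,
      cdr_train_config("tiny", max_epochs = 3, seed = 1))
  }
  list(model = .fixture_cache$model, world = .fixture_cache$world,
       enc = .fixture_cache$enc)
}

# independent Mann-Whitney AUC by brute-force pair counting
auc_bruteforce <- function(scores, truth, positive = "positive") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
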