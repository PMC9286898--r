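make_pairs <- function(compounds, diseases) {
  expand.grid(compound_id = compounds, disease_id = diseases,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

test_that("the unknown-pair pool is the exact grid complement", {
  expect_equal(nrow(complement_pool(c("c1", "c2"), c("d1", "d2"),
                                    make_pairs(character(0), character(0)))),
               4L)

  set.seed(2)
  compounds <- paste0("c", 1:15)
  diseases <- paste0("d", 1:6)
  grid <- make_pairs(compounds, diseases)
  pos <- grid[sample(nrow(grid), 23), ]
  pool <- complement_pool(compounds, diseases, pos)
  expect_equal(nrow(pool), 15 * 6 - 23)
  # brute-force complement
  key <- function(df) paste(df$compound_id, df$disease_id)
  expect_setequal(key(pool), setdiff(key(grid), key(pos)))
  # sizes always sum to the full grid
  expect_equal(nrow(pool) + nrow(pos), nrow(grid))

  bad <- rbind(pos, data.frame(compound_id = "c99", disease_id = "d1"))
  expect_error(complement_pool(compounds, diseases, bad), "c99")
})

test_that("negative sampling is uniform, seeded and bounded", {
  pool <- make_pairs(paste0("c", 1:5), paste0("d", 1:2))

  expect_setequal(paste(sample_negatives(pool, 10, 1)$compound_id,
                        sample_negatives(pool, 10, 1)$disease_id),
                  paste(pool$compound_id, pool$disease_id))
  expect_error(sample_negatives(pool, 11, 1), "only")
  expect_identical(sample_negatives(pool, 4, 99), sample_negatives(pool, 4, 99))
  expect_true(all(sample_negatives(pool, 4, 1)$label == "negative"))

  # inclusion frequency of each pair ~ Binomial(n, 1/2) over repeated draws
  reps <- 10000
  counts <- numeric(nrow(pool))
  for (i in seq_len(reps)) {
    s <- sample_negatives(pool, 5, i)
    counts <- counts + (paste(pool$compound_id, pool$disease_id) %in%
                          paste(s$compound_id, s$disease_id))
  }
  freq <- counts / reps
  sigma <- sqrt(0.5 * 0.5 / reps)
  expect_true(all(abs(freq - 0.5) <= 3 * sigma))
})

test_that("ratio datasets honour class arithmetic and the 75/25 split", {
  set.seed(4)
  compounds <- paste0("c", 1:40)
  diseases <- paste0("d", 1:10)
  grid <- make_pairs(compounds, diseases)
  pos <- grid[sample(nrow(grid), 60), ]
  pool <- complement_pool(compounds, diseases, pos)

  # 1:3 at sample size 8 -> 2 positives + 6 negatives
  sets <- make_ratio_datasets(pos, pool,
                              split_spec(sample_size = 8, repeats = 1,
                                         ratio_neg_per_pos = 3, seed = 1))
  sp <- sets[["3"]][[1]]
  all_pairs <- rbind(sp$train, sp$test)
  expect_equal(sum(all_pairs$label == "positive"), 2L)
  expect_equal(sum(all_pairs$label == "negative"), 6L)

  # counts preserved across the whole ratio series
  spec <- split_spec(sample_size = 120, repeats = 2, seed = 5)
  sets <- make_ratio_datasets(pos, pool, spec, ratios = 1:5)
  for (r in 1:5) {
    for (i in 1:2) {
      sp <- sets[[as.character(r)]][[i]]
      n_pos <- 120 %/% (1 + r)
      expect_equal(sum(sp$train$label == "positive"), floor(0.75 * n_pos))
      expect_equal(sum(rbind(sp$train, sp$test)$label == "positive"), n_pos)
      expect_equal(nrow(sp$train) + nrow(sp$test), 120L)
      # train and test never share a pair
      expect_length(intersect(paste(sp$train$compound_id, sp$train$disease_id),
                              paste(sp$test$compound_id, sp$test$disease_id)),
                    0L)
    }
  }

  # reproducible from the master seed
  again <- make_ratio_datasets(pos, pool, spec, ratios = 1:5)
  expect_identical(sets, again)

  expect_error(make_ratio_datasets(pos, pool,
                                   split_spec(sample_size = 20000, seed = 1)),
               "available|pool")
})

test_that("held-out splits move whole groups and stay disjoint", {
  # 2 diseases x 10 positives each; target 10 forces exactly one disease
  pos <- make_pairs(paste0("c", 1:10), c("dA", "dB"))
  neg <- make_pairs(paste0("n", 1:10), c("dA", "dB"))
  sp <- disease_held_out_split(pos, neg, n_train_pos = 10, n_test_pos = 5,
                               seed = 2)
  tr_pos <- sp$train[sp$train$label == "positive", ]
  te_pos <- sp$test[sp$test$label == "positive", ]
  expect_length(unique(tr_pos$disease_id), 1L)
  expect_equal(nrow(tr_pos), 10L)
  expect_equal(nrow(te_pos), 5L)
  expect_length(intersect(unique(tr_pos$disease_id),
                          unique(te_pos$disease_id)), 0L)

  # a single compound cannot be separated
  one <- make_pairs("c1", paste0("d", 1:30))
  expect_error(compound_held_out_split(one, one, 10, 5, seed = 1), "single")

  # unreachable targets fail loudly
  expect_error(disease_held_out_split(pos, neg, 100, 5, seed = 1),
               "cannot reach")
  expect_error(disease_held_out_split(pos, neg, 20, 5, seed = 1),
               "left for testing")
})

test_that("held-out splits are reproducible and leak-free across seeds", {
  set.seed(8)
  w <- simulate_cdr_world(sim_config(n_compounds = 30, n_diseases = 12,
                                     d_compound = 8, d_disease = 6, seed = 21))
  pos <- w$pairs[w$pairs$label == "positive", ]
  neg <- w$pairs[w$pairs$label == "negative", ]
  for (seed in c(1, 7, 23)) {
    for (fn in list(disease_held_out_split, compound_held_out_split)) {
      sp <- fn(pos, neg, n_train_pos = 60, n_test_pos = 20, seed = seed)
      expect_identical(sp, fn(pos, neg, n_train_pos = 60, n_test_pos = 20,
                              seed = seed))
      grp <- if (identical(fn, disease_held_out_split)) "disease_id" else
        "compound_id"
      for (lab in c("positive", "negative")) {
        tr <- sp$train[sp$train$label == lab, ]
        te <- sp$test[sp$test$label == lab, ]
        expect_length(intersect(unique(tr[[grp]]), unique(te[[grp]])), 0L)
      }
      expect_gte(sp$provenance$realized_train_pos, 60)
      expect_equal(sum(sp$test$label == "positive"), 20L)
    }
  }
})

test_that("split manifests serialize to JSON", {
  pos <- make_pairs(paste0("c", 1:10), c("dA", "dB"))
  sp <- disease_held_out_split(pos, pos, 10, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$train), nrow(sp$train))
  expect_equal(back$provenance$mode, "disease_held_out")
})
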