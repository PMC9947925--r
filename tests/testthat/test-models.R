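test_that("forward pass yields row-stochastic outputs and normalized attention", {
  m <- build_seq_designer(tiny_config(seed = 1))
  for (seed in 1:3) {
    ft <- random_tensors(seed = seed, site_size = sample(24:48, 1))
    p <- predict_single(m, ft)
    expect_equal(dim(p$probs), c(6, 20))
    expect_equal(rowSums(p$probs), rep(1, 6), tolerance = 1e-9)
    expect_true(all(p$probs >= 0))
    expect_equal(dim(p$attention), c(6, 6))
    expect_equal(rowSums(p$attention), rep(1, 6), tolerance = 1e-9)
    expect_true(all(p$attention >= 0))
    # decoded sequence is the argmax of probs
    expect_equal(p$sequence,
                 paste(pepdesign:::AA_VOCAB[max.col(p$probs,
                                                    ties.method = "first")],
                       collapse = ""))
  }
})

test_that("the feature tensor F spans exactly the 6 peptide positions", {
  m <- build_seq_designer(tiny_config(seed = 2))
  ft <- featurize_complex(toy_record(seed = 3))
  bt <- pepdesign:::batch_tensors(list(ft))
  tp <- pepdesign:::new_tape()
  f_list <- pepdesign:::encoder_forward(m$encoder, m$config, tp, bt)
  expect_length(f_list, 6L)
  for (f in f_list)
    expect_equal(dim(f$value), c(1, m$config$d_model))
})

test_that("prediction is deterministic and invariant to extra zero padding", {
  m <- build_seq_designer(tiny_config(seed = 3))
  cr <- toy_record(seed = 4, site_size = 26L)
  ft48 <- featurize_complex(cr)                 # standard 48-row capacity
  expect_identical(predict_single(m, ft48)$probs,
                   predict_single(m, ft48)$probs)
  ft26 <- featurize_complex(cr, capacity = 26L) # no padding at all
  ft60 <- featurize_complex(cr, capacity = 60L) # extra all-zero rows
  p48 <- predict_single(m, ft48)
  p26 <- predict_single(m, ft26)
  p60 <- predict_single(m, ft60)
  expect_equal(p26$probs, p48$probs, tolerance = 1e-10)
  expect_equal(p60$probs, p48$probs, tolerance = 1e-10)
  expect_equal(p26$sequence, p48$sequence)
  expect_equal(p60$sequence, p48$sequence)
})

test_that("batched and single predictions agree", {
  m <- build_seq_designer(tiny_config(seed = 4))
  fts <- lapply(11:13, function(s) featurize_complex(toy_record(seed = s)))
  batch <- predict_batch(m, fts)
  for (i in seq_along(fts)) {
    solo <- predict_single(m, fts[[i]])
    expect_equal(batch[[i]]$probs, solo$probs, tolerance = 1e-8)
    expect_equal(batch[[i]]$sequence, solo$sequence)
  }
})

test_that("model selection is argmax of summed validation recovery, ties first", {
  ds <- planted_mapping_dataset(toy_spec(n_complexes = 4, seed = 21))
  fts <- lapply(ds$records, featurize_complex)
  val <- list(list(fts = fts, targets = ds$targets))
  m1 <- build_seq_designer(tiny_config(seed = 1))
  m2 <- build_seq_designer(tiny_config(seed = 2))
  r1 <- model_recovery(m1, fts, ds$targets)
  r2 <- model_recovery(m2, fts, ds$targets)
  best <- select_best_model(list(m1, m2), val)
  expect_identical(best, if (r2 > r1) m2 else m1)
  expect_identical(select_best_model(list(m1), val), m1)
  # exact tie: the same model twice -> first listed
  expect_identical(select_best_model(list(m1, m1), val), m1)
})

test_that("six-output designer meets its structural contracts", {
  single <- build_seq_designer(tiny_config(seed = 5))
  multi <- build_multi_designer(single)
  ft <- featurize_complex(toy_record(seed = 31))
  ds <- predict_designs(multi, ft)[[1]]
  expect_s3_class(ds, "design_set")
  expect_length(ds$predictions, 6L)
  # entry 6 is the single-output model's prediction
  solo <- predict_single(single, ft)
  expect_equal(ds$predictions[[6]]$sequence, solo$sequence)
  expect_equal(ds$predictions[[6]]$probs, solo$probs)
  # best-of-six dominates the single output on any native sequence
  native <- "ACDEFG"
  seqs <- vapply(ds$predictions, `[[`, character(1), "sequence")
  expect_gte(best_of_n_recovery(native, seqs),
             sequence_recovery(native, solo$sequence))
  expect_error(build_multi_designer("not a model"), "seq_designer")
})

test_that("the copied encoder is frozen and bit-identical", {
  single <- build_seq_designer(tiny_config(seed = 6))
  multi <- build_multi_designer(single)
  enc_single <- lapply(pepdesign:::flatten_params(single$encoder),
                       function(p) p$value)
  enc_multi <- lapply(pepdesign:::flatten_params(multi$encoder),
                      function(p) p$value)
  expect_identical(enc_single, enc_multi)
  expect_true(all(!vapply(pepdesign:::flatten_params(multi$encoder),
                          function(p) p$trainable, logical(1))))
})

test_that("PSSM export orders residues by probability with alphabetical ties", {
  uni <- structure(list(probs = matrix(1 / 20, 6, 20),
                        sequence = "AAAAAA", attention = NULL),
                   class = "seq_prediction")
  ps <- export_pssm(uni)
  expect_equal(rowSums(ps$table), rep(1, 6))
  expect_equal(ps$allowed$k3[[1]], c("A", "C", "D"))
  expect_equal(length(ps$allowed$k5[[2]]), 5L)
  expect_equal(sort(ps$allowed$k20[[1]]), sort(pepdesign:::AA_VOCAB))

  onehot <- matrix(0, 6, 20)
  onehot[, 19] <- 1   # W
  oh <- structure(list(probs = onehot, sequence = "WWWWWW",
                       attention = NULL), class = "seq_prediction")
  expect_equal(export_pssm(oh)$allowed$k3[[4]][1], "W")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(ps, path)
  tab <- read.delim(path)
  expect_equal(dim(tab), c(6, 21))
  expect_equal(colnames(tab)[2], "A")
  expect_error(export_pssm(1:3), "seq_prediction")
})

test_that("checkpoints round-trip models exactly", {
  single <- build_seq_designer(tiny_config(seed = 7))
  ft <- featurize_complex(toy_record(seed = 41))
  path <- withr::local_tempfile(fileext = ".rds")
  save_designer(single, path)
  back <- load_designer(path)
  expect_equal(predict_single(back, ft)$probs,
               predict_single(single, ft)$probs)
  multi <- build_multi_designer(single)
  path2 <- withr::local_tempfile(fileext = ".rds")
  save_designer(multi, path2)
  back2 <- load_designer(path2)
  s1 <- predict_designs(multi, ft)[[1]]
  s2 <- predict_designs(back2, ft)[[1]]
  for (i in 1:6)
    expect_equal(s2$predictions[[i]]$probs, s1$predictions[[i]]$probs)
  expect_error(load_designer(withr::local_tempfile(fileext = ".rds",
                                                   lines = "x")))
})

test_that("malformed configurations are rejected at build time", {
  expect_error(designer_config(conv_inter = c(8, 8)), "8 layer widths")
  expect_error(designer_config(conv_intra = c(8, 8)), "4 layer widths")
  expect_error(designer_config(d_model = 0))
})
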