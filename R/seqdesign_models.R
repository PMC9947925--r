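# Attention-based encoder-decoder models for peptide sequence design.
#
# Encoder: two convolutional blocks. Block A (8 masked 3x3 conv layers)
# reads the intermolecular distance maps; block B (4 layers) reads the
# peptide-internal maps. Binding-site amino-acid/secondary-structure
# embeddings (masked mean over true site residues) and the oligomeric
# label form a per-complex context vector. Per-position block outputs and
# the broadcast context are projected to the feature tensor F, whose
# second dimension equals the 6 peptide positions.
#
# Decoder: a bidirectional LSTM pass over F provides annotations
# (concatenated forward/backward hidden states); an LSTM with additive
# (Bahdanau-style) attention over the annotations then emits one 20-way
# amino-acid distribution per position, with teacher forcing during
# training and greedy argmax decoding at prediction time.
#
# The six-output model reuses the single-output model's encoder with
# frozen weights and runs its own decoder five times, each pass seeded
# with the final LSTM state of the previous pass; the single-output
# model's prediction is appended as the sixth design.

#' Configuration of the sequence-design model
#'
#' Sizes are reconstructions chosen for desk-scale training, not published
#' values; all are configurable.
#'
#' @param conv_inter channel widths of the 8 conv layers over the
#'   intermolecular maps.
#' @param conv_intra channel widths of the 4 conv layers over the
#'   peptide-internal maps.
#' @param emb_aa,emb_ss site amino-acid / secondary-structure embedding
#'   dimensions.
#' @param emb_dec decoder previous-token embedding dimension.
#' @param d_model depth of the feature tensor F (per peptide position).
#' @param enc_rnn hidden units per direction of the bidirectional LSTM.
#' @param dec_rnn decoder LSTM hidden units.
#' @param att attention projection dimension.
#' @param seed parameter-initialization seed.
#' @return an object of class `designer_config`.
#' @export
designer_config <- function(conv_inter = c(16, 16, 16, 24, 24, 24, 32, 32),
                            conv_intra = c(16, 16, 24, 24),
                            emb_aa = 16, emb_ss = 8, emb_dec = 24,
                            d_model = 256, enc_rnn = 48, dec_rnn = 96,
                            att = 64, seed = 1L) {
  if (length(conv_inter) != 8) stop("conv_inter must list 8 layer widths")
  if (length(conv_intra) != 4) stop("conv_intra must list 4 layer widths")
  stopifnot(d_model > 0, enc_rnn > 0, dec_rnn > 0, att > 0,
            emb_aa > 0, emb_ss > 0, emb_dec > 0)
  structure(list(conv_inter = as.integer(conv_inter),
                 conv_intra = as.integer(conv_intra),
                 emb_aa = as.integer(emb_aa), emb_ss = as.integer(emb_ss),
                 emb_dec = as.integer(emb_dec),
                 d_model = as.integer(d_model),
                 enc_rnn = as.integer(enc_rnn),
                 dec_rnn = as.integer(dec_rnn), att = as.integer(att),
                 seed = as.integer(seed)),
            class = "designer_config")
}

init_encoder_params <- function(cfg) {
  p <- list()
  widths <- c(2L, cfg$conv_inter)
  p$conv_a <- lapply(seq_len(8), function(l)
    list(w = new_param(glorot(9 * widths[l], widths[l + 1]),
                       sprintf("conv_a%d_w", l)),
         b = new_param(numeric(widths[l + 1]), sprintf("conv_a%d_b", l))))
  widths <- c(2L, cfg$conv_intra)
  p$conv_b <- lapply(seq_len(4), function(l)
    list(w = new_param(glorot(9 * widths[l], widths[l + 1]),
                       sprintf("conv_b%d_w", l)),
         b = new_param(numeric(widths[l + 1]), sprintf("conv_b%d_b", l))))
  p$E_aa <- new_param(glorot(21, cfg$emb_aa), "E_aa")
  p$E_ss <- new_param(glorot(4, cfg$emb_ss), "E_ss")
  d_in <- cfg$conv_inter[8] + cfg$conv_intra[4] + cfg$emb_aa + cfg$emb_ss + 1L
  p$W_f <- new_param(glorot(d_in, cfg$d_model), "W_f")
  p$b_f <- new_param(numeric(cfg$d_model), "b_f")
  p
}

init_decoder_params <- function(cfg) {
  U <- cfg$enc_rnn
  H <- cfg$dec_rnn
  p <- list()
  p$fwd <- list(wx = new_param(glorot(cfg$d_model, 4 * U), "enc_fwd_wx"),
                wh = new_param(glorot(U, 4 * U), "enc_fwd_wh"),
                b = new_param(numeric(4 * U), "enc_fwd_b"))
  p$bwd <- list(wx = new_param(glorot(cfg$d_model, 4 * U), "enc_bwd_wx"),
                wh = new_param(glorot(U, 4 * U), "enc_bwd_wh"),
                b = new_param(numeric(4 * U), "enc_bwd_b"))
  p$W1 <- new_param(glorot(2 * U, cfg$att), "att_w1")
  p$W2 <- new_param(glorot(H, cfg$att), "att_w2")
  p$b_att <- new_param(numeric(cfg$att), "att_b")
  p$v <- new_param(glorot(cfg$att, 1), "att_v")
  p$E_dec <- new_param(glorot(21, cfg$emb_dec), "E_dec")
  p$lstm <- list(wx = new_param(glorot(cfg$emb_dec + 2 * U, 4 * H),
                                "dec_wx"),
                 wh = new_param(glorot(H, 4 * H), "dec_wh"),
                 b = new_param(numeric(4 * H), "dec_b"))
  p$W_o <- new_param(glorot(H + 2 * U, 20), "out_w")
  p$b_o <- new_param(numeric(20), "out_b")
  p
}

flatten_params <- function(p) {
  out <- list()
  rec <- function(x) {
    if (inherits(x, "nn_param")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) rec(e)
  }
  rec(p)
  out
}

#' Build the single-output sequence designer
#'
#' @param config a [designer_config()].
#' @return an object of class `seq_designer`.
#' @export
build_seq_designer <- function(config = designer_config()) {
  stopifnot(inherits(config, "designer_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  structure(list(config = config,
                 encoder = init_encoder_params(config),
                 decoder = init_decoder_params(config)),
            class = "seq_designer")
}

# Fixed input conditioning: distance maps enter the convolutions scaled by
# 0.1 (values ~O(1)) so Glorot-initialized layers start in their linear
# regime.  This is a network-side constant, not a featurization option;
# stored tensors stay in raw Angstrom.
DIST_INPUT_SCALE <- 0.1

# Encoder forward pass: returns F as a list of 6 per-position nodes (B x D)
encoder_forward <- function(enc, cfg, tp, bt) {
  B <- bt$B; S <- bt$S; W <- bt$W
  idx_inter <- conv_indices(B, S, W)
  x <- tp_const(tp, bt$inter * DIST_INPUT_SCALE)
  for (l in seq_len(8))
    x <- conv_layer(tp, x, idx_inter, enc$conv_a[[l]]$w, enc$conv_a[[l]]$b,
                    mask = bt$mask)
  feat_a <- tp_group_mean(tp, x, bt$pool_group, rep(bt$size, each = W))
  idx_intra <- conv_indices(B, W, W)
  y <- tp_const(tp, bt$intra * DIST_INPUT_SCALE)
  for (l in seq_len(4))
    y <- conv_layer(tp, y, idx_intra, enc$conv_b[[l]]$w, enc$conv_b[[l]]$b)
  grp_intra <- (rep(seq_len(B), each = W * W) - 1L) * W +
    rep(rep(seq_len(W), times = W), times = B)
  feat_b <- tp_group_mean(tp, y, grp_intra, rep(W, B * W))
  # masked mean of site embeddings + oligomeric label -> complex context
  tok_aa <- as.vector(t(bt$site_aa)) + 1L
  tok_ss <- as.vector(t(bt$site_ss)) + 1L
  row_mask <- as.numeric(as.vector(t(bt$site_aa)) > 0)
  grp_site <- rep(seq_len(B), each = S)
  e_aa <- tp_mask_rows(tp, tp_rows(tp, tp_leaf(tp, enc$E_aa), tok_aa),
                       row_mask)
  e_ss <- tp_mask_rows(tp, tp_rows(tp, tp_leaf(tp, enc$E_ss), tok_ss),
                       row_mask)
  ctx <- tp_cbind(tp, list(tp_group_mean(tp, e_aa, grp_site, bt$size),
                           tp_group_mean(tp, e_ss, grp_site, bt$size),
                           tp_const(tp, matrix(bt$oligo, ncol = 1))))
  ctx_bw <- tp_rows(tp, ctx, rep(seq_len(B), each = W))
  f_flat <- tp_tanh(tp, tp_add_bias(tp,
                                    tp_matmul(tp,
                                              tp_cbind(tp, list(feat_a, feat_b,
                                                                ctx_bw)),
                                              tp_leaf(tp, enc$W_f)),
                                    tp_leaf(tp, enc$b_f)))
  lapply(seq_len(W), function(w)
    tp_rows(tp, f_flat, seq(w, by = W, length.out = B)))
}

# Bidirectional LSTM pass over F -> annotation nodes (B x 2U)
annotate_forward <- function(dec, cfg, tp, f_list, B) {
  U <- cfg$enc_rnn
  W <- length(f_list)
  zero <- tp_const(tp, matrix(0, B, U))
  h <- zero; c <- zero
  fwd <- vector("list", W)
  for (w in seq_len(W)) {
    st <- lstm_step(tp, f_list[[w]], h, c, dec$fwd$wx, dec$fwd$wh,
                    dec$fwd$b, U)
    h <- st$h; c <- st$c; fwd[[w]] <- h
  }
  h <- zero; c <- zero
  bwd <- vector("list", W)
  for (w in rev(seq_len(W))) {
    st <- lstm_step(tp, f_list[[w]], h, c, dec$bwd$wx, dec$bwd$wh,
                    dec$bwd$b, U)
    h <- st$h; c <- st$c; bwd[[w]] <- h
  }
  lapply(seq_len(W), function(w) tp_cbind(tp, list(fwd[[w]], bwd[[w]])))
}

# Attention LSTM decode over 6 steps.  If targets (B x 6 integer matrix)
# is supplied the previous true token conditions each step (teacher
# forcing); otherwise the previous argmax does (greedy decoding).
# Returns logits nodes, attention matrices, decoded tokens and the final
# LSTM state.
decode_forward <- function(dec, cfg, tp, annotations, B, targets = NULL,
                           init = NULL) {
  H <- cfg$dec_rnn
  W <- length(annotations)
  w1leaf <- tp_leaf(tp, dec$W1)
  proj_ann <- lapply(annotations, function(a) tp_matmul(tp, a, w1leaf))
  h <- if (is.null(init)) tp_const(tp, matrix(0, B, H)) else init$h
  c <- if (is.null(init)) tp_const(tp, matrix(0, B, H)) else init$c
  prev <- rep(0L, B)                      # start token = pad code 0
  logits <- vector("list", W)
  alphas <- vector("list", W)
  tokens <- matrix(0L, B, W)
  for (t in seq_len(W)) {
    att <- attention_step(tp, annotations, proj_ann, h, dec$W2, dec$v,
                          dec$b_att)
    emb <- tp_rows(tp, tp_leaf(tp, dec$E_dec), prev + 1L)
    st <- lstm_step(tp, tp_cbind(tp, list(emb, att$context)), h, c,
                    dec$lstm$wx, dec$lstm$wh, dec$lstm$b, H)
    h <- st$h; c <- st$c
    lg <- tp_add_bias(tp,
                      tp_matmul(tp, tp_cbind(tp, list(h, att$context)),
                                tp_leaf(tp, dec$W_o)),
                      tp_leaf(tp, dec$b_o))
    logits[[t]] <- lg
    alphas[[t]] <- att$alpha$value
    tokens[, t] <- max.col(lg$value, ties.method = "first")
    prev <- if (is.null(targets)) tokens[, t] else targets[, t]
  }
  list(logits = logits, alphas = alphas, tokens = tokens,
       final = list(h = h, c = c))
}

softmax_rows <- function(m) {
  z <- m - apply(m, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

seq_prediction <- function(probs, alphas) {
  idx <- max.col(probs, ties.method = "first")
  structure(list(probs = probs, sequence = paste(AA_VOCAB[idx],
                                                 collapse = ""),
                 attention = alphas),
            class = "seq_prediction")
}

#' @export
print.seq_prediction <- function(x, ...) {
  cat(sprintf("<seq_prediction> %s\n", x$sequence))
  invisible(x)
}

#' Predict sequences for a batch of featurized complexes
#'
#' Greedy argmax decoding; deterministic.
#'
#' @param model a `seq_designer`.
#' @param fts list of `feature_tensors` (or a single one).
#' @return list of `seq_prediction` (fields `probs` 6 x 20 row-stochastic,
#'   `sequence`, `attention` 6 x 6 step-by-position weights).
#' @export
predict_batch <- function(model, fts) {
  stopifnot(inherits(model, "seq_designer"))
  if (inherits(fts, "feature_tensors")) fts <- list(fts)
  bt <- batch_tensors(fts)
  tp <- new_tape()
  f_list <- encoder_forward(model$encoder, model$config, tp, bt)
  ann <- annotate_forward(model$decoder, model$config, tp, f_list, bt$B)
  dc <- decode_forward(model$decoder, model$config, tp, ann, bt$B)
  lapply(seq_len(bt$B), function(b) {
    probs <- do.call(rbind, lapply(dc$logits, function(lg)
      softmax_rows(lg$value[b, , drop = FALSE])))
    alph <- do.call(rbind, lapply(dc$alphas, function(a)
      a[b, , drop = FALSE]))
    seq_prediction(probs, alph)
  })
}

#' Predict a single design
#'
#' @param model a `seq_designer`.
#' @param ft one `feature_tensors`.
#' @return a `seq_prediction`.
#' @export
predict_single <- function(model, ft) {
  stopifnot(inherits(ft, "feature_tensors"))
  predict_batch(model, list(ft))[[1]]
}

#' Training configuration
#'
#' The default schedule is three stages: 5 epochs at learning rate 1e-3,
#' 5 at 1e-4 and 2 at 2e-5 (single-output model); see
#' [train_config_multi()] for the 4/4/2 six-output schedule and
#' [train_config_overfit()] for the extended memorization schedule.
#'
#' @param stages list of `c(epochs, lr)` pairs.
#' @param batch_size minibatch size.
#' @param seed shuffling seed.
#' @param loss `"ce"` (categorical cross-entropy); the six-output model
#'   additionally accepts `"min_ce"` (default) and `"mse"`.
#' @param lambda_div diversity-penalty weight (six-output model only).
#' @return an object of class `train_config`.
#' @export
train_config <- function(stages = list(c(5, 1e-3), c(5, 1e-4), c(2, 2e-5)),
                         batch_size = 16L, seed = 1L, loss = "ce",
                         lambda_div = 0.1, clip = 5) {
  stopifnot(length(stages) >= 1,
            all(vapply(stages, function(s) length(s) == 2 && s[2] > 0,
                       logical(1))))
  structure(list(stages = stages, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = loss,
                 lambda_div = lambda_div, clip = clip),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_multi <- function(stages = list(c(4, 1e-3), c(4, 1e-4),
                                             c(2, 2e-5)),
                               batch_size = 16L, seed = 1L,
                               loss = "min_ce", lambda_div = 0.1,
                               clip = 5) {
  train_config(stages, batch_size, seed, loss, lambda_div, clip)
}

#' @rdname train_config
#' @export
train_config_overfit <- function(seed = 1L) {
  train_config(stages = list(c(90, 2e-3), c(30, 1e-3), c(20, 5e-4)),
               batch_size = 10L, seed = seed)
}

targets_to_tokens <- function(targets) {
  do.call(rbind, lapply(strsplit(targets, ""), aa_encode))
}

#' Train the single-output designer
#'
#' Minibatch Adam with teacher forcing and categorical cross-entropy,
#' following the staged learning-rate schedule in `tc`. Reproducible
#' given `tc$seed`.
#'
#' @param model a `seq_designer` (updated in place and returned).
#' @param fts list of `feature_tensors`.
#' @param targets character vector of 6-letter target sequences.
#' @param tc a [train_config()].
#' @return list with `model` and `history` (mean loss per epoch, with a
#'   `stage` attribute giving each epoch's stage index).
#' @export
train_seq_designer <- function(model, fts, targets, tc = train_config()) {
  stopifnot(inherits(model, "seq_designer"), inherits(tc, "train_config"))
  if (length(fts) == 0) stop("empty training dataset")
  stopifnot(length(fts) == length(targets))
  tok <- targets_to_tokens(targets)
  params <- flatten_params(list(model$encoder, model$decoder))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tc$seed)
  history <- numeric(0)
  stage_of <- integer(0)
  step <- 0L
  n <- length(fts)
  for (si in seq_along(tc$stages)) {
    epochs <- tc$stages[[si]][1]
    lr <- tc$stages[[si]][2]
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1, n)]
        bt <- batch_tensors(fts[idx])
        tgt <- tok[idx, , drop = FALSE]
        tp <- new_tape()
        f_list <- encoder_forward(model$encoder, model$config, tp, bt)
        ann <- annotate_forward(model$decoder, model$config, tp, f_list,
                                bt$B)
        dc <- decode_forward(model$decoder, model$config, tp, ann, bt$B,
                             targets = tgt)
        ce <- NULL
        for (t in seq_len(PEPTIDE_LEN)) {
          term <- tp_ce_rows(tp, dc$logits[[t]], tgt[, t])
          ce <- if (is.null(ce)) term else tp_add(tp, ce, term)
        }
        loss <- tp_scale(tp, tp_sum(tp, ce), 1 / (bt$B * PEPTIDE_LEN))
        nn_backward(tp, loss)
        step <- step + 1L
        adam_step(params, lr, t = step, clip = tc$clip)
        ep_loss <- ep_loss + loss$value[1, 1]
        nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
      stage_of <- c(stage_of, si)
    }
  }
  attr(history, "stage") <- stage_of
  list(model = model, history = history)
}

#' Training-set sequence recovery of a model
#'
#' @param model a `seq_designer` or `multi_designer`.
#' @param fts list of `feature_tensors`.
#' @param targets character vector of native sequences.
#' @param best_of_n for a `multi_designer`, score each complex by its best
#'   design (default) instead of the mean over designs.
#' @return mean per-residue recovery over the dataset.
#' @export
model_recovery <- function(model, fts, targets, best_of_n = TRUE) {
  if (inherits(model, "multi_designer")) {
    sets <- predict_designs(model, fts)
    r <- vapply(seq_along(fts), function(i) {
      seqs <- vapply(sets[[i]]$predictions, `[[`, character(1), "sequence")
      if (best_of_n) best_of_n_recovery(targets[i], seqs)
      else mean(vapply(seqs, function(s)
        sequence_recovery(targets[i], s), numeric(1)))
    }, numeric(1))
  } else {
    preds <- predict_batch(model, fts)
    r <- vapply(seq_along(fts), function(i)
      sequence_recovery(targets[i], preds[[i]]$sequence), numeric(1))
  }
  mean(r)
}

#' Select the best model by validation recovery
#'
#' Returns the candidate with the highest summed recovery over the
#' designated validation subsets (ties: first listed).
#'
#' @param candidates list of models.
#' @param val_sets list of validation subsets, each a list with `fts` and
#'   `targets` (hetero-oligomeric subsets in the reference protocol).
#' @return the winning model.
#' @export
select_best_model <- function(candidates, val_sets) {
  stopifnot(length(candidates) >= 1)
  scores <- vapply(candidates, function(m)
    sum(vapply(val_sets, function(v)
      model_recovery(m, v$fts, v$targets), numeric(1))), numeric(1))
  candidates[[which.max(scores)]]
}

#' Build the six-output designer from a trained single-output model
#'
#' The encoder weights are copied from the single-output model and frozen
#' (untrainable); the decoder is initialized fresh. At prediction time the
#' decoder runs five sequential passes, each receiving the previous pass's
#' final LSTM state as its initial state, and the single-output model's
#' prediction is appended as the sixth design.
#'
#' @param single a trained `seq_designer`.
#' @param config optional `designer_config` for the new decoder; defaults
#'   to the single model's config.
#' @return an object of class `multi_designer`.
#' @export
build_multi_designer <- function(single, config = NULL) {
  if (!inherits(single, "seq_designer"))
    stop("a trained seq_designer is required")
  cfg <- config %||% single$config
  stopifnot(identical(cfg$d_model, single$config$d_model))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  enc <- init_encoder_params(single$config)
  src <- flatten_params(single$encoder)
  dst <- flatten_params(enc)
  for (i in seq_along(src)) {
    dst[[i]]$value <- src[[i]]$value
    dst[[i]]$trainable <- FALSE
  }
  structure(list(config = cfg, encoder = enc,
                 decoder = init_decoder_params(cfg),
                 single = single, n_designs = 5L),
            class = "multi_designer")
}

multi_forward <- function(model, tp, bt, targets = NULL) {
  f_list <- encoder_forward(model$encoder, model$config, tp, bt)
  ann <- annotate_forward(model$decoder, model$config, tp, f_list, bt$B)
  passes <- vector("list", model$n_designs)
  init <- NULL
  for (k in seq_len(model$n_designs)) {
    dc <- decode_forward(model$decoder, model$config, tp, ann, bt$B,
                         targets = targets, init = init)
    init <- dc$final
    passes[[k]] <- dc
  }
  passes
}

#' Predict six designs per complex
#'
#' @param model a `multi_designer`.
#' @param fts list of `feature_tensors` (or one).
#' @return list of `design_set` objects (6 `seq_prediction` entries; entry
#'   6 is the single-output model's prediction).
#' @export
predict_designs <- function(model, fts) {
  stopifnot(inherits(model, "multi_designer"))
  if (inherits(fts, "feature_tensors")) fts <- list(fts)
  bt <- batch_tensors(fts)
  tp <- new_tape()
  passes <- multi_forward(model, tp, bt)
  singles <- predict_batch(model$single, fts)
  lapply(seq_len(bt$B), function(b) {
    preds <- lapply(passes, function(dc) {
      probs <- do.call(rbind, lapply(dc$logits, function(lg)
        softmax_rows(lg$value[b, , drop = FALSE])))
      alph <- do.call(rbind, lapply(dc$alphas, function(a)
        a[b, , drop = FALSE]))
      seq_prediction(probs, alph)
    })
    preds[[6]] <- singles[[b]]
    structure(list(predictions = preds, single_index = 6L),
              class = "design_set")
  })
}

#' @export
print.design_set <- function(x, ...) {
  cat("<design_set>\n")
  for (i in seq_along(x$predictions))
    cat(sprintf("  %d: %s%s\n", i, x$predictions[[i]]$sequence,
                if (i == x$single_index) "  (single-output model)" else ""))
  invisible(x)
}

#' Train the six-output designer
#'
#' Encoder gradients are blocked (frozen weights). The default objective
#' is the per-sample minimum over the five decoder passes of the
#' cross-entropy against the single target, plus a pairwise diversity
#' penalty `lambda_div * mean probability overlap`; `loss = "mse"`
#' substitutes squared error between output distributions and the one-hot
#' target for the cross-entropy term.
#'
#' @param model a `multi_designer` (updated in place and returned).
#' @param fts list of `feature_tensors`.
#' @param targets character vector of 6-letter target sequences.
#' @param tc a [train_config_multi()].
#' @return list with `model` and `history`.
#' @export
train_multi_designer <- function(model, fts, targets,
                                 tc = train_config_multi()) {
  stopifnot(inherits(model, "multi_designer"), inherits(tc, "train_config"))
  if (length(fts) == 0) stop("empty training dataset")
  use_mse <- identical(tc$loss, "mse")
  tok <- targets_to_tokens(targets)
  params <- flatten_params(model$decoder)   # encoder frozen by flag anyway
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tc$seed)
  history <- numeric(0)
  step <- 0L
  n <- length(fts)
  K <- model$n_designs
  for (si in seq_along(tc$stages)) {
    for (ep in seq_len(tc$stages[[si]][1])) {
      lr <- tc$stages[[si]][2]
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1, n)]
        bt <- batch_tensors(fts[idx])
        tgt <- tok[idx, , drop = FALSE]
        tp <- new_tape()
        passes <- multi_forward(model, tp, bt, targets = tgt)
        per_pass <- lapply(passes, function(dc) {
          acc <- NULL
          for (t in seq_len(PEPTIDE_LEN)) {
            term <- if (use_mse) tp_mse_rows(tp, dc$logits[[t]], tgt[, t])
                    else tp_ce_rows(tp, dc$logits[[t]], tgt[, t])
            acc <- if (is.null(acc)) term else tp_add(tp, acc, term)
          }
          acc
        })
        best <- tp_row_min(tp, tp_cbind(tp, per_pass))
        loss <- tp_scale(tp, tp_sum(tp, best), 1 / (bt$B * PEPTIDE_LEN))
        if (tc$lambda_div > 0) {
          probs <- lapply(passes, function(dc)
            lapply(dc$logits, function(lg) tp_softmax(tp, lg)))
          overlap <- NULL
          for (k in seq_len(K - 1)) for (l in (k + 1):K)
            for (t in seq_len(PEPTIDE_LEN)) {
              term <- tp_sum(tp, tp_mul(tp, probs[[k]][[t]],
                                        probs[[l]][[t]]))
              overlap <- if (is.null(overlap)) term
                         else tp_add(tp, overlap, term)
            }
          npair <- K * (K - 1) / 2
          loss <- tp_add(tp, loss,
                         tp_scale(tp, overlap,
                                  tc$lambda_div /
                                    (npair * PEPTIDE_LEN * bt$B)))
        }
        nn_backward(tp, loss)
        step <- step + 1L
        adam_step(params, lr, t = step, clip = tc$clip)
        ep_loss <- ep_loss + loss$value[1, 1]
        nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
    }
  }
  list(model = model, history = history)
}

#' Export a position-specific scoring matrix
#'
#' The 6 x 20 probability table of a prediction (or the element-wise mean
#' over a design set's entries), with per-position allowed-residue lists
#' for k in {3, 5, 20} (the top-k restriction sets used for constrained
#' redesign). Ties are broken alphabetically.
#'
#' @param pred a `seq_prediction` or `design_set`.
#' @return an object of class `pssm`: list with `table` (6 x 20, rows sum
#'   to 1, columns named by amino acid) and `allowed` (per k, a list of 6
#'   character vectors).
#' @export
export_pssm <- function(pred) {
  probs <- if (inherits(pred, "design_set")) {
    Reduce(`+`, lapply(pred$predictions, `[[`, "probs")) /
      length(pred$predictions)
  } else if (inherits(pred, "seq_prediction")) {
    pred$probs
  } else stop("pred must be a seq_prediction or design_set")
  colnames(probs) <- AA_VOCAB
  allowed <- lapply(c(3, 5, 20), function(k)
    lapply(seq_len(nrow(probs)), function(i) {
      ord <- order(-probs[i, ], AA_VOCAB)
      AA_VOCAB[ord][seq_len(k)]
    }))
  names(allowed) <- paste0("k", c(3, 5, 20))
  structure(list(table = probs, allowed = allowed), class = "pssm")
}

#' Write a PSSM as a tab-separated table
#'
#' Header row holds the 20 amino-acid letters; one row per peptide
#' position.
#'
#' @param pssm a `pssm` from [export_pssm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  df <- as.data.frame(pssm$table)
  df <- cbind(position = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a designer checkpoint
#'
#' Single-file archive holding the config, all weights and the vocabulary;
#' a `multi_designer` checkpoint embeds its single-output model.
#'
#' @param model a `seq_designer` or `multi_designer`.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly (save); the model (load).
#' @export
save_designer <- function(model, path) {
  strip <- function(m) {
    if (inherits(m, "multi_designer"))
      list(class = "multi_designer", config = m$config,
           encoder = param_values(m$encoder),
           decoder = param_values(m$decoder),
           single = strip(m$single), n_designs = m$n_designs)
    else
      list(class = "seq_designer", config = m$config,
           encoder = param_values(m$encoder),
           decoder = param_values(m$decoder))
  }
  saveRDS(list(format = "pepdesign-checkpoint-1", vocab = AA_VOCAB,
               model = strip(model)), path)
  invisible(path)
}

param_values <- function(p) {
  if (inherits(p, "nn_param")) list(.value = p$value,
                                    .trainable = p$trainable)
  else lapply(p, param_values)
}

restore_values <- function(p, v) {
  if (inherits(p, "nn_param")) {
    p$value <- v$.value
    p$trainable <- v$.trainable
  } else for (nm in names(p)) restore_values(p[[nm]], v[[nm]])
  invisible(NULL)
}

#' @rdname save_designer
#' @export
load_designer <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pepdesign-checkpoint-1"))
    stop("not a designer checkpoint: ", path)
  if (!identical(ck$vocab, AA_VOCAB))
    stop("checkpoint vocabulary does not match this package build")
  rebuild <- function(m) {
    if (identical(m$class, "multi_designer")) {
      single <- rebuild(m$single)
      out <- build_multi_designer(single, m$config)
      restore_values(out$encoder, m$encoder)
      restore_values(out$decoder, m$decoder)
      out$n_designs <- m$n_designs
      out
    } else {
      out <- build_seq_designer(m$config)
      restore_values(out$encoder, m$encoder)
      restore_values(out$decoder, m$decoder)
      out
    }
  }
  rebuild(ck$model)
}
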