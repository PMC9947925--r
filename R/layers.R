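# Network building blocks on top of the autodiff tape: batched 3x3
# convolutions over (site x peptide) grids via gather + matmul (im2col),
# LSTM steps, and additive attention.  Feature maps are stored as flat
# matrices with row index r = ((b-1)*S + (s-1))*W + w for batch b, first
# grid axis s (site residue), second grid axis w (peptide position).

# 3x3 neighbor gather indices for a (B, S, W) grid; out-of-range neighbors
# point at an appended all-zero row (index B*S*W + 1).  Cached per shape.
.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(B, S, W) {
  key <- paste(B, S, W, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- B * S * W
  b <- rep(seq_len(B), each = S * W)
  s <- rep(rep(seq_len(S), each = W), times = B)
  w <- rep(seq_len(W), times = B * S)
  offs <- expand.grid(dw = -1:1, ds = -1:1)
  idx <- matrix(N + 1L, N, 9L)
  for (k in 1:9) {
    ss <- s + offs$ds[k]
    ww <- w + offs$dw[k]
    ok <- ss >= 1 & ss <= S & ww >= 1 & ww <= W
    idx[ok, k] <- ((b[ok] - 1L) * S + (ss[ok] - 1L)) * W + ww[ok]
  }
  .conv_cache[[key]] <- idx
  idx
}

# one masked 3x3 conv layer: im2col gather, matmul, bias, ReLU, then the
# padding mask zeroes rows belonging to padded site residues so padded
# input stays exactly zero at every depth (required for the
# padding-extension invariance of predictions)
conv_layer <- function(tp, x, idx9, w_param, b_param, mask = NULL) {
  xe <- tp_pad_zero_row(tp, x)
  parts <- lapply(seq_len(ncol(idx9)), function(k) tp_rows(tp, xe, idx9[, k]))
  m <- tp_cbind(tp, parts)
  z <- tp_add_bias(tp, tp_matmul(tp, m, tp_leaf(tp, w_param)),
                   tp_leaf(tp, b_param))
  y <- tp_relu(tp, z)
  if (!is.null(mask)) y <- tp_mask_rows(tp, y, mask) else y
}

# one LSTM step; z is split into input/forget/output/candidate gates
lstm_step <- function(tp, x, h, c, wx, wh, b, H) {
  z <- tp_add_bias(tp,
                   tp_add(tp,
                          tp_matmul(tp, x, tp_leaf(tp, wx)),
                          tp_matmul(tp, h, tp_leaf(tp, wh))),
                   tp_leaf(tp, b))
  i <- tp_sigmoid(tp, tp_cols(tp, z, 1:H))
  f <- tp_sigmoid(tp, tp_cols(tp, z, (H + 1):(2 * H)))
  o <- tp_sigmoid(tp, tp_cols(tp, z, (2 * H + 1):(3 * H)))
  g <- tp_tanh(tp, tp_cols(tp, z, (3 * H + 1):(4 * H)))
  c_new <- tp_add(tp, tp_mul(tp, f, c), tp_mul(tp, i, g))
  h_new <- tp_mul(tp, o, tp_tanh(tp, c_new))
  list(h = h_new, c = c_new)
}

# additive (Bahdanau) attention over a list of annotation nodes (B x A).
# proj_ann: precomputed a_j %*% W1 nodes; h: decoder state (B x H).
# Returns list(alpha = B x n node, context = B x A node).
attention_step <- function(tp, annotations, proj_ann, h, w2, v, b_att) {
  hw <- tp_add_bias(tp, tp_matmul(tp, h, tp_leaf(tp, w2)),
                    tp_leaf(tp, b_att))
  vleaf <- tp_leaf(tp, v)
  scores <- lapply(seq_along(annotations), function(j)
    tp_matmul(tp, tp_tanh(tp, tp_add(tp, proj_ann[[j]], hw)), vleaf))
  alpha <- tp_softmax(tp, tp_cbind(tp, scores))
  ctx <- NULL
  for (j in seq_along(annotations)) {
    term <- tp_scale_rows(tp, annotations[[j]], tp_cols(tp, alpha, j))
    ctx <- if (is.null(ctx)) term else tp_add(tp, ctx, term)
  }
  list(alpha = alpha, context = ctx)
}

# Stack a list of feature_tensors into flat batch matrices.
batch_tensors <- function(fts) {
  B <- length(fts)
  cap <- vapply(fts, function(f) dim(f$inter_maps)[1], integer(1))
  S <- max(cap)
  W <- PEPTIDE_LEN
  inter <- matrix(0, B * S * W, 2)
  intra <- matrix(0, B * W * W, 2)
  site_aa <- matrix(0L, B, S)
  site_ss <- matrix(0L, B, S)
  oligo <- numeric(B)
  size <- integer(B)
  for (b in seq_len(B)) {
    ft <- fts[[b]]
    sb <- dim(ft$inter_maps)[1]
    rows <- (b - 1) * S * W + seq_len(sb * W)
    # row-major over (s, w): transpose each channel slice
    inter[rows, 1] <- as.numeric(t(ft$inter_maps[, , 1]))
    inter[rows, 2] <- as.numeric(t(ft$inter_maps[, , 2]))
    rows2 <- (b - 1) * W * W + seq_len(W * W)
    intra[rows2, 1] <- as.numeric(t(ft$intra_maps[, , 1]))
    intra[rows2, 2] <- as.numeric(t(ft$intra_maps[, , 2]))
    site_aa[b, seq_len(length(ft$site_aa))] <- ft$site_aa
    site_ss[b, seq_len(length(ft$site_ss))] <- ft$site_ss
    oligo[b] <- ft$oligo
    size[b] <- ft$site_size
  }
  s_of_row <- rep(rep(seq_len(S), each = W), times = B)
  b_of_row <- rep(seq_len(B), each = S * W)
  mask <- as.numeric(s_of_row <= size[b_of_row])
  list(B = B, S = S, W = W, inter = inter, intra = intra,
       site_aa = site_aa, site_ss = site_ss, oligo = oligo, size = size,
       mask = mask,
       # group id (b-1)*W + w for each (b,s,w) row: pools the site axis
       pool_group = (b_of_row - 1L) * W +
         rep(rep(seq_len(W), times = S), times = B))
}
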