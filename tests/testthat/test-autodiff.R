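# Finite-difference verification of the reverse-mode engine.  Checks run
# away from ReLU kinks (shifted inputs) so central differences are valid.

fd_check <- function(loss_fn, params, n_probe = 4, eps = 1e-6, tol = 1e-5) {
  pepdesign:::clear_grads(params)
  r <- loss_fn()
  pepdesign:::nn_backward(r$tp, r$loss)
  for (p in params) {
    expect_false(is.null(p$grad), label = paste("gradient reaches", p$name))
    for (i in sample(length(p$value), min(n_probe, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps
      lp <- loss_fn()$loss$value[1, 1]
      p$value[i] <- v0 - eps
      lm <- loss_fn()$loss$value[1, 1]
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_equal(p$grad[i], num, tolerance = tol,
                   label = sprintf("d loss / d %s[%d]", p$name, i))
    }
  }
}

test_that("dense, activation and softmax gradients match finite differences", {
  withr::with_seed(1, {
    w1 <- new_param(pepdesign:::glorot(5, 7), "w1")
    b1 <- new_param(rnorm(7) * 0.1, "b1")
    w2 <- new_param(pepdesign:::glorot(7, 4), "w2")
    x <- matrix(rnorm(15), 3, 5)
    tgt <- c(1L, 3L, 2L)
    loss_fn <- function() {
      tp <- pepdesign:::new_tape()
      h <- pepdesign:::tp_tanh(tp, pepdesign:::tp_add_bias(
        tp, pepdesign:::tp_matmul(tp, pepdesign:::tp_const(tp, x),
                                  pepdesign:::tp_leaf(tp, w1)),
        pepdesign:::tp_leaf(tp, b1)))
      lg <- pepdesign:::tp_matmul(tp, h, pepdesign:::tp_leaf(tp, w2))
      ce <- pepdesign:::tp_ce_rows(tp, lg, tgt)
      loss <- pepdesign:::tp_scale(tp, pepdesign:::tp_sum(tp, ce), 1 / 3)
      list(tp = tp, loss = loss)
    }
    fd_check(loss_fn, list(w1, b1, w2))
  })
})

test_that("LSTM step and additive attention gradients match finite differences", {
  withr::with_seed(2, {
    U <- 4; H <- 5; B <- 3
    dec <- list(wx = new_param(pepdesign:::glorot(6, 4 * H), "wx"),
                wh = new_param(pepdesign:::glorot(H, 4 * H), "wh"),
                b = new_param(rnorm(4 * H) * 0.1, "b"),
                W1 = new_param(pepdesign:::glorot(2 * U, 6), "W1"),
                W2 = new_param(pepdesign:::glorot(H, 6), "W2"),
                b_att = new_param(rnorm(6) * 0.1, "b_att"),
                v = new_param(pepdesign:::glorot(6, 1), "v"))
    anns <- lapply(1:3, function(j) matrix(rnorm(B * 2 * U), B, 2 * U))
    x0 <- matrix(rnorm(B * 6), B, 6)
    tgt <- c(2L, 1L, 3L)
    wo <- new_param(pepdesign:::glorot(H, 4), "wo")
    loss_fn <- function() {
      tp <- pepdesign:::new_tape()
      ann_nodes <- lapply(anns, function(a) pepdesign:::tp_const(tp, a))
      w1leaf <- pepdesign:::tp_leaf(tp, dec$W1)
      proj <- lapply(ann_nodes, function(a)
        pepdesign:::tp_matmul(tp, a, w1leaf))
      h <- pepdesign:::tp_const(tp, matrix(0, B, H))
      c <- pepdesign:::tp_const(tp, matrix(0, B, H))
      att <- pepdesign:::attention_step(tp, ann_nodes, proj, h, dec$W2,
                                        dec$v, dec$b_att)
      st <- pepdesign:::lstm_step(tp, pepdesign:::tp_const(tp, x0), h, c,
                                  dec$wx, dec$wh, dec$b, H)
      mix <- pepdesign:::tp_scale_rows(tp, st$h,
                                       pepdesign:::tp_cols(tp, att$alpha, 1))
      lg <- pepdesign:::tp_matmul(tp, mix, pepdesign:::tp_leaf(tp, wo))
      ce <- pepdesign:::tp_ce_rows(tp, lg, tgt)
      loss <- pepdesign:::tp_scale(tp, pepdesign:::tp_sum(tp, ce), 1 / 3)
      list(tp = tp, loss = loss)
    }
    fd_check(loss_fn, list(dec$wx, dec$wh, dec$b, dec$W1, dec$W2, dec$b_att,
                           dec$v, wo))
  })
})

test_that("conv layer, group mean, row-min and MSE gradients match finite differences", {
  withr::with_seed(3, {
    B <- 2; S <- 5; W <- 4; C <- 3
    x <- matrix(rnorm(B * S * W * 2) + 3, B * S * W, 2)
    wp <- new_param(pepdesign:::glorot(18, C), "conv_w")
    bp <- new_param(rnorm(C) * 0.1, "conv_b")
    wo <- new_param(pepdesign:::glorot(C, 3), "wo")
    mask <- as.numeric(rep(rep(seq_len(S), each = W), B) <= 4)
    group <- (rep(seq_len(B), each = S * W) - 1L) * W +
      rep(rep(seq_len(W), times = S), times = B)
    tgt <- sample(3, B * W, replace = TRUE)
    loss_fn <- function(use_mse = FALSE) {
      tp <- pepdesign:::new_tape()
      y <- pepdesign:::conv_layer(tp, pepdesign:::tp_const(tp, x),
                                  pepdesign:::conv_indices(B, S, W),
                                  wp, bp, mask)
      g <- pepdesign:::tp_group_mean(tp, y, group, rep(4, B * W))
      lg <- pepdesign:::tp_matmul(tp, g, pepdesign:::tp_leaf(tp, wo))
      err <- if (use_mse) pepdesign:::tp_mse_rows(tp, lg, tgt)
             else pepdesign:::tp_ce_rows(tp, lg, tgt)
      both <- pepdesign:::tp_cbind(tp, list(err, pepdesign:::tp_scale(tp, err, 0.5)))
      best <- pepdesign:::tp_row_min(tp, both)
      loss <- pepdesign:::tp_scale(tp, pepdesign:::tp_sum(tp, best),
                                   1 / (B * W))
      list(tp = tp, loss = loss)
    }
    fd_check(loss_fn, list(wp, bp, wo))
    fd_check(function() loss_fn(use_mse = TRUE), list(wp, bp, wo))
  })
})

test_that("softmax outputs are row-stochastic with correct gradients", {
  withr::with_seed(4, {
    w <- new_param(pepdesign:::glorot(4, 5), "w")
    x <- matrix(rnorm(12), 3, 4)
    tp <- pepdesign:::new_tape()
    sm <- pepdesign:::tp_softmax(tp, pepdesign:::tp_matmul(
      tp, pepdesign:::tp_const(tp, x), pepdesign:::tp_leaf(tp, w)))
    expect_equal(rowSums(sm$value), rep(1, 3))
    expect_true(all(sm$value >= 0))
    tgt_mix <- matrix(rnorm(15), 3, 5)
    loss_fn <- function() {
      tp <- pepdesign:::new_tape()
      sm <- pepdesign:::tp_softmax(tp, pepdesign:::tp_matmul(
        tp, pepdesign:::tp_const(tp, x), pepdesign:::tp_leaf(tp, w)))
      prod <- pepdesign:::tp_mul(tp, sm, pepdesign:::tp_const(tp, tgt_mix))
      loss <- pepdesign:::tp_scale(tp, pepdesign:::tp_sum(tp, prod), 1 / 3)
      list(tp = tp, loss = loss)
    }
    fd_check(loss_fn, list(w))
  })
})

test_that("Adam updates only trainable parameters", {
  p1 <- new_param(matrix(1, 2, 2), "p1")
  p2 <- new_param(matrix(1, 2, 2), "p2", trainable = FALSE)
  p1$grad <- matrix(1, 2, 2)
  p2$grad <- matrix(1, 2, 2)
  pepdesign:::adam_step(list(p1, p2), lr = 0.1, t = 1)
  expect_false(all(p1$value == 1))
  expect_true(all(p2$value == 1))
})
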