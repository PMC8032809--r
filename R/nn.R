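# Minimal convolutional-network primitives used by the cGAN.
#
# Feature maps are (H*W) x C matrices with pixel p = row + col*H (0-based,
# column-major flattening, identical to as.vector() of an H x W matrix).
# Convolutions use k x k kernels with zero padding; weights are stored as
# (k*k*in_ch) x out_ch matrices (transposed convs as (k*k*out_ch) x in_ch).
# The fused per-block forward/backward kernels (pre-activation, im2col +
# GEMM, bias, instance norm, post-activation) live in src/nnops.cpp.

nn_block <- function(kind, in_ch, out_ch, k = 4L, stride = 2L, pad = 1L,
                     norm = FALSE, pre_act = "none", post_act = "none") {
  wrows <- if (kind == "conv") k * k * in_ch else k * k * out_ch
  wcols <- if (kind == "conv") out_ch else in_ch
  W <- matrix(rnorm(wrows * wcols, 0, 0.02), wrows, wcols)
  b <- numeric(out_ch)
  blk <- list(kind = kind, in_ch = in_ch, out_ch = out_ch, k = k,
              stride = stride, pad = pad, norm = norm,
              pre_act = pre_act, post_act = post_act,
              W = W, b = b)
  if (norm) { blk$gamma <- rep(1, out_ch); blk$beta <- rep(0, out_ch) }
  blk$adam <- NULL
  blk
}

act_code <- function(act) {
  switch(act, none = 0L, lrelu = 1L, relu = 2L, tanh = 3L,
         stop("unknown activation: ", act))
}

# Forward one block. x: (H*W) x in_ch. Returns out, output dims, cache.
block_fw <- function(blk, x, H, W) {
  cpp_block_fw(x, H, W, blk$in_ch, blk$out_ch, blk$k, blk$stride, blk$pad,
               if (blk$kind == "conv") 0L else 1L, blk$W, blk$b,
               blk$norm, blk$gamma %||% numeric(0), blk$beta %||% numeric(0),
               act_code(blk$pre_act), act_code(blk$post_act))
}

# Backward one block. dy matches the block output. Returns dx and grads.
block_bw <- function(blk, dy, cache) {
  bb <- cpp_block_bw(dy, blk$in_ch, blk$out_ch, blk$k, blk$stride, blk$pad,
                     if (blk$kind == "conv") 0L else 1L, blk$W,
                     blk$norm, blk$gamma %||% numeric(0),
                     act_code(blk$pre_act), act_code(blk$post_act), cache)
  grads <- list(W = bb$dW, b = as.numeric(bb$db))
  if (blk$norm) {
    grads$gamma <- as.numeric(bb$dgamma)
    grads$beta <- as.numeric(bb$dbeta)
  }
  list(dx = bb$dx, grads = grads)
}

zero_like_grads <- function(blk) {
  g <- list(W = matrix(0, nrow(blk$W), ncol(blk$W)), b = numeric(length(blk$b)))
  if (blk$norm) {
    g$gamma <- numeric(length(blk$gamma)); g$beta <- numeric(length(blk$beta))
  }
  g
}

# In-place accumulation: acc's members are freshly allocated per batch and
# uniquely owned, so the C++ += is safe.
add_grads <- function(acc, g) {
  for (nm in names(g)) cpp_axpy(acc[[nm]], g[[nm]])
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# Adam update of one block (beta1 = 0.5 as customary for image GANs).
# The C++ step mutates parameters and moments in place, so training must
# own unshared copies of all weights (see deep_copy_block).
adam_update <- function(blk, grads, lr, t, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.null(blk$adam))
    blk$adam <- lapply(grads, function(g) list(m = g * 0, v = g * 0))
  for (nm in names(grads)) {
    cpp_adam_step(blk[[nm]], grads[[nm]], blk$adam[[nm]]$m, blk$adam[[nm]]$v,
                  lr, beta1, beta2, beta1^t, beta2^t, eps)
  }
  blk
}

deep_copy_block <- function(blk) {
  for (nm in c("W", "b", "gamma", "beta"))
    if (!is.null(blk[[nm]])) blk[[nm]] <- blk[[nm]] + 0
  if (!is.null(blk$adam))
    blk$adam <- lapply(blk$adam, function(st) list(m = st$m + 0, v = st$v + 0))
  blk
}

# Binary cross-entropy with logits; target is a scalar 0/1.
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}
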