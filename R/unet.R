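# U-Net generator and patch discriminator (internal).
#
# Generator: n_down strided 4x4 conv encoder blocks and n_down transposed-conv
# decoder blocks with skip concatenation, leaky-ReLU encoder / ReLU decoder
# activations, instance normalization except on the outermost and bottleneck
# layers, tanh output. With n_down = 8 this is the standard pix2pix "unet_256"
# configuration; n_down = 6 / base_filters = 16 is the small-tile preset.

gen_channels <- function(n_down, base_filters) {
  pmin(base_filters * 2^(0:(n_down - 1)), 8L * base_filters)
}

build_generator <- function(n_down = 8L, base_filters = 64L,
                            in_channels = 1L, out_channels = 1L) {
  ch <- gen_channels(n_down, base_filters)
  enc <- vector("list", n_down)
  for (i in seq_len(n_down)) {
    enc[[i]] <- nn_block("conv",
                         in_ch = if (i == 1L) in_channels else ch[i - 1L],
                         out_ch = ch[i],
                         norm = (i > 1L && i < n_down),
                         pre_act = if (i == 1L) "none" else "lrelu")
  }
  dec <- vector("list", n_down)
  for (i in seq_len(n_down)) {
    lev <- n_down - i + 1L            # encoder level whose resolution doubles
    in_ch <- if (i == 1L) ch[n_down] else 2L * ch[lev]
    out_ch <- if (i == n_down) out_channels else ch[lev - 1L]
    dec[[i]] <- nn_block("convt", in_ch = in_ch, out_ch = out_ch,
                         norm = (i < n_down), pre_act = "relu",
                         post_act = if (i == n_down) "tanh" else "none")
  }
  # output bias starts at the background prior: masks are mostly empty, and
  # keeping the early tanh output off its -1 rail preserves the per-pixel
  # gradient for the sparse foreground
  dec[[n_down]]$b[] <- -0.5
  list(enc = enc, dec = dec, n_down = n_down, base_filters = base_filters,
       in_channels = in_channels, out_channels = out_channels)
}

gen_forward <- function(G, x, H, W) {
  d <- G$n_down
  ecache <- vector("list", d)
  e_out <- vector("list", d)
  dims <- matrix(0L, d, 2L)
  h <- x; Hh <- H; Wh <- W
  for (i in seq_len(d)) {
    f <- block_fw(G$enc[[i]], h, Hh, Wh)
    ecache[[i]] <- f$cache
    e_out[[i]] <- f$out
    Hh <- f$H; Wh <- f$W
    dims[i, ] <- c(Hh, Wh)
    h <- f$out
  }
  dcache <- vector("list", d)
  for (i in seq_len(d)) {
    f <- block_fw(G$dec[[i]], h, Hh, Wh)
    dcache[[i]] <- f$cache
    Hh <- f$H; Wh <- f$W
    if (i < d) {
      skip <- e_out[[d - i]]
      h <- cbind(f$out, skip)
    } else {
      h <- f$out
    }
  }
  list(out = h, H = Hh, W = Wh,
       cache = list(ecache = ecache, dcache = dcache, dims = dims))
}

gen_backward <- function(G, dy, cache) {
  d <- G$n_down
  egrads <- vector("list", d)
  dgrads <- vector("list", d)
  dskip <- vector("list", d)          # gradient flowing into enc output via skip
  dh <- dy
  for (i in rev(seq_len(d))) {
    bb <- block_bw(G$dec[[i]], dh, cache$dcache[[i]])
    dgrads[[i]] <- bb$grads
    if (i == 1L) {
      dh <- bb$dx                      # gradient w.r.t. e_out[[d]]
    } else {
      nch <- G$dec[[i]]$in_ch %/% 2L   # first half: previous dec out; second: skip
      dh_prev <- bb$dx[, seq_len(nch), drop = FALSE]
      dskip[[d - (i - 1L)]] <- bb$dx[, nch + seq_len(nch), drop = FALSE]
      dh <- dh_prev
    }
  }
  # dh now is gradient w.r.t. e_out[[d]]; walk the encoder backwards adding
  # skip contributions.
  for (i in rev(seq_len(d))) {
    if (!is.null(dskip[[i]])) dh <- dh + dskip[[i]]
    bb <- block_bw(G$enc[[i]], dh, cache$ecache[[i]])
    egrads[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(dx = dh, enc = egrads, dec = dgrads)
}

gen_zero_grads <- function(G) {
  list(enc = lapply(G$enc, zero_like_grads),
       dec = lapply(G$dec, zero_like_grads))
}

gen_add_grads <- function(acc, g) {
  for (i in seq_along(acc$enc)) acc$enc[[i]] <- add_grads(acc$enc[[i]], g$enc[[i]])
  for (i in seq_along(acc$dec)) acc$dec[[i]] <- add_grads(acc$dec[[i]], g$dec[[i]])
  acc
}

gen_update <- function(G, grads, lr, t) {
  for (i in seq_along(G$enc)) G$enc[[i]] <- adam_update(G$enc[[i]], grads$enc[[i]], lr, t)
  for (i in seq_along(G$dec)) G$dec[[i]] <- adam_update(G$dec[[i]], grads$dec[[i]], lr, t)
  G
}

# Patch discriminator: judges (input, mask) channel pairs. Two strided
# blocks, one stride-1 block, then a stride-1 projection to per-patch logits.
build_discriminator <- function(base_filters = 64L, in_channels = 2L) {
  f <- base_filters
  list(blocks = list(
    nn_block("conv", in_channels, f, stride = 2L, pre_act = "none"),
    nn_block("conv", f, 2L * f, stride = 2L, norm = TRUE, pre_act = "lrelu"),
    nn_block("conv", 2L * f, 4L * f, stride = 1L, norm = TRUE, pre_act = "lrelu"),
    nn_block("conv", 4L * f, 1L, stride = 1L, pre_act = "lrelu")
  ))
}

seq_forward <- function(net, x, H, W) {
  caches <- vector("list", length(net$blocks))
  h <- x; Hh <- H; Wh <- W
  for (i in seq_along(net$blocks)) {
    f <- block_fw(net$blocks[[i]], h, Hh, Wh)
    caches[[i]] <- f$cache
    h <- f$out; Hh <- f$H; Wh <- f$W
  }
  list(out = h, H = Hh, W = Wh, cache = caches)
}

seq_backward <- function(net, dy, caches) {
  grads <- vector("list", length(net$blocks))
  dh <- dy
  for (i in rev(seq_along(net$blocks))) {
    bb <- block_bw(net$blocks[[i]], dh, caches[[i]])
    grads[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(dx = dh, grads = grads)
}

seq_zero_grads <- function(net) lapply(net$blocks, zero_like_grads)

seq_add_grads <- function(acc, g) {
  for (i in seq_along(acc)) acc[[i]] <- add_grads(acc[[i]], g[[i]])
  acc
}

seq_update <- function(net, grads, lr, t) {
  for (i in seq_along(net$blocks))
    net$blocks[[i]] <- adam_update(net$blocks[[i]], grads[[i]], lr, t)
  net
}
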