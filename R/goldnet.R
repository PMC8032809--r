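#' Fit the conditional-GAN particle annotator
#'
#' Trains a pix2pix-style conditional GAN that translates grayscale image
#' tiles into particle masks: a U-Net generator against a patch
#' discriminator, with the generator objective
#' \deqn{L = L_{GAN}(G, D) + \lambda \, \|G(x) - y\|_1,}
#' optimized with Adam (\eqn{\beta_1 = 0.5}). Defaults are the reference
#' full-scale recipe: batch size 2, 200 epochs, learning rate 2e-4 held
#' constant for the first half of training and decayed linearly to zero over
#' the second half. Inputs are mapped linearly from `[0, 1]` to `[-1, 1]`;
#' the recorded normalization is applied identically at inference.
#'
#' @param pairs list of training pairs; each element is a `rendered_pair`
#'   (see [render_scene()]) or a list with `input` and `mask` matrices. All
#'   tiles must be square with side `tile_px`.
#' @param tile_px tile side in pixels; must be divisible by `2^n_down`.
#' @param n_down encoder depth (8 for 256x256 tiles; 6 for the 64x64
#'   small-tile preset).
#' @param base_filters filters in the first encoder block (64 standard; 16
#'   for the small-tile preset).
#' @param epochs training epochs. `epochs = 0` returns the initialized (or
#'   `init`) weights untouched with an empty loss history.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param lr_policy `"linear"` (constant then linear decay to zero over the
#'   second half) or `"constant"`.
#' @param l1_weight weight \eqn{\lambda} of the L1 reconstruction term.
#' @param seed integer seed controlling initialization and batch order.
#' @param init optional `goldnet` object to start from (transfer learning /
#'   resumed training); its architecture must match the arguments.
#' @param max_restarts with sparse masks, GAN training occasionally falls
#'   into an all-background local optimum (the tanh output saturates and
#'   the per-pixel gradient vanishes). When `collapse_l1` is set and the
#'   final epoch's training L1 stays above it, training is restarted from a
#'   fresh seeded initialization, up to `max_restarts` times. Detection
#'   uses only the training loss.
#' @param collapse_l1 training-L1 level above which a finished run counts
#'   as collapsed (`NULL` disables restarts). An all-background generator
#'   plateaus at the mean foreground fraction of the masks; an escaped run
#'   ends well below it.
#' @param verbose print per-epoch losses.
#' @return an object of class `goldnet`: generator and discriminator
#'   weights, the architecture and training configuration, the input
#'   normalization, and `loss_history` (one row per epoch with the mean
#'   discriminator loss, generator adversarial loss and L1 loss; L1 is on
#'   the `[0, 1]` mask scale).
#' @seealso [predict.goldnet()], [detect_image()], [pretraining_benefit()]
#' @export
goldnet <- function(pairs, tile_px = 256L, n_down = 8L, base_filters = 64L,
                    epochs = 200L, batch_size = 2L, lr = 2e-4,
                    lr_policy = c("linear", "constant"), l1_weight = 100,
                    seed = 1L, init = NULL, max_restarts = 0L,
                    collapse_l1 = NULL, verbose = FALSE) {
  lr_policy <- match.arg(lr_policy)
  if (!is.null(collapse_l1) && max_restarts > 0L && epochs > 0L) {
    for (r in 0:max_restarts) {
      seed_r <- if (r == 0L) seed else derive_seed(seed, 9000L + r)
      model <- goldnet(pairs, tile_px = tile_px, n_down = n_down,
                       base_filters = base_filters, epochs = epochs,
                       batch_size = batch_size, lr = lr,
                       lr_policy = lr_policy, l1_weight = l1_weight,
                       seed = seed_r, init = init, verbose = verbose)
      final_l1 <- tail_1(model$loss_history$g_l1)
      if (final_l1 <= collapse_l1 || r == max_restarts) {
        model$restarts <- r
        return(model)
      }
      if (verbose)
        message(sprintf(
          "training collapsed (final L1 %.4f > %.4f); restart %d",
          final_l1, collapse_l1, r + 1L))
    }
  }
  stopifnot(length(pairs) >= 1, epochs >= 0, batch_size >= 1, lr > 0,
            l1_weight >= 0, tile_px >= 1, n_down >= 1, base_filters >= 1)
  if (tile_px %% 2^n_down != 0)
    stop("tile_px (", tile_px, ") must be divisible by 2^n_down (",
         2^n_down, ")")
  xs <- vector("list", length(pairs))
  ys <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    img <- as_plain_matrix(unclass(p$input))
    msk <- as_plain_matrix(unclass(p$mask))
    if (nrow(img) != tile_px || ncol(img) != tile_px ||
        nrow(msk) != tile_px || ncol(msk) != tile_px)
      stop("pair ", i, ": tiles must be ", tile_px, " x ", tile_px, " px")
    xs[[i]] <- matrix(2 * as.vector(img) - 1, ncol = 1L)
    ys[[i]] <- matrix(2 * as.vector(msk) - 1, ncol = 1L)
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "goldnet"))
    if (init$tile_px != tile_px || init$G$n_down != n_down ||
        init$G$base_filters != base_filters)
      stop("init model architecture does not match the requested one")
  }
  with_seed(seed, function() {
    if (is.null(init)) {
      G <- build_generator(n_down, base_filters)
      D <- build_discriminator(base_filters)
    } else {
      # weights are updated in place during training; never alias init's
      G <- init$G
      G$enc <- lapply(G$enc, deep_copy_block)
      G$dec <- lapply(G$dec, deep_copy_block)
      D <- init$D
      D$blocks <- lapply(D$blocks, deep_copy_block)
    }
    t_g <- if (is.null(init)) 0L else init$adam_steps %||% 0L
    t_d <- t_g
    hist <- data.frame(epoch = integer(0), d_loss = numeric(0),
                       g_gan = numeric(0), g_l1 = numeric(0),
                       lr = numeric(0))
    n <- length(xs)
    half <- floor(epochs / 2)
    for (e in seq_len(epochs)) {
      lr_e <- if (lr_policy == "constant" || e <= half) lr
              else lr * (1 - (e - half) / (epochs - half + 1))
      ord <- sample.int(n)
      bstarts <- seq(1, n, by = batch_size)
      ep_d <- ep_gan <- ep_l1 <- 0; nb <- 0L
      for (bs in bstarts) {
        idx <- ord[bs:min(bs + batch_size - 1, n)]
        nbatch <- length(idx)
        gfw <- vector("list", nbatch)
        # --- discriminator step (fakes treated as constants) ---
        dgr <- seq_zero_grads(D)
        d_loss <- 0
        for (s in seq_len(nbatch)) {
          x <- xs[[idx[s]]]; y <- ys[[idx[s]]]
          gf <- gen_forward(G, x, tile_px, tile_px)
          gfw[[s]] <- gf
          dreal <- seq_forward(D, cbind(x, y), tile_px, tile_px)
          dfake <- seq_forward(D, cbind(x, gf$out), tile_px, tile_px)
          d_loss <- d_loss +
            0.5 * (bce_logits(dreal$out, 1) + bce_logits(dfake$out, 0))
          br <- seq_backward(D, 0.5 * bce_logits_grad(dreal$out, 1), dreal$cache)
          bf <- seq_backward(D, 0.5 * bce_logits_grad(dfake$out, 0), dfake$cache)
          dgr <- seq_add_grads(dgr, br$grads)
          dgr <- seq_add_grads(dgr, bf$grads)
        }
        t_d <- t_d + 1L
        D <- seq_update(D, lapply(dgr, scale_grads, s = 1 / nbatch), lr_e, t_d)
        # --- generator step (through the updated discriminator) ---
        ggr <- gen_zero_grads(G)
        g_gan <- g_l1 <- 0
        for (s in seq_len(nbatch)) {
          x <- xs[[idx[s]]]; y <- ys[[idx[s]]]
          gf <- gfw[[s]]
          dfake <- seq_forward(D, cbind(x, gf$out), tile_px, tile_px)
          g_gan <- g_gan + bce_logits(dfake$out, 1)
          l1 <- mean(abs(gf$out - y))
          g_l1 <- g_l1 + l1
          bd <- seq_backward(D, bce_logits_grad(dfake$out, 1), dfake$cache)
          dfake_in <- bd$dx[, 2L, drop = FALSE]   # channel 2 = generated mask
          dfake_in <- dfake_in +
            l1_weight * sign(gf$out - y) / length(y)
          gb <- gen_backward(G, dfake_in, gf$cache)
          ggr <- gen_add_grads(ggr, gb)
        }
        t_g <- t_g + 1L
        gsc <- list(enc = lapply(ggr$enc, scale_grads, s = 1 / nbatch),
                    dec = lapply(ggr$dec, scale_grads, s = 1 / nbatch))
        G <- gen_update(G, gsc, lr_e, t_g)
        ep_d <- ep_d + d_loss / nbatch
        ep_gan <- ep_gan + g_gan / nbatch
        ep_l1 <- ep_l1 + g_l1 / nbatch
        nb <- nb + 1L
      }
      hist <- rbind(hist, data.frame(epoch = e, d_loss = ep_d / nb,
                                     g_gan = ep_gan / nb,
                                     g_l1 = ep_l1 / nb / 2,  # [0,1] mask scale
                                     lr = lr_e))
      if (verbose)
        message(sprintf("epoch %3d  D %.4f  G_gan %.4f  G_L1 %.4f",
                        e, ep_d / nb, ep_gan / nb, ep_l1 / nb / 2))
    }
    structure(list(G = G, D = D, tile_px = as.integer(tile_px),
                   config = list(epochs = epochs, batch_size = batch_size,
                                 lr = lr, lr_policy = lr_policy,
                                 l1_weight = l1_weight, seed = seed,
                                 optimizer = "adam(beta1=0.5)"),
                   normalization = list(input_range = c(0, 1),
                                        net_range = c(-1, 1)),
                   loss_history = hist,
                   adam_steps = t_g,
                   n_pairs = length(pairs)),
              class = "goldnet")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the particle mask for one tile
#'
#' A pure function of `(model, tile)`: the tile is normalized exactly as at
#' training time, passed through the generator, and returned as a mask with
#' values in `[0, 1]` (binarize downstream, see [extract_particles()]).
#'
#' @param object a fitted [goldnet()] model.
#' @param tile matrix or [image_plane()] whose side equals the model's
#'   `tile_px` (no silent resizing).
#' @param ... unused.
#' @return numeric matrix of the same size with values in `[0, 1]`.
#' @export
predict.goldnet <- function(object, tile, ...) {
  m <- as_plain_matrix(unclass(tile))
  tp <- object$tile_px
  if (nrow(m) != tp || ncol(m) != tp)
    stop("tile must be ", tp, " x ", tp, " px (got ",
         nrow(m), " x ", ncol(m), "); pad or retile the image")
  x <- matrix(2 * as.vector(m) - 1, ncol = 1L)
  out <- gen_forward(object$G, x, tp, tp)$out
  matrix((out + 1) / 2, tp, tp)
}

# Mean L1 between generated and target masks over a set of pairs, on the
# [0, 1] mask scale (evaluation only, no training).
generator_l1 <- function(model, pairs) {
  tp <- model$tile_px
  l1 <- vapply(pairs, function(p) {
    fake <- predict(model, p$input)
    mean(abs(fake - as_plain_matrix(unclass(p$mask))))
  }, numeric(1))
  mean(l1)
}

#' @export
print.goldnet <- function(x, ...) {
  cat(sprintf("<goldnet> U-Net generator (depth %d, %d base filters), %d x %d tiles\n",
              x$G$n_down, x$G$base_filters, x$tile_px, x$tile_px))
  cat(sprintf("  trained %d epoch(s) on %d pair(s); lambda_L1 = %g, lr = %g (%s)\n",
              nrow(x$loss_history), x$n_pairs, x$config$l1_weight,
              x$config$lr, x$config$lr_policy))
  if (nrow(x$loss_history) > 0)
    cat(sprintf("  final losses: D %.4f, G_gan %.4f, G_L1 %.4f\n",
                tail_1(x$loss_history$d_loss), tail_1(x$loss_history$g_gan),
                tail_1(x$loss_history$g_l1)))
  invisible(x)
}

tail_1 <- function(v) v[length(v)]

#' @export
summary.goldnet <- function(object, ...) {
  h <- object$loss_history
  out <- list(architecture = sprintf("U-Net depth %d, base %d; patch discriminator",
                                     object$G$n_down, object$G$base_filters),
              tile_px = object$tile_px, config = object$config,
              epochs_trained = nrow(h),
              initial_l1 = if (nrow(h)) h$g_l1[1] else NA_real_,
              final_l1 = if (nrow(h)) tail_1(h$g_l1) else NA_real_)
  class(out) <- "summary.goldnet"
  out
}

#' @export
print.summary.goldnet <- function(x, ...) {
  cat(x$architecture, "\n")
  cat(sprintf("tiles %d px; %d epoch(s); L1 %.4f -> %.4f\n",
              x$tile_px, x$epochs_trained, x$initial_l1, x$final_l1))
  invisible(x)
}

#' @export
coef.goldnet <- function(object, ...) {
  list(generator = lapply(c(object$G$enc, object$G$dec),
                          function(b) list(W = b$W, b = b$b,
                                           gamma = b$gamma, beta = b$beta)),
       discriminator = lapply(object$D$blocks,
                              function(b) list(W = b$W, b = b$b,
                                               gamma = b$gamma, beta = b$beta)))
}

#' Plot training loss curves
#' @param x a `goldnet` object with non-empty loss history.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.goldnet <- function(x, ...) {
  h <- x$loss_history
  if (nrow(h) == 0) stop("model has no loss history (epochs = 0)")
  graphics::matplot(h$epoch, cbind(h$d_loss, h$g_gan, h$g_l1), type = "l",
                    lty = 1, col = c("gray40", "firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("D", "G adversarial", "G L1"),
                   col = c("gray40", "firebrick", "steelblue"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds weights, architecture, training configuration and
#' normalization, and can be passed back as `init` to [goldnet()] for
#' fine-tuning or resumed training.
#'
#' @param model a `goldnet` object.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `goldnet` object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "goldnet"))
  obj <- list(format = "goldpick-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "goldpick-checkpoint"))
    stop("not a goldpick checkpoint: ", path)
  obj$model
}
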