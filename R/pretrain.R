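#' Measure the benefit of pretraining (transfer learning)
#'
#' Trains, for each seed, (a) a naive generator fine-tuned directly on task
#' B and (b) a generator pretrained on task A then fine-tuned on task B,
#' and reports the generator L1 loss curves on task B. The curves start at
#' the evaluation L1 of the initial weights (epoch 0), so with
#' `finetune_epochs = 0` each curve reduces to its initial-loss point.
#' Pretraining moves the weights from their random initialization toward
#' ones useful for the annotation task, which shows up as a lower initial
#' loss and fewer epochs to reach a given loss level.
#'
#' @param task_a list of training pairs for the pretraining task.
#' @param task_b list of training pairs for the target task.
#' @param tile_px,n_down,base_filters architecture (see [goldnet()]).
#' @param pretrain_epochs epochs of pretraining on task A.
#' @param finetune_epochs epochs of fine-tuning on task B.
#' @param l1_threshold loss level used for the epochs-to-threshold summary.
#' @param seeds integer vector of replicate seeds.
#' @param ... further arguments passed to [goldnet()].
#' @return a `pretraining_benefit` list: per-seed `naive_curve` and
#'   `pretrained_curve` (L1 on the mask scale, element 1 = initial loss),
#'   mean initial losses, and epochs-to-threshold for each arm.
#' @export
pretraining_benefit <- function(task_a, task_b, tile_px = 64L, n_down = 6L,
                                base_filters = 16L, pretrain_epochs = 5L,
                                finetune_epochs = 5L, l1_threshold = 0.05,
                                seeds = 1:3, ...) {
  run_arm <- function(seed, init) {
    m0 <- goldnet(task_b, tile_px = tile_px, n_down = n_down,
                  base_filters = base_filters, epochs = 0L, seed = seed,
                  init = init, ...)
    init_l1 <- generator_l1(m0, task_b)
    mt <- goldnet(task_b, tile_px = tile_px, n_down = n_down,
                  base_filters = base_filters, epochs = finetune_epochs,
                  seed = seed, init = m0, ...)
    c(init_l1, mt$loss_history$g_l1)
  }
  res <- lapply(seeds, function(sd) {
    naive <- run_arm(sd, init = NULL)
    pre_model <- goldnet(task_a, tile_px = tile_px, n_down = n_down,
                         base_filters = base_filters, epochs = pretrain_epochs,
                         seed = sd, ...)
    pre <- run_arm(sd, init = pre_model)
    list(naive_curve = naive, pretrained_curve = pre)
  })
  ett <- function(curve) {
    hit <- which(curve <= l1_threshold)
    if (length(hit)) hit[1] - 1L else NA_integer_
  }
  structure(list(
    per_seed = res, seeds = seeds,
    naive_initial_l1 = mean(vapply(res, function(r) r$naive_curve[1], numeric(1))),
    pretrained_initial_l1 = mean(vapply(res, function(r) r$pretrained_curve[1], numeric(1))),
    naive_epochs_to_threshold =
      vapply(res, function(r) ett(r$naive_curve), integer(1)),
    pretrained_epochs_to_threshold =
      vapply(res, function(r) ett(r$pretrained_curve), integer(1)),
    l1_threshold = l1_threshold
  ), class = "pretraining_benefit")
}

#' @export
print.pretraining_benefit <- function(x, ...) {
  cat(sprintf("mean initial L1: naive %.4f vs pretrained %.4f (%d seed(s))\n",
              x$naive_initial_l1, x$pretrained_initial_l1, length(x$seeds)))
  cat(sprintf("epochs to L1 <= %.3g: naive %s; pretrained %s\n",
              x$l1_threshold,
              paste(x$naive_epochs_to_threshold, collapse = "/"),
              paste(x$pretrained_epochs_to_threshold, collapse = "/")))
  invisible(x)
}
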