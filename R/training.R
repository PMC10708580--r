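# Dual-GAN training: alternate one discriminator update (ascending the
# adversarial log-likelihood) and one generator update (descending the
# weighted total loss, with the non-saturating adversarial surrogate) per
# batch.  Images live in [0,1] on disk and [-1,1] inside the networks; the
# mask composite is applied in storage space, so generator A's effective
# output agrees bit-exactly with its input outside the repair region.

#' Training configuration
#'
#' Defaults follow the published protocol: RMSprop with generator learning
#' rate 5e-4 and discriminator learning rate 1e-4, batch size 4, loss
#' weights (50, 1, 100, 1, 1).
#'
#' @param image_size Training image side (power of two).
#' @param base_channels,max_channels Generator channel schedule.
#' @param disc_base_channels Discriminator first-stage channels.
#' @param lr_generator,lr_discriminator RMSprop learning rates.
#' @param rmsprop_alpha,rmsprop_eps RMSprop smoothing constant and epsilon.
#' @param batch_size Images per step.
#' @param steps Total optimization steps.
#' @param weights A [loss_weights()].
#' @param ssim An [ssim_params()] used by the SSIM loss.
#' @param seed Master seed: weight initialization, batch order and dropout
#'   all derive from it.
#' @param log_every Record losses every `log_every` steps (1 = every step).
#' @param checkpoint_dir Directory for periodic checkpoints (`NULL` = none).
#' @param checkpoint_every Steps between checkpoints (0 = final only).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(image_size = 256L, base_channels = 64L,
                         max_channels = 512L, disc_base_channels = 64L,
                         lr_generator = 5e-4, lr_discriminator = 1e-4,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8,
                         batch_size = 4L, steps = 2000L,
                         weights = loss_weights(), ssim = ssim_params(),
                         seed = 1L, log_every = 1L,
                         checkpoint_dir = NULL, checkpoint_every = 0L) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, batch_size >= 1,
            steps >= 1, image_size >= 32)
  structure(list(image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 disc_base_channels = as.integer(disc_base_channels),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), weights = weights, ssim = ssim,
                 seed = as.integer(seed), log_every = as.integer(log_every),
                 checkpoint_dir = checkpoint_dir,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

# ---- parameter-tree helpers -------------------------------------------------

tree_keys <- function(g) {
  nm <- names(g)
  if (!is.null(nm) && all(nzchar(nm))) nm else seq_along(g)
}

safe_get <- function(lst, k) {
  if (is.character(k)) return(lst[[k]])
  if (k > length(lst)) NULL else lst[[k]]
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(b)) return(a + b)
  for (k in tree_keys(b)) {
    bk <- b[[k]]
    if (is.null(bk)) next
    a[[k]] <- tree_add(safe_get(a, k), bk)
  }
  a
}

rmsprop_step <- function(p, g, v, lr, alpha, eps) {
  for (k in tree_keys(g)) {
    gk <- g[[k]]
    if (is.null(gk)) next
    if (is.numeric(gk)) {
      vk <- safe_get(v, k)
      if (is.null(vk)) vk <- numeric(0)
      res <- rmsprop_kernel(p[[k]], gk, vk, lr, alpha, eps)
      p[[k]] <- res$p
      v[[k]] <- res$v
    } else {
      vk <- safe_get(v, k)
      res <- rmsprop_step(p[[k]], gk, if (is.null(vk)) list() else vk,
                          lr, alpha, eps)
      p[[k]] <- res$p
      v[[k]] <- res$v
    }
  }
  list(p = p, v = v)
}

apply_gen_bn <- function(gen, bn_updates) {
  for (i in seq_along(bn_updates)) {
    if (!is.null(bn_updates[[i]]))
      gen$params$dec[[i]]$bn <- bn_updates[[i]]
  }
  gen
}

apply_disc_bn <- function(disc, bn_updates) {
  for (i in seq_along(bn_updates)) {
    if (!is.null(bn_updates[[i]]))
      disc$params[[i]]$bn <- bn_updates[[i]]
  }
  disc
}

# ---- model state ------------------------------------------------------------

#' Initialize a dual-GAN model state
#'
#' Builds the two generators and two discriminators with seeds derived from
#' `config$seed`.
#'
#' @param config A [train_config()].
#' @return An object of class `"dualgan_state"`.
#' @export
init_dualgan_state <- function(config) {
  gspec <- generator_spec(size = config$image_size,
                          base_channels = config$base_channels,
                          max_channels = config$max_channels)
  dspec <- discriminator_spec(base_channels = config$disc_base_channels)
  structure(list(ga = build_generator(gspec, config$seed),
                 gb = build_generator(gspec, config$seed + 1L),
                 da = build_discriminator(dspec, config$seed + 2L),
                 db = build_discriminator(dspec, config$seed + 3L),
                 opt = list(ga = list(), gb = list(), da = list(), db = list()),
                 step = 0L),
            class = "dualgan_state")
}

disc_bce_grads <- function(disc, real, fake, train = TRUE) {
  fr <- disc_forward(disc, real, train = train, retain = TRUE)
  disc <- apply_disc_bn(disc, fr$bn_updates)
  ff <- disc_forward(disc, fake, train = train, retain = TRUE)
  disc <- apply_disc_bn(disc, ff$bn_updates)
  pr <- length(fr$logits); pf <- length(ff$logits)
  g_real <- (fr$scores - 1) / pr         # d/dz of -mean log sigma(z)
  g_fake <- ff$scores / pf               # d/dz of -mean log(1 - sigma(z))
  br <- disc_backward(disc, fr$cache, g_real)
  bf <- disc_backward(disc, ff$cache, g_fake)
  list(disc = disc, grads = tree_add(br$grads, bf$grads),
       score_real = mean(fr$scores), score_fake = mean(ff$scores))
}

#' One dual-GAN training step
#'
#' Performs one discriminator update followed by one generator update on a
#' paired batch.  Generator A's output is composited with the mask before
#' any loss is evaluated, so its supervised terms act on the repair region
#' only.  With `weights$adversarial == 0` the discriminators are left
#' untouched (supervised regression); with `weights$reconstruction == 0`
#' the cycle passes are skipped.
#'
#' @param batch List with elements `s`, `w`, `m`: equal-length lists of
#'   artifact images, clean images and masks (matrices in `[0, 1]`).
#' @param state A [init_dualgan_state()] state.
#' @param config A [train_config()].
#' @return List with the updated `state` and a one-row data frame `record`
#'   of the per-term losses and discriminator scores.
#' @export
train_step <- function(batch, state, config) {
  lw <- config$weights
  S <- stack_batch(batch$s); W <- stack_batch(batch$w)
  M <- stack_batch(batch$m)
  n_total <- length(S)

  # generator forwards
  fa <- unet_forward(state$ga, to_net(S), train = TRUE)
  state$ga <- apply_gen_bn(state$ga, fa$bn_updates)
  ga_img <- to_store(fa$y)
  ga_comp <- S * (1 - M) + ga_img * M
  fb <- unet_forward(state$gb, to_net(W), train = TRUE)
  state$gb <- apply_gen_bn(state$gb, fb$bn_updates)
  gb_img <- to_store(fb$y)

  score_da_real <- score_da_fake <- score_db_real <- score_db_fake <- NA_real_
  adv_value <- 0
  d_ga_comp <- array(0, dim = dim(S))
  d_gb_img <- array(0, dim = dim(W))

  if (lw$adversarial > 0) {
    # discriminator updates (ascend the adversarial log-likelihood)
    da_upd <- disc_bce_grads(state$da, to_net(W), to_net(ga_comp))
    state$da <- da_upd$disc
    res <- rmsprop_step(state$da$params, da_upd$grads, state$opt$da,
                        config$lr_discriminator, config$rmsprop_alpha,
                        config$rmsprop_eps)
    state$da$params <- res$p; state$opt$da <- res$v
    db_upd <- disc_bce_grads(state$db, to_net(S), to_net(gb_img))
    state$db <- db_upd$disc
    res <- rmsprop_step(state$db$params, db_upd$grads, state$opt$db,
                        config$lr_discriminator, config$rmsprop_alpha,
                        config$rmsprop_eps)
    state$db$params <- res$p; state$opt$db <- res$v

    # adversarial value (Eq.-8 form) and generator surrogate gradients
    fr_a <- disc_forward(state$da, to_net(W), train = TRUE, retain = FALSE)
    ff_a <- disc_forward(state$da, to_net(ga_comp), train = TRUE, retain = TRUE)
    fr_b <- disc_forward(state$db, to_net(S), train = TRUE, retain = FALSE)
    ff_b <- disc_forward(state$db, to_net(gb_img), train = TRUE, retain = TRUE)
    score_da_real <- mean(fr_a$scores); score_da_fake <- mean(ff_a$scores)
    score_db_real <- mean(fr_b$scores); score_db_fake <- mean(ff_b$scores)
    adv_value <- mean(log(fr_a$scores)) + mean(log1p(-ff_a$scores)) +
      mean(log(fr_b$scores)) + mean(log1p(-ff_b$scores))
    # non-saturating surrogate: descend -lambda_adv * mean log D(fake)
    gz_a <- lw$adversarial * (ff_a$scores - 1) / length(ff_a$logits)
    d_ga_comp <- d_ga_comp + 2 * disc_backward(state$da, ff_a$cache, gz_a)$gx
    gz_b <- lw$adversarial * (ff_b$scores - 1) / length(ff_b$logits)
    d_gb_img <- d_gb_img + 2 * disc_backward(state$db, ff_b$cache, gz_b)$gx
  }

  grads_ga <- NULL; grads_gb <- NULL
  recon_value <- 0
  if (lw$reconstruction > 0) {
    # cycle passes: GB(GA(s)) toward s, GA(GB(w)) toward w (the A-direction
    # cycle output is composited with the mask, like any GA application)
    fs_cyc <- unet_forward(state$gb, to_net(ga_comp), train = TRUE)
    state$gb <- apply_gen_bn(state$gb, fs_cyc$bn_updates)
    s_cyc <- to_store(fs_cyc$y)
    fw_cyc <- unet_forward(state$ga, to_net(gb_img), train = TRUE)
    state$ga <- apply_gen_bn(state$ga, fw_cyc$bn_updates)
    w_cyc <- gb_img * (1 - M) + to_store(fw_cyc$y) * M
    recon_value <- mean(abs(s_cyc - S)) + mean(abs(w_cyc - W))

    g_s_cyc <- lw$reconstruction * sign(s_cyc - S) / n_total
    bb1 <- unet_backward(state$gb, fs_cyc$cache, 0.5 * g_s_cyc)
    grads_gb <- tree_add(grads_gb, bb1$grads)
    d_ga_comp <- d_ga_comp + 2 * bb1$gx

    g_w_cyc <- lw$reconstruction * sign(w_cyc - W) / n_total
    bb2 <- unet_backward(state$ga, fw_cyc$cache, 0.5 * (g_w_cyc * M))
    grads_ga <- tree_add(grads_ga, bb2$grads)
    d_gb_img <- d_gb_img + g_w_cyc * (1 - M) + 2 * bb2$gx
  }

  # supervised terms (SSIM, frequency, L1) on both directions
  w_list <- unstack_batch(W); s_list <- unstack_batch(S)
  ga_list <- unstack_batch(ga_comp); gb_list <- unstack_batch(gb_img)
  sg <- ssim_loss_grad(w_list, ga_list, s_list, gb_list, config$ssim)
  fg <- frequency_loss_grad(w_list, ga_list, s_list, gb_list)
  lg <- l1_loss_grad(w_list, ga_list, s_list, gb_list)
  for (i in seq_along(ga_list)) {
    d_ga_comp[i, 1, , ] <- d_ga_comp[i, 1, , ] +
      lw$ssim * sg$g_ga[[i]] + lw$frequency * fg$g_ga[[i]] +
      lw$l1 * lg$g_ga[[i]]
    d_gb_img[i, 1, , ] <- d_gb_img[i, 1, , ] +
      lw$ssim * sg$g_gb[[i]] + lw$frequency * fg$g_gb[[i]] +
      lw$l1 * lg$g_gb[[i]]
  }

  # backprop into the generators and update
  ba <- unet_backward(state$ga, fa$cache, 0.5 * (d_ga_comp * M))
  grads_ga <- tree_add(grads_ga, ba$grads)
  bb <- unet_backward(state$gb, fb$cache, 0.5 * d_gb_img)
  grads_gb <- tree_add(grads_gb, bb$grads)
  res <- rmsprop_step(state$ga$params, grads_ga, state$opt$ga,
                      config$lr_generator, config$rmsprop_alpha,
                      config$rmsprop_eps)
  state$ga$params <- res$p; state$opt$ga <- res$v
  res <- rmsprop_step(state$gb$params, grads_gb, state$opt$gb,
                      config$lr_generator, config$rmsprop_alpha,
                      config$rmsprop_eps)
  state$gb$params <- res$p; state$opt$gb <- res$v

  report <- total_loss(list(ssim = sg$value, frequency = fg$value,
                            l1 = lg$value, adversarial = adv_value,
                            reconstruction = recon_value),
                       lw)
  state$step <- state$step + 1L
  record <- data.frame(step = state$step, ssim = sg$value,
                       frequency = fg$value, l1 = lg$value,
                       adversarial = adv_value, reconstruction = recon_value,
                       total = report$total,
                       da_real = score_da_real, da_fake = score_da_fake,
                       db_real = score_db_real, db_fake = score_db_fake)
  list(state = state, record = record)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the dual-GAN artifact-inpainting model
#'
#' Trains two U-Net generators and two PatchGAN discriminators on the
#' training split of a paired phantom dataset, alternating discriminator
#' and generator updates over shuffled batches.  The whole run is
#' deterministic in `config$seed`.
#'
#' @param manifest Dataset directory or manifest from [read_manifest()].
#' @param config A [train_config()].
#' @param resume_from Optional checkpoint path or fitted object: continue
#'   its run up to `config$steps` total steps, reproducing exactly the
#'   records an uninterrupted run would have produced.
#' @param verbose Print a progress line every `config$log_every` steps.
#' @return An object of class `"dualgan"`: list with the model `state`,
#'   `config`, the per-step loss `history` and the dataset directory.
#' @export
dualgan <- function(manifest, config = train_config(), resume_from = NULL,
                    verbose = FALSE) {
  if (is.character(manifest) && length(manifest) == 1 && dir.exists(manifest))
    manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir")
  rows <- which(manifest$split == "train")
  if (length(rows) == 0) stop("manifest has no training rows")
  data <- lapply(rows, function(i) {
    paths <- file.path(dir, c(manifest$path_artifact[i], manifest$path_clean[i],
                              manifest$path_mask[i]))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("missing dataset files: ", paste(missing, collapse = ", "))
    list(s = load_image(paths[1]), w = load_image(paths[2]),
         m = load_mask(paths[3]))
  })
  if (dim(data[[1]]$s)[1] != config$image_size)
    stop("dataset image size ", dim(data[[1]]$s)[1],
         " does not match config$image_size ", config$image_size)

  if (is.null(resume_from)) {
    state <- init_dualgan_state(config)
    history <- NULL
    set.seed(config$seed + 7L)
  } else {
    prev <- if (is.character(resume_from)) load_checkpoint(resume_from)
            else resume_from
    state <- prev$state
    history <- prev$history
    assign(".Random.seed", prev$rng, envir = globalenv())
  }

  n <- length(data)
  records <- list()
  first <- state$step + 1L
  if (first > config$steps && is.null(resume_from))
    stop("config$steps must exceed the resumed step count")
  for (step in seq(from = first, length.out = max(0L, config$steps - first + 1L))) {
    idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
    batch <- list(s = lapply(data[idx], `[[`, "s"),
                  w = lapply(data[idx], `[[`, "w"),
                  m = lapply(data[idx], `[[`, "m"))
    out <- train_step(batch, state, config)
    state <- out$state
    if (!all(is.finite(out$record$total)))
      stop("non-finite loss at step ", step, "; aborting")
    if (step %% config$log_every == 0 || step == config$steps)
      records[[length(records) + 1L]] <- out$record
    if (verbose && (step %% config$log_every == 0))
      message(sprintf("step %d  total %.4f  l1 %.4f  ssim %.4f",
                      step, out$record$total, out$record$l1,
                      out$record$ssim))
    if (!is.null(config$checkpoint_dir) && config$checkpoint_every > 0 &&
        step %% config$checkpoint_every == 0) {
      fit <- new_dualgan(state, config,
                         rbind(history, do.call(rbind, records)), dir)
      save_checkpoint(fit, file.path(config$checkpoint_dir,
                                     sprintf("checkpoint_%06d.rds", step)))
    }
  }
  history <- rbind(history, do.call(rbind, records))
  fit <- new_dualgan(state, config, history, dir)
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(fit, file.path(config$checkpoint_dir, "checkpoint_final.rds"))
  }
  fit
}

new_dualgan <- function(state, config, history, data_dir) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(config$seed)
  structure(list(state = state, config = config, history = history,
                 data_dir = data_dir,
                 rng = get(".Random.seed", envir = globalenv())),
            class = "dualgan")
}

#' Save a model checkpoint
#'
#' Serializes the full model (network parameters, optimizer state, RNG
#' state, config and history) atomically; [load_checkpoint()] restores it
#' bit-exactly.
#'
#' @param fit A [dualgan()] object.
#' @param path Output path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "dualgan"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  atomic_write(path, function(p) saveRDS(fit, p))
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The restored `"dualgan"` object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  fit <- readRDS(path)
  if (!inherits(fit, "dualgan") || is.null(fit$state$ga))
    stop("file is not a dualgan checkpoint: ", path)
  fit
}

#' Inpaint the artifact region of an image
#'
#' Applies generator A in inference mode and composites the result into the
#' input: `out = image * (1 - mask) + G_A(image) * mask`, in `[0, 1]`
#' storage space.  Pixels outside the mask are bit-identical to the input
#' regardless of the training state.
#'
#' @param image Artifact image (matrix in `[0, 1]`).
#' @param mask Binary artifact mask.
#' @param model A fitted [dualgan()] object, a `"dualgan_state"`, or a
#'   checkpoint path.
#' @return The inpainted image (matrix in `[0, 1]`).
#' @export
inpaint <- function(image, mask, model) {
  check_same_shape(image, mask, "inpaint")
  if (is.character(model)) model <- load_checkpoint(model)
  state <- if (inherits(model, "dualgan")) model$state else model
  if (!inherits(state, "dualgan_state")) stop("model must be a dualgan fit or state")
  ga <- state$ga
  if (nrow(image) %% 2^ga$spec$depth != 0)
    stop("image side must be divisible by 2^depth = ", 2^ga$spec$depth)
  raw <- unet_forward(ga, stack_batch(list(to_net(image))),
                      train = FALSE, retain = FALSE)$y
  s_hat <- clamp01(to_store(unstack_batch(raw)[[1]]))
  composite(image, mask, s_hat)
}
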