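# Sequential per-fraction training: RMSProp on the composite BCE+Dice loss,
# one optimizer step per fraction, per-patient memory clearing, per-epoch
# patient shuffling, and a two-phase (pre-train, fine-tune) schedule with a
# plateau learning-rate scheduler.

#' Training settings
#'
#' @param lr initial learning rate (default `1e-5`).
#' @param min_lr learning-rate floor of the plateau scheduler
#'   (default `1e-8`).
#' @param pretrain_epochs epochs of the pre-training phase (default 40).
#' @param finetune_epochs epochs of the fine-tuning phase (default 30).
#' @param plateau_patience epochs without improvement of the monitored loss
#'   before the learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor multiplicative learning-rate decay (default 0.1).
#' @param rmsprop_alpha RMSProp smoothing constant.
#' @param rmsprop_eps RMSProp denominator offset.
#' @param tbptt if `TRUE` (default) memory is detached between fraction
#'   steps (truncated backpropagation, one optimizer step per fraction);
#'   if `FALSE` gradients flow through the whole fraction sequence and one
#'   step is taken per patient.
#' @param seed master seed for per-epoch patient shuffling.
#' @return A `train_config` list. Loss weights are fixed at 0.5/0.5
#'   (equally weighted BCE and Dice) and the batch size at 1.
#' @export
train_config <- function(lr = 1e-5, min_lr = 1e-8, pretrain_epochs = 40L,
                         finetune_epochs = 30L, plateau_patience = 3L,
                         plateau_factor = 0.1, rmsprop_alpha = 0.99,
                         rmsprop_eps = 1e-8, tbptt = TRUE, seed = 1L) {
  stopifnot(min_lr <= lr, pretrain_epochs >= 1L, finetune_epochs >= 0L,
            plateau_patience >= 1L, plateau_factor > 0, plateau_factor < 1)
  structure(list(lr = lr, min_lr = min_lr,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
                 tbptt = isTRUE(tbptt), batch_size = 1L,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- RMSProp -----------------------------------------------------------------

rmsprop_init <- function(model) {
  lapply(model$params, function(p) lapply(p, function(a) a * 0))
}

# One RMSProp update in place on the model's parameters. `grads` mirrors the
# parameter structure; NULL entries are skipped.
rmsprop_step <- function(model, grads, state, lr, alpha, eps) {
  for (nm in names(model$params)) {
    for (f in names(model$params[[nm]])) {
      g <- grads[[nm]][[f]]
      if (is.null(g)) next
      v <- alpha * state[[nm]][[f]] + (1 - alpha) * g * g
      state[[nm]][[f]] <- v
      model$params[[nm]][[f]] <- model$params[[nm]][[f]] -
        lr * g / (sqrt(v) + eps)
    }
  }
  state
}

# Gradients collected from a tape's wrapped parameter leaves.
collect_grads <- function(pn) {
  lapply(pn, function(p) lapply(p, function(node) node$grad))
}

# Binary masks of a structure set stacked into a (D,H,W,C) target array.
as_target_array <- function(contours) {
  do.call(stack_channels, unname(contours$masks))
}

# The 3-channel (or 1-channel) training input for fraction k of a series:
# fraction 1 uses the planning image and contours as prior; fraction k > 1
# uses fraction k-1's image with its ground-truth (clinician-approved)
# contours — teacher forcing, mirroring the clinical workflow where past
# fractions' contours have been revised.
training_input <- function(model, series, k) {
  cur <- series$fractions[[k]]
  if (model$config$variant == "unet_ds")
    return(stack_channels(cur$image$data))
  if (k == 1L)
    assemble_input(series$planning_image, series$planning_contours,
                   cur$image)
  else
    assemble_input(series$fractions[[k - 1L]]$image,
                   series$fractions[[k - 1L]]$contours, cur$image)
}

#' Train on one patient's fraction sequence
#'
#' Memory is zeroed on entry; fractions are visited in chronological order,
#' each contributing one composite-loss optimizer step (under truncated
#' backpropagation, the default); memory is carried between fractions of
#' the same patient and zeroed again on exit.
#'
#' @param model a `progseg_model` (updated in place).
#' @param series a [patient_series()].
#' @param opt_state RMSProp state carried from a previous pass, or `NULL`
#'   to start fresh.
#' @param config a [train_config()].
#' @param lr learning rate for this pass (defaults to `config$lr`).
#' @return `list(losses = , opt_state = , memory = )`: per-fraction
#'   composite losses, the updated optimizer state, and the (zeroed)
#'   memory a following patient would start from.
#' @export
train_patient_pass <- function(model, series, opt_state = NULL,
                               config = train_config(), lr = config$lr) {
  stopifnot(inherits(model, "progseg_model"),
            inherits(series, "patient_series"))
  if (is.null(opt_state)) opt_state <- rmsprop_init(model)
  n <- length(series$fractions)
  if (n < 1L) stop("series has no fractions", call. = FALSE)
  shp <- dim(series$planning_image$data)
  is_lstm <- model$config$variant == "lstm_unet"
  mem <- if (is_lstm) init_memory(model$config, shp)
  losses <- numeric(n)
  if (config$tbptt || !is_lstm) {
    for (k in seq_len(n)) {
      input <- training_input(model, series, k)
      target <- as_target_array(series$fractions[[k]]$contours)
      ft <- forward_tape(model, input, mem)
      loss <- tg_scalar_mix(tg_bce(ft$probs, target),
                            tg_soft_dice(ft$probs, target), 0.5, 0.5)
      losses[k] <- loss$value
      if (!is.finite(loss$value))
        stop("non-finite training loss at fraction ", k, call. = FALSE)
      tg_backward(loss)
      opt_state <- rmsprop_step(model, collect_grads(ft$params), opt_state,
                                lr, config$rmsprop_alpha, config$rmsprop_eps)
      if (is_lstm)  # carry values only: detached between fraction steps
        mem <- lapply(ft$memory, function(s)
          list(h = s$h$value, c = s$c$value))
    }
  } else {
    # full backpropagation through time: one step per patient
    pn <- wrap_params(model)
    total <- NULL
    for (k in seq_len(n)) {
      input <- training_input(model, series, k)
      target <- as_target_array(series$fractions[[k]]$contours)
      ft <- forward_tape(model, input, mem, pn = pn)
      loss <- tg_scalar_mix(tg_bce(ft$probs, target),
                            tg_soft_dice(ft$probs, target), 0.5, 0.5)
      losses[k] <- loss$value
      if (!is.finite(loss$value))
        stop("non-finite training loss at fraction ", k, call. = FALSE)
      mem <- ft$memory  # keep nodes: gradient flows across fractions
      total <- if (is.null(total)) loss else tg_add(total, loss)
    }
    tg_backward(total)
    opt_state <- rmsprop_step(model, collect_grads(pn), opt_state, lr,
                              config$rmsprop_alpha, config$rmsprop_eps)
  }
  list(losses = losses, opt_state = opt_state,
       memory = if (is_lstm) init_memory(model$config, shp))
}

#' Run one training epoch over a cohort
#'
#' Visits every patient exactly once in a seed-derived per-epoch random
#' order and runs [train_patient_pass()] on each.
#'
#' @inheritParams train_patient_pass
#' @param cohort list of [patient_series()].
#' @param epoch epoch number (determines the shuffling permutation).
#' @return `list(visit_order = , losses = , opt_state = )`; `losses` has
#'   one mean per patient in visit order.
#' @export
train_epoch <- function(model, cohort, opt_state = NULL,
                        config = train_config(), epoch = 1L,
                        lr = config$lr) {
  stopifnot(length(cohort) >= 1L)
  if (is.null(opt_state)) opt_state <- rmsprop_init(model)
  perm_seed <- (config$seed + 104729L * as.integer(epoch)) %%
    (.Machine$integer.max - 1L) + 1L
  perm <- with_seed(perm_seed, sample(length(cohort)))
  losses <- numeric(length(cohort))
  for (i in seq_along(perm)) {
    res <- train_patient_pass(model, cohort[[perm[i]]], opt_state, config,
                              lr = lr)
    opt_state <- res$opt_state
    losses[i] <- mean(res$losses)
  }
  list(visit_order = perm, losses = losses, opt_state = opt_state)
}

# Mean teacher-forced composite loss over a cohort (no parameter updates);
# used to drive the plateau scheduler.
cohort_loss <- function(model, cohort) {
  total <- 0; count <- 0L
  for (series in cohort) {
    mem <- if (model$config$variant == "lstm_unet")
      init_memory(model$config, dim(series$planning_image$data))
    for (k in seq_along(series$fractions)) {
      input <- training_input(model, series, k)
      target <- as_target_array(series$fractions[[k]]$contours)
      out <- model_forward(model, input, mem)
      mem <- out$memory
      total <- total + composite_loss(out$probs, target)
      count <- count + 1L
    }
  }
  total / count
}

#' Fit a model with pre-training and fine-tuning
#'
#' Runs `pretrain_epochs` over the pre-training cohort with RMSProp from
#' the configured learning rate, then `finetune_epochs` over the
#' fine-tuning cohort starting from the last pre-trained parameters (the
#' learning rate and scheduler are reset between phases). A
#' reduce-on-plateau scheduler multiplies the learning rate by
#' `plateau_factor` when the monitored loss (validation if a validation
#' cohort is given, else training) has not improved for
#' `plateau_patience` epochs, floored at `min_lr`.
#'
#' @inheritParams train_epoch
#' @param pretrain_cohort list of [patient_series()] for pre-training.
#' @param finetune_cohort optional cohort for fine-tuning (skipped if
#'   `NULL` or `finetune_epochs = 0`).
#' @param validation_cohort optional cohort whose loss drives the
#'   scheduler.
#' @param checkpoint_path optional path; the last pre-trained checkpoint is
#'   saved there and reloaded to initialize fine-tuning.
#' @param verbose print one line per epoch.
#' @return `list(model = , log = )`; `log` is a data.frame with one row per
#'   epoch (phase, epoch, lr, train_loss, monitor_loss).
#' @export
fit <- function(model, pretrain_cohort, finetune_cohort = NULL,
                validation_cohort = NULL, config = train_config(),
                checkpoint_path = NULL, verbose = FALSE) {
  opt_state <- rmsprop_init(model)
  log <- data.frame()
  run_phase <- function(phase, cohort, epochs) {
    lr <- config$lr
    best <- Inf; wait <- 0L
    for (ep in seq_len(epochs)) {
      res <- train_epoch(model, cohort, opt_state, config, epoch = ep,
                         lr = lr)
      opt_state <<- res$opt_state
      train_loss <- mean(res$losses)
      monitor <- if (!is.null(validation_cohort))
        cohort_loss(model, validation_cohort) else train_loss
      log <<- rbind(log, data.frame(phase = phase, epoch = ep, lr = lr,
                                    train_loss = train_loss,
                                    monitor_loss = monitor))
      if (verbose)
        message(sprintf("[%s] epoch %d  lr %.2e  train %.4f  monitor %.4f",
                        phase, ep, lr, train_loss, monitor))
      if (monitor < best) {
        best <- monitor; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          lr <- max(lr * config$plateau_factor, config$min_lr)
          wait <- 0L
        }
      }
    }
  }
  run_phase("pretrain", pretrain_cohort, config$pretrain_epochs)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path, extra = list(log = log))
    model <- load_checkpoint(checkpoint_path)$model
  }
  if (!is.null(finetune_cohort) && config$finetune_epochs > 0L) {
    opt_state <- rmsprop_init(model)  # fresh optimizer, lr reset
    run_phase("finetune", finetune_cohort, config$finetune_epochs)
  }
  list(model = model, log = log)
}
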