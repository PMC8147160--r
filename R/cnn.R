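#' Specification of the three-stage patch conversion network
#'
#' Three valid (unpadded) convolution stages map a 32x32 MRI patch to an
#' 18x18 HU patch, so the kernel sizes must satisfy
#' `sum(kernel_sizes - 1) == 14`.  Hidden stages use a rectifier; the
#' output stage is linear.  Deep supervision attaches a 1x1 auxiliary
#' regression head after stages 1 and 2, whose center-cropped mean-squared
#' errors join the main loss with the given weights.
#'
#' @param kernel_sizes three odd integers summing to a reduction of 14
#'   (default `c(7, 5, 5)`).
#' @param channels three integers, last one 1 (default `c(64, 64, 1)`).
#'   Widths of 4-16 train the pointwise conversion task in minutes on one
#'   CPU core and are used throughout the examples and tests.
#' @param dsn_weights non-negative auxiliary-loss weights after stages 1
#'   and 2 (default `c(0.3, 0.3)`; the main loss has weight 1).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kernel_sizes = c(7L, 5L, 5L),
                       channels = c(64L, 64L, 1L),
                       dsn_weights = c(0.3, 0.3)) {
  kernel_sizes <- as.integer(kernel_sizes)
  channels <- as.integer(channels)
  if (length(kernel_sizes) != 3L || length(channels) != 3L)
    stop("need 3 kernel sizes and 3 channel counts", call. = FALSE)
  if (sum(kernel_sizes - 1L) != 14L)
    stop("kernel sizes must reduce 32 to 18: sum(kernel - 1) must be 14, ",
         "got ", sum(kernel_sizes - 1L), call. = FALSE)
  if (any(kernel_sizes %% 2L == 0L))
    stop("kernel sizes must be odd", call. = FALSE)
  if (channels[3] != 1L)
    stop("final stage must have 1 output channel", call. = FALSE)
  if (any(channels < 1L))
    stop("channel counts must be positive", call. = FALSE)
  if (length(dsn_weights) != 2L || any(dsn_weights < 0))
    stop("'dsn_weights' must be 2 non-negative reals", call. = FALSE)
  structure(list(stages = 3L, kernel_sizes = kernel_sizes,
                 channels = channels, dsn_weights = as.numeric(dsn_weights)),
            class = "model_spec")
}

#' Training configuration for the conversion network
#'
#' @param batch_size mini-batch size (default 128).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param epochs training epochs (default 50).
#' @param patience early-stopping patience on validation loss (epochs
#'   without improvement; `Inf` disables).  The best-validation weights are
#'   restored.
#' @param clip_norm global gradient-norm ceiling (on the standardized
#'   loss); mini-batch gradients larger than this are rescaled, which tames
#'   the start-of-training transient that momentum otherwise amplifies.
#'   `Inf` disables.
#' @param seed RNG seed for shuffling.
#' @return A list of class `train_config`.  Loss is mean squared error on
#'   Hounsfield units; internally targets are standardized during
#'   optimization (see [train_model()]) and all reported losses are in
#'   HU^2.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 0.01,
                         momentum = 0.9, epochs = 50L, patience = 10L,
                         clip_norm = 5, seed = 0L) {
  if (batch_size < 1L || learning_rate <= 0 || momentum < 0 ||
      momentum >= 1 || epochs < 0L || clip_norm <= 0)
    stop("invalid training hyperparameters", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), patience = patience,
                 clip_norm = clip_norm, loss = "mse",
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- im2col machinery ------------------------------------------------
## Feature maps live in matrices of dim (h*w*N, C): row = in-slice pixel
## index (column-major) plus (n-1)*h*w; one column per channel.

make_im2col_index <- function(h, w, k, n) {
  oh <- h - k + 1L; ow <- w - k + 1L
  out_r <- rep(seq_len(oh), ow)
  out_c <- rep(seq_len(ow), each = oh)
  ispat <- matrix(0L, oh * ow, k * k)
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    ispat[, dr + 1L + dc * k] <- (out_r + dr) + (out_c + dc - 1L) * h
  }
  offs <- rep((0:(n - 1L)) * h * w, each = oh * ow)
  idx <- ispat[rep(seq_len(oh * ow), n), , drop = FALSE] + offs
  list(idx = idx, idx_vec = as.vector(idx), rows = oh * ow * n,
       oh = oh, ow = ow)
}

## gather patch columns: one indexed read, then a dimension shuffle so the
## column order is (kernel offset, input channel)
im2col <- function(f, index, k, c_in) {
  kk <- k * k
  g <- f[index$idx_vec, , drop = FALSE]
  dim(g) <- c(index$rows, kk, c_in)
  g <- aperm(g, c(1, 3, 2))
  dim(g) <- c(index$rows, kk * c_in)
  g
}

## adjoint of im2col: scatter-add patch-column gradients back to the map
col2im <- function(dxc, index, k, c_in, n_rows) {
  kk <- k * k
  g <- dxc
  dim(g) <- c(index$rows, c_in, kk)
  g <- aperm(g, c(1, 3, 2))
  dim(g) <- c(index$rows * kk, c_in)
  acc <- rowsum(g, index$idx_vec, reorder = FALSE)
  df <- matrix(0, n_rows, c_in)
  df[as.integer(rownames(acc)), ] <- acc
  df
}

## rows of the centered (crop x crop) sub-map within (oh x ow x N) maps
crop_rows <- function(oh, ow, crop, n) {
  m_r <- (oh - crop) %/% 2L; m_c <- (ow - crop) %/% 2L
  rr <- rep(m_r + seq_len(crop), crop)
  cc <- rep(m_c + seq_len(crop), each = crop)
  base <- rr + (cc - 1L) * oh
  rep(base, n) + rep((0:(n - 1L)) * oh * ow, each = crop * crop)
}

init_weight <- function(fan_in, n_out, gain = 2) {
  matrix(stats::rnorm(fan_in * n_out, sd = sqrt(gain / fan_in)),
         fan_in, n_out)
}

#' Build an (untrained) conversion network
#'
#' Verifies the receptive-field arithmetic (a 32x32 input must yield an
#' 18x18 output) and draws seeded initial weights: He-scaled normal for the
#' rectified stages, variance-1/fan-in for the linear output and the 1x1
#' auxiliary heads, zero biases.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return A list of class `trained_model` with `spec`, `params`,
#'   `input_scaling` (fit during training), `loss_history` (empty),
#'   `trained = FALSE`.
#' @export
build_model <- function(spec = model_spec(), seed = 0L) {
  if (!inherits(spec, "model_spec")) stop("'spec' must be a model_spec",
                                          call. = FALSE)
  k <- spec$kernel_sizes; ch <- spec$channels
  sizes <- c(32L, 32L - cumsum(k - 1L))
  if (sizes[4] != 18L)
    stop("receptive-field arithmetic violated: 32x32 input yields ",
         sizes[4], "x", sizes[4], " output", call. = FALSE)
  params <- with_seed(seed, list(
    w1 = init_weight(k[1]^2 * 1L, ch[1]), b1 = numeric(ch[1]),
    w2 = init_weight(k[2]^2 * ch[1], ch[2]), b2 = numeric(ch[2]),
    w3 = init_weight(k[3]^2 * ch[2], ch[3], gain = 1), b3 = numeric(ch[3]),
    a1 = init_weight(ch[1], 1L, gain = 1), a1b = 0,
    a2 = init_weight(ch[2], 1L, gain = 1), a2b = 0
  ))
  structure(list(spec = spec, params = params,
                 input_scaling = c(center = 0, scale = 1),
                 label_scaling = c(center = 0, scale = 1),
                 loss_history = data.frame(epoch = integer(0),
                                           train_loss = numeric(0),
                                           val_loss = numeric(0)),
                 trained = FALSE, seed = as.integer(seed)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> kernels %s, channels %s, %s\n",
              paste(x$spec$kernel_sizes, collapse = "/"),
              paste(x$spec$channels, collapse = "/"),
              if (x$trained) sprintf("trained (%d epochs logged)",
                                     nrow(x$loss_history))
              else "untrained"))
  invisible(x)
}

## forward pass on a batch; x: (32*32*N, 1) scaled inputs.
## Returns activations needed for backprop.
cnn_forward <- function(params, spec, x, n, caches) {
  k <- spec$kernel_sizes; ch <- spec$channels
  i1 <- caches[[1]]; i2 <- caches[[2]]; i3 <- caches[[3]]
  xc1 <- im2col(x, i1, k[1], 1L)
  z1 <- xc1 %*% params$w1
  z1 <- sweep(z1, 2L, params$b1, `+`)
  h1 <- z1 * (z1 > 0)
  xc2 <- im2col(h1, i2, k[2], ch[1])
  z2 <- xc2 %*% params$w2
  z2 <- sweep(z2, 2L, params$b2, `+`)
  h2 <- z2 * (z2 > 0)
  xc3 <- im2col(h2, i3, k[3], ch[2])
  out <- xc3 %*% params$w3
  out <- out + params$b3[1]
  list(xc1 = xc1, h1 = h1, xc2 = xc2, h2 = h2, xc3 = xc3, out = out)
}

## total loss and gradients for a batch; y: (18*18*N, 1)
cnn_backward <- function(params, spec, fw, x, y, n, caches) {
  k <- spec$kernel_sizes; ch <- spec$channels
  i1 <- caches[[1]]; i2 <- caches[[2]]; i3 <- caches[[3]]
  dsn <- spec$dsn_weights
  len <- length(y)
  err <- fw$out - y
  loss_main <- mean(err^2)
  dout <- 2 * err / len
  ## stage-3 backward
  g_w3 <- crossprod(fw$xc3, dout)
  g_b3 <- sum(dout)
  dh2 <- col2im(dout %*% t(params$w3), i3, k[3], ch[2], nrow(fw$h2))
  ## DSN head on stage 2
  rows2 <- caches$rows2
  loss_aux2 <- 0
  if (dsn[2] > 0) {
    p2 <- fw$h2[rows2, , drop = FALSE] %*% params$a2 + params$a2b
    e2 <- p2 - y
    loss_aux2 <- mean(e2^2)
    dp2 <- 2 * e2 / len * dsn[2]
    g_a2 <- crossprod(fw$h2[rows2, , drop = FALSE], dp2)
    g_a2b <- sum(dp2)
    dh2[rows2, ] <- dh2[rows2, ] + dp2 %*% t(params$a2)
  } else { g_a2 <- params$a2 * 0; g_a2b <- 0 }
  dz2 <- dh2 * (fw$h2 > 0)
  g_w2 <- crossprod(fw$xc2, dz2)
  g_b2 <- colSums(dz2)
  dh1 <- col2im(dz2 %*% t(params$w2), i2, k[2], ch[1], nrow(fw$h1))
  ## DSN head on stage 1
  rows1 <- caches$rows1
  loss_aux1 <- 0
  if (dsn[1] > 0) {
    p1 <- fw$h1[rows1, , drop = FALSE] %*% params$a1 + params$a1b
    e1 <- p1 - y
    loss_aux1 <- mean(e1^2)
    dp1 <- 2 * e1 / len * dsn[1]
    g_a1 <- crossprod(fw$h1[rows1, , drop = FALSE], dp1)
    g_a1b <- sum(dp1)
    dh1[rows1, ] <- dh1[rows1, ] + dp1 %*% t(params$a1)
  } else { g_a1 <- params$a1 * 0; g_a1b <- 0 }
  dz1 <- dh1 * (fw$h1 > 0)
  g_w1 <- crossprod(fw$xc1, dz1)
  g_b1 <- colSums(dz1)
  list(loss = loss_main + dsn[1] * loss_aux1 + dsn[2] * loss_aux2,
       loss_main = loss_main,
       grads = list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2,
                    w3 = g_w3, b3 = g_b3, a1 = g_a1, a1b = g_a1b,
                    a2 = g_a2, a2b = g_a2b))
}

make_caches <- function(spec, n) {
  k <- spec$kernel_sizes
  i1 <- make_im2col_index(32L, 32L, k[1], n)
  i2 <- make_im2col_index(i1$oh, i1$ow, k[2], n)
  i3 <- make_im2col_index(i2$oh, i2$ow, k[3], n)
  list(i1, i2, i3,
       rows1 = crop_rows(i1$oh, i1$ow, 18L, n),
       rows2 = crop_rows(i2$oh, i2$ow, 18L, n))
}

## patches (N, 32, 32) -> scaled input matrix (32*32*N, 1)
patches_to_input <- function(patches, scaling) {
  x <- aperm(patches, c(2, 3, 1))
  matrix((as.vector(x) - scaling[["center"]]) / scaling[["scale"]], ncol = 1)
}

labels_to_output <- function(labels) {
  matrix(as.vector(aperm(labels, c(2, 3, 1))), ncol = 1)
}

model_loss <- function(model, patches, labels, batch = 256L) {
  n <- dim(patches)[1]
  tot <- 0
  done <- 0L
  while (done < n) {
    take <- min(batch, n - done)
    idx <- (done + 1L):(done + take)
    caches <- make_caches(model$spec, take)
    x <- patches_to_input(patches[idx, , , drop = FALSE],
                          model$input_scaling)
    y <- labels_to_output(labels[idx, , , drop = FALSE])
    fw <- cnn_forward(model$params, model$spec, x, take, caches)
    pred <- fw$out * model$label_scaling[["scale"]] +
      model$label_scaling[["center"]]
    tot <- tot + sum((pred - y)^2)
    done <- done + take
  }
  tot / (n * 18 * 18)
}

#' Train the conversion network with SGD
#'
#' Stochastic gradient descent with momentum on the deeply supervised loss
#' (main mean-squared error plus weighted auxiliary MSEs).  Affine scalings
#' to zero mean / unit variance of the training set are fit here for both
#' the inputs and the HU targets; the optimizer sees standardized targets
#' (raw-HU errors are two to three orders of magnitude larger than unit
#' activations, which makes plain SGD at the stated learning rate diverge)
#' and predictions are mapped back to HU, so the model's outputs and every
#' reported loss are in Hounsfield units.  Mini-batch gradients are
#' norm-clipped at `cfg$clip_norm`.  Per-epoch training and validation
#' losses (main MSE, HU^2) are appended to the loss history.  Training is
#' reproducible for a fixed seed on a fixed platform.
#'
#' @param model a [build_model()] result.
#' @param train,val `paired_patch_set`s (see [crop_patches()]).
#' @param cfg a [train_config()].
#' @return The trained model; with early stopping, the weights achieving
#'   the best validation loss.  An error is raised if the loss diverges to
#'   a non-finite value.
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  if (!inherits(model, "trained_model")) stop("'model' must come from ",
                                              "build_model()", call. = FALSE)
  n <- dim(train$inputs)[1]
  if (is.null(n) || n == 0L) stop("empty training set", call. = FALSE)
  if (cfg$epochs == 0L) { model$trained <- TRUE; return(model) }
  mu <- mean(train$inputs)
  sdv <- stats::sd(as.vector(train$inputs))
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  model$input_scaling <- c(center = mu, scale = sdv)
  ymu <- mean(train$labels)
  ysd <- stats::sd(as.vector(train$labels))
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  model$label_scaling <- c(center = ymu, scale = ysd)
  params <- model$params
  vel <- lapply(params, function(p) p * 0)
  cache_by_n <- list()
  get_caches <- function(nb) {
    key <- as.character(nb)
    if (is.null(cache_by_n[[key]]))
      cache_by_n[[key]] <<- make_caches(model$spec, nb)
    cache_by_n[[key]]
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- model$loss_history
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        nb <- length(idx)
        caches <- get_caches(nb)
        x <- patches_to_input(train$inputs[idx, , , drop = FALSE],
                              model$input_scaling)
        y <- (labels_to_output(train$labels[idx, , , drop = FALSE]) -
                ymu) / ysd
        fw <- cnn_forward(params, model$spec, x, nb, caches)
        bk <- cnn_backward(params, model$spec, fw, x, y, nb, caches)
        if (!is.finite(bk$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        gn <- sqrt(sum(vapply(bk$grads, function(g) sum(g^2), numeric(1))))
        sc <- if (is.finite(cfg$clip_norm) && gn > cfg$clip_norm)
          cfg$clip_norm / gn else 1
        for (nm in names(params)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] -
            cfg$learning_rate * sc * bk$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + bk$loss_main * ysd^2 * nb
        ep_n <- ep_n + nb
      }
      model$params <- params
      vl <- if (!is.null(val) && dim(val$inputs)[1] > 0)
        model_loss(model, val$inputs, val$labels) else NA_real_
      history <- rbind(history, data.frame(
        epoch = nrow(history) + 1L, train_loss = ep_loss / ep_n,
        val_loss = vl))
      if (is.finite(vl) && vl < best$loss)
        best <- list(loss = vl, params = params, epoch = epoch)
      if (is.finite(best$loss) && is.finite(cfg$patience) &&
          epoch - best$epoch >= cfg$patience) break
    }
  })
  if (is.finite(best$loss)) model$params <- best$params
  model$loss_history <- history
  model$trained <- TRUE
  model
}

#' Predict HU patches from MRI patches
#'
#' @param model a trained model.
#' @param patches `(N, 32, 32)` array of MRI patches.
#' @return `(N, 18, 18)` array of predicted HU.
#' @export
predict_patches <- function(model, patches) {
  if (!isTRUE(model$trained)) stop("model is untrained", call. = FALSE)
  n <- dim(patches)[1]
  caches <- make_caches(model$spec, n)
  x <- patches_to_input(patches, model$input_scaling)
  fw <- cnn_forward(model$params, model$spec, x, n, caches)
  pred <- fw$out * model$label_scaling[["scale"]] +
    model$label_scaling[["center"]]
  aperm(array(pred, c(18, 18, n)), c(3, 1, 2))
}

reflect_pad_matrix <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  m[ri, ci, drop = FALSE]
}

#' Convert a corrected MRI volume to pseudo-CT
#'
#' Sliding-window inference per axial slice: the slice is reflect-padded by
#' 7 pixels, 32x32 windows are tiled at the given stride (plus a final
#' window flush with each edge), and the 18x18 outputs are placed at their
#' window centers; overlapping outputs are averaged.  The output grid
#' matches the input grid.
#'
#' @param model a trained model.
#' @param mri_corrected normalized MRI [volume()].
#' @param stride window stride in pixels (default 18 = non-overlapping).
#' @param batch windows per forward pass.
#' @return A `PSEUDO_CT` [volume()] in HU.
#' @export
predict_volume <- function(model, mri_corrected, stride = 18L,
                           batch = 256L) {
  if (!isTRUE(model$trained)) stop("model is untrained", call. = FALSE)
  stopifnot_volume(mri_corrected)
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1", call. = FALSE)
  d <- dim(mri_corrected$data)
  nr <- d[2]; nc <- d[3]
  if (nr < 18L || nc < 18L)
    stop("slices must be at least 18x18 pixels", call. = FALSE)
  pad <- 7L
  starts <- function(extent) {
    s <- seq(1L, extent - 17L, by = stride)
    if (s[length(s)] != extent - 17L) s <- c(s, extent - 17L)
    s
  }
  rs <- starts(nr); cs <- starts(nc)
  grid <- expand.grid(r = rs, c = cs)
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    padded <- reflect_pad_matrix(mri_corrected$data[s, , ], pad)
    acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    done <- 0L
    while (done < nrow(grid)) {
      take <- min(batch, nrow(grid) - done)
      idx <- (done + 1L):(done + take)
      patches <- array(0, c(take, 32L, 32L))
      for (i in seq_len(take)) {
        r <- grid$r[idx[i]]; c <- grid$c[idx[i]]
        patches[i, , ] <- padded[r:(r + 31L), c:(c + 31L)]
      }
      preds <- predict_patches(model, patches)
      for (i in seq_len(take)) {
        r <- grid$r[idx[i]]; c <- grid$c[idx[i]]
        rr <- r:(r + 17L); cc <- c:(c + 17L)
        acc[rr, cc] <- acc[rr, cc] + preds[i, , ]
        cnt[rr, cc] <- cnt[rr, cc] + 1
      }
      done <- done + take
    }
    out[s, , ] <- acc / cnt
  }
  volume(out, spacing = mri_corrected$spacing, modality = "PSEUDO_CT",
         units = "HU")
}

#' Composite bone from a registered real CT into a pseudo-CT
#'
#' Non-bone pseudo-CT synthesis leaves bone to other means; this utility
#' pastes registered real-CT intensities inside a bone mask and keeps the
#' pseudo-CT elsewhere.
#'
#' @param pseudo_ct,real_ct_registered [volume()]s on one grid.
#' @param bone_mask logical/0-1 array on the same grid.
#' @return A `PSEUDO_CT` [volume()].
#' @export
compose_bone <- function(pseudo_ct, real_ct_registered, bone_mask) {
  stopifnot_volume(pseudo_ct); stopifnot_volume(real_ct_registered)
  check_same_grid(pseudo_ct, real_ct_registered, "pseudo and real CT")
  if (!identical(dim(bone_mask), dim(pseudo_ct$data)))
    stop("bone mask must share the volume grid", call. = FALSE)
  out <- pseudo_ct$data
  sel <- bone_mask > 0
  out[sel] <- real_ct_registered$data[sel]
  volume(out, spacing = pseudo_ct$spacing, modality = "PSEUDO_CT",
         units = "HU")
}

#' Save a trained model to a directory
#'
#' Writes `spec.json` (architecture, scaling, history, seed) plus
#' `weights.rds` (exact parameter values).  [load_model()] restores a model
#' whose predictions are bit-identical.
#'
#' @param model a `trained_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    kernel_sizes = model$spec$kernel_sizes,
    channels = model$spec$channels,
    dsn_weights = model$spec$dsn_weights,
    input_scaling = as.list(model$input_scaling),
    label_scaling = as.list(model$label_scaling),
    trained = model$trained, seed = model$seed,
    loss_history = model$loss_history
  ), file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  ## scalings ride with the weights so reloaded predictions are
  ## bit-identical (JSON carries a readable copy only)
  saveRDS(list(params = model$params,
               input_scaling = model$input_scaling,
               label_scaling = model$label_scaling),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model saved by [save_model()]
#' @param dir model directory.
#' @return A `trained_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  spec <- model_spec(meta$kernel_sizes, meta$channels, meta$dsn_weights)
  blob <- readRDS(file.path(dir, "weights.rds"))
  params <- blob$params
  lh <- as.data.frame(meta$loss_history)
  if (nrow(lh) == 0L) lh <- data.frame(epoch = integer(0),
                                       train_loss = numeric(0),
                                       val_loss = numeric(0))
  structure(list(spec = spec, params = params,
                 input_scaling = blob$input_scaling,
                 label_scaling = blob$label_scaling,
                 loss_history = lh,
                 trained = isTRUE(meta$trained),
                 seed = meta$seed %||% 0L),
            class = "trained_model")
}

#' Piecewise-linear intensity lookup converter
#'
#' A transparent baseline alongside the network: the pointwise pairs define
#' an MRI-to-HU map directly, realized as linear interpolation through the
#' (MRI, mean HU) graph (duplicate MRI intensities are averaged; queries
#' outside the covered range clamp to the end values).
#'
#' @param pairs an [extract_pairs()] result (any subset of tissues).
#' @return A function mapping a [volume()] (or numeric vector) of MRI
#'   intensities to pseudo-CT HU.
#' @export
fit_lookup_converter <- function(pairs) {
  if (nrow(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  agg <- stats::aggregate(ct_hu ~ mri_au, data = as.data.frame(pairs), mean)
  agg <- agg[order(agg$mri_au), ]
  if (nrow(agg) == 1L) {
    f <- function(x) rep(agg$ct_hu[1], length(x))
  } else {
    f <- stats::approxfun(agg$mri_au, agg$ct_hu, rule = 2)
  }
  function(x) {
    if (is_volume(x)) {
      volume(array(f(as.vector(x$data)), dim = dim(x$data)),
             spacing = x$spacing, modality = "PSEUDO_CT", units = "HU")
    } else {
      f(x)
    }
  }
}
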