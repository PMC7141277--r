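#' Configuration of the volumetric convolutional autoencoder
#'
#' The autoencoder compresses a 3D index map through three stages of
#' size-preserving 3D convolution + 2x2x2 max pooling down to a bottleneck
#' of shape (x/8, y/8, z/8, 16), then mirrors back up with three stages of
#' 2x upsampling + convolution to a sigmoid reconstruction. It is trained
#' unsupervised with a binary cross-entropy reconstruction loss under the
#' Adadelta optimizer.
#'
#' @param input_shape 3 integers, each divisible by 8.
#' @param channels encoder channel taper (3 integers, last must be 16, the
#'   bottleneck width).
#' @param kernel_size odd convolution kernel size (default 3).
#' @param learning_rate Adadelta learning-rate multiplier (default 0.01).
#' @param epochs training epochs (default 50).
#' @param optimizer_name only `"adadelta"` is implemented.
#' @param loss_name only `"binary cross-entropy"` is implemented.
#' @param batch_size mini-batch size (default 8).
#' @param rho,epsilon Adadelta decay and stabiliser.
#' @param seed seed for weight initialisation and batch shuffling.
#' @return an object of class `ae_config`.
#' @export
ae_config <- function(input_shape,
                      channels = c(32, 16, 16),
                      kernel_size = 3,
                      learning_rate = 0.01,
                      epochs = 50,
                      optimizer_name = "adadelta",
                      loss_name = "binary cross-entropy",
                      batch_size = 8,
                      rho = 0.95,
                      epsilon = 1e-6,
                      seed = 0L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape %% 8 != 0))
    stop_invalid("input_shape must be 3 integers divisible by 8")
  if (length(channels) != 3 || channels[3] != 16)
    stop_invalid("channels must be 3 integers with bottleneck width 16")
  if (kernel_size %% 2 != 1) stop_invalid("kernel_size must be odd")
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (epochs < 0) stop_invalid("epochs must be >= 0")
  if (!identical(optimizer_name, "adadelta"))
    stop_invalid("only the adadelta optimizer is implemented")
  structure(list(input_shape = input_shape, channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer_name = optimizer_name, loss_name = loss_name,
                 batch_size = as.integer(batch_size), rho = rho,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "ae_config")
}

# Layer plan: six convolutions, three max-pools, three upsamples.
ae_layer_plan <- function(cfg) {
  s0 <- cfg$input_shape; s1 <- s0 %/% 2L; s2 <- s0 %/% 4L; s3 <- s0 %/% 8L
  ch <- cfg$channels
  list(
    list(op = "conv", dims = s0, cin = 1L, cout = ch[1], act = "relu"),
    list(op = "pool", dims = s0),
    list(op = "conv", dims = s1, cin = ch[1], cout = ch[2], act = "relu"),
    list(op = "pool", dims = s1),
    list(op = "conv", dims = s2, cin = ch[2], cout = ch[3], act = "relu"),
    list(op = "pool", dims = s2),  # -> bottleneck at s3 x ch[3]
    list(op = "up", dims = s3),
    list(op = "conv", dims = s2, cin = ch[3], cout = 16L, act = "relu"),
    list(op = "up", dims = s2),
    list(op = "conv", dims = s1, cin = 16L, cout = 16L, act = "relu"),
    list(op = "up", dims = s1),
    list(op = "conv", dims = s0, cin = 16L, cout = 1L, act = "sigmoid"))
}

#' Build the 3D convolutional autoencoder
#'
#' Instantiates the six-convolution / three-pool / three-upsample network
#' with Glorot-uniform weights (seeded from the config).
#'
#' @param cfg an [ae_config()].
#' @return an object of class `conv_autoencoder`.
#' @examples
#' m <- build_autoencoder(ae_config(c(24, 24, 24)))
#' encoder_output_shape(m)   # 3 3 3 16
#' @export
build_autoencoder <- function(cfg) {
  stopifnot(inherits(cfg, "ae_config"))
  plan <- ae_layer_plan(cfg)
  k3 <- cfg$kernel_size^3
  weights <- with_seed(cfg$seed, lapply(plan, function(l) {
    if (l$op != "conv") return(NULL)
    fan_in <- k3 * l$cin; fan_out <- k3 * l$cout
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * l$cout, -lim, lim), fan_in, l$cout),
         b = numeric(l$cout))
  }))
  structure(list(cfg = cfg, plan = plan, weights = weights, trained = FALSE),
            class = "conv_autoencoder")
}

#' @exportS3Method base::print
print.conv_autoencoder <- function(x, ...) {
  census <- table(vapply(x$plan, `[[`, "", "op"))
  np <- sum(vapply(x$weights, function(w)
    if (is.null(w)) 0L else length(w$W) + length(w$b), integer(1)))
  bs <- encoder_output_shape(x)
  cat(sprintf(paste0("3D convolutional autoencoder: input %s; ",
                     "%d conv / %d pool / %d upsample layers; ",
                     "bottleneck (%s); %d parameters; %s\n"),
              paste(x$cfg$input_shape, collapse = "x"),
              census[["conv"]], census[["pool"]], census[["up"]],
              paste(bs, collapse = ", "), np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Encoder output shape and flattened feature length
#'
#' @param x a `conv_autoencoder`, `ae_config`, or 3-vector input shape.
#' @return integer vector (x/8, y/8, z/8, 16); `ae_flat_length` returns
#'   its product.
#' @export
encoder_output_shape <- function(x) {
  shape <- if (inherits(x, "conv_autoencoder")) x$cfg$input_shape
           else if (inherits(x, "ae_config")) x$input_shape
           else as.integer(x)
  if (any(shape %% 8 != 0)) stop_invalid("input dims must be divisible by 8")
  c(shape %/% 8L, 16L)
}

#' @rdname encoder_output_shape
#' @export
ae_flat_length <- function(x) prod(encoder_output_shape(x))

# Forward pass on one volume (as an nvox x 1 matrix). With cache = TRUE,
# stores what the backward pass needs: im2col matrices, ReLU masks, pool
# argmax indices.
ae_forward <- function(model, x, cache = FALSE) {
  k <- model$cfg$kernel_size
  caches <- if (cache) vector("list", length(model$plan)) else NULL
  bott <- NULL
  for (li in seq_along(model$plan)) {
    l <- model$plan[[li]]
    d <- l$dims
    if (l$op == "conv") {
      col <- cpp_im2col(x, d[1], d[2], d[3], k)
      w <- model$weights[[li]]
      pre <- col %*% w$W
      pre <- sweep(pre, 2, w$b, "+")
      if (l$act == "relu") {
        y <- pre * (pre > 0)
      } else {
        y <- 1 / (1 + exp(-pre))
      }
      if (cache) caches[[li]] <- list(col = col, pre = pre)
      x <- y
    } else if (l$op == "pool") {
      p <- cpp_maxpool(x, d[1], d[2], d[3])
      if (cache) caches[[li]] <- list(idx = p$idx, nvox_in = nrow(x))
      x <- p$y
      if (li == 6) bott <- x
    } else {
      x <- cpp_upsample(x, d[1], d[2], d[3])
    }
  }
  list(recon = x, bottleneck = bott, caches = caches)
}

# Backward pass for the BCE + sigmoid head; returns per-layer gradients.
ae_backward <- function(model, fwd, target) {
  nvox <- length(target)
  grads <- vector("list", length(model$plan))
  # d(loss)/d(pre-activation) of the sigmoid output layer
  dz <- (fwd$recon - matrix(target, ncol = 1)) / nvox
  for (li in rev(seq_along(model$plan))) {
    l <- model$plan[[li]]
    if (l$op == "conv") {
      ch <- fwd$caches[[li]]
      if (l$act == "relu") dz <- dz * (ch$pre > 0)
      # for the sigmoid layer dz already includes the activation derivative
      w <- model$weights[[li]]
      grads[[li]] <- list(W = crossprod(ch$col, dz), b = colSums(dz))
      if (li > 1)
        dz <- cpp_col2im(dz %*% t(w$W), l$dims[1], l$dims[2], l$dims[3],
                         model$cfg$kernel_size, l$cin)
    } else if (l$op == "pool") {
      ch <- fwd$caches[[li]]
      dz <- cpp_maxpool_bw(dz, ch$idx, ch$nvox_in)
    } else {
      dz <- cpp_upsample_bw(dz, l$dims[1], l$dims[2], l$dims[3])
    }
  }
  grads
}

bce_loss <- function(p, t, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Train the autoencoder on a set of volumes
#'
#' Unsupervised reconstruction training: mini-batch gradient descent under
#' Adadelta (decay `rho`, stabiliser `epsilon`, learning-rate multiplier
#' `learning_rate`) on the mean binary cross-entropy between each volume
#' and its reconstruction. Volumes must be normalized to [0, 1] (see
#' [normalize_intensity()]). Deterministic for a fixed config seed.
#'
#' @param model a [build_autoencoder()] model.
#' @param volumes list of 3D arrays matching the config's `input_shape`.
#' @param cfg optional override of the model's config (epochs etc.).
#' @return list with `model` (trained) and `loss_history` (per-epoch mean
#'   training loss; length `epochs`).
#' @export
train_autoencoder <- function(model, volumes, cfg = model$cfg) {
  stopifnot(inherits(model, "conv_autoencoder"))
  if (length(volumes) == 0) stop_invalid("need at least one training volume")
  xs <- lapply(volumes, function(v) {
    if (!identical(as.integer(dim(v)), cfg$input_shape))
      stop_invalid("volume shape (%s) does not match input_shape (%s)",
                   paste(dim(v), collapse = "x"),
                   paste(cfg$input_shape, collapse = "x"))
    if (any(v < 0 | v > 1)) stop_invalid("volumes must be scaled to [0, 1]")
    matrix(as.vector(v), ncol = 1)
  })
  if (cfg$epochs == 0)
    return(list(model = model, loss_history = numeric(0)))

  opt <- lapply(model$weights, function(w) {
    if (is.null(w)) return(NULL)
    list(EgW = w$W * 0, ExW = w$W * 0, Egb = w$b * 0, Exb = w$b * 0)
  })
  n <- length(xs)
  history <- numeric(cfg$epochs)
  conv_idx <- which(vapply(model$plan, function(l) l$op == "conv", logical(1)))

  with_seed(derive_seed(cfg$seed, 29L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_losses <- numeric(0)
      for (bt in batches) {
        acc <- NULL
        bloss <- 0
        for (i in bt) {
          fwd <- ae_forward(model, xs[[i]], cache = TRUE)
          bloss <- bloss + bce_loss(fwd$recon, xs[[i]])
          g <- ae_backward(model, fwd, xs[[i]])
          if (is.null(acc)) acc <- g
          else for (li in conv_idx) {
            acc[[li]]$W <- acc[[li]]$W + g[[li]]$W
            acc[[li]]$b <- acc[[li]]$b + g[[li]]$b
          }
        }
        nb <- length(bt)
        ep_losses <- c(ep_losses, bloss / nb)
        for (li in conv_idx) {
          gW <- acc[[li]]$W / nb
          gb <- acc[[li]]$b / nb
          st <- opt[[li]]
          st$EgW <- cfg$rho * st$EgW + (1 - cfg$rho) * gW^2
          dW <- -cfg$learning_rate *
            sqrt(st$ExW + cfg$epsilon) / sqrt(st$EgW + cfg$epsilon) * gW
          st$ExW <- cfg$rho * st$ExW + (1 - cfg$rho) * dW^2
          st$Egb <- cfg$rho * st$Egb + (1 - cfg$rho) * gb^2
          db <- -cfg$learning_rate *
            sqrt(st$Exb + cfg$epsilon) / sqrt(st$Egb + cfg$epsilon) * gb
          st$Exb <- cfg$rho * st$Exb + (1 - cfg$rho) * db^2
          opt[[li]] <- st
          model$weights[[li]]$W <- model$weights[[li]]$W + dW
          model$weights[[li]]$b <- model$weights[[li]]$b + db
        }
      }
      history[ep] <- mean(ep_losses)
    }
  })
  model$trained <- TRUE
  list(model = model, loss_history = history)
}

#' Encode volumes and flatten the bottleneck into a feature matrix
#'
#' Row j is the flattened encoder output of volume j. Flattening is
#' column-major over (voxels within channel, then channel), with the voxel
#' linear index running x-fastest — i.e. feature `(v, c)` sits at column
#' `(c - 1) * nvox + v`.
#'
#' @param model a `conv_autoencoder`.
#' @param volumes list of 3D arrays matching the input shape.
#' @return numeric matrix, subjects x features; row names from the list
#'   names when present.
#' @export
encode_and_flatten <- function(model, volumes) {
  stopifnot(inherits(model, "conv_autoencoder"))
  flat <- ae_flat_length(model)
  out <- matrix(NA_real_, length(volumes), flat)
  for (j in seq_along(volumes)) {
    v <- volumes[[j]]
    if (!identical(as.integer(dim(v)), model$cfg$input_shape))
      stop_invalid("volume %d shape does not match the model input shape", j)
    fwd <- ae_forward(model, matrix(as.vector(v), ncol = 1), cache = FALSE)
    out[j, ] <- as.vector(fwd$bottleneck)
  }
  rownames(out) <- names(volumes)
  out
}

#' @param object a `conv_autoencoder`.
#' @param newdata a 3D array (or list of arrays) to reconstruct.
#' @param ... unused.
#' @return reconstruction array(s) with values in [0, 1].
#' @rdname build_autoencoder
#' @export
predict.conv_autoencoder <- function(object, newdata, ...) {
  one <- !is.list(newdata)
  vols <- if (one) list(newdata) else newdata
  rec <- lapply(vols, function(v) {
    fwd <- ae_forward(object, matrix(as.vector(v), ncol = 1), cache = FALSE)
    array(fwd$recon, dim = object$cfg$input_shape)
  })
  if (one) rec[[1]] else rec
}

# -- pruning and intensity normalization ------------------------------------

prune_margins <- list(lo = c(1L, 2L, 1L), hi = c(2L, 3L, 2L),
                      from = c(91L, 109L, 91L), to = c(88L, 104L, 88L))

#' Prune a template-grid volume to the autoencoder grid
#'
#' Center-crops a (91, 109, 91) volume to (88, 104, 88) — each dimension
#' must become divisible by 8 — removing (1, 2, 1) voxels from the low
#' sides and (2, 3, 2) from the high sides. The retained block is
#' bit-identical to the corresponding sub-block of the input.
#'
#' @param vol 3D array of shape (91, 109, 91).
#' @return 3D array of shape (88, 104, 88).
#' @export
prune_volume <- function(vol) {
  d <- dim(vol)
  if (length(d) != 3 || !identical(as.integer(d), prune_margins$from))
    stop_invalid("prune_volume expects shape (91, 109, 91), got (%s)",
                 paste(d, collapse = ", "))
  lo <- prune_margins$lo
  to <- prune_margins$to
  vol[lo[1] + seq_len(to[1]), lo[2] + seq_len(to[2]), lo[3] + seq_len(to[3])]
}

#' @param pruned 3D array of shape (88, 104, 88).
#' @param fill value for the discarded margins.
#' @rdname prune_volume
#' @export
pad_pruned <- function(pruned, fill = 0) {
  d <- dim(pruned)
  if (!identical(as.integer(d), prune_margins$to))
    stop_invalid("pad_pruned expects shape (88, 104, 88)")
  out <- array(fill, dim = prune_margins$from)
  lo <- prune_margins$lo
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    pruned
  out
}

#' Min-max intensity normalization to [0, 1]
#'
#' Per-volume linear rescaling; a constant volume maps to all zeros so the
#' binary cross-entropy loss stays defined.
#'
#' @param vol numeric array with finite values.
#' @return array of the same shape with values in [0, 1].
#' @export
normalize_intensity <- function(vol) {
  if (any(!is.finite(vol))) stop_invalid("volume contains non-finite values")
  lo <- min(vol); hi <- max(vol)
  if (hi == lo) return(vol * 0)
  (vol - lo) / (hi - lo)
}
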