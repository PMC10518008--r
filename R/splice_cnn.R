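# ---- splice-site CNN -------------------------------------------------------
# A small convolutional classifier over 21-bp one-hot windows: three blocks of
# (3x3 convolution, 50 channels) + ReLU + batch normalization, then a dense
# softmax head over the 21 boundary offsets.  Implemented directly on BLAS
# matrix products (im2col); trained with Adam on the categorical
# cross-entropy.

.win_h <- 21L  # window length (rows of the one-hot grid)
.win_w <- 4L   # one-hot width (columns)

#' One-hot encode a 21-base window
#'
#' `A`, `C`, `G`, `T` map to the four unit vectors and `N` (padding) to the
#' zero vector.
#'
#' @param seq A 21-character string over A/C/G/T/N.
#' @return A 21 x 4 numeric matrix.
#' @export
encode_window <- function(seq) {
  if (nchar(seq) != .win_h) abort("window must be exactly 21 bases")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) abort("window contains characters outside A/C/G/T/N")
  m <- matrix(0, .win_h, .win_w)
  hit <- which(code <= 4L)
  m[cbind(hit, code[hit])] <- 1
  m
}

# stack windows (character vector) into the (B*84) x 1 input matrix used by
# the conv layers; rows ordered batch-major, cell (column-major grid) fast
encode_batch <- function(seqs) {
  B <- length(seqs)
  out <- matrix(0, B * .win_h * .win_w, 1L)
  for (b in seq_len(B)) {
    out[(b - 1L) * .win_h * .win_w + seq_len(.win_h * .win_w), 1L] <-
      as.vector(encode_window(seqs[b]))
  }
  out
}

# neighbour table of the 21x4 grid for 3x3 'same' convolution: 84 cells x 9
# offsets, 0 marking padding; offsets ordered so that offset o and 10-o are
# opposite (used by the backward pass)
conv_neighbours <- function() {
  cells <- .win_h * .win_w
  nb <- matrix(0L, cells, 9L)
  o <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    o <- o + 1L
    for (col in seq_len(.win_w)) for (row in seq_len(.win_h)) {
      cell <- (col - 1L) * .win_h + row
      r2 <- row + dr; c2 <- col + dc
      if (r2 >= 1L && r2 <= .win_h && c2 >= 1L && c2 <= .win_w) {
        nb[cell, o] <- (c2 - 1L) * .win_h + r2
      }
    }
  }
  nb
}
.nb <- conv_neighbours()

# gather indices for a batch: rows index (b-1)*84 + cell; zero neighbours are
# redirected to the appended all-zero row (B*84 + 1)
batch_gather_idx <- function(B) {
  cells <- .win_h * .win_w
  base <- rep((seq_len(B) - 1L) * cells, each = cells)
  zero_row <- B * cells + 1L
  idx <- matrix(0L, B * cells, 9L)
  for (o in 1:9) {
    nbr <- rep(.nb[, o], times = B)
    idx[, o] <- ifelse(nbr == 0L, zero_row, base + nbr)
  }
  idx
}

# fast column-wise ops (sweep() is aperm-heavy on these shapes)
addcol <- function(x, v) x + rep(v, each = nrow(x))
subcol <- function(x, v) x - rep(v, each = nrow(x))
mulcol <- function(x, v) x * rep(v, each = nrow(x))

pad_zero_row <- function(M) {
  out <- matrix(0, nrow(M) + 1L, ncol(M))
  out[seq_len(nrow(M)), ] <- M
  out
}

conv_forward <- function(M, W, b, idx) {
  cin <- ncol(M)
  Mpad <- pad_zero_row(M)
  xcol <- matrix(0, nrow(M), 9L * cin)
  for (o in 1:9) {
    xcol[, ((o - 1L) * cin + 1L):(o * cin)] <- Mpad[idx[, o], , drop = FALSE]
  }
  y <- addcol(xcol %*% W, b)
  list(y = y, xcol = xcol)
}

conv_backward <- function(dy, xcol, W, idx) {
  cin <- ncol(xcol) / 9L
  dW <- crossprod(xcol, dy)
  db <- colSums(dy)
  dxcol <- dy %*% t(W)
  dxpad <- pad_zero_row(dxcol)
  dM <- matrix(0, nrow(dy), cin)
  for (o in 1:9) {
    oinv <- 10L - o
    cols <- ((o - 1L) * cin + 1L):(o * cin)
    dM <- dM + dxpad[idx[, oinv], cols, drop = FALSE]
  }
  list(dM = dM, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, rm, rv, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- subcol(x, mu)
    v <- colMeans(xc * xc)
    rm <- momentum * rm + (1 - momentum) * mu
    rv <- momentum * rv + (1 - momentum) * v
  } else {
    mu <- rm; v <- rv
    xc <- subcol(x, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- mulcol(xc, inv)
  y <- addcol(mulcol(xhat, gamma), beta)
  list(y = y, xhat = xhat, inv = inv, rm = rm, rv = rv)
}

bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  xhat <- cache$xhat; inv <- cache$inv
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- mulcol(dy, gamma)
  t1 <- subcol(dxhat, colMeans(dxhat))
  t2 <- mulcol(xhat, colMeans(dxhat * xhat))
  dx <- mulcol(t1 - t2, inv)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# flatten (B*84) x C feature matrix to B x (84*C), channel-major blocks
flatten_features <- function(M, B) {
  cells <- .win_h * .win_w
  C <- ncol(M)
  out <- matrix(0, B, cells * C)
  for (c in seq_len(C)) {
    out[, ((c - 1L) * cells + 1L):(c * cells)] <- t(matrix(M[, c], cells, B))
  }
  out
}

unflatten_features <- function(F, B, C) {
  cells <- .win_h * .win_w
  out <- matrix(0, B * cells, C)
  for (c in seq_len(C)) {
    out[, c] <- as.vector(t(F[, ((c - 1L) * cells + 1L):(c * cells)]))
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

new_splice_model <- function(channels = 50L, n_classes = 21L) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  cells <- .win_h * .win_w
  list(
    conv = list(list(W = he(9L, channels), b = numeric(channels)),
                list(W = he(9L * channels, channels), b = numeric(channels)),
                list(W = he(9L * channels, channels), b = numeric(channels))),
    bn = lapply(1:3, function(i)
      list(gamma = rep(1, channels), beta = numeric(channels),
           rm = numeric(channels), rv = rep(1, channels))),
    dense = list(W = he(cells * channels, n_classes), b = numeric(n_classes)),
    channels = channels, n_classes = n_classes
  )
}

model_forward <- function(model, seqs, training = FALSE) {
  B <- length(seqs)
  idx <- batch_gather_idx(B)
  M <- encode_batch(seqs)
  cache <- list(idx = idx, B = B)
  for (l in 1:3) {
    cv <- conv_forward(M, model$conv[[l]]$W, model$conv[[l]]$b, idx)
    relu_mask <- cv$y > 0
    a <- cv$y * relu_mask
    bn <- bn_forward(a, model$bn[[l]]$gamma, model$bn[[l]]$beta,
                     model$bn[[l]]$rm, model$bn[[l]]$rv, training)
    cache[[paste0("l", l)]] <- list(xcol = cv$xcol, relu_mask = relu_mask,
                                    bn = bn)
    if (training) {
      model$bn[[l]]$rm <- bn$rm
      model$bn[[l]]$rv <- bn$rv
    }
    M <- bn$y
  }
  F <- flatten_features(M, B)
  logits <- addcol(F %*% model$dense$W, model$dense$b)
  probs <- softmax_rows(logits)
  list(probs = probs, F = F, cache = cache, model = model)
}

model_backward <- function(model, fwd, labels) {
  B <- nrow(fwd$probs)
  d <- fwd$probs
  d[cbind(seq_len(B), labels)] <- d[cbind(seq_len(B), labels)] - 1
  d <- d / B
  grads <- list(dense = list(W = crossprod(fwd$F, d), b = colSums(d)))
  dF <- d %*% t(model$dense$W)
  dM <- unflatten_features(dF, B, model$channels)
  for (l in 3:1) {
    cc <- fwd$cache[[paste0("l", l)]]
    bb <- bn_backward(dM, cc$bn, model$bn[[l]]$gamma)
    da <- bb$dx * cc$relu_mask
    cb <- conv_backward(da, cc$xcol, model$conv[[l]]$W, fwd$cache$idx)
    grads[[paste0("conv", l)]] <- list(W = cb$dW, b = cb$db)
    grads[[paste0("bn", l)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dM <- cb$dM
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(t = 0L,
       m = list(dense = zero_like(model$dense),
                conv1 = zero_like(model$conv[[1]]),
                conv2 = zero_like(model$conv[[2]]),
                conv3 = zero_like(model$conv[[3]]),
                bn1 = list(gamma = numeric(model$channels),
                           beta = numeric(model$channels)),
                bn2 = list(gamma = numeric(model$channels),
                           beta = numeric(model$channels)),
                bn3 = list(gamma = numeric(model$channels),
                           beta = numeric(model$channels))),
       v = NULL)
}

adam_step <- function(model, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$v)) state$v <- state$m
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  apply_part <- function(part, gpart, key) {
    for (nm in names(gpart)) {
      u <- upd(part[[nm]], gpart[[nm]], state$m[[key]][[nm]],
               state$v[[key]][[nm]])
      part[[nm]] <- u$p
      state$m[[key]][[nm]] <<- u$m
      state$v[[key]][[nm]] <<- u$v
    }
    part
  }
  model$dense <- apply_part(model$dense, grads$dense, "dense")
  for (l in 1:3) {
    model$conv[[l]] <- apply_part(model$conv[[l]],
                                  grads[[paste0("conv", l)]],
                                  paste0("conv", l))
    bn_g <- grads[[paste0("bn", l)]]
    part <- model$bn[[l]][c("gamma", "beta")]
    part <- apply_part(part, bn_g, paste0("bn", l))
    model$bn[[l]]$gamma <- part$gamma
    model$bn[[l]]$beta <- part$beta
  }
  list(model = model, state = state)
}

#' Train the splice-site boundary classifier
#'
#' Trains the three-block convolutional network (3x3 kernels, 50 channels,
#' ReLU + batch normalization per block, dense softmax head over the 21
#' boundary offsets) with Adam at learning rate 0.01 on the categorical
#' cross-entropy. Desk-scale defaults train for a reduced epoch budget; the
#' full-scale settings (1000 epochs, 10 repeats) remain available through the
#' arguments.
#'
#' @param train Tibble with `seq` (21-base windows) and `label` (boundary
#'   offset, 1-20).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param repeats Independent training repeats; the model with the lowest
#'   final training loss is kept.
#' @param channels Convolution channels per block.
#' @param seed Integer seed (weights, shuffling).
#' @param validation Optional tibble like `train`; accuracy is recorded per
#'   epoch when supplied.
#' @param verbose Print per-epoch progress.
#' @return A `splice_model` object.
#' @export
train_model <- function(train, epochs = 50L, batch_size = 64L, lr = 0.01,
                        repeats = 1L, channels = 50L, seed = 1L,
                        validation = NULL, verbose = FALSE) {
  if (nrow(train) == 0L) abort("empty training set")
  with_seed(seed, {
    best <- NULL
    for (rep_i in seq_len(repeats)) {
      model <- new_splice_model(channels)
      state <- adam_init(model)
      n <- nrow(train)
      loss <- NA_real_
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0; nb <- 0L
        for (start in seq(1L, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1L, n)]
          fwd <- model_forward(model, train$seq[idx], training = TRUE)
          model <- fwd$model
          p <- fwd$probs[cbind(seq_along(idx), train$label[idx])]
          ep_loss <- ep_loss - mean(log(pmax(p, 1e-12)))
          nb <- nb + 1L
          grads <- model_backward(model, fwd, train$label[idx])
          st <- adam_step(model, grads, state, lr = lr)
          model <- st$model; state <- st$state
        }
        loss <- ep_loss / nb
        if (verbose) {
          msg <- sprintf("repeat %d epoch %d loss %.4f", rep_i, ep, loss)
          if (!is.null(validation)) {
            msg <- paste0(msg, sprintf(" val_acc %.3f",
                                       model_accuracy(model, validation)))
          }
          message(msg)
        }
      }
      if (is.null(best) || loss < best$loss) {
        best <- list(model = model, loss = loss)
      }
    }
    structure(c(best$model, list(final_loss = best$loss)),
              class = "splice_model")
  })
}

#' @export
print.splice_model <- function(x, ...) {
  cat("<splice_model> 3 conv blocks, ", x$channels, " channels, ",
      x$n_classes, "-way boundary head\n", sep = "")
  invisible(x)
}

#' Predict boundary-offset probabilities for 21-bp windows
#'
#' @param object A `splice_model`.
#' @param newdata Character vector of 21-base windows (or a tibble with a
#'   `seq` column).
#' @param ... Unused.
#' @return Matrix (windows x 21) of class probabilities; rows sum to 1.
#' @export
predict.splice_model <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$seq else newdata
  raw_predict(object, seqs)
}

raw_predict <- function(model, seqs) {
  out <- matrix(NA_real_, length(seqs), model$n_classes)
  # bounded batches keep memory flat on large inputs
  for (start in seq(1L, length(seqs), by = 512L)) {
    idx <- start:min(start + 511L, length(seqs))
    out[idx, ] <- model_forward(model, seqs[idx], training = FALSE)$probs
  }
  out
}

#' Classification accuracy of a splice model on labeled windows
#'
#' @param model A `splice_model`.
#' @param data Tibble with `seq` and `label`.
#' @return Fraction of windows whose argmax probability hits the label.
#' @export
model_accuracy <- function(model, data) {
  probs <- raw_predict(model, data$seq)
  mean(max.col(probs, ties.method = "first") == data$label)
}
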