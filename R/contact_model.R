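# Indirect estimation of ground contact and vertical GRF from the six
# inertial channels (3 accelerations, 3 angular rates) with a recurrent
# sequence model.
#
# The network is implemented natively: GRU / LSTM layers with
# backpropagation through time, a dense head (sigmoid for per-foot
# contact probability, ReLU for non-negative GRF), masked losses that
# ignore the first half of each sequence (the network must "see" some
# data before predicting), and Adam. All tensor work is batched matrix
# algebra over (features x batch) slices per time step, so it runs at
# BLAS speed on CPU.

#' Cut a trial into overlapping training sequences
#'
#' Windows of `seq_len` samples with 50% overlap (hop = floor(seq_len/2)).
#' The first half of each window is warm-up: it is masked out of the loss
#' and never used as output. A trailing window aligned to the end of the
#' trial is added when the hop grid does not reach it, and the stitching
#' map guarantees that every sample after the initial warm-up is produced
#' by exactly one window's second half.
#'
#' @param features numeric matrix, samples x channels (the 6 inertial
#'   channels, on the 400 Hz grid).
#' @param targets optional numeric matrix, samples x outputs, same rows.
#' @param seq_len window length in samples (1201 at 400 Hz).
#' @param scaling optional per-channel scale factors (from a trained
#'   model); when `NULL`, computed as the per-channel max absolute value
#'   so inputs land roughly in [-1, 1].
#' @return list of class `sequence_batch`: `x` array (channels, seq_len,
#'   n_windows), `y` (outputs, seq_len, n_windows) or `NULL`, `starts`
#'   (1-based window starts), `mask` (logical, length seq_len; FALSE over
#'   the warm-up half), `warmup`, `seq_len`, `n_samples`, `scaling`.
#' @export
make_sequences <- function(features, targets = NULL, seq_len = 1201,
                           scaling = NULL) {
  features <- as.matrix(features)
  n <- nrow(features); nf <- ncol(features)
  if (n < seq_len)
    stop(sprintf("trial has %d samples; need at least seq_len = %d",
                 n, seq_len), call. = FALSE)
  warmup <- floor(seq_len / 2)
  hop <- warmup
  if (is.null(scaling)) {
    scaling <- apply(abs(features), 2, max)
    scaling[scaling == 0] <- 1
  }
  xs <- sweep(features, 2, scaling, "/")
  starts <- seq(1, n - seq_len + 1, by = hop)
  if (max(starts) + seq_len - 1 < n) starts <- c(starts, n - seq_len + 1)
  nw <- length(starts)
  x <- array(0, dim = c(nf, seq_len, nw))
  for (j in seq_len(nw))
    x[, , j] <- t(xs[starts[j]:(starts[j] + seq_len - 1), , drop = FALSE])
  y <- NULL
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    if (nrow(targets) != n)
      stop("features and targets must be on the same grid", call. = FALSE)
    y <- array(0, dim = c(ncol(targets), seq_len, nw))
    for (j in seq_len(nw))
      y[, , j] <- t(targets[starts[j]:(starts[j] + seq_len - 1), ,
                            drop = FALSE])
  }
  mask <- c(rep(FALSE, warmup), rep(TRUE, seq_len - warmup))
  structure(list(x = x, y = y, starts = starts, mask = mask,
                 warmup = warmup, seq_len = seq_len, n_samples = n,
                 scaling = scaling),
            class = "sequence_batch")
}

#' Reassemble per-window predictions into a full series
#'
#' Inverse of the windowing: each window contributes its second half, in
#' order, each sample exactly once. The first `warmup` samples of the
#' trial cannot be predicted and are `NA`.
#'
#' @param pred array (outputs, seq_len, n_windows) of per-window outputs.
#' @param starts,seq_len,n_samples from the [make_sequences()] batch.
#' @return matrix n_samples x outputs with `NA` over the initial warm-up.
#' @export
stitch_windows <- function(pred, starts, seq_len, n_samples) {
  warmup <- floor(seq_len / 2)
  k <- dim(pred)[1]
  out <- matrix(NA_real_, n_samples, k)
  nxt <- warmup + 1              # next uncovered trial sample
  nw <- length(starts)
  for (j in seq_len(nw)) {
    lo <- starts[j] + warmup     # first second-half sample of this window
    hi <- starts[j] + seq_len - 1
    if (j < nw) hi <- min(hi, starts[j + 1] + warmup - 1)
    lo <- max(lo, nxt)
    if (lo > hi) next
    win_idx <- (lo - starts[j] + 1):(hi - starts[j] + 1)
    out[lo:hi, ] <- t(matrix(pred[, win_idx, j], nrow = k))
    nxt <- hi + 1
  }
  out
}

#' Recurrent model specification
#'
#' Architecture and optimizer settings for [train_rnn()]. The default is
#' a compact two-layer GRU with dropout between the recurrent layers and
#' a two-output dense head; layer types may mix `"gru"` and `"lstm"`.
#'
#' @param units integer vector, one entry per recurrent layer.
#' @param type layer types, `"gru"` or `"lstm"` (recycled).
#' @param dropout dropout rate between recurrent layers (variational:
#'   one mask per unit and sequence, constant over time).
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size sequences per minibatch.
#' @param patience early-stopping patience on validation loss, epochs.
#' @param clip global gradient-norm clip.
#' @param val_fraction fraction of windows held out for early stopping.
#' @param seed seed for initialization, shuffling and dropout.
#' @return list of class `gait_model_spec`.
#' @export
model_spec <- function(units = c(64, 64), type = "gru", dropout = 0.2,
                       lr = 3e-3, epochs = 40, batch_size = 32,
                       patience = 6, clip = 5, val_fraction = 0.1,
                       seed = 1) {
  type <- rep(match.arg(type, c("gru", "lstm"), several.ok = TRUE),
              length.out = length(units))
  if (length(units) < 1) stop("need at least one recurrent layer",
                              call. = FALSE)
  structure(list(units = as.integer(units), type = type, dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), clip = clip,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "gait_model_spec")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_layer <- function(type, n_in, h) {
  if (type == "gru") {
    list(type = "gru",
         Wz = glorot(h, n_in), Uz = glorot(h, h), bz = numeric(h),
         Wr = glorot(h, n_in), Ur = glorot(h, h), br = numeric(h),
         Wc = glorot(h, n_in), Uc = glorot(h, h), bc = numeric(h))
  } else {
    list(type = "lstm",
         Wi = glorot(h, n_in), Ui = glorot(h, h), bi = numeric(h),
         Wf = glorot(h, n_in), Uf = glorot(h, h), bf = rep(1, h),
         Wo = glorot(h, n_in), Uo = glorot(h, h), bo = numeric(h),
         Wg = glorot(h, n_in), Ug = glorot(h, h), bg = numeric(h))
  }
}

init_params <- function(spec, n_in, n_out) {
  layers <- list()
  prev <- n_in
  for (l in seq_along(spec$units)) {
    layers[[l]] <- init_layer(spec$type[l], prev, spec$units[l])
    prev <- spec$units[l]
  }
  list(layers = layers, V = glorot(n_out, prev), d = numeric(n_out))
}

sigm <- function(x) 1 / (1 + exp(-x))

# forward pass of one recurrent layer over x: (n_in, T, B).
# returns H (h, T, B) and, if cache, the gate activations.
layer_forward <- function(p, x, cache = FALSE) {
  d <- dim(x); Tt <- d[2]; B <- d[3]
  h <- length(p$bz %||% p$bi)
  H <- array(0, dim = c(h, Tt, B))
  hprev <- matrix(0, h, B)
  if (p$type == "gru") {
    Z <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    R <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    C <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    for (t in seq_len(Tt)) {
      xt <- matrix(x[, t, ], ncol = B)
      z <- sigm(p$Wz %*% xt + p$Uz %*% hprev + p$bz)
      r <- sigm(p$Wr %*% xt + p$Ur %*% hprev + p$br)
      cc <- tanh(p$Wc %*% xt + p$Uc %*% (r * hprev) + p$bc)
      hprev <- z * hprev + (1 - z) * cc
      H[, t, ] <- hprev
      if (cache) { Z[, t, ] <- z; R[, t, ] <- r; C[, t, ] <- cc }
    }
    list(H = H, Z = Z, R = R, C = C)
  } else {
    I <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    Fg <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    O <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    G <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    Cs <- if (cache) array(0, dim = c(h, Tt, B)) else NULL
    cprev <- matrix(0, h, B)
    for (t in seq_len(Tt)) {
      xt <- matrix(x[, t, ], ncol = B)
      i <- sigm(p$Wi %*% xt + p$Ui %*% hprev + p$bi)
      f <- sigm(p$Wf %*% xt + p$Uf %*% hprev + p$bf)
      o <- sigm(p$Wo %*% xt + p$Uo %*% hprev + p$bo)
      g <- tanh(p$Wg %*% xt + p$Ug %*% hprev + p$bg)
      cprev <- f * cprev + i * g
      hprev <- o * tanh(cprev)
      H[, t, ] <- hprev
      if (cache) {
        I[, t, ] <- i; Fg[, t, ] <- f; O[, t, ] <- o; G[, t, ] <- g
        Cs[, t, ] <- cprev
      }
    }
    list(H = H, I = I, Fg = Fg, O = O, G = G, Cs = Cs)
  }
}

# backward pass of one layer. dH: gradient wrt layer output (h, T, B).
# Returns parameter gradients and dX (n_in, T, B).
layer_backward <- function(p, x, fw, dH) {
  d <- dim(x); Tt <- d[2]; B <- d[3]
  h <- dim(fw$H)[1]
  grads <- lapply(p[names(p) != "type"], function(m) m * 0)
  dX <- array(0, dim = d)
  dh_next <- matrix(0, h, B)
  if (p$type == "gru") {
    for (t in rev(seq_len(Tt))) {
      dh <- matrix(dH[, t, ], ncol = B) + dh_next
      hprev <- if (t > 1) matrix(fw$H[, t - 1, ], ncol = B) else
        matrix(0, h, B)
      z <- matrix(fw$Z[, t, ], ncol = B)
      r <- matrix(fw$R[, t, ], ncol = B)
      cc <- matrix(fw$C[, t, ], ncol = B)
      xt <- matrix(x[, t, ], ncol = B)
      dz <- dh * (hprev - cc)
      daz <- dz * z * (1 - z)
      dc <- dh * (1 - z)
      dac <- dc * (1 - cc^2)
      uc_dac <- crossprod(p$Uc, dac)
      dr <- uc_dac * hprev
      dar <- dr * r * (1 - r)
      grads$Wz <- grads$Wz + tcrossprod(daz, xt)
      grads$Uz <- grads$Uz + tcrossprod(daz, hprev)
      grads$bz <- grads$bz + rowSums(daz)
      grads$Wr <- grads$Wr + tcrossprod(dar, xt)
      grads$Ur <- grads$Ur + tcrossprod(dar, hprev)
      grads$br <- grads$br + rowSums(dar)
      grads$Wc <- grads$Wc + tcrossprod(dac, xt)
      grads$Uc <- grads$Uc + tcrossprod(dac, r * hprev)
      grads$bc <- grads$bc + rowSums(dac)
      dX[, t, ] <- crossprod(p$Wz, daz) + crossprod(p$Wr, dar) +
        crossprod(p$Wc, dac)
      dh_next <- dh * z + crossprod(p$Uz, daz) + crossprod(p$Ur, dar) +
        uc_dac * r
    }
  } else {
    dc_next <- matrix(0, h, B)
    for (t in rev(seq_len(Tt))) {
      dh <- matrix(dH[, t, ], ncol = B) + dh_next
      hprev <- if (t > 1) matrix(fw$H[, t - 1, ], ncol = B) else
        matrix(0, h, B)
      cprev <- if (t > 1) matrix(fw$Cs[, t - 1, ], ncol = B) else
        matrix(0, h, B)
      i <- matrix(fw$I[, t, ], ncol = B)
      f <- matrix(fw$Fg[, t, ], ncol = B)
      o <- matrix(fw$O[, t, ], ncol = B)
      g <- matrix(fw$G[, t, ], ncol = B)
      cs <- matrix(fw$Cs[, t, ], ncol = B)
      xt <- matrix(x[, t, ], ncol = B)
      tc <- tanh(cs)
      do_ <- dh * tc
      dao <- do_ * o * (1 - o)
      dcs <- dh * o * (1 - tc^2) + dc_next
      di <- dcs * g;  dai <- di * i * (1 - i)
      df <- dcs * cprev; daf <- df * f * (1 - f)
      dg <- dcs * i;  dag <- dg * (1 - g^2)
      grads$Wi <- grads$Wi + tcrossprod(dai, xt)
      grads$Ui <- grads$Ui + tcrossprod(dai, hprev)
      grads$bi <- grads$bi + rowSums(dai)
      grads$Wf <- grads$Wf + tcrossprod(daf, xt)
      grads$Uf <- grads$Uf + tcrossprod(daf, hprev)
      grads$bf <- grads$bf + rowSums(daf)
      grads$Wo <- grads$Wo + tcrossprod(dao, xt)
      grads$Uo <- grads$Uo + tcrossprod(dao, hprev)
      grads$bo <- grads$bo + rowSums(dao)
      grads$Wg <- grads$Wg + tcrossprod(dag, xt)
      grads$Ug <- grads$Ug + tcrossprod(dag, hprev)
      grads$bg <- grads$bg + rowSums(dag)
      dX[, t, ] <- crossprod(p$Wi, dai) + crossprod(p$Wf, daf) +
        crossprod(p$Wo, dao) + crossprod(p$Wg, dag)
      dh_next <- crossprod(p$Ui, dai) + crossprod(p$Uf, daf) +
        crossprod(p$Uo, dao) + crossprod(p$Ug, dag)
      dc_next <- dcs * f
    }
  }
  grads$type <- NULL
  list(grads = grads, dX = dX)
}

# forward through all layers; drop_masks: list of (h x B) masks or NULL
net_forward <- function(params, x, drop_masks = NULL, cache = FALSE) {
  inputs <- list(x)
  fws <- list()
  cur <- x
  for (l in seq_along(params$layers)) {
    fw <- layer_forward(params$layers[[l]], cur, cache = cache)
    H <- fw$H
    if (!is.null(drop_masks) && l < length(params$layers)) {
      m <- drop_masks[[l]]                  # (h, B), constant over time
      H <- fw$H * aperm(array(m, dim = c(dim(m)[1], dim(m)[2],
                                         dim(fw$H)[2])), c(1, 3, 2))
    }
    fws[[l]] <- fw
    inputs[[l + 1]] <- H
    cur <- H
  }
  d <- dim(cur)
  H2 <- matrix(cur, nrow = d[1])            # (h, T*B)
  logits <- params$V %*% H2 + params$d
  list(logits = array(logits, dim = c(nrow(params$V), d[2], d[3])),
       inputs = inputs, fws = fws, top = cur)
}

# masked loss + gradient wrt logits.
# head "contact": binary cross-entropy on sigmoid(logits);
# head "grf": squared error on relu(logits).
masked_loss <- function(logits, y, mask, head) {
  d <- dim(logits)
  mw <- array(rep(rep(mask, each = d[1]), d[3]), dim = d)
  n_eff <- sum(mw)
  if (head == "contact") {
    p <- sigm(logits)
    ll <- ifelse(logits > 0,
                 logits - logits * y + log1p(exp(-logits)),
                 -logits * y + log1p(exp(logits)))
    loss <- sum(ll * mw) / n_eff
    dlogit <- (p - y) * mw / n_eff
  } else {
    yhat <- pmax(logits, 0)
    loss <- sum((yhat - y)^2 * mw) / n_eff
    dlogit <- 2 * (yhat - y) * (logits > 0) * mw / n_eff
  }
  list(loss = loss, dlogit = dlogit)
}

# full forward+backward for a minibatch; returns loss and gradients
net_loss_grads <- function(params, x, y, mask, head, drop_masks = NULL) {
  fwd <- net_forward(params, x, drop_masks, cache = TRUE)
  ml <- masked_loss(fwd$logits, y, mask, head)
  d <- dim(fwd$top)
  dl2 <- matrix(ml$dlogit, nrow = dim(fwd$logits)[1])
  H2 <- matrix(fwd$top, nrow = d[1])
  gV <- tcrossprod(dl2, H2)
  gd <- rowSums(dl2)
  dH <- array(crossprod(params$V, dl2), dim = d)
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    if (!is.null(drop_masks) && l < length(params$layers)) {
      m <- drop_masks[[l]]
      dH <- dH * aperm(array(m, dim = c(dim(m)[1], dim(m)[2], d[2])),
                       c(1, 3, 2))
    }
    bk <- layer_backward(params$layers[[l]], fwd$inputs[[l]],
                         fwd$fws[[l]], dH)
    glayers[[l]] <- bk$grads
    dH <- bk$dX
    d <- dim(dH)
  }
  list(loss = ml$loss, grads = list(layers = glayers, V = gV, d = gd))
}

# ---- flat parameter walking (Adam, clipping, numeric checks) ----

flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$layers))
    for (nm in setdiff(names(p$layers[[l]]), "type"))
      out[[sprintf("L%d.%s", l, nm)]] <- p$layers[[l]][[nm]]
  out$V <- p$V; out$d <- p$d
  out
}

unflatten_params <- function(flat, skeleton) {
  for (l in seq_along(skeleton$layers))
    for (nm in setdiff(names(skeleton$layers[[l]]), "type"))
      skeleton$layers[[l]][[nm]] <- flat[[sprintf("L%d.%s", l, nm)]]
  skeleton$V <- flat$V; skeleton$d <- flat$d
  skeleton
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(flat, gflat, st, lr, clip = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(gflat, function(g) sum(g^2), numeric(1))))
    if (is.finite(gn) && gn > clip)
      gflat <- lapply(gflat, function(g) g * clip / gn)
  }
  st$t <- st$t + 1
  corr1 <- 1 - beta1^st$t; corr2 <- 1 - beta2^st$t
  for (nm in names(flat)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gflat[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gflat[[nm]]^2
    flat[[nm]] <- flat[[nm]] - lr * (st$m[[nm]] / corr1) /
      (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(flat = flat, state = st)
}

#' Train a recurrent contact / GRF model
#'
#' Trains on a [make_sequences()] batch with the masked loss (binary
#' cross-entropy for the contact head, squared error for the ReLU GRF
#' head), Adam, minibatch shuffling and early stopping on a held-out
#' validation subset of the windows. Deterministic under the spec seed.
#'
#' @param batch a [make_sequences()] batch with targets.
#' @param spec a [model_spec()].
#' @param head `"contact"` or `"grf"`.
#' @param verbose print per-epoch losses.
#' @return object of class `gait_rnn`: parameters, spec, head, the
#'   feature scaling of the batch, and the training history.
#' @export
train_rnn <- function(batch, spec = model_spec(), head = c("contact", "grf"),
                      verbose = FALSE) {
  head <- match.arg(head)
  if (is.null(batch$y)) stop("batch has no targets", call. = FALSE)
  set.seed(spec$seed)
  nf <- dim(batch$x)[1]; nw <- dim(batch$x)[3]
  n_out <- dim(batch$y)[1]
  params <- init_params(spec, nf, n_out)
  nval <- max(1L, round(spec$val_fraction * nw))
  if (nw - nval < 1) stop("too few windows to split off validation",
                          call. = FALSE)
  val_idx <- sort(sample.int(nw, nval))
  tr_idx <- setdiff(seq_len(nw), val_idx)
  flat <- flatten_params(params)
  st <- adam_init(flat)
  best <- list(loss = Inf, flat = flat)
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  wait <- 0
  xv <- batch$x[, , val_idx, drop = FALSE]
  yv <- batch$y[, , val_idx, drop = FALSE]
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(tr_idx)
    bs <- spec$batch_size
    tl <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, length(ord))]
      if (length(idx) < 2) next
      xb <- batch$x[, , idx, drop = FALSE]
      yb <- batch$y[, , idx, drop = FALSE]
      dm <- NULL
      if (spec$dropout > 0 && length(spec$units) > 1) {
        dm <- lapply(seq_len(length(spec$units) - 1), function(l) {
          keep <- matrix(stats::rbinom(spec$units[l] * length(idx), 1,
                                       1 - spec$dropout),
                         spec$units[l], length(idx))
          keep / (1 - spec$dropout)
        })
      }
      params <- unflatten_params(flat, params)
      lg <- net_loss_grads(params, xb, yb, batch$mask, head, dm)
      if (!is.finite(lg$loss))
        stop("non-finite training loss; inspect feature scaling / lr",
             call. = FALSE)
      gflat <- flatten_params(list(layers = lg$grads$layers,
                                   V = lg$grads$V, d = lg$grads$d))
      up <- adam_step(flat, gflat, st, spec$lr, spec$clip)
      flat <- up$flat; st <- up$state
      tl <- tl + lg$loss; nb <- nb + 1
    }
    params <- unflatten_params(flat, params)
    vfwd <- net_forward(params, xv)
    vl <- masked_loss(vfwd$logits, yv, batch$mask, head)$loss
    history <- rbind(history,
                     data.frame(epoch = ep, train = tl / max(nb, 1),
                                val = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      tl / max(nb, 1), vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, flat = flat)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= spec$patience) break
    }
  }
  params <- unflatten_params(best$flat, params)
  structure(list(params = params, spec = spec, head = head,
                 scaling = batch$scaling, seq_len = batch$seq_len,
                 n_features = nf, n_outputs = n_out, history = history,
                 best_val = best$loss),
            class = "gait_rnn")
}

#' Train the per-foot ground-contact model
#'
#' @param features samples x 6 matrix of inertial channels.
#' @param contact_targets samples x 2 binary matrix (left, right), e.g.
#'   from a binarized, resampled insole stream.
#' @param spec a [model_spec()].
#' @param ... passed to [train_rnn()].
#' @return a `gait_rnn` with a sigmoid contact head.
#' @export
train_contact_model <- function(features, contact_targets,
                                spec = model_spec(), ...) {
  batch <- make_sequences(features, contact_targets)
  train_rnn(batch, spec, head = "contact", ...)
}

#' Train the per-foot vertical-GRF model
#'
#' Identical trunk to the contact model; the output head is ReLU so the
#' predicted force is non-negative. Targets may be newtons or body
#' weights; record the unit choice alongside the model.
#'
#' @param features samples x 6 matrix of inertial channels.
#' @param grf_targets samples x 2 force matrix (left, right).
#' @param spec a [model_spec()].
#' @param ... passed to [train_rnn()].
#' @return a `gait_rnn` with a ReLU GRF head.
#' @export
train_grf_model <- function(features, grf_targets, spec = model_spec(),
                            ...) {
  batch <- make_sequences(features, grf_targets)
  train_rnn(batch, spec, head = "grf", ...)
}

#' Predict contact probability / GRF for a trial
#'
#' Windows the trial with the model's stored sequence length and feature
#' scaling, runs the network, and stitches the second halves back into a
#' per-sample series. The first half-window of the trial is warm-up and
#' returns `NA`.
#'
#' @param object a trained `gait_rnn`.
#' @param features samples x channels matrix matching the training
#'   features.
#' @param threshold contact binarization threshold on the probability.
#' @param batch_size windows evaluated per forward block.
#' @param ... unused.
#' @return for a contact head: list with `probability` (n x 2),
#'   `contact` (binary n x 2); for a GRF head: list with `grf` (n x 2).
#'   Both carry the warm-up as `NA` rows.
#' @export
predict.gait_rnn <- function(object, features, threshold = 0.5,
                             batch_size = 64, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$n_features)
    stop(sprintf("model expects %d feature channels, got %d",
                 object$n_features, ncol(features)), call. = FALSE)
  batch <- make_sequences(features, NULL, seq_len = object$seq_len,
                          scaling = object$scaling)
  nw <- dim(batch$x)[3]
  logits <- array(0, dim = c(object$n_outputs, batch$seq_len, nw))
  for (b0 in seq(1, nw, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, nw)
    xb <- batch$x[, , idx, drop = FALSE]
    logits[, , idx] <- net_forward(object$params, xb)$logits
  }
  series <- stitch_windows(logits, batch$starts, batch$seq_len,
                           batch$n_samples)
  if (object$head == "contact") {
    prob <- sigm(series)
    list(probability = prob,
         contact = ifelse(is.na(prob), NA, as.integer(prob > threshold)))
  } else {
    list(grf = pmax(series, 0))
  }
}

#' Ground contact times from a binary contact series
#'
#' Run-length encodes the 1-runs of one foot's contact signal; each run is
#' a stance whose duration is the ground contact time. Runs shorter than
#' `min_duration` (40 ms) are discarded as spurious.
#'
#' @param contact binary vector for one foot (`NA` allowed; treated as 0).
#' @param t time, seconds (same length), or `NULL` with `rate` given.
#' @param rate sample rate, Hz (used when `t` is `NULL`).
#' @param min_duration minimum stance duration, seconds.
#' @return data.frame `touchdown`, `toeoff`, `duration` (may be empty).
#' @export
gct_from_contact <- function(contact, t = NULL, rate = 400,
                             min_duration = 0.04) {
  contact[is.na(contact)] <- 0
  if (is.null(t)) t <- (seq_along(contact) - 1) / rate else
    rate <- 1 / stats::median(diff(t))
  contact_runs(contact, t, rate, min_duration)
}

#' Match predicted stances to reference stances
#'
#' Each reference stance is paired with the predicted stance overlapping
#' it most; unmatched reference stances are dropped (the match fraction
#' is reported so misses are visible).
#'
#' @param pred,ref stance tables from [gct_from_contact()].
#' @return data.frame `ref_touchdown`, `ref_gct`, `pred_gct`, with
#'   attribute `match_fraction`.
#' @export
match_stances <- function(pred, ref) {
  out <- data.frame(ref_touchdown = ref$touchdown, ref_gct = ref$duration,
                    pred_gct = NA_real_)
  for (i in seq_len(nrow(ref))) {
    if (nrow(pred) == 0) break
    ov <- pmin(pred$toeoff, ref$toeoff[i]) -
      pmax(pred$touchdown, ref$touchdown[i])
    j <- which.max(ov)
    if (length(j) == 1 && ov[j] > 0) out$pred_gct[i] <- pred$duration[j]
  }
  matched <- !is.na(out$pred_gct)
  res <- out[matched, , drop = FALSE]
  attr(res, "match_fraction") <- mean(matched)
  res
}

#' Normalized root-mean-square error
#'
#' RMSE normalized by the range of the reference, in percent: the score
#' used for both GCT and GRF prediction.
#'
#' @param pred,ref equal-length aligned numeric vectors.
#' @param na.rm drop pairs where either value is `NA` (e.g. warm-up).
#' @return percent.
#' @export
nrmse <- function(pred, ref, na.rm = TRUE) {
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length", call. = FALSE)
  if (na.rm) {
    ok <- !(is.na(pred) | is.na(ref))
    pred <- pred[ok]; ref <- ref[ok]
  }
  rng <- max(ref) - min(ref)
  if (rng == 0)
    stop("reference series is constant; nRMSE undefined", call. = FALSE)
  100 * sqrt(mean((pred - ref)^2)) / rng
}
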