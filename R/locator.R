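#' Locator model configuration
#'
#' Hyperparameters of the trainable growing-seed locator: a small transformer
#' encoder over fixed-size image patches with an extra learnable location
#' token whose output state classifies which patch holds the organ's semantic
#' center. Defaults are deliberately small so the model trains in seconds on
#' a CPU; `lr` and `epochs` default to the standard Adam settings used for
#' this task (0.001, 500).
#'
#' @param embed_dim token dimension D (divisible by `heads`).
#' @param depth number of encoder layers L.
#' @param heads attention heads.
#' @param patch patch side P in pixels.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param mlp_ratio hidden width of the MLP block as a multiple of D.
#' @param seed RNG seed: initialization and training are reproducible.
#' @return An object of class `locator_config`.
#' @export
locator_config <- function(embed_dim = 64L, depth = 2L, heads = 4L,
                           patch = 32L, lr = 1e-3, epochs = 500L,
                           mlp_ratio = 2, seed = 1L) {
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  structure(list(embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), patch = as.integer(patch),
                 lr = lr, epochs = as.integer(epochs), mlp_ratio = mlp_ratio,
                 seed = as.integer(seed)),
            class = "locator_config")
}

# ---- tiny transformer internals (dense linear algebra, analytic gradients) --

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dX = cache$inv * (dxhat - m1 - cache$xhat * m2),
       dg = colSums(dY * cache$xhat), db = colSums(dY))
}

.softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

.patchify <- function(slice, grid) {
  p <- grid$p
  X <- matrix(0, grid$n, p * p)
  i <- 0L
  for (pr in seq_len(grid$rows)) for (pc in seq_len(grid$cols)) {
    i <- i + 1L
    X[i, ] <- as.vector(slice[((pr - 1L) * p + 1L):(pr * p),
                              ((pc - 1L) * p + 1L):(pc * p)])
  }
  X
}

.locator_init <- function(config, n_region, p2) {
  D <- config$embed_dim
  Dm <- as.integer(round(config$mlp_ratio * D))
  rn <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  layers <- lapply(seq_len(config$depth), function(l) list(
    g1 = rep(1, D), b1 = rep(0, D),
    Wq = rn(D, D), bq = rep(0, D), Wk = rn(D, D), bk = rep(0, D),
    Wv = rn(D, D), bv = rep(0, D), Wo = rn(D, D), bo = rep(0, D),
    g2 = rep(1, D), b2 = rep(0, D),
    W1 = rn(D, Dm), b1m = rep(0, Dm), W2 = rn(Dm, D), b2m = rep(0, D)))
  list(We = rn(p2, D), xloc = rnorm(D, sd = 0.02),
       Epos = rn(n_region + 1L, D), layers = layers,
       gf = rep(1, D), bf = rep(0, D),
       Wh = rn(D, n_region), bh = rep(0, n_region))
}

# forward pass for one patch matrix X (N x P^2); returns caches for backprop
.locator_fwd <- function(params, X, heads) {
  D <- ncol(params$We)
  dh <- D / heads
  Z <- rbind(matrix(params$xloc, 1), X %*% params$We) + params$Epos
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    Zin <- Z
    c1 <- .ln_fwd(Zin, ly$g1, ly$b1)
    A <- c1$y
    Q <- A %*% ly$Wq + rep(ly$bq, each = nrow(A))
    K <- A %*% ly$Wk + rep(ly$bk, each = nrow(A))
    V <- A %*% ly$Wv + rep(ly$bv, each = nrow(A))
    Ocat <- matrix(0, nrow(A), D)
    Ps <- vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      Sr <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
      P <- .softmax_rows(Sr)
      Ps[[h]] <- P
      Ocat[, idx] <- P %*% V[, idx, drop = FALSE]
    }
    O <- Ocat %*% ly$Wo + rep(ly$bo, each = nrow(A))
    Z1 <- Zin + O
    c2 <- .ln_fwd(Z1, ly$g2, ly$b2)
    M1 <- c2$y %*% ly$W1 + rep(ly$b1m, each = nrow(A))
    Rl <- pmax(M1, 0)
    Z <- Z1 + Rl %*% ly$W2 + rep(ly$b2m, each = nrow(A))
    caches[[l]] <- list(Zin = Zin, c1 = c1, A = A, Q = Q, K = K, V = V,
                        Ps = Ps, Ocat = Ocat, Z1 = Z1, c2 = c2, M1 = M1,
                        Rl = Rl)
  }
  cf <- .ln_fwd(Z[1, , drop = FALSE], params$gf, params$bf)
  logits <- as.vector(cf$y %*% params$Wh) + params$bh
  e <- exp(logits - max(logits))
  list(Z = Z, caches = caches, cf = cf, logits = logits, probs = e / sum(e))
}

# zero-filled gradient structure matching params
.locator_zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

.acc_add <- function(g1, g2) {  # elementwise sum of two grad structures
  if (is.list(g1)) mapply(.acc_add, g1, g2, SIMPLIFY = FALSE) else g1 + g2
}

# backward pass: cross-entropy on the location token; returns grads + loss
.locator_bwd <- function(params, X, label, heads, fwd) {
  D <- ncol(params$We)
  dh <- D / heads
  grads <- .locator_zero_grads(params)
  loss <- -log(max(fwd$probs[label], 1e-12))
  dlog <- fwd$probs
  dlog[label] <- dlog[label] - 1
  dlog <- matrix(dlog, 1)
  grads$Wh <- t(fwd$cf$y) %*% dlog
  grads$bh <- as.vector(dlog)
  du <- dlog %*% t(params$Wh)
  lf <- .ln_bwd(du, fwd$cf, params$gf)
  grads$gf <- lf$dg; grads$bf <- lf$db
  dZ <- matrix(0, nrow(fwd$Z), D)
  dZ[1, ] <- lf$dX
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    ca <- fwd$caches[[l]]
    gl <- grads$layers[[l]]
    # MLP block
    dM <- dZ
    gl$W2 <- t(ca$Rl) %*% dM; gl$b2m <- colSums(dM)
    dRl <- dM %*% t(ly$W2)
    dM1 <- dRl * (ca$M1 > 0)
    gl$W1 <- t(ca$c2$y) %*% dM1; gl$b1m <- colSums(dM1)
    dB <- dM1 %*% t(ly$W1)
    l2 <- .ln_bwd(dB, ca$c2, ly$g2)
    gl$g2 <- l2$dg; gl$b2 <- l2$db
    dZ1 <- dZ + l2$dX
    # attention block
    dO <- dZ1
    gl$Wo <- t(ca$Ocat) %*% dO; gl$bo <- colSums(dO)
    dOcat <- dO %*% t(ly$Wo)
    dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      P <- ca$Ps[[h]]
      dOh <- dOcat[, idx, drop = FALSE]
      dP <- dOh %*% t(ca$V[, idx, drop = FALSE])
      dV[, idx] <- t(P) %*% dOh
      dSr <- P * (dP - rowSums(dP * P))
      dSr <- dSr / sqrt(dh)
      dQ[, idx] <- dSr %*% ca$K[, idx, drop = FALSE]
      dK[, idx] <- t(dSr) %*% ca$Q[, idx, drop = FALSE]
    }
    gl$Wq <- t(ca$A) %*% dQ; gl$bq <- colSums(dQ)
    gl$Wk <- t(ca$A) %*% dK; gl$bk <- colSums(dK)
    gl$Wv <- t(ca$A) %*% dV; gl$bv <- colSums(dV)
    dA <- dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
    l1 <- .ln_bwd(dA, ca$c1, ly$g1)
    gl$g1 <- l1$dg; gl$b1 <- l1$db
    grads$layers[[l]] <- gl
    dZ <- dZ1 + l1$dX
  }
  grads$Epos <- dZ
  grads$xloc <- dZ[1, ]
  grads$We <- t(X) %*% dZ[-1, , drop = FALSE]
  list(loss = loss, grads = grads)
}

# mean loss and mean gradients over a batch of (X, label)
.locator_batch <- function(params, Xs, labels, heads) {
  n <- length(Xs)
  total <- NULL; loss <- 0; correct <- 0L
  for (i in seq_len(n)) {
    fwd <- .locator_fwd(params, Xs[[i]], heads)
    bw <- .locator_bwd(params, Xs[[i]], labels[i], heads, fwd)
    loss <- loss + bw$loss
    correct <- correct + (which.max(fwd$probs) == labels[i])
    total <- if (is.null(total)) bw$grads else .acc_add(total, bw$grads)
  }
  list(loss = loss / n, acc = correct / n,
       grads = rapply(total, function(x) x / n, how = "replace"))
}

# Adam update on nested parameter lists
.adam_step <- function(state, params, grads, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  walk(params, grads, state$m, state$v)
}

#' Train the patch-locator transformer
#'
#' Full-batch Adam on the multiclass cross-entropy of the location-token
#' softmax over the `N` patch indices. Training is fully determined by
#' `config$seed`.
#'
#' @param dataset list of `list(slice = matrix, label = integer)`; all slices
#'   share one shape and labels are 1-based patch indices.
#' @param config a [locator_config()].
#' @return An object of class `locator_model` holding the parameters, the
#'   `patch_grid`, the config and a training `history` data frame
#'   (epoch, loss, acc).
#' @export
train_locator <- function(dataset, config = locator_config()) {
  if (length(dataset) == 0L) stop("empty dataset")
  dims <- dim(dataset[[1]]$slice)
  for (d in dataset)
    if (!identical(dim(d$slice), dims)) stop("slices must share one shape")
  grid <- make_patch_grid(dims[1], dims[2], config$patch)
  labels <- vapply(dataset, function(d) as.integer(d$label), integer(1))
  if (any(labels < 1L | labels > grid$n)) stop("label out of range")
  set.seed(config$seed)
  params <- .locator_init(config, grid$n, config$patch^2)
  Xs <- lapply(dataset, function(d) .patchify(d$slice, grid))
  state <- list(m = .locator_zero_grads(params),
                v = .locator_zero_grads(params))
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    bt <- .locator_batch(params, Xs, labels, config$heads)
    upd <- .adam_step(state, params, bt$grads, config$lr, ep)
    params <- upd$p
    state <- list(m = upd$m, v = upd$v)
    hist <- rbind(hist, data.frame(epoch = ep, loss = bt$loss, acc = bt$acc))
  }
  final <- .locator_batch(params, Xs, labels, config$heads)
  structure(list(params = params, config = config, grid = grid,
                 history = hist, final_loss = final$loss,
                 final_acc = final$acc),
            class = "locator_model")
}

#' @export
print.locator_model <- function(x, ...) {
  cat(sprintf(
    "locator_model: D=%d, L=%d, %d heads, %d patches; final loss %.4g, ACC %.3f\n",
    x$config$embed_dim, x$config$depth, x$config$heads, x$grid$n,
    x$final_loss, x$final_acc))
  invisible(x)
}

#' Localize the central patch with a trained model
#'
#' @param slice numeric matrix matching the model's grid.
#' @param model a `locator_model`.
#' @return 1-based patch index (argmax of the softmax), with the full
#'   probability vector as attribute `probabilities`.
#' @export
locate_model <- function(slice, model) {
  stopifnot(inherits(model, "locator_model"))
  if (!identical(dim(slice), c(model$grid$h, model$grid$w)))
    stop("slice shape does not match the model's grid")
  fwd <- .locator_fwd(model$params, .patchify(slice, model$grid),
                      model$config$heads)
  structure(which.max(fwd$probs), probabilities = fwd$probs)
}

#' Save / load a locator checkpoint (config embedded)
#' @param model a `locator_model`.
#' @param path file path (.rds).
#' @rdname locator_io
#' @export
save_locator <- function(model, path) {
  stopifnot(inherits(model, "locator_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname locator_io
#' @export
load_locator <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "locator_model")) stop("not a locator checkpoint")
  model
}

#' Write a training log as delimited text
#' @param model a `locator_model`.
#' @param path text file; columns epoch, loss, acc.
#' @export
write_training_log <- function(model, path) {
  write.table(model$history, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
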