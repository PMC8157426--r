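#' Encoder architecture configuration
#'
#' The encoder is a small multilayer perceptron of stacked affine layers.
#' Every hidden layer (all but the last) is followed by the nonlinearity and,
#' when `norm_after_hidden` is on, a feature-normalization (batch-norm) layer
#' with learned scale and shift. The final affine layer is the representation
#' layer: its width is the embedding size.
#'
#' @param input_dim Number of input genes d'.
#' @param layer_sizes Integer vector of layer widths; the last entry is the
#'   embedding size. Default `c(200, 40, 60)`, giving 60-dimensional cell
#'   embeddings.
#' @param norm_after_hidden Include feature normalization after each hidden
#'   layer (default TRUE).
#' @param activation Nonlinearity, currently `"relu"`.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(input_dim, layer_sizes = c(200L, 40L, 60L),
                           norm_after_hidden = TRUE, activation = "relu") {
  layer_sizes <- as.integer(layer_sizes)
  input_dim <- as.integer(input_dim)
  if (length(layer_sizes) < 1L || length(layer_sizes) > 8L) {
    stop("layer_sizes must have between 1 and 8 entries", call. = FALSE)
  }
  if (any(layer_sizes < 2L)) stop("all layer sizes must be >= 2",
                                  call. = FALSE)
  if (input_dim < 2L) stop("input_dim must be >= 2", call. = FALSE)
  activation <- match.arg(activation, "relu")
  structure(
    list(input_dim = input_dim, layer_sizes = layer_sizes,
         norm_after_hidden = isTRUE(norm_after_hidden),
         activation = activation),
    class = "encoder_config"
  )
}

#' Training configuration
#'
#' Defaults follow the method's reference protocol: Adam with an initial
#' learning rate of 0.4 decayed by a cosine schedule, 30 epochs of randomly
#' sampled mini-batches of 200 cells, contrastive temperature 0.5.
#'
#' @param epochs Number of passes over the data (default 30).
#' @param batch_size Mini-batch size (default 200).
#' @param learning_rate Initial Adam learning rate (default 0.4).
#' @param scheduler `"cosine"` (default) or `"constant"`.
#' @param temperature NT-Xent temperature tau > 0 (default 0.5).
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation (default 0).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 200L,
                         learning_rate = 0.4,
                         scheduler = c("cosine", "constant"),
                         temperature = 0.5, seed = 0L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  scheduler <- match.arg(scheduler)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 2L) stop("batch_size must be >= 2", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(
    list(epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, scheduler = scheduler,
         temperature = temperature, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Cell embedding container
#'
#' @param z Numeric matrix, one row per cell, one column per embedding
#'   dimension.
#' @param cell_ids Character vector of cell identifiers.
#' @return An `embedding` object.
#' @export
embedding <- function(z, cell_ids = rownames(z)) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("embedding must be finite", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(z)))
  rownames(z) <- cell_ids
  structure(list(z = z, cell_ids = as.character(cell_ids)),
            class = "embedding")
}

#' @export
dim.embedding <- function(x) dim(x$z)

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> ", nrow(x$z), " cells x ", ncol(x$z), " dimensions\n",
      sep = "")
  invisible(x)
}

#' Tidy an embedding into a tibble
#'
#' @param x An [embedding()].
#' @param ... Unused.
#' @return A tibble with `cell_id` and one `e*` column per dimension.
#' @export
tidy.embedding <- function(x, ...) {
  df <- tibble::as_tibble(x$z, .name_repair = "minimal")
  names(df) <- paste0("e", seq_len(ncol(x$z)))
  dplyr::bind_cols(tibble::tibble(cell_id = x$cell_ids), df)
}

#' Build an encoder model
#'
#' Affine weights are initialized with the standard uniform fan-in scheme
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))` for both weights and biases);
#' normalization layers start at identity (scale 1, shift 0) with zeroed
#' running statistics. Initialization is deterministic under `seed`.
#'
#' @param cfg An [encoder_config()].
#' @param seed Optional integer seed; when NULL the current RNG state is
#'   used.
#' @return An `encoder_model`.
#' @export
build_encoder <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "encoder_config"))
  if (!is.null(seed)) set.seed(seed)
  dims <- c(cfg$input_dim, cfg$layer_sizes)
  n_layers <- length(cfg$layer_sizes)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  bn <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    fan_in <- dims[i]
    bound <- 1 / sqrt(fan_in)
    W[[i]] <- matrix(stats::runif(fan_in * dims[i + 1L], -bound, bound),
                     fan_in, dims[i + 1L])
    b[[i]] <- stats::runif(dims[i + 1L], -bound, bound)
    if (cfg$norm_after_hidden && i < n_layers) {
      w <- dims[i + 1L]
      bn[[i]] <- list(gamma = rep(1, w), beta = rep(0, w),
                      run_mean = rep(0, w), run_var = rep(1, w))
    }
  }
  structure(list(cfg = cfg, W = W, b = b, bn = bn),
            class = "encoder_model")
}

#' Count trainable parameters of an encoder architecture
#'
#' Sums `in * out + out` over the affine layers plus, when feature
#' normalization is enabled, 2 parameters (scale and shift) per unit of each
#' normalized hidden layer. The default architecture on 500 input genes has
#' 111,180 trainable parameters
#' (100,200 + 400 + 8,040 + 80 + 2,460).
#'
#' @param cfg An [encoder_config()].
#' @return Integer parameter count.
#' @examples
#' count_parameters(encoder_config(500))
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  dims <- c(cfg$input_dim, cfg$layer_sizes)
  n_layers <- length(cfg$layer_sizes)
  total <- 0L
  for (i in seq_len(n_layers)) {
    total <- total + dims[i] * dims[i + 1L] + dims[i + 1L]
    if (cfg$norm_after_hidden && i < n_layers) {
      total <- total + 2L * dims[i + 1L]
    }
  }
  as.integer(total)
}

# Forward pass. training=TRUE uses batch statistics in the normalization
# layers (and returns updated running stats); training=FALSE uses the stored
# running statistics. Returns list(out, cache, bn) where bn carries the
# updated running statistics.
encoder_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  n_layers <- length(model$W)
  eps <- 1e-5
  momentum <- 0.1
  cache <- vector("list", n_layers)
  bn <- model$bn
  h <- X
  for (i in seq_len(n_layers)) {
    a <- h %*% model$W[[i]]
    a <- sweep(a, 2L, model$b[[i]], "+")
    layer_cache <- list(input = h, pre = a)
    if (i < n_layers) {
      r <- pmax(a, 0)
      layer_cache$post_relu <- r
      if (cfg$norm_after_hidden) {
        p <- bn[[i]]
        if (training) {
          m_rows <- nrow(r)
          mu <- colMeans(r)
          va <- colMeans(sweep(r, 2L, mu, "-")^2)  # biased batch variance
          bn[[i]]$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
          bn[[i]]$run_var <- (1 - momentum) * p$run_var + momentum * va
        } else {
          mu <- p$run_mean
          va <- p$run_var
        }
        invstd <- 1 / sqrt(va + eps)
        xhat <- sweep(sweep(r, 2L, mu, "-"), 2L, invstd, "*")
        h <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
        layer_cache$xhat <- xhat
        layer_cache$invstd <- invstd
      } else {
        h <- r
      }
    } else {
      h <- a
    }
    cache[[i]] <- layer_cache
  }
  list(out = h, cache = cache, bn = bn)
}

# Backward pass given d(loss)/d(output); returns gradients for all trainable
# parameters. Assumes the cache came from a training-mode forward.
encoder_backward <- function(model, cache, d_out) {
  cfg <- model$cfg
  n_layers <- length(model$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  ggamma <- vector("list", n_layers)
  gbeta <- vector("list", n_layers)
  dh <- d_out
  for (i in rev(seq_len(n_layers))) {
    lc <- cache[[i]]
    if (i < n_layers) {
      if (cfg$norm_after_hidden) {
        p <- model$bn[[i]]
        dy <- dh
        ggamma[[i]] <- colSums(dy * lc$xhat)
        gbeta[[i]] <- colSums(dy)
        dxhat <- sweep(dy, 2L, p$gamma, "*")
        m_rows <- nrow(dy)
        sum_dxhat <- colSums(dxhat)
        sum_dxhat_xhat <- colSums(dxhat * lc$xhat)
        dr <- sweep(
          m_rows * dxhat -
            matrix(sum_dxhat, m_rows, length(sum_dxhat), byrow = TRUE) -
            lc$xhat * matrix(sum_dxhat_xhat, m_rows,
                             length(sum_dxhat_xhat), byrow = TRUE),
          2L, lc$invstd / m_rows, "*")
      } else {
        dr <- dh
      }
      da <- dr * (lc$pre > 0)
    } else {
      da <- dh
    }
    gW[[i]] <- crossprod(lc$input, da)
    gb[[i]] <- colSums(da)
    if (i > 1L) dh <- tcrossprod(da, model$W[[i]])
  }
  list(W = gW, b = gb, gamma = ggamma, beta = gbeta)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' Rows of `z` are arranged as consecutive positive pairs: rows `2i-1` and
#' `2i` are the two augmented views of cell `i`. With cosine similarity
#' `sim(u, v) = u.v / (|u||v|)`, the per-pair loss is
#' `-log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`
#' and the returned value is the mean over all `2N` ordered positive pairs.
#' Log-sum-exp is stabilized by max subtraction, so no overflow occurs for
#' any `tau >= 0.01`.
#'
#' @param z Numeric matrix with `2N` rows (N >= 1 pairs); no row may have
#'   zero norm.
#' @param temperature Temperature tau > 0.
#' @return Non-negative scalar loss.
#' @examples
#' z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
#' nt_xent_loss(z, temperature = 0.5)
#' @export
nt_xent_loss <- function(z, temperature = 0.5) {
  nt_xent(z, temperature, want_grad = FALSE)$loss
}

# Shared loss/gradient implementation. The gradient is with respect to the
# raw (unnormalized) rows of z, back-propagated through the row L2
# normalization of the cosine similarity.
nt_xent <- function(z, temperature, want_grad = TRUE) {
  z <- as.matrix(z)
  m <- nrow(z)
  if (m < 2L || m %% 2L != 0L) {
    stop("z must have 2N rows of paired views (N >= 1), got ", m,
         call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (any(!is.finite(z))) stop("embeddings must be finite", call. = FALSE)
  norms <- sqrt(rowSums(z^2))
  if (any(norms == 0)) {
    stop("row ", which(norms == 0)[1L], " of z has zero norm", call. = FALSE)
  }
  u <- z / norms
  s <- tcrossprod(u) / temperature
  diag(s) <- -Inf
  # positive partner of row i: i+1 when i is odd, i-1 when even
  pos <- ifelse(seq_len(m) %% 2L == 1L, seq_len(m) + 1L, seq_len(m) - 1L)
  row_max <- apply(s, 1L, max)
  exps <- exp(s - row_max)
  denom <- rowSums(exps)
  log_denom <- row_max + log(denom)
  pos_s <- s[cbind(seq_len(m), pos)]
  loss <- mean(log_denom - pos_s)
  if (!want_grad) return(list(loss = loss))
  p <- exps / denom
  p[cbind(seq_len(m), pos)] <- p[cbind(seq_len(m), pos)] - 1
  g <- p / m  # d loss / d s, ordered rows; diagonal is exactly 0
  du <- (g + t(g)) %*% u / temperature
  # back through u_i = z_i / |z_i|
  dz <- (du - u * rowSums(du * u)) / norms
  list(loss = loss, grad = dz)
}

#' Train the contrastive encoder
#'
#' Each epoch shuffles the cells and iterates mini-batches; for each batch
#' two independently masked views are created, both are encoded by the same
#' encoder, and an Adam step is taken on the NT-Xent loss between paired
#' views. The learning rate follows a cosine decay from its initial value to
#' ~0 over the epochs. A trailing batch with fewer than 2 cells is dropped;
#' when there are fewer cells than `batch_size` each epoch is one
#' full-dataset batch. After training, the embedding is the encoder applied
#' to the un-augmented input in evaluation mode.
#'
#' @param pm A [preprocess()] result (or any list with `values` and
#'   `cell_ids`).
#' @param ecfg An [encoder_config()]; default architecture `c(200, 40, 60)`
#'   on the input width.
#' @param tcfg A [train_config()].
#' @param acfg An [augment_config()].
#' @return An `encoder_fit`: list with `embedding` (an [embedding()]),
#'   `loss_history` (one mean loss per epoch), `model`, and the configs.
#' @export
train_encoder <- function(pm, ecfg = NULL, tcfg = train_config(),
                          acfg = augment_config()) {
  X <- pm$values
  n <- nrow(X)
  if (n < 4L) stop("training needs at least 4 cells", call. = FALSE)
  if (is.null(ecfg)) ecfg <- encoder_config(input_dim = ncol(X))
  stopifnot(inherits(ecfg, "encoder_config"), inherits(tcfg, "train_config"),
            inherits(acfg, "augment_config"))
  if (ecfg$input_dim != ncol(X)) {
    stop("encoder input_dim (", ecfg$input_dim, ") does not match data (",
         ncol(X), ")", call. = FALSE)
  }
  set.seed(tcfg$seed)
  model <- build_encoder(ecfg)
  adam <- adam_state(model)
  batch_size <- min(tcfg$batch_size, n)
  loss_history <- numeric(tcfg$epochs)
  for (epoch in seq_len(tcfg$epochs)) {
    lr <- if (tcfg$scheduler == "cosine") {
      tcfg$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / tcfg$epochs))
    } else {
      tcfg$learning_rate
    }
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    batch_losses <- numeric(0L)
    for (st in starts) {
      idx <- perm[st:min(st + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # drop degenerate trailing batch
      batch <- X[idx, , drop = FALSE]
      views <- make_views(batch, acfg)
      f1 <- encoder_forward(model, views$view1, training = TRUE)
      model$bn <- f1$bn
      f2 <- encoder_forward(model, views$view2, training = TRUE)
      model$bn <- f2$bn
      b <- length(idx)
      e_dim <- ncol(f1$out)
      z <- matrix(0, 2L * b, e_dim)
      z[seq(1L, 2L * b, by = 2L), ] <- f1$out
      z[seq(2L, 2L * b, by = 2L), ] <- f2$out
      res <- nt_xent(z, tcfg$temperature)
      if (!is.finite(res$loss)) {
        stop("non-finite contrastive loss at epoch ", epoch,
             " (lr=", signif(lr, 3), "); inspect input scaling",
             call. = FALSE)
      }
      g1 <- encoder_backward(model, f1$cache,
                             res$grad[seq(1L, 2L * b, by = 2L), , drop = FALSE])
      g2 <- encoder_backward(model, f2$cache,
                             res$grad[seq(2L, 2L * b, by = 2L), , drop = FALSE])
      grads <- add_grads(g1, g2)
      upd <- adam_step(model, grads, adam, lr)
      model <- upd$model
      adam <- upd$state
      batch_losses <- c(batch_losses, res$loss)
    }
    loss_history[epoch] <- mean(batch_losses)
  }
  emb_out <- encoder_forward(model, X, training = FALSE)$out
  structure(
    list(embedding = embedding(emb_out, cell_ids = pm$cell_ids),
         loss_history = loss_history, model = model,
         encoder_config = ecfg, train_config = tcfg, augment_config = acfg),
    class = "encoder_fit"
  )
}

#' @export
print.encoder_fit <- function(x, ...) {
  cat("<encoder_fit> embedding ", nrow(x$embedding$z), " x ",
      ncol(x$embedding$z), "; final loss ",
      signif(utils::tail(x$loss_history, 1L), 5), " after ",
      length(x$loss_history), " epochs\n", sep = "")
  invisible(x)
}

#' One-row summary of a trained encoder
#'
#' @param x An `encoder_fit` from [train_encoder()].
#' @param ... Unused.
#' @return A tibble with parameter count, epochs, first/final loss and
#'   embedding size.
#' @export
glance.encoder_fit <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x$encoder_config),
    epochs = length(x$loss_history),
    first_loss = x$loss_history[1L],
    final_loss = utils::tail(x$loss_history, 1L),
    embedding_dim = ncol(x$embedding$z)
  )
}

#' Encode data with a trained model (evaluation mode, no masking)
#'
#' @param object An `encoder_fit`.
#' @param newdata Numeric matrix with the same width the model was trained
#'   on; default re-encodes nothing and returns the stored embedding.
#' @param ... Unused.
#' @return An [embedding()].
#' @export
predict.encoder_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$embedding)
  out <- encoder_forward(object$model, as.matrix(newdata),
                         training = FALSE)$out
  embedding(out, cell_ids = rownames(newdata))
}

# ---- Adam optimizer on the model's parameter lists -------------------------

adam_state <- function(model) {
  zeros_like <- function(x) if (is.matrix(x)) x * 0 else rep(0, length(x))
  st <- list(t = 0L, m = list(), v = list())
  for (nm in c("W", "b")) {
    st$m[[nm]] <- lapply(model[[nm]], zeros_like)
    st$v[[nm]] <- lapply(model[[nm]], zeros_like)
  }
  st$m$gamma <- lapply(model$bn, function(p) if (is.null(p)) NULL
                       else rep(0, length(p$gamma)))
  st$v$gamma <- st$m$gamma
  st$m$beta <- st$m$gamma
  st$v$beta <- st$m$gamma
  st
}

adam_step <- function(model, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(param, grad, m, v) {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    param <- param - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(param = param, m = m, v = v)
  }
  for (i in seq_along(model$W)) {
    r <- upd(model$W[[i]], grads$W[[i]], state$m$W[[i]], state$v$W[[i]])
    model$W[[i]] <- r$param; state$m$W[[i]] <- r$m; state$v$W[[i]] <- r$v
    r <- upd(model$b[[i]], grads$b[[i]], state$m$b[[i]], state$v$b[[i]])
    model$b[[i]] <- r$param; state$m$b[[i]] <- r$m; state$v$b[[i]] <- r$v
    if (!is.null(model$bn[[i]]) && !is.null(grads$gamma[[i]])) {
      r <- upd(model$bn[[i]]$gamma, grads$gamma[[i]],
               state$m$gamma[[i]], state$v$gamma[[i]])
      model$bn[[i]]$gamma <- r$param
      state$m$gamma[[i]] <- r$m; state$v$gamma[[i]] <- r$v
      r <- upd(model$bn[[i]]$beta, grads$beta[[i]],
               state$m$beta[[i]], state$v$beta[[i]])
      model$bn[[i]]$beta <- r$param
      state$m$beta[[i]] <- r$m; state$v$beta[[i]] <- r$v
    }
  }
  list(model = model, state = state)
}

add_grads <- function(g1, g2) {
  out <- g1
  for (nm in c("W", "b", "gamma", "beta")) {
    for (i in seq_along(g1[[nm]])) {
      if (!is.null(g1[[nm]][[i]])) {
        out[[nm]][[i]] <- g1[[nm]][[i]] + g2[[nm]][[i]]
      }
    }
  }
  out
}
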