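# Minimal matrix-based neural-network engine.
#
# All layers operate on one of three batch representations:
#   dense  — numeric matrix B x d
#   seq    — list(X = (B*L) x C matrix, B, L)  [token/conv pipelines; the
#            embedding layer turns an integer id matrix B x L into this]
#   graph  — list(H = (B*N) x F, Ahat = sparse (B*N) x (B*N), mask, group,
#            B, N) for graph convolution + pooling
# The output layer is linear; the sigmoid lives in the loss/predict path
# (binary cross-entropy with logits) for numerical stability.

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

nn_dense <- function(units, activation = c("relu", "linear"),
                     l2 = 0, l2_bias = 0, dropout = 0) {
  list(type = "dense", units = units, activation = match.arg(activation),
       l2 = l2, l2_bias = l2_bias, dropout = dropout)
}
nn_embedding <- function(vocab_size, dim) {
  list(type = "embedding", vocab_size = vocab_size, dim = dim)
}
nn_conv1d <- function(filters, kernel) {
  list(type = "conv1d", filters = filters, kernel = kernel)
}
nn_global_max_pool <- function() list(type = "gmaxpool")
nn_graph_conv <- function(channels, l2 = 0) {
  list(type = "gconv", channels = channels, l2 = l2)
}
nn_gated_pool <- function(channels) list(type = "gpool", channels = channels)

# Instantiate parameters once input widths are known.
.nn_build <- function(layers, input_dim) {
  dim <- input_dim          # semantic: current feature width
  built <- list()
  for (ly in layers) {
    p <- ly
    if (ly$type == "dense") {
      p$W <- .glorot(dim, ly$units); p$b <- numeric(ly$units)
      dim <- ly$units
    } else if (ly$type == "embedding") {
      p$E <- .glorot(ly$vocab_size + 1L, ly$dim)
      dim <- ly$dim
    } else if (ly$type == "conv1d") {
      p$W <- .glorot(ly$kernel * dim, ly$filters); p$b <- numeric(ly$filters)
      dim <- ly$filters
    } else if (ly$type == "gconv") {
      p$W <- .glorot(dim, ly$channels); p$b <- numeric(ly$channels)
      dim <- ly$channels
    } else if (ly$type == "gpool") {
      p$Wg <- .glorot(dim, ly$channels); p$bg <- numeric(ly$channels)
      p$Wt <- .glorot(dim, ly$channels); p$bt <- numeric(ly$channels)
      dim <- ly$channels
    }
    built[[length(built) + 1L]] <- p
  }
  list(layers = built, out_dim = dim)
}

.param_names <- function(ly) switch(ly$type,
  dense = c("W", "b"), conv1d = c("W", "b"), gconv = c("W", "b"),
  embedding = "E", gpool = c("Wg", "bg", "Wt", "bt"), character(0))

.conv_cols <- function(X, B, L, k) {
  Lout <- L - k + 1L
  C <- ncol(X)
  cols <- matrix(0, B * Lout, k * C)
  base <- rep((seq_len(B) - 1L) * L, each = Lout) + rep(seq_len(Lout), B)
  for (j in seq_len(k)) {
    cols[, ((j - 1L) * C + 1L):(j * C)] <- X[base + (j - 1L), , drop = FALSE]
  }
  list(cols = cols, base = base, Lout = Lout)
}

.nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      X <- if (is.list(x)) x$X else x
      Z <- X %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      A <- if (ly$activation == "relu") pmax(Z, 0) else Z
      drop_mask <- NULL
      if (training && ly$dropout > 0) {
        drop_mask <- matrix(stats::rbinom(length(A), 1, 1 - ly$dropout) /
                              (1 - ly$dropout), nrow(A), ncol(A))
        A <- A * drop_mask
      }
      caches[[i]] <- list(X = X, Z = Z, drop = drop_mask, was_list = is.list(x))
      x <- A
    } else if (ly$type == "embedding") {
      ids <- x$ids                      # B x L integer matrix, 0 = pad
      Xe <- ly$E[as.vector(t(ids)) + 1L, , drop = FALSE]  # row-major: (b,l)
      caches[[i]] <- list(ids = ids)
      x <- list(X = Xe, B = nrow(ids), L = ncol(ids))
    } else if (ly$type == "conv1d") {
      cc <- .conv_cols(x$X, x$B, x$L, ly$kernel)
      Z <- cc$cols %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      A <- pmax(Z, 0)
      caches[[i]] <- list(cols = cc$cols, Z = Z, base = cc$base,
                          B = x$B, L = x$L, Cin = ncol(x$X))
      x <- list(X = A, B = x$B, L = cc$Lout)
    } else if (ly$type == "gmaxpool") {
      B <- x$B; L <- x$L; C <- ncol(x$X)
      out <- matrix(-Inf, B, C)
      arg <- matrix(0L, B, C)
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * L + 1L):(b * L)
        sub <- x$X[rows, , drop = FALSE]
        am <- max.col(t(sub), ties.method = "first")
        arg[b, ] <- rows[am]
        out[b, ] <- sub[cbind(am, seq_len(C))]
      }
      caches[[i]] <- list(arg = arg, nrow_in = nrow(x$X), C = C)
      x <- out
    } else if (ly$type == "gconv") {
      AH <- as.matrix(x$Ahat %*% x$H)
      Z <- AH %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      Z <- Z * x$mask
      A <- pmax(Z, 0)
      caches[[i]] <- list(AH = AH, Z = Z, Ahat = x$Ahat, mask = x$mask)
      x <- list(H = A, Ahat = x$Ahat, mask = x$mask, group = x$group,
                B = x$B, N = x$N)
    } else if (ly$type == "gpool") {
      H <- x$H
      G0 <- 1 / (1 + exp(-sweep(H %*% ly$Wg, 2, ly$bg, "+")))
      G <- G0 * x$mask
      Tm <- sweep(H %*% ly$Wt, 2, ly$bt, "+")
      S <- G * Tm
      out <- rowsum(S, x$group, reorder = TRUE)
      caches[[i]] <- list(H = H, G0 = G0, G = G, Tm = Tm, mask = x$mask,
                          group = x$group)
      x <- out
    }
  }
  list(out = x, caches = caches)
}

.nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cache <- caches[[i]]
    if (ly$type == "dense") {
      dA <- if (is.list(dout)) dout$X else dout
      if (!is.null(cache$drop)) dA <- dA * cache$drop
      dZ <- if (ly$activation == "relu") dA * (cache$Z > 0) else dA
      gW <- crossprod(cache$X, dZ)
      if (ly$l2 > 0) gW <- gW + 2 * ly$l2 * ly$W
      gb <- colSums(dZ)
      if (ly$l2_bias > 0) gb <- gb + 2 * ly$l2_bias * ly$b
      grads[[i]] <- list(W = gW, b = gb)
      dX <- dZ %*% t(ly$W)
      dout <- if (cache$was_list) list(X = dX) else dX
    } else if (ly$type == "embedding") {
      dX <- dout$X
      ids <- as.vector(t(cache$ids)) + 1L
      gE <- matrix(0, nrow(ly$E), ncol(ly$E))
      agg <- rowsum(dX, ids)
      gE[as.integer(rownames(agg)), ] <- agg
      grads[[i]] <- list(E = gE)
      dout <- NULL                       # embedding is the input layer
    } else if (ly$type == "conv1d") {
      dA <- dout$X
      dZ <- dA * (cache$Z > 0)
      gW <- crossprod(cache$cols, dZ)
      gb <- colSums(dZ)
      grads[[i]] <- list(W = gW, b = gb)
      dcols <- dZ %*% t(ly$W)
      C <- cache$Cin
      dX <- matrix(0, cache$B * cache$L, C)
      for (j in seq_len(ly$kernel)) {
        # the target rows are distinct within one kernel offset, so a
        # direct indexed add accumulates correctly across offsets
        rows <- cache$base + (j - 1L)
        dX[rows, ] <- dX[rows, , drop = FALSE] +
          dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      }
      dout <- list(X = dX)
    } else if (ly$type == "gmaxpool") {
      dX <- matrix(0, cache$nrow_in, cache$C)
      B <- nrow(dout)
      for (b in seq_len(B)) {
        dX[cbind(cache$arg[b, ], seq_len(cache$C))] <-
          dX[cbind(cache$arg[b, ], seq_len(cache$C))] + dout[b, ]
      }
      grads[[i]] <- list()
      dout <- list(X = dX)
    } else if (ly$type == "gconv") {
      dA <- if (is.list(dout)) dout$H else dout
      dZ <- dA * (cache$Z > 0) * cache$mask
      gW <- crossprod(cache$AH, dZ)
      if (ly$l2 > 0) gW <- gW + 2 * ly$l2 * ly$W
      gb <- colSums(dZ)
      grads[[i]] <- list(W = gW, b = gb)
      dAH <- dZ %*% t(ly$W)
      dH <- as.matrix(cache$Ahat %*% dAH)   # Ahat symmetric
      dout <- list(H = dH)
    } else if (ly$type == "gpool") {
      dS <- dout[cache$group, , drop = FALSE]
      dG <- dS * cache$Tm
      dT <- dS * cache$G
      dpre_g <- dG * cache$mask * cache$G0 * (1 - cache$G0)
      gWg <- crossprod(cache$H, dpre_g); gbg <- colSums(dpre_g)
      gWt <- crossprod(cache$H, dT);     gbt <- colSums(dT)
      grads[[i]] <- list(Wg = gWg, bg = gbg, Wt = gWt, bt = gbt)
      dH <- dpre_g %*% t(ly$Wg) + dT %*% t(ly$Wt)
      dout <- list(H = dH)
    }
  }
  grads
}

# Adam state shaped like the model parameters.
.adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    nm <- .param_names(ly)
    stats::setNames(lapply(nm, function(p) {
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    }), nm)
  })
}

.adam_step <- function(net, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (p in .param_names(net$layers[[i]])) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# Binary cross-entropy with logits; returns loss and dL/dz (already / B).
.bce_with_logits <- function(z, y) {
  z <- as.vector(z)
  loss <- mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - y * z)
  p <- 1 / (1 + exp(-z))
  list(loss = loss, dz = matrix((p - y) / length(y), ncol = 1))
}

.l2_penalty <- function(net) {
  s <- 0
  for (ly in net$layers) {
    if (!is.null(ly$l2) && ly$l2 > 0 && !is.null(ly$W)) s <- s + ly$l2 * sum(ly$W^2)
    if (!is.null(ly$l2_bias) && ly$l2_bias > 0 && !is.null(ly$b))
      s <- s + ly$l2_bias * sum(ly$b^2)
  }
  s
}
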