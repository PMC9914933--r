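# Differentiable operations used by the Informer-style network.
#
# Sequences are stored batch-major: a tensor of B sequences of length L
# and width d is a (B*L) x d matrix whose rows 1..L belong to sequence 1,
# rows L+1..2L to sequence 2, and so on.

op_linear <- function(x, W, b = NULL) {
  v <- x$val %*% W$val
  if (!is.null(b)) v <- sweep(v, 2, b$val, "+")
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_node(v, parents, function(g) {
    .acc(x, tcrossprod(g, W$val))
    .acc(W, crossprod(x$val, g))
    if (!is.null(b)) .acc(b, colSums(g))
  })
}

op_add <- function(a, b) {
  ad_node(a$val + b$val, list(a, b), function(g) {
    .acc(a, g); .acc(b, g)
  })
}

# Elementwise product with a constant matrix (dropout masks, additive
# encodings are op_add with ad_const).
op_mul_const <- function(x, m) {
  ad_node(x$val * m, list(x), function(g) .acc(x, g * m))
}

op_elu <- function(x) {
  v <- x$val
  neg <- v < 0
  v[neg] <- exp(v[neg]) - 1
  ad_node(v, list(x), function(g) {
    dv <- g
    dv[neg] <- dv[neg] * (v[neg] + 1)
    .acc(x, dv)
  })
}

op_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$val)), nrow(x$val)) >= p) / (1 - p)
  op_mul_const(x, mask)
}

op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, gamma$val, "*")
  y <- sweep(y, 2, beta$val, "+")
  ad_node(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gamma$val, "*")
    dvar <- rowSums(dxhat * xc) * (-0.5) * inv^3
    dmu <- -rowSums(dxhat) * inv
    dx <- dxhat * inv + (dvar * 2 / d) * xc + dmu / d
    .acc(x, dx)
    .acc(gamma, colSums(g * xhat))
    .acc(beta, colSums(g))
  })
}

# Row subset; backward scatters into the source shape.
op_slice <- function(x, rows) {
  ad_node(x$val[rows, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[rows, ] <- g                      # `rows` has no duplicates here
    .acc(x, gx)
  })
}

op_rbind2 <- function(a, b) {
  na <- nrow(a$val)
  ad_node(rbind(a$val, b$val), list(a, b), function(g) {
    .acc(a, g[seq_len(na), , drop = FALSE])
    .acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

# Row lookup into an embedding table; duplicate indices accumulate.
op_embed <- function(table, idx) {
  ad_node(table$val[idx, , drop = FALSE], list(table), function(g) {
    gt <- matrix(0, nrow(table$val), ncol(table$val))
    agg <- rowsum(g, idx)
    gt[as.integer(rownames(agg)), ] <- agg
    .acc(table, gt)
  })
}

# 1-D convolution along time with same padding, as im2col + matmul.
# W is a (kernel*din) x dout parameter; offsets run -pad..+pad.
op_conv1d <- function(x, W, b, B, L, kernel = 3) {
  din <- ncol(x$val)
  pad <- (kernel - 1) %/% 2
  n <- B * L
  pos <- rep(seq_len(L), B)
  base <- rep((seq_len(B) - 1L) * L, each = L)
  idxs <- vector("list", kernel)
  xcat <- matrix(0, n, kernel * din)
  for (s in seq_len(kernel)) {
    off <- s - 1L - pad
    src <- pos + off
    ok <- src >= 1L & src <= L
    idx <- ifelse(ok, base + src, NA_integer_)
    idxs[[s]] <- idx
    block <- matrix(0, n, din)
    block[ok, ] <- x$val[idx[ok], , drop = FALSE]
    xcat[, (s - 1L) * din + seq_len(din)] <- block
  }
  v <- sweep(xcat %*% W$val, 2, b$val, "+")
  ad_node(v, list(x, W, b), function(g) {
    dxcat <- tcrossprod(g, W$val)
    gx <- matrix(0, n, din)
    for (s in seq_len(kernel)) {
      idx <- idxs[[s]]
      ok <- !is.na(idx)
      # for fixed s the target rows are distinct, so plain indexed add works
      gx[idx[ok], ] <- gx[idx[ok], , drop = FALSE] +
        dxcat[ok, (s - 1L) * din + seq_len(din), drop = FALSE]
    }
    .acc(x, gx)
    .acc(W, crossprod(xcat, g))
    .acc(b, colSums(g))
  })
}

# Max pooling along time (kernel 3, stride 2, pad 1): halves the length
# of each sequence to ceiling(L/2).
op_maxpool <- function(x, B, L, kernel = 3L, stride = 2L, pad = 1L) {
  d <- ncol(x$val)
  Lout <- (L + 2L * pad - kernel) %/% stride + 1L
  nOut <- B * Lout
  posOut <- rep(seq_len(Lout), B)
  base <- rep((seq_len(B) - 1L) * L, each = Lout)
  cand <- vector("list", kernel)
  vals <- vector("list", kernel)
  for (s in seq_len(kernel)) {
    src <- (posOut - 1L) * stride - pad + s
    ok <- src >= 1L & src <= L
    idx <- ifelse(ok, base + src, NA_integer_)
    cand[[s]] <- idx
    vb <- matrix(-Inf, nOut, d)
    vb[ok, ] <- x$val[idx[ok], , drop = FALSE]
    vals[[s]] <- vb
  }
  v <- vals[[1]]
  arg <- matrix(1L, nOut, d)
  for (s in 2:kernel) {
    better <- vals[[s]] > v
    v[better] <- vals[[s]][better]
    arg[better] <- s
  }
  ad_node(v, list(x), function(g) {
    gx <- matrix(0, nrow(x$val), d)
    for (s in seq_len(kernel)) {
      idx <- cand[[s]]
      ok <- !is.na(idx)
      gpart <- g * (arg == s)
      gx[idx[ok], ] <- gx[idx[ok], , drop = FALSE] + gpart[ok, , drop = FALSE]
    }
    .acc(x, gx)
  })
}

# Add a constant matrix (e.g. the forecast-origin anchor); gradient
# passes through unchanged.
op_add_const <- function(x, m) {
  ad_node(x$val + m, list(x), function(g) .acc(x, g))
}

op_mse <- function(pred, target) {
  d <- pred$val - target
  ad_node(mean(d^2), list(pred), function(g) {
    .acc(pred, g * 2 * d / length(d))
  })
}

# ---- ProbSparse attention core (shared by the AD op and the exported
# ---- numeric front ends) ----

.logsumexp <- function(s) {
  m <- max(s)
  m + log(sum(exp(s - m)))
}

# Sparsity measures of all queries given a score matrix S (Lq x Lk,
# masked entries NA): max-shifted log-sum-exp minus the mean, per row.
.sparsity_rows <- function(S) {
  V <- S
  V[is.na(V)] <- -Inf
  mx <- V[cbind(seq_len(nrow(V)), max.col(V, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(V - mx)))
  lse - rowSums(S, na.rm = TRUE) / rowSums(!is.na(S))
}

# Which queries get full softmax rows.  Non-causal: global top-u by
# sparsity measure (ties toward the lower index).  Causal: streaming rule
# -- query i is selected iff its measure ranks in the top u among queries
# 1..i -- so selection of a row never depends on later positions.
.select_queries <- function(M, u, causal) {
  Lq <- length(M)
  u <- max(1L, min(u, Lq))
  if (u >= Lq) return(seq_len(Lq))
  if (!causal) return(sort(utils::head(order(-M), u)))
  .select_stream(M, u)
}

# Streaming prefix top-u: query i is kept iff fewer than u earlier
# queries have a measure >= M_i (running buffer of the u largest).
.select_stream <- function(M, u) {
  sel <- logical(length(M))
  topu <- numeric(0)
  for (i in seq_along(M)) {
    if (length(topu) < u) {
      sel[i] <- TRUE
      topu <- c(topu, M[i])
    } else {
      j <- which.min(topu)
      if (M[i] > topu[j]) {
        sel[i] <- TRUE
        topu[j] <- M[i]
      }
    }
  }
  which(sel)
}

# Cached strictly-upper-triangular masks (causal attention reuses the
# same L x L mask thousands of times per training run).
.mask_env <- new.env(parent = emptyenv())
.upper_mask <- function(L) {
  key <- as.character(L)
  m <- .mask_env[[key]]
  if (is.null(m)) {
    m <- upper.tri(matrix(0, L, L))
    .mask_env[[key]] <- m
  }
  m
}

.softmax_rows <- function(S) {
  V <- S
  V[is.na(V)] <- -Inf
  mx <- V[cbind(seq_len(nrow(V)), max.col(V, ties.method = "first"))]
  E <- exp(V - mx)
  E / rowSums(E)
}

# One (batch, head) slice of ProbSparse attention.
# q: Lq x dh, k/v: Lk x dh.  Returns out, plus internals for backward.
.attn_forward_one <- function(q, k, v, u, causal) {
  Lq <- nrow(q); Lk <- nrow(k); dh <- ncol(q)
  S <- tcrossprod(q, k) / sqrt(dh)
  if (causal) {
    if (Lq != Lk) stop("causal attention requires Lq == Lk")
    ut <- .upper_mask(Lq)
    Sm <- S
    Sm[ut] <- -Inf                      # masked scores for max / softmax
    if (u >= Lq) {
      M <- NULL
      sel <- seq_len(Lq)
    } else {
      Ssum <- S
      Ssum[ut] <- 0
      mx <- Sm[cbind(seq_len(Lq), max.col(Sm, ties.method = "first"))]
      M <- mx + log(rowSums(exp(Sm - mx))) - rowSums(Ssum) / seq_len(Lq)
      sel <- .select_stream(M, u)
    }
    Ssel <- Sm[sel, , drop = FALSE]
  } else {
    if (u >= Lq) {
      M <- NULL
      sel <- seq_len(Lq)
    } else {
      mx <- S[cbind(seq_len(Lq), max.col(S, ties.method = "first"))]
      M <- mx + log(rowSums(exp(S - mx))) - rowMeans(S)
      sel <- sort(utils::head(order(-M), u))
    }
    Ssel <- S[sel, , drop = FALSE]
  }
  mxs <- Ssel[cbind(seq_along(sel), max.col(Ssel, ties.method = "first"))]
  E <- exp(Ssel - mxs)                  # exp(-Inf) = 0 handles the mask
  A <- E / rowSums(E)
  out <- matrix(0, Lq, dh)
  out[sel, ] <- A %*% v
  unsel <- if (length(sel) == Lq) integer(0) else seq_len(Lq)[-sel]
  if (length(unsel)) {
    if (causal) {
      cum <- apply(v, 2, cumsum)
      if (!is.matrix(cum)) cum <- matrix(cum, nrow = nrow(v))
      cum <- cum / seq_len(Lk)
      out[unsel, ] <- cum[unsel, , drop = FALSE]
    } else {
      out[unsel, ] <- matrix(colMeans(v), length(unsel), dh, byrow = TRUE)
    }
  }
  list(out = out, A = A, sel = sel, unsel = unsel, M = M)
}

# Multi-head ProbSparse attention over a batch.  Qn/Kn/Vn are projected
# activations of shape (B*Lq) x d and (B*Lk) x d; heads split d evenly.
op_attn_core <- function(Qn, Kn, Vn, nHeads, u, causal, B, Lq, Lk) {
  d <- ncol(Qn$val)
  dh <- d %/% nHeads
  out <- matrix(0, B * Lq, d)
  keep <- vector("list", B * nHeads)
  for (b in seq_len(B)) {
    rq <- (b - 1L) * Lq + seq_len(Lq)
    rk <- (b - 1L) * Lk + seq_len(Lk)
    for (h in seq_len(nHeads)) {
      hc <- (h - 1L) * dh + seq_len(dh)
      fw <- .attn_forward_one(Qn$val[rq, hc, drop = FALSE],
                              Kn$val[rk, hc, drop = FALSE],
                              Vn$val[rk, hc, drop = FALSE], u, causal)
      out[rq, hc] <- fw$out
      keep[[(b - 1L) * nHeads + h]] <- fw
    }
  }
  ad_node(out, list(Qn, Kn, Vn), function(g) {
    gQ <- matrix(0, nrow(Qn$val), d)
    gK <- matrix(0, nrow(Kn$val), d)
    gV <- matrix(0, nrow(Vn$val), d)
    sq <- sqrt(dh)
    for (b in seq_len(B)) {
      rq <- (b - 1L) * Lq + seq_len(Lq)
      rk <- (b - 1L) * Lk + seq_len(Lk)
      for (h in seq_len(nHeads)) {
        hc <- (h - 1L) * dh + seq_len(dh)
        fw <- keep[[(b - 1L) * nHeads + h]]
        gh <- g[rq, hc, drop = FALSE]
        kv <- Kn$val[rk, hc, drop = FALSE]
        vv <- Vn$val[rk, hc, drop = FALSE]
        if (length(fw$sel)) {
          gsel <- gh[fw$sel, , drop = FALSE]
          A <- fw$A
          gV[rk, hc] <- gV[rk, hc] + crossprod(A, gsel)
          dA <- tcrossprod(gsel, vv)
          dS <- A * (dA - rowSums(dA * A))
          gQ[rq[fw$sel], hc] <- gQ[rq[fw$sel], hc] + dS %*% kv / sq
          gK[rk, hc] <- gK[rk, hc] +
            crossprod(dS, Qn$val[rq[fw$sel], hc, drop = FALSE]) / sq
        }
        if (length(fw$unsel)) {
          if (causal) {
            W <- matrix(0, Lk, dh)
            W[fw$unsel, ] <- gh[fw$unsel, , drop = FALSE] / fw$unsel
            if (nrow(W) > 1)           # reverse cumulative sum over time
              for (j in seq(nrow(W) - 1L, 1L)) W[j, ] <- W[j, ] + W[j + 1L, ]
            gV[rk, hc] <- gV[rk, hc] + W
          } else {
            gV[rk, hc] <- gV[rk, hc] +
              matrix(colSums(gh[fw$unsel, , drop = FALSE]) / Lk,
                     Lk, dh, byrow = TRUE)
          }
        }
      }
    }
    .acc(Qn, gQ); .acc(Kn, gK); .acc(Vn, gV)
  })
}

# Full multi-head (Prob)Sparse attention block with projections.
# p: list with Wq, Wk, Wv, Wo (+ biases bq, bk, bv, bo).
op_mha <- function(xq, xkv, p, nHeads, u, causal, B, Lq, Lk) {
  Qn <- op_linear(xq, p$Wq, p$bq)
  Kn <- op_linear(xkv, p$Wk, p$bk)
  Vn <- op_linear(xkv, p$Wv, p$bv)
  core <- op_attn_core(Qn, Kn, Vn, nHeads, u, causal, B, Lq, Lk)
  op_linear(core, p$Wo, p$bo)
}
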