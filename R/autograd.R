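# Minimal reverse-mode autodiff tape over 4-axis arrays (h, w, c, n).
# Internal only: the recurrent cells and forecasting networks are expressed
# as tape ops, so one implementation serves both prediction and training.
# Backward closures capture the values they need at record time; gradients
# are accumulated by walking node ids in reverse (ids are a topological order
# because the tape is append-only).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_push <- function(tp, val, parents = integer(), backward = NULL) {
  # force the arguments first: evaluating them may create nodes (R lazily
  # evaluates arguments), and this node's id must come after theirs
  force(val)
  force(parents)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- list(parents = parents, backward = backward)
  tp$n <- n
  list(id = n, val = val)
}

ag_const <- function(tp, val) {
  nd <- ag_push(tp, val)
  nd$const <- TRUE
  nd
}
ag_param <- function(tp, val) ag_push(tp, val)

# Walk the tape from `node` down, return list of gradients indexed by node id.
ag_backward <- function(tp, node, seed_grad = 1) {
  grads <- vector("list", tp$n)
  grads[[node$id]] <- seed_grad
  for (id in seq(node$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL) # free this node's gradient as we go (keep length)
  }
  grads
}

ag_conv <- function(tp, x, w, b) {
  xv <- x$val
  wv <- w$val
  want_dx <- !isTRUE(x$const) # no gradient into constant leaves
  ag_push(tp, .conv2d_fwd(xv, wv, b$val),
    parents = c(x$id, w$id, b$id),
    backward = function(g) {
      bw <- .conv2d_bwd(xv, wv, g, want_dx)
      list(bw$dx, bw$dw, bw$db)
    }
  )
}

ag_add <- function(tp, a, b) {
  ag_push(tp, a$val + b$val,
    parents = c(a$id, b$id),
    backward = function(g) list(g, g)
  )
}

ag_sub <- function(tp, a, b) {
  ag_push(tp, a$val - b$val,
    parents = c(a$id, b$id),
    backward = function(g) list(g, -g)
  )
}

ag_mul <- function(tp, a, b) {
  av <- a$val
  bv <- b$val
  ag_push(tp, av * bv,
    parents = c(a$id, b$id),
    backward = function(g) list(g * bv, g * av)
  )
}

ag_scale <- function(tp, a, k) {
  ag_push(tp, a$val * k,
    parents = a$id,
    backward = function(g) list(g * k)
  )
}

ag_sigmoid <- function(tp, a) {
  v <- 1 / (1 + exp(-a$val))
  ag_push(tp, v,
    parents = a$id,
    backward = function(g) list(g * v * (1 - v))
  )
}

ag_tanh <- function(tp, a) {
  v <- tanh(a$val)
  ag_push(tp, v,
    parents = a$id,
    backward = function(g) list(g * (1 - v * v))
  )
}

ag_one_minus <- function(tp, a) {
  ag_push(tp, 1 - a$val,
    parents = a$id,
    backward = function(g) list(-g)
  )
}

ag_leaky_relu <- function(tp, a, slope = 0.2) {
  av <- a$val
  v <- ifelse(av >= 0, av, slope * av)
  dim(v) <- dim(av)
  ag_push(tp, v,
    parents = a$id,
    backward = function(g) {
      dg <- ifelse(av >= 0, g, slope * g)
      dim(dg) <- dim(g)
      list(dg)
    }
  )
}

# Hadamard product with a (h, w, c) parameter grid broadcast over the batch
# axis (used for the peephole terms of the peephole ConvLSTM).
ag_hadamard_param <- function(tp, p, a) {
  pv <- p$val
  av <- a$val
  v <- av * c(pv)
  dim(v) <- dim(av)
  ag_push(tp, v,
    parents = c(p$id, a$id),
    backward = function(g) {
      dp <- rowSums(g * av, dims = 3L)
      da <- g * c(pv)
      dim(da) <- dim(g)
      list(dp, da)
    }
  )
}

# Channel concatenation along axis 3 of a list of same-shaped nodes.
ag_concat_c <- function(tp, nodes) {
  vals <- lapply(nodes, `[[`, "val")
  d <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (k in seq_along(vals)) {
    out[, , at + seq_len(chans[k]), ] <- vals[[k]]
    at <- at + chans[k]
  }
  ag_push(tp, out,
    parents = vapply(nodes, `[[`, integer(1), "id"),
    backward = function(g) {
      res <- vector("list", length(chans))
      at <- 0L
      for (k in seq_along(chans)) {
        gk <- g[, , at + seq_len(chans[k]), , drop = FALSE]
        res[[k]] <- gk
        at <- at + chans[k]
      }
      res
    }
  )
}

ag_slice_c <- function(tp, a, from, to) {
  av <- a$val
  d <- dim(av)
  v <- av[, , from:to, , drop = FALSE]
  ag_push(tp, v,
    parents = a$id,
    backward = function(g) {
      da <- array(0, d)
      da[, , from:to, ] <- g
      list(da)
    }
  )
}

# Group normalization over (h, w, channels-in-group) per batch element, with
# per-channel affine parameters gamma and beta (plain vectors of length c).
ag_groupnorm <- function(tp, x, gamma, beta, groups, eps = 1e-5) {
  xv <- x$val
  d <- dim(xv)
  cpg <- d[3] %/% groups
  if (cpg * groups != d[3]) stop("channels not divisible by groups")
  m <- d[1] * d[2] * cpg
  xhat <- array(0, d)
  sd_store <- matrix(0, groups, d[4])
  for (s in seq_len(d[4])) {
    for (gidx in seq_len(groups)) {
      ch <- (gidx - 1L) * cpg + seq_len(cpg)
      blk <- xv[, , ch, s]
      mu <- mean(blk)
      va <- sum((blk - mu)^2) / m
      sdv <- sqrt(va + eps)
      xhat[, , ch, s] <- (blk - mu) / sdv
      sd_store[gidx, s] <- sdv
    }
  }
  gv <- gamma$val
  bv <- beta$val
  v <- xhat * rep(gv, each = d[1] * d[2]) # broadcast per channel
  v <- v + rep(bv, each = d[1] * d[2])
  dim(v) <- d
  ag_push(tp, v,
    parents = c(x$id, gamma$id, beta$id),
    backward = function(g) {
      dgamma <- numeric(d[3])
      dbeta <- numeric(d[3])
      for (ch in seq_len(d[3])) {
        dgamma[ch] <- sum(g[, , ch, ] * xhat[, , ch, ])
        dbeta[ch] <- sum(g[, , ch, ])
      }
      dx <- array(0, d)
      for (s in seq_len(d[4])) {
        for (gidx in seq_len(groups)) {
          ch <- (gidx - 1L) * cpg + seq_len(cpg)
          gh <- g[, , ch, s] * rep(gv[ch], each = d[1] * d[2]) # d x-hat grad
          xh <- xhat[, , ch, s]
          dx[, , ch, s] <- (gh - mean(gh) - xh * mean(gh * xh)) / sd_store[gidx, s]
        }
      }
      list(dx, dgamma, dbeta)
    }
  )
}

# Add a ch-wide array into the channel slice of z starting at `from`.
ag_add_slice <- function(tp, z, extra, from) {
  ev <- extra$val
  idx <- from:(from + dim(ev)[3] - 1L)
  v <- z$val
  v[, , idx, ] <- v[, , idx, , drop = FALSE] + ev
  ag_push(tp, v,
    parents = c(z$id, extra$id),
    backward = function(g) list(g, g[, , idx, , drop = FALSE])
  )
}

# Fused ConvLSTM cell update (C++ pointwise kernels).  z holds the gate
# pre-activations (i, f, g, o); the optional peephole grids couple the
# gates to the cell state by Hadamard products.
ag_lstm_cnew <- function(tp, z, cprev, pci = NULL, pcf = NULL) {
  cv <- cprev$val
  pciv <- if (!is.null(pci)) pci$val else NULL
  pcfv <- if (!is.null(pcf)) pcf$val else NULL
  fw <- .lstm_cnew_fwd(z$val, cv, pciv, pcfv)
  parents <- c(z$id, cprev$id, if (!is.null(pci)) c(pci$id, pcf$id))
  ag_push(tp, fw$c,
    parents = parents,
    backward = function(g) {
      bw <- .lstm_cnew_bwd(g, fw$i, fw$f, fw$g, cv, pciv, pcfv)
      if (is.null(pci)) {
        list(bw$dz, bw$dcprev)
      } else {
        list(bw$dz, bw$dcprev, bw$dpci, bw$dpcf)
      }
    }
  )
}

ag_lstm_hout <- function(tp, z, cnew, pco = NULL, zo_extra = NULL) {
  cv <- cnew$val
  pcov <- if (!is.null(pco)) pco$val else NULL
  fw <- .lstm_hout_fwd(z$val, cv, pcov, if (!is.null(zo_extra)) zo_extra$val else NULL)
  parents <- c(
    z$id, cnew$id, if (!is.null(pco)) pco$id,
    if (!is.null(zo_extra)) zo_extra$id
  )
  ag_push(tp, fw$h,
    parents = parents,
    backward = function(g) {
      bw <- .lstm_hout_bwd(g, fw$o, cv, pcov, !is.null(zo_extra))
      out <- list(bw$dz, bw$dcnew)
      if (!is.null(pco)) out <- c(out, list(bw$dpco))
      if (!is.null(zo_extra)) out <- c(out, list(bw$dzo_extra))
      out
    }
  )
}

# Mean squared error against a constant target; returns a scalar node.
ag_mse <- function(tp, a, target) {
  av <- a$val
  diff <- av - target
  n_el <- length(diff)
  ag_push(tp, sum(diff^2) / n_el,
    parents = a$id,
    backward = function(g) list((2 * g / n_el) * diff)
  )
}

# Mean of scalar nodes (used to pool per-step losses with equal weights).
ag_mean_scalars <- function(tp, nodes) {
  k <- length(nodes)
  ag_push(tp, mean(vapply(nodes, `[[`, numeric(1), "val")),
    parents = vapply(nodes, `[[`, integer(1), "id"),
    backward = function(g) rep(list(g / k), k)
  )
}
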