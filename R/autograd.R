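# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is an `ag_node` environment holding its value,
# its parents and a pullback closure; nodes are appended to a tape in creation
# order so the reverse sweep is a single backwards pass over the tape. Inputs
# that are plain matrices are treated as constants, and ops short-circuit to
# plain arithmetic when no argument requires gradients, so the same forward
# code serves both training (taped) and inference (untaped).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- vector("list", 512L)
  tp
}

ag_is <- function(x) is.environment(x)

# value of a node or constant
vof <- function(x) if (ag_is(x)) x$val else x

ag_new <- function(tape, val, parents = list(), back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  class(nd) <- "ag_node"
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# leaf parameter node (gradient accumulated here)
ag_param <- function(tape, val) ag_new(tape, val)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# y = x %*% W + b (b a length-q vector, broadcast over rows)
ag_affine <- function(tape, x, W, b) {
  xv <- vof(x); Wv <- vof(W); bv <- vof(b)
  val <- xv %*% Wv
  val <- val + rep(as.numeric(bv), each = nrow(val))
  if (!ag_is(x) && !ag_is(W) && !ag_is(b)) return(val)
  ag_new(tape, val, list(x, W, b), function(g) {
    list(
      if (ag_is(x)) g %*% t(Wv) else NULL,
      if (ag_is(W)) crossprod(xv, g) else NULL,
      if (ag_is(b)) colSums(g) else NULL
    )
  })
}

ag_tanh <- function(tape, x) {
  if (!ag_is(x)) return(tanh(x))
  val <- tanh(x$val)
  ag_new(tape, val, list(x), function(g) list(g * (1 - val^2)))
}

ag_sigmoid <- function(tape, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  if (!ag_is(x)) return(sig(x))
  val <- sig(x$val)
  ag_new(tape, val, list(x), function(g) list(g * val * (1 - val)))
}

ag_log <- function(tape, x) {
  if (!ag_is(x)) return(log(x))
  xv <- x$val
  ag_new(tape, log(xv), list(x), function(g) list(g / xv))
}

ag_add <- function(tape, x, y) {
  if (!ag_is(x) && !ag_is(y)) return(x + y)
  ag_new(tape, vof(x) + vof(y), list(x, y), function(g) {
    list(if (ag_is(x)) g else NULL, if (ag_is(y)) g else NULL)
  })
}

ag_sub <- function(tape, x, y) {
  if (!ag_is(x) && !ag_is(y)) return(x - y)
  ag_new(tape, vof(x) - vof(y), list(x, y), function(g) {
    list(if (ag_is(x)) g else NULL, if (ag_is(y)) -g else NULL)
  })
}

# elementwise product; either argument may be a scalar or a constant matrix
ag_mul <- function(tape, x, y) {
  xv <- vof(x); yv <- vof(y)
  if (!ag_is(x) && !ag_is(y)) return(xv * yv)
  ag_new(tape, xv * yv, list(x, y), function(g) {
    list(if (ag_is(x)) g * yv else NULL, if (ag_is(y)) g * xv else NULL)
  })
}

# sum_i coef[i] * xs[[i]] (coefs numeric constants), used by the RK4 update
ag_lincomb <- function(tape, coefs, xs) {
  taped <- any(vapply(xs, ag_is, logical(1)))
  val <- coefs[1] * vof(xs[[1]])
  if (length(xs) > 1L) for (i in 2:length(xs)) val <- val + coefs[i] * vof(xs[[i]])
  if (!taped) return(val)
  ag_new(tape, val, xs, function(g) {
    lapply(seq_along(xs), function(i) if (ag_is(xs[[i]])) coefs[i] * g else NULL)
  })
}

# contract the CDE vector field output with a control increment:
#   out[i, p] = sum_c Fout[i, (p-1)*C + c] * dX[i, c]
# Fout is n x (P*C) with channels fastest; dX is a constant n x C matrix.
ag_contract <- function(tape, Fout, dX, P, C) {
  Fv <- vof(Fout)
  val <- matrix(0, nrow(Fv), P)
  for (p in seq_len(P)) {
    idx <- ((p - 1L) * C + 1L):(p * C)
    val[, p] <- rowSums(Fv[, idx, drop = FALSE] * dX)
  }
  if (!ag_is(Fout)) return(val)
  ag_new(tape, val, list(Fout), function(g) {
    gF <- matrix(0, nrow(Fv), P * C)
    for (p in seq_len(P)) {
      idx <- ((p - 1L) * C + 1L):(p * C)
      gF[, idx] <- g[, p] * dX
    }
    list(gF)
  })
}

# cbind a node with a constant block on the right
ag_cbind <- function(tape, x, const_right) {
  if (!ag_is(x)) return(cbind(x, const_right))
  k <- ncol(x$val)
  ag_new(tape, cbind(x$val, const_right), list(x), function(g) list(g[, seq_len(k), drop = FALSE]))
}

ag_sumall <- function(tape, x) {
  if (!ag_is(x)) return(sum(x))
  dims <- dim(x$val)
  ag_new(tape, matrix(sum(x$val), 1L, 1L), list(x),
         function(g) list(matrix(g[1L], dims[1L], dims[2L])))
}

# log(1 + exp(x)), computed overflow-safe; gradient is sigmoid(x)
ag_softplus <- function(tape, x) {
  sp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  if (!ag_is(x)) return(sp(x))
  xv <- x$val
  ag_new(tape, sp(xv), list(x), function(g) list(g / (1 + exp(-xv))))
}

# Fused two-hidden-layer tanh MLP, optionally contracted with a control
# increment dX (n x C): out[i,p] = sum_c mlp(x)[i,(p-1)*C+c] * dX[i,c].
# One tape node with a hand-written pullback: the MLP evaluation sits in the
# innermost loop of the CDE solver, where per-node overhead dominates.
ag_mlp <- function(tape, x, p, dX = NULL, P = NULL, C = NULL) {
  xv <- vof(x)
  W1 <- vof(p$W1); b1 <- vof(p$b1); W2 <- vof(p$W2); b2 <- vof(p$b2)
  W3 <- vof(p$W3); b3 <- vof(p$b3)
  n <- nrow(xv)
  h1 <- tanh(xv %*% W1 + rep(b1, each = n))
  h2 <- tanh(h1 %*% W2 + rep(b2, each = n))
  o <- h2 %*% W3 + rep(b3, each = n)
  val <- if (is.null(dX)) o else {
    out <- matrix(0, n, P)
    for (pp in seq_len(P)) {
      idx <- ((pp - 1L) * C + 1L):(pp * C)
      out[, pp] <- rowSums(o[, idx, drop = FALSE] * dX)
    }
    out
  }
  taped <- ag_is(x) || ag_is(p$W1)
  if (!taped) return(val)
  ag_new(tape, val, list(x, p$W1, p$b1, p$W2, p$b2, p$W3, p$b3), function(g) {
    go <- if (is.null(dX)) g else {
      go <- matrix(0, n, ncol(o))
      for (pp in seq_len(P)) {
        idx <- ((pp - 1L) * C + 1L):(pp * C)
        go[, idx] <- g[, pp] * dX
      }
      go
    }
    gh2 <- (go %*% t(W3)) * (1 - h2^2)
    gh1 <- (gh2 %*% t(W2)) * (1 - h1^2)
    want_p <- ag_is(p$W1)
    list(
      if (ag_is(x)) gh1 %*% t(W1) else NULL,
      if (want_p) crossprod(xv, gh1) else NULL,
      if (want_p) colSums(gh1) else NULL,
      if (want_p) crossprod(h1, gh2) else NULL,
      if (want_p) colSums(gh2) else NULL,
      if (want_p) crossprod(h2, go) else NULL,
      if (want_p) colSums(go) else NULL
    )
  })
}

# gradient reversal: identity forward, -lambda * g backward (adversarial balancing)
ag_grev <- function(tape, x, lambda = 1) {
  if (!ag_is(x)) return(x)
  ag_new(tape, x$val, list(x), function(g) list(-lambda * g))
}

# identity forward, gradient blocked
ag_stopgrad <- function(tape, x) vof(x)

# reverse sweep from `loss` (a 1x1 node); gradients land in node$grad
ag_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
    }
    if (!identical(nd, loss)) nd$grad <- NULL  # free memory as we go
  }
  invisible(NULL)
}
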