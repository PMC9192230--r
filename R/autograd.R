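#' @useDynLib uatransnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- Reverse-mode autodiff tape ------------------------------------------
#
# Each forward op appends a node to a tape held in a package-local
# environment.  A node is an environment with: $val (numeric array/matrix/
# scalar), $parents (list of nodes), $backfn (function(grad) -> list of
# gradients aligned with $parents), $grad (accumulated during backward).
# Gradients are plain arrays of the same shape as $val.

.ag <- new.env(parent = emptyenv())

ag_reset <- function() {
  .ag$nodes <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  n <- .ag$n + 1L
  if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
  .ag$nodes[[n]] <- nd
  .ag$n <- n
  nd
}

ag_leaf <- function(x) ag_node(x)

#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- 1
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# --- elementwise / arithmetic ops ----------------------------------------

ag_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

ag_relu <- function(x) {
  m <- x$val > 0
  ag_node(x$val * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# scalar (length-1 node) times tensor node
ag_smul <- function(s, x) {
  ag_node(s$val * x$val, list(s, x),
          function(g) list(sum(g * x$val), s$val * g))
}

ag_scale <- function(x, k) {
  ag_node(x$val * k, list(x), function(g) list(g * k))
}

ag_mean <- function(x) {
  n <- length(x$val)
  ag_node(mean(x$val), list(x), function(g) list(array(g / n, dim(x$val) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- structural ops -------------------------------------------------------

# h x w x c array -> c x (h*w) matrix, position index = row + h * col
ag_c2m <- function(x) {
  d <- dim(x$val)
  m <- t(matrix(x$val, d[1] * d[2], d[3]))
  ag_node(m, list(x), function(g) list(array(t(g), d)))
}

ag_m2c <- function(m, h, w) {
  c0 <- nrow(m$val)
  ag_node(array(t(m$val), c(h, w, c0)), list(m),
          function(g) list(t(matrix(g, h * w, c0))))
}

ag_concat <- function(xs) {
  vals <- lapply(xs, function(x) x$val)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs)))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  ag_node(out, xs, function(g) {
    at <- 0L
    lapply(cs, function(ci) {
      sl <- g[, , at + seq_len(ci), drop = FALSE]
      at <<- at + ci
      sl
    })
  })
}

ag_matmul <- function(a, b) {
  ag_node(a$val %*% b$val, list(a, b),
          function(g) list(g %*% t(b$val), t(a$val) %*% g))
}

ag_transpose <- function(a) {
  ag_node(t(a$val), list(a), function(g) list(t(g)))
}

# --- softmax --------------------------------------------------------------

softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1, max))
  z / rowSums(z)
}

softmax_cols <- function(m) {
  z <- exp(sweep(m, 2, apply(m, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

ag_softmax <- function(x, axis = c("row", "col")) {
  axis <- match.arg(axis)
  p <- if (axis == "row") softmax_rows(x$val) else softmax_cols(x$val)
  ag_node(p, list(x), function(g) {
    if (axis == "row") list(p * (g - rowSums(g * p)))
    else list(p * sweep(g, 2, colSums(g * p)))
  })
}

# --- conv / pool / resize (C++ kernels) ----------------------------------

ag_conv <- function(x, w, b, pad = NULL) {
  k <- dim(w$val)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  y <- .conv2d_fwd(x$val, w$val, b$val, k, pad)
  ag_node(y, list(x, w, b), function(g) {
    bw <- .conv2d_bwd(x$val, w$val, g, k, pad)
    list(bw$dx, bw$dw, as.numeric(bw$db))
  })
}

ag_maxpool <- function(x) {
  d <- dim(x$val)
  fw <- .maxpool2_fwd(x$val)
  ag_node(fw$y, list(x), function(g) list(.maxpool2_bwd(g, fw$idx, d[1], d[2])))
}

ag_resize <- function(x, oh, ow) {
  d <- dim(x$val)
  if (d[1] == oh && d[2] == ow) return(x)
  ag_node(.resize_bilinear_fwd(x$val, oh, ow), list(x),
          function(g) list(.resize_bilinear_bwd(g, d[1], d[2])))
}

# --- group normalization --------------------------------------------------

ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$val)
  h <- d[1]; w <- d[2]; c0 <- d[3]
  stopifnot(c0 %% groups == 0)
  cg <- c0 %/% groups
  m <- h * w * cg
  xg <- array(x$val, c(h * w * cg, groups))
  mu <- colMeans(xg)
  va <- colMeans(sweep(xg, 2, mu)^2)
  istd <- 1 / sqrt(va + eps)
  xhat_g <- sweep(sweep(xg, 2, mu), 2, istd, "*")
  xhat <- array(xhat_g, c(h, w, c0))
  gam <- rep(gamma$val, each = h * w)
  y <- array(xhat * gam + rep(beta$val, each = h * w), c(h, w, c0))
  ag_node(y, list(x, gamma, beta), function(g) {
    gmat <- matrix(g, h * w, c0)
    xh <- matrix(xhat, h * w, c0)
    dgamma <- colSums(gmat * xh)
    dbeta <- colSums(gmat)
    dxhat <- array(g * gam, c(h * w * cg, groups))
    xh_g <- array(xhat, c(h * w * cg, groups))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xh_g)
    dx <- sweep(sweep(m * dxhat, 2, s1) - sweep(xh_g, 2, s2, "*"),
                2, istd / m, "*")
    list(array(dx, c(h, w, c0)), dgamma, dbeta)
  })
}

# --- heads and losses -----------------------------------------------------

# global average pooling: h x w x c -> length-c vector
ag_gap <- function(x) {
  d <- dim(x$val)
  v <- colMeans(matrix(x$val, d[1] * d[2], d[3]))
  ag_node(v, list(x), function(g) {
    list(array(rep(g, each = d[1] * d[2]) / (d[1] * d[2]), d))
  })
}

# fully connected: W (out x in) %*% v + b
ag_affine <- function(v, w, b) {
  ag_node(as.numeric(w$val %*% v$val + b$val), list(v, w, b),
          function(g) list(as.numeric(t(w$val) %*% g), outer(g, v$val), g))
}

# numerically stable mean binary cross-entropy on logits
ag_bce_logits <- function(z, target) {
  n <- length(z$val)
  zl <- z$val
  val <- mean(pmax(zl, 0) - zl * target + log1p(exp(-abs(zl))))
  ag_node(val, list(z), function(g) {
    p <- 1 / (1 + exp(-zl))
    list(g * (p - target) / n)
  })
}

# soft Dice loss on probabilities: 1 - (2*sum(p*t)+s)/(sum(p)+sum(t)+s)
ag_dice_loss <- function(p, target, smooth = 1) {
  a <- sum(p$val * target)
  b <- sum(p$val) + sum(target)
  val <- 1 - (2 * a + smooth) / (b + smooth)
  ag_node(val, list(p), function(g) {
    list(g * (-(2 * target * (b + smooth) - (2 * a + smooth)) / (b + smooth)^2))
  })
}

# mean Jensen-Shannon divergence between sigmoid(z) and fixed probs q,
# both read as two-point distributions (p, 1-p); dJS/dp = 0.5*ln(p/m) -
# 0.5*ln((1-p)/(1-m)) with m = (p+q)/2.
ag_js_binary <- function(z, q, eps = 1e-7) {
  n <- length(z$val)
  p <- pmin(pmax(1 / (1 + exp(-z$val)), eps), 1 - eps)
  qc <- pmin(pmax(q, eps), 1 - eps)
  m <- (p + qc) / 2
  js <- 0.5 * (p * log(p / m) + (1 - p) * log((1 - p) / (1 - m))) +
        0.5 * (qc * log(qc / m) + (1 - qc) * log((1 - qc) / (1 - m)))
  ag_node(mean(js), list(z), function(g) {
    djs_dp <- 0.5 * log(p / m) - 0.5 * log((1 - p) / (1 - m))
    list(g * djs_dp * p * (1 - p) / n)
  })
}
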