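# Multilevel guided self-aware attention module (MGAM): a channel-level
# transformer self-attention component (TSAC) and a position-level global
# context aggregation component (GCAC), fused with the encoder feature
# through two learnable scale parameters initialized to 0 -- so the module is
# exactly the identity at initialization.
#
# Feature maps are h x w x c arrays; the flattened form is a c x n matrix
# with n = h * w and position index = row + h * (col - 1).

fm_flatten <- function(fm) {
  d <- dim(fm)
  t(matrix(fm, d[1] * d[2], d[3]))
}

fm_unflatten <- function(m, h, w) array(t(m), c(h, w, nrow(m)))

#' Add the learned position encoding to a feature map
#'
#' @param fm h x w x c feature map.
#' @param embedding h x w x c learned position embedding.
#' @return the elementwise sum, same shape.
#' @export
position_encode <- function(fm, embedding) {
  if (!identical(dim(fm), dim(embedding)))
    stop("position embedding shape must match the feature map")
  fm + embedding
}

#' Project a feature map to query, key and value matrices
#'
#' The map is flattened to `c x (h*w)` and multiplied by per-channel linear
#' projections: `Q = W_q F`, `K = W_k F`, `V = W_v F`.
#'
#' @param fm h x w x c feature map.
#' @param w_q,w_k,w_v c x c projection matrices.
#' @return list with matrices `Q`, `K`, `V` (each `c x (h*w)`).
#' @export
tsac_project <- function(fm, w_q, w_k, w_v) {
  f <- fm_flatten(fm)
  c0 <- nrow(f)
  for (m in list(w_q, w_k, w_v))
    if (!is.matrix(m) || ncol(m) != c0) stop("projection shape mismatch")
  list(Q = w_q %*% f, K = w_k %*% f, V = w_v %*% f)
}

#' Scaled dot-product channel attention
#'
#' Computes the contextual attention map `CAM = softmax(Q K' / sqrt(d_k))`
#' (c x c, rows normalized) and returns `CAM V`.  Logits are shifted by their
#' row maximum before exponentiation.
#'
#' @param Q,K,V `c x n` matrices.
#' @param d_k scaling dimension (> 0).
#' @param shape optional `c(h, w)`; when given, the output is reshaped to an
#'   h x w x c feature map, otherwise the `c x n` matrix is returned.
#' @return list with `out` and the attention map `cam`.
#' @export
tsac_attend <- function(Q, K, V, d_k, shape = NULL) {
  if (d_k <= 0) stop("d_k must be > 0")
  cam <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  out <- cam %*% V
  if (!is.null(shape)) out <- fm_unflatten(out, shape[1], shape[2])
  list(out = out, cam = cam)
}

#' Project a feature map for global context aggregation
#'
#' `U` is the reshaped `c0 x n` input; `V` and `W` come from two 1x1
#' convolutions (channel linear maps) down to `c1 = max(1, c0 / 8)` channels.
#'
#' @param fm h x w x c0 feature map.
#' @param w_v,w_w `c1 x c0` projection matrices of the two 1x1 convolutions.
#' @return list with `U` (c0 x n), `V` and `W` (c1 x n).
#' @export
gcac_project <- function(fm, w_v, w_w) {
  u <- fm_flatten(fm)
  stopifnot(ncol(w_v) == nrow(u), ncol(w_w) == nrow(u),
            nrow(w_v) == nrow(w_w))
  list(U = u, V = w_v %*% u, W = w_w %*% u)
}

#' Reduced channel count of the GCAC projections
#' @param c0 input channel count.
#' @export
gcac_c1 <- function(c0) max(1L, as.integer(c0) %/% 8L)

#' Position attention map
#'
#' `L[i, j] = exp(<V_i, W_j>) / sum_i exp(<V_i, W_j>)`, a softmax over the
#' source position `i` for each target position `j`: columns sum to 1.
#'
#' @param V,W `c1 x n` matrices (columns index positions).
#' @return n x n position attention map.
#' @export
gcac_attention <- function(V, W) {
  stopifnot(identical(dim(V), dim(W)))
  softmax_cols(t(V) %*% W)
}

#' Aggregate features with a position attention map
#'
#' Output position `j` is `sum_i L[i, j] * U[, i]`, i.e. `U %*% L`.
#'
#' @param L n x n position attention map.
#' @param U `c0 x n` feature matrix.
#' @param shape optional `c(h, w)` to reshape the result to h x w x c0.
#' @export
gcac_aggregate <- function(L, U, shape = NULL) {
  stopifnot(ncol(U) == nrow(L), nrow(L) == ncol(L))
  out <- U %*% L
  if (!is.null(shape)) out <- fm_unflatten(out, shape[1], shape[2])
  out
}

#' Fuse attention outputs with the encoder feature
#'
#' `a1 * tsac_out + a2 * gcac_out + enc`; with the scale parameters at their
#' initial value 0 this is exactly the encoder feature.
#'
#' @param enc,tsac_out,gcac_out equal-shaped feature maps.
#' @param a1,a2 learnable scalars.
#' @export
mgam_fuse <- function(enc, tsac_out, gcac_out, a1 = 0, a2 = 0) {
  if (!identical(dim(enc), dim(tsac_out)) ||
      !identical(dim(enc), dim(gcac_out)))
    stop("fusion inputs must share one shape")
  a1 * tsac_out + a2 * gcac_out + enc
}

#' The alpha grid explored for the fusion weights
#'
#' Fixed-weight `(a1, a2)` combinations evaluated in the fusion-weight
#' experiment mode.
#' @export
mgam_alpha_grid <- function() {
  list(c(1, 0), c(0.75, 0.25), c(0, 1), c(0.5, 0.5), c(0.25, 0.75))
}

# --- autodiff path used inside the network -------------------------------

# node-level forward of the full MGAM block; `lv` is the named list of leaf
# nodes, `px` the parameter-name prefix (e.g. "mgam."), `enc` the bottleneck
# feature node
mgam_forward_ag <- function(lv, px, enc, n_heads = 1L) {
  d <- dim(enc$val)
  h <- d[1]; w <- d[2]; c0 <- d[3]
  pe <- ag_add(enc, lv[[paste0(px, "pos")]])
  f <- ag_c2m(pe)
  q <- ag_matmul(lv[[paste0(px, "wq")]], f)
  k <- ag_matmul(lv[[paste0(px, "wk")]], f)
  v <- ag_matmul(lv[[paste0(px, "wv")]], f)
  d_k <- c0 / n_heads
  heads <- split(seq_len(c0), rep(seq_len(n_heads), each = c0 %/% n_heads))
  outs <- lapply(heads, function(idx) {
    qh <- ag_rows(q, idx); kh <- ag_rows(k, idx); vh <- ag_rows(v, idx)
    cam <- ag_softmax(ag_scale(ag_matmul(qh, ag_transpose(kh)), 1 / sqrt(d_k)),
                      "row")
    ag_matmul(cam, vh)
  })
  tsac_m <- if (n_heads == 1L) outs[[1]] else
    ag_matmul(lv[[paste0(px, "wo")]], ag_rbind(outs))
  tsac <- ag_m2c(tsac_m, h, w)

  vv <- ag_conv(enc, lv[[paste0(px, "gcv.w")]], lv[[paste0(px, "gcv.b")]])
  ww <- ag_conv(enc, lv[[paste0(px, "gcw.w")]], lv[[paste0(px, "gcw.b")]])
  u <- ag_c2m(enc)
  lmap <- ag_softmax(ag_matmul(ag_transpose(ag_c2m(vv)), ag_c2m(ww)), "col")
  gcac <- ag_m2c(ag_matmul(u, lmap), h, w)

  ag_add(ag_add(ag_smul(lv[[paste0(px, "a1")]], tsac),
                ag_smul(lv[[paste0(px, "a2")]], gcac)),
         enc)
}

ag_rows <- function(x, idx) {
  nr <- nrow(x$val)
  ag_node(x$val[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nr, ncol(g))
    out[idx, ] <- g
    list(out)
  })
}

ag_rbind <- function(xs) {
  nrs <- vapply(xs, function(x) nrow(x$val), numeric(1))
  ag_node(do.call(rbind, lapply(xs, function(x) x$val)), xs, function(g) {
    at <- 0L
    lapply(nrs, function(nr) {
      sl <- g[at + seq_len(nr), , drop = FALSE]
      at <<- at + nr
      sl
    })
  })
}
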