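# Spatial-channel synergistic attention (SCSA): a shared multi-semantic
# spatial gate (SMSA) followed serially by a progressive channel-wise
# self-attention gate (PCSA). Both gates are multiplicative sigmoids, so the
# block rescales features without changing shape.

#' Directional global average pooling
#'
#' Collapses a (B, C, H, W) feature map into two one-dimensional sequences by
#' averaging over height and over width respectively. These are the inputs of
#' the multi-semantic spatial gate.
#'
#' @param x numeric rank-4 array (B, C, H, W).
#' @return list with `xh` of shape (B, C, W) (mean over H) and `xw` of shape
#'   (B, C, H) (mean over W).
#' @examples
#' x <- array(3, c(1, 4, 8, 8))
#' p <- directional_pool(x)
#' dim(p$xh)  # 1 4 8
#' @export
directional_pool <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("directional_pool: input must be rank-4 (B,C,H,W)")
  h <- directional_pool_ag(NULL, list(id = NA_integer_, value = x))
  list(xh = hval(h$xh), xw = hval(h$xw))
}

directional_pool_ag <- function(tp, x) {
  d <- dim(hval(x))
  xh <- ag_reshape(tp, ag_mean_axes(tp, x, 3L), c(d[1], d[2], d[4]))
  xw <- ag_reshape(tp, ag_mean_axes(tp, x, 4L), c(d[1], d[2], d[3]))
  list(xh = xh, xw = xw)
}

#' Shared multi-semantic spatial attention (SMSA) module
#'
#' Splits channels into `group_count` equal sub-features; each sub-feature of
#' both pooled sequences passes through a depthwise 1-D convolution of kernel
#' size `kernel_sizes[i]` (weights shared between the height- and width-wise
#' sequences, hence "shared"). The concatenated responses are group-normalized
#' (4 groups) and squashed by a sigmoid, giving one gate along each spatial
#' axis; the input map is multiplied by both gates.
#'
#' @param c_in channel count; must be divisible by `group_count`.
#' @param kernel_sizes four odd depthwise kernel sizes (default 3, 5, 7, 9).
#' @param group_count number of sub-features and GN groups (default 4).
#' @return an SMSA module usable with [sd_forward()].
#' @export
new_smsa <- function(c_in, kernel_sizes = c(3L, 5L, 7L, 9L), group_count = 4L) {
  if (length(kernel_sizes) != 4L || any(kernel_sizes %% 2L != 1L) ||
      any(kernel_sizes < 1L)) {
    stop("kernel_sizes must be four odd integers >= 1")
  }
  if (c_in %% group_count != 0L) {
    stop(sprintf("SMSA channel count %d not divisible by group count %d",
                 c_in, group_count))
  }
  cg <- c_in %/% group_count
  params <- list()
  for (i in seq_len(4L)) {
    k <- kernel_sizes[i]
    params[[paste0("w", i)]] <- init_unif(c(cg, k), k)
    params[[paste0("b", i)]] <- rep(0, cg)
  }
  params$gn_h_gamma <- rep(1, c_in)
  params$gn_h_beta <- rep(0, c_in)
  params$gn_w_gamma <- rep(1, c_in)
  params$gn_w_beta <- rep(0, c_in)
  new_module("sd_smsa", params = params, c_in = c_in,
             kernel_sizes = as.integer(kernel_sizes),
             group_count = as.integer(group_count))
}

# shared depthwise-conv stack applied to one pooled sequence (B, C, L)
smsa_gate <- function(mod, tp, lv, seq_h, gn_gamma, gn_beta) {
  cg <- mod$c_in %/% mod$group_count
  parts <- vector("list", 4L)
  for (i in seq_len(4L)) {
    sub <- ag_narrow(tp, seq_h, 2L, (i - 1L) * cg + 1L, i * cg)
    parts[[i]] <- ag_dwconv1d(tp, sub, lv[[paste0("w", i)]], lv[[paste0("b", i)]])
  }
  y <- ag_concat(tp, parts, 2L)
  y <- ag_gn(tp, y, gn_gamma, gn_beta, groups = mod$group_count, eps = 1e-5)
  ag_sigmoid(tp, y)
}

#' @export
sd_forward.sd_smsa <- function(mod, tp, x, training = FALSE) {
  d <- dim(hval(x))
  if (d[2] != mod$c_in) {
    stop(sprintf("SMSA built for %d channels, got %d", mod$c_in, d[2]))
  }
  lv <- mod_leaves(mod, tp)
  p <- directional_pool_ag(tp, x)
  attn_h <- smsa_gate(mod, tp, lv, p$xh, lv$gn_h_gamma, lv$gn_h_beta)  # (B,C,W)
  attn_w <- smsa_gate(mod, tp, lv, p$xw, lv$gn_w_gamma, lv$gn_w_beta)  # (B,C,H)
  gh <- ag_reshape(tp, attn_h, c(d[1], d[2], 1L, d[4]))
  gw <- ag_reshape(tp, attn_w, c(d[1], d[2], d[3], 1L))
  ag_mul(tp, ag_mul(tp, x, gw), gh)
}

#' Progressive channel-wise self-attention (PCSA) module
#'
#' Compresses the spatially gated map to a small token grid by adaptive
#' average pooling (default 7x7, clamped to the input size), forms Q/K/V by
#' per-channel depthwise projections (kernel 1), computes channel-channel
#' scaled dot-product attention (rows softmax-normalized), pools the attention
#' output to one value per channel and applies it as a sigmoid channel gate.
#'
#' @param c_in channel count.
#' @param pooled_resolution target (H', W') of the compression, default c(7, 7).
#' @param scale_denominator "sqrt_C" (default, standard scaled dot product) or
#'   "C".
#' @return a PCSA module usable with [sd_forward()].
#' @export
new_pcsa <- function(c_in, pooled_resolution = c(7L, 7L),
                     scale_denominator = c("sqrt_C", "C")) {
  scale_denominator <- match.arg(scale_denominator)
  stopifnot(all(pooled_resolution >= 1L))
  # depthwise kernel-1 projections: one scale + shift per channel
  params <- list(wq = as.numeric(init_unif(c_in, 1)), bq = rep(0, c_in),
                 wk = as.numeric(init_unif(c_in, 1)), bk = rep(0, c_in),
                 wv = as.numeric(init_unif(c_in, 1)), bv = rep(0, c_in))
  new_module("sd_pcsa", params = params, c_in = c_in,
             pooled = as.integer(pooled_resolution),
             scale_denominator = scale_denominator)
}

#' @export
sd_forward.sd_pcsa <- function(mod, tp, x, training = FALSE) {
  d <- dim(hval(x))
  C <- d[2]
  if (C != mod$c_in) stop(sprintf("PCSA built for %d channels, got %d", mod$c_in, C))
  oh <- min(mod$pooled[1], d[3])
  ow <- min(mod$pooled[2], d[4])
  lv <- mod_leaves(mod, tp)
  xp <- ag_adaptive_avgpool2d(tp, x, oh, ow)
  n <- oh * ow
  xt <- ag_reshape(tp, xp, c(d[1], C, n))                 # token axis last
  proj <- function(w, b) {
    ag_add(tp, ag_mul(tp, xt, ag_reshape(tp, w, c(1L, C, 1L))),
           ag_reshape(tp, b, c(1L, C, 1L)))
  }
  q <- proj(lv$wq, lv$bq)
  k <- proj(lv$wk, lv$bk)
  v <- proj(lv$wv, lv$bv)
  denom <- if (mod$scale_denominator == "sqrt_C") sqrt(C) else C
  scores <- ag_mulc(tp, ag_bmm(tp, q, ag_aperm(tp, k, c(1L, 3L, 2L))), 1 / denom)
  attn <- ag_softmax_last(tp, scores)                     # (B, C, C), rows sum 1
  xa <- ag_bmm(tp, attn, v)                               # (B, C, n)
  gate <- ag_sigmoid(tp, ag_mean_axes(tp, xa, 3L))        # (B, C, 1)
  ag_mul(tp, x, ag_reshape(tp, gate, c(d[1], C, 1L, 1L)))
}

#' Spatial-channel synergistic attention (SCSA) block
#'
#' Serial composition: the multi-semantic spatial gate first, the progressive
#' channel self-attention gate second. Output shape equals input shape.
#'
#' @inheritParams new_smsa
#' @inheritParams new_pcsa
#' @return an SCSA module usable with [sd_forward()].
#' @export
new_scsa <- function(c_in, kernel_sizes = c(3L, 5L, 7L, 9L), group_count = 4L,
                     pooled_resolution = c(7L, 7L),
                     scale_denominator = "sqrt_C") {
  new_module("sd_scsa",
             children = list(smsa = new_smsa(c_in, kernel_sizes, group_count),
                             pcsa = new_pcsa(c_in, pooled_resolution,
                                             scale_denominator)),
             c_in = c_in)
}

#' @export
sd_forward.sd_scsa <- function(mod, tp, x, training = FALSE) {
  sd_forward(mod$children$pcsa, tp,
             sd_forward(mod$children$smsa, tp, x, training), training)
}

#' Run an attention/convolution module on a plain array
#'
#' Convenience wrapper: wraps `x` in a handle, runs [sd_forward()] in eager
#' mode, returns the plain output array.
#'
#' @param mod module.
#' @param x numeric array.
#' @param training logical.
#' @return numeric array of the module output.
#' @export
module_apply <- function(mod, x, training = FALSE) {
  hval(sd_forward(mod, NULL, list(id = NA_integer_, value = x), training))
}
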