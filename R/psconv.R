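# Pinwheel-shaped convolution (PSConv): four directional branches, each an
# asymmetrically zero-padded 1x3 or 3x1 convolution + BN + SiLU, concatenated
# and fused by a grouped 2x2 convolution. The asymmetric pads are arranged so
# every branch emits h' = h/s + 1, w' = w/s + 1, and the unpadded 2x2 fusion
# brings the map to exactly h/s x w/s.

#' Asymmetric zero padding
#'
#' Pads a (B, C, H, W) feature map with zeros; `pad` gives the pixel counts on
#' the left, right, top and bottom edges.
#'
#' @param x numeric rank-4 array.
#' @param pad integer vector c(left, right, top, bottom), all >= 0.
#' @return padded array of shape (B, C, H + top + bottom, W + left + right).
#' @examples
#' dim(asymmetric_pad(array(0, c(1, 3, 8, 8)), c(1, 0, 0, 3)))  # 1 3 11 9
#' @export
asymmetric_pad <- function(x, pad) {
  if (length(dim(x)) != 4L) stop("asymmetric_pad: input must be rank-4")
  if (length(pad) != 4L || any(pad < 0)) stop("pad must be 4 non-negative ints")
  if (all(pad == 0L)) return(x)
  hval(ag_pad2d(NULL, list(id = NA_integer_, value = x), as.integer(pad)))
}

# Branch layouts. Each row: left, right, top, bottom padding and the kernel
# orientation ("h" = 1x3, "v" = 3x1).
#  - "pinwheel": pads of 3 along the kernel's long axis, pads of 1 along the
#    short axis, one branch per direction; every branch satisfies
#    h' = h/s + 1, w' = w/s + 1 for s in {1, 2}.
#  - "printed": the literal pad/kernel pairs as printed in the source design
#    (P(1,0,0,3)+1x3 etc.); kept for reference, branch output sizes differ.
psconv_branch_table <- function(pairing = c("pinwheel", "printed")) {
  pairing <- match.arg(pairing)
  if (pairing == "pinwheel") {
    list(list(pad = c(0L, 3L, 0L, 1L), orient = "h"),
         list(pad = c(3L, 0L, 1L, 0L), orient = "h"),
         list(pad = c(0L, 1L, 3L, 0L), orient = "v"),
         list(pad = c(1L, 0L, 0L, 3L), orient = "v"))
  } else {
    list(list(pad = c(1L, 0L, 0L, 3L), orient = "h"),
         list(pad = c(0L, 3L, 0L, 1L), orient = "v"),
         list(pad = c(0L, 1L, 3L, 0L), orient = "h"),
         list(pad = c(3L, 0L, 1L, 0L), orient = "v"))
  }
}

#' Pinwheel-shaped convolution module
#'
#' @param c1 input channels.
#' @param c2 output channels; must be divisible by 4 (branch width c2/4).
#' @param s stride of the directional branches (1 or 2).
#' @param pairing branch pad/kernel layout; see Details.
#' @details The default `"pinwheel"` pairing places each branch's 3-pixel pad
#'   along its kernel's long axis and the 1-pixel pad along the short axis, so
#'   all four branches produce identical spatial dims h/s + 1 x w/s + 1 (the
#'   constructor asserts this); the `"printed"` alternative keeps the literal
#'   pad/kernel tuples of the original design sheet and does not. The 2x2
#'   fusion convolution uses 4 channel groups (one per direction), which is
#'   what keeps the block lighter than a standard 3x3 convolution.
#' @return a PSConv module usable with [sd_forward()].
#' @export
new_psconv <- function(c1, c2, s = 1L, pairing = "pinwheel") {
  if (c2 %% 4L != 0L) {
    stop(sprintf("PSConv output channels %d not divisible by 4", c2))
  }
  cp <- c2 %/% 4L
  br <- psconv_branch_table(pairing)
  children <- list()
  for (i in seq_len(4L)) {
    k <- if (br[[i]]$orient == "h") c(1L, 3L) else c(3L, 1L)
    children[[paste0("branch", i)]] <-
      new_cbs(c1, cp, k = k, s = s, p = br[[i]]$pad)
  }
  children$fuse <- new_cbs(c2, c2, k = 2L, s = 1L, p = c(0L, 0L, 0L, 0L), g = 4L)
  if (pairing == "pinwheel") {
    # assert the spatial contract h' = h/s + 1 symbolically for a probe size
    for (h0 in c(8L, 16L)) {
      for (i in seq_len(4L)) {
        p <- br[[i]]$pad
        k <- if (br[[i]]$orient == "h") c(1L, 3L) else c(3L, 1L)
        hp <- (h0 + p[3] + p[4] - k[1]) %/% s + 1L
        wp <- (h0 + p[1] + p[2] - k[2]) %/% s + 1L
        stopifnot(hp == h0 %/% s + 1L, wp == h0 %/% s + 1L)
      }
    }
  }
  new_module("sd_psconv", children = children, c1 = c1, c2 = c2,
             s = as.integer(s), pairing = pairing)
}

#' @export
sd_forward.sd_psconv <- function(mod, tp, x, training = FALSE) {
  parts <- lapply(1:4, function(i) {
    sd_forward(mod$children[[paste0("branch", i)]], tp, x, training)
  })
  dims <- lapply(parts, function(p) dim(hval(p)))
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L) {
    stop("PSConv branches produced unequal spatial dims (check pairing)")
  }
  sd_forward(mod$children$fuse, tp, ag_concat(tp, parts, 2L), training)
}

#' Dual-path cross-stage block built on pinwheel convolutions (C3k2-PSConv)
#'
#' Entry 1x1 conv to the hidden width, channel split into two equal halves,
#' one half kept as an identity path, the other passed through two sequential
#' PSConv modules, concatenation, exit 1x1 conv.
#'
#' @param c1 input channels.
#' @param c2 output channels (also the hidden width); must be even with
#'   c2/2 divisible by 4.
#' @return a C3k2-PSConv module usable with [sd_forward()].
#' @export
new_c3k2_psconv <- function(c1, c2) {
  if (c2 %% 2L != 0L) stop("C3k2-PSConv hidden width must be even")
  ch <- c2 %/% 2L
  if (ch %% 4L != 0L) {
    stop(sprintf("C3k2-PSConv half width %d not divisible by 4", ch))
  }
  new_module("sd_c3k2ps",
             children = list(entry = new_cbs(c1, c2, 1L),
                             ps1 = new_psconv(ch, ch, 1L),
                             ps2 = new_psconv(ch, ch, 1L),
                             exit = new_cbs(c2, c2, 1L)),
             c1 = c1, c2 = c2, ch = ch)
}

#' @export
sd_forward.sd_c3k2ps <- function(mod, tp, x, training = FALSE) {
  y <- sd_forward(mod$children$entry, tp, x, training)
  keep <- ag_narrow(tp, y, 2L, 1L, mod$ch)
  tr <- ag_narrow(tp, y, 2L, mod$ch + 1L, 2L * mod$ch)
  tr <- sd_forward(mod$children$ps1, tp, tr, training)
  tr <- sd_forward(mod$children$ps2, tp, tr, training)
  sd_forward(mod$children$exit, tp, ag_concat(tp, list(keep, tr), 2L), training)
}
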