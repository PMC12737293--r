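# Module system: each layer is an environment holding `params` (named arrays),
# `buffers` (running statistics), and `children` (sub-modules). Environments
# give reference semantics, so optimizer updates and running-stat updates
# mutate in place. `sd_forward()` is the single dispatch point; passing a tape
# records the computation for backprop, passing NULL runs eager inference.

new_module <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$buffers)) e$buffers <- list()
  if (is.null(e$children)) e$children <- list()
  class(e) <- c(class, "sd_module")
  e
}

# fan-in uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)); draws from the
# session RNG, which build_model() seeds once for reproducibility
init_unif <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dims)
}

#' Forward pass through a layer module
#'
#' @param mod a module created by one of the `new_*` constructors.
#' @param tp an autodiff tape from [ag_tape()], or NULL for eager inference.
#' @param x input handle (or list of handles for concat-type modules).
#' @param training logical; batch-norm layers use batch statistics and update
#'   running statistics when TRUE.
#' @return an output handle (list(id, value)).
#' @export
sd_forward <- function(mod, tp, x, training = FALSE) UseMethod("sd_forward")

# create tape leaves for this module's own params, cache for grad retrieval
mod_leaves <- function(mod, tp) {
  lv <- lapply(mod$params, function(p) ag_leaf(tp, p))
  if (!is.null(tp)) mod$.leaves <- lv   # keep tape leaves across eager calls
  lv
}

# recursive walk: references to every parameter array, named by dotted path
sd_param_refs <- function(mod, path = "") {
  out <- list()
  for (nm in names(mod$params)) {
    out[[paste0(path, nm)]] <- list(env = mod, key = nm)
  }
  for (cn in names(mod$children)) {
    out <- c(out, sd_param_refs(mod$children[[cn]], paste0(path, cn, ".")))
  }
  out
}

# gradients for every parameter after ag_backward(); same naming as refs
sd_param_grads <- function(mod, grads, path = "") {
  out <- list()
  for (nm in names(mod$params)) {
    id <- mod$.leaves[[nm]]$id
    out[[paste0(path, nm)]] <- if (!is.na(id)) grads[[id]] else NULL
  }
  for (cn in names(mod$children)) {
    out <- c(out, sd_param_grads(mod$children[[cn]], grads, paste0(path, cn, ".")))
  }
  out
}

# (raw trainable count, BN channel count) for the subtree; the BN channel
# count is what conv+BN fusion removes (each fused conv keeps a bias)
sd_param_census <- function(mod) {
  raw <- sum(vapply(mod$params, length, numeric(1)), 0)
  bn <- if (inherits(mod, "sd_bn2d")) length(mod$params$gamma) else 0
  for (cn in names(mod$children)) {
    cc <- sd_param_census(mod$children[[cn]])
    raw <- raw + cc[1]
    bn <- bn + cc[2]
  }
  c(raw, bn)
}

# flatten / restore all parameter values (checkpointing, optimizer)
sd_get_params <- function(mod) {
  refs <- sd_param_refs(mod)
  lapply(refs, function(r) r$env$params[[r$key]])
}

sd_set_params <- function(mod, values) {
  refs <- sd_param_refs(mod)
  stopifnot(all(names(values) %in% names(refs)))
  for (nm in names(values)) {
    r <- refs[[nm]]
    stopifnot(length(r$env$params[[r$key]]) == length(values[[nm]]))
    v <- values[[nm]]
    dim(v) <- dim(r$env$params[[r$key]])
    r$env$params[[r$key]] <- v
  }
  invisible(mod)
}

# ---- basic layers -----------------------------------------------------------

new_conv2d <- function(c1, c2, k, s = 1L, p = NULL, g = 1L, bias = FALSE) {
  kh <- if (length(k) == 2L) k[1] else k
  kw <- if (length(k) == 2L) k[2] else k
  if (is.null(p)) p <- c(kw %/% 2L, kw %/% 2L, kh %/% 2L, kh %/% 2L)
  if (length(p) == 1L) p <- rep(p, 4L)
  stopifnot(c1 %% g == 0L, c2 %% g == 0L)
  fan_in <- (c1 %/% g) * kh * kw
  params <- list(w = init_unif(c(c2, c1 %/% g, kh, kw), fan_in))
  if (bias) params$b <- as.numeric(init_unif(c2, fan_in))
  new_module("sd_conv2d", params = params, stride = as.integer(s),
             pad = as.integer(p), groups = as.integer(g),
             c1 = c1, c2 = c2)
}

#' @export
sd_forward.sd_conv2d <- function(mod, tp, x, training = FALSE) {
  lv <- mod_leaves(mod, tp)
  ag_conv2d(tp, x, lv$w, lv$b, stride = mod$stride, pad = mod$pad,
            groups = mod$groups)
}

new_bn2d <- function(c, eps = 1e-3, momentum = 0.03) {
  new_module("sd_bn2d",
             params = list(gamma = rep(1, c), beta = rep(0, c)),
             buffers = list(rmean = rep(0, c), rvar = rep(1, c)),
             eps = eps, momentum = momentum, nch = c)
}

#' @export
sd_forward.sd_bn2d <- function(mod, tp, x, training = FALSE) {
  lv <- mod_leaves(mod, tp)
  h <- ag_bn2d(tp, x, lv$gamma, lv$beta, mod$buffers$rmean, mod$buffers$rvar,
               training = training, eps = mod$eps)
  if (training) {
    m <- mod$momentum
    mod$buffers$rmean <- (1 - m) * mod$buffers$rmean + m * attr(h, "batch_mean")
    mod$buffers$rvar <- (1 - m) * mod$buffers$rvar + m * attr(h, "batch_var")
  }
  h
}

# Conv + BN + SiLU, the detector's standard convolution block ("CBS")
new_cbs <- function(c1, c2, k = 1L, s = 1L, p = NULL, g = 1L) {
  new_module("sd_cbs",
             children = list(conv = new_conv2d(c1, c2, k, s, p, g, bias = FALSE),
                             bn = new_bn2d(c2)),
             c1 = c1, c2 = c2)
}

#' @export
sd_forward.sd_cbs <- function(mod, tp, x, training = FALSE) {
  y <- sd_forward(mod$children$conv, tp, x, training)
  y <- sd_forward(mod$children$bn, tp, y, training)
  ag_silu(tp, y)
}

new_bottleneck <- function(c1, c2, shortcut = TRUE, e = 1.0) {
  ch <- as.integer(c2 * e)
  new_module("sd_bottleneck",
             children = list(cv1 = new_cbs(c1, ch, 1L),
                             cv2 = new_cbs(ch, c2, 3L)),
             shortcut = shortcut && c1 == c2)
}

#' @export
sd_forward.sd_bottleneck <- function(mod, tp, x, training = FALSE) {
  y <- sd_forward(mod$children$cv2, tp,
                  sd_forward(mod$children$cv1, tp, x, training), training)
  if (mod$shortcut) ag_add(tp, x, y) else y
}

# cross-stage-partial block with n inner bottlenecks
new_c3 <- function(c1, c2, n = 1L, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(c2 * e)
  m <- lapply(seq_len(n), function(i) new_bottleneck(ch, ch, shortcut, e = 1.0))
  names(m) <- paste0("m", seq_len(n))
  new_module("sd_c3",
             children = c(list(cv1 = new_cbs(c1, ch, 1L),
                               cv2 = new_cbs(c1, ch, 1L)),
                          m,
                          list(cv3 = new_cbs(2L * ch, c2, 1L))),
             n = n, c1 = c1, c2 = c2)
}

#' @export
sd_forward.sd_c3 <- function(mod, tp, x, training = FALSE) {
  a <- sd_forward(mod$children$cv1, tp, x, training)
  for (i in seq_len(mod$n)) {
    a <- sd_forward(mod$children[[paste0("m", i)]], tp, a, training)
  }
  b <- sd_forward(mod$children$cv2, tp, x, training)
  sd_forward(mod$children$cv3, tp, ag_concat(tp, list(a, b), 2L), training)
}

# fast spatial pyramid pooling: cascaded max-pools sharing one kernel
new_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  new_module("sd_sppf",
             children = list(cv1 = new_cbs(c1, ch, 1L),
                             cv2 = new_cbs(4L * ch, c2, 1L)),
             k = as.integer(k))
}

#' @export
sd_forward.sd_sppf <- function(mod, tp, x, training = FALSE) {
  y0 <- sd_forward(mod$children$cv1, tp, x, training)
  p <- mod$k %/% 2L
  y1 <- ag_maxpool2d(tp, y0, mod$k, 1L, p)
  y2 <- ag_maxpool2d(tp, y1, mod$k, 1L, p)
  y3 <- ag_maxpool2d(tp, y2, mod$k, 1L, p)
  sd_forward(mod$children$cv2, tp, ag_concat(tp, list(y0, y1, y2, y3), 2L),
             training)
}

new_upsample <- function() new_module("sd_upsample")
#' @export
sd_forward.sd_upsample <- function(mod, tp, x, training = FALSE) ag_upsample2(tp, x)

new_concat <- function() new_module("sd_concat")
#' @export
sd_forward.sd_concat <- function(mod, tp, x, training = FALSE) ag_concat(tp, x, 2L)

# three-scale anchor-based detection head: one biased 1x1 conv per scale,
# output reshaped to (B, anchors, gy, gx, 5 + nc)
new_detect <- function(nc, ch, anchors, strides = c(8L, 16L, 32L)) {
  stopifnot(length(ch) == 3L, dim(anchors)[1] == 3L, dim(anchors)[2] == 3L)
  no <- 3L * (5L + nc)
  convs <- lapply(ch, function(c1) new_conv2d(c1, no, 1L, bias = TRUE))
  names(convs) <- paste0("cv", seq_along(ch))
  new_module("sd_detect", children = convs, nc = as.integer(nc),
             anchors = anchors, strides = as.integer(strides), no = no)
}

#' @export
sd_forward.sd_detect <- function(mod, tp, x, training = FALSE) {
  # x: list of three feature maps, strides 8/16/32
  nattr <- 5L + mod$nc
  lapply(seq_along(x), function(i) {
    y <- sd_forward(mod$children[[paste0("cv", i)]], tp, x[[i]], training)
    d <- dim(hval(y))
    B <- d[1]; gy <- d[3]; gx <- d[4]
    y <- ag_reshape(tp, y, c(B, nattr, 3L, gy, gx))
    ag_aperm(tp, y, c(1L, 3L, 4L, 5L, 2L))      # (B, 3, gy, gx, 5+nc)
  })
}
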