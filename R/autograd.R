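# Reverse-mode autodiff on plain R arrays.
#
# A "handle" is list(id, value): `id` indexes a node on the tape, `value` is a
# numeric array (dims always set for rank >= 1 tensors; scalars are length-1
# numerics). Passing tape = NULL runs every op in plain eager mode with no
# recording, so the same forward code serves training and inference.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an empty autodiff tape
#'
#' The tape records each primitive operation so that [ag_backward()] can
#' accumulate gradients by reverse traversal.
#'
#' @return An environment holding the tape state.
#' @keywords internal
ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

hid <- function(x) if (is.list(x)) x$id else NA_integer_
hval <- function(x) if (is.list(x)) x$value else x

ag_record <- function(tp, value, parents = NULL, backfn = NULL) {
  if (is.null(tp) || is.null(parents) || all(is.na(parents))) {
    return(list(id = NA_integer_, value = value))
  }
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- list(parents = parents, backfn = backfn)
  list(id = tp$n, value = value)
}

#' @keywords internal
ag_leaf <- function(tp, value) {
  if (is.null(tp)) return(list(id = NA_integer_, value = value))
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- list(parents = NULL, backfn = NULL)
  list(id = tp$n, value = value)
}

#' Reverse sweep over a tape
#'
#' @param tp tape from [ag_tape()].
#' @param out handle of the (scalar) output node.
#' @param seed upstream gradient; defaults to 1 for scalar outputs.
#' @return list of gradients indexed by node id (NULL where unused).
#' @keywords internal
ag_backward <- function(tp, out, seed = NULL) {
  grads <- vector("list", tp$n)
  v <- out$value
  grads[[out$id]] <- seed %||% {
    s <- v; s[] <- 1; s
  }
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    grads[[i]] <- g
    if (is.null(nd$parents)) next
    pg <- nd$backfn(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[j]
      if (is.na(p) || is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- shape utilities --------------------------------------------------------

dims_of <- function(x) dim(x) %||% length(x)

# sum over axis `ax`, keeping it as a singleton
axis_sum_keep <- function(x, ax) {
  d <- dim(x)
  if (is.null(d)) return(sum(x))
  for (a in sort(ax, decreasing = TRUE)) {
    d <- dim(x)
    perm <- c(setdiff(seq_along(d), a), a)
    m <- matrix(aperm(x, perm), ncol = d[a])
    s <- rowSums(m)
    nd <- d
    nd[a] <- 1L
    x <- aperm(array(s, nd[perm]), order(perm))
  }
  x
}

# expand singleton dims of x to target dims td (same rank)
bc_expand <- function(x, td) {
  xd <- dim(x)
  if (is.null(xd)) {
    if (length(x) == 1L) return(array(x, td))
    stop("cannot broadcast dimensionless vector")
  }
  stopifnot(length(xd) == length(td))
  if (all(xd == td)) return(x)
  stopifnot(all(xd == td | xd == 1L))
  idx <- lapply(seq_along(td), function(i) {
    if (xd[i] == td[i]) seq_len(td[i]) else rep.int(1L, td[i])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# reduce gradient g (dims td) back to original dims xd by summing broadcast axes
bc_reduce <- function(g, xd) {
  if (is.null(xd) || length(xd) == 1L && is.null(dim(g))) {
    # scalar or plain vector target
  }
  gd <- dim(g) %||% length(g)
  if (is.null(dim(g))) dim(g) <- gd
  if (is.null(xd)) return(sum(g))      # scalar input
  if (length(xd) == 1L && length(gd) == 1L && xd == gd) {
    dim(g) <- NULL
    return(g)
  }
  ax <- which(xd == 1L & gd > 1L)
  if (length(ax)) g <- axis_sum_keep(g, ax)
  dim(g) <- xd
  g
}

ew_dims <- function(av, bv) {
  da <- dim(av)
  db <- dim(bv)
  if (is.null(da) && is.null(db)) return(NULL)
  if (is.null(da)) {
    stopifnot(length(av) == 1L)
    return(db)
  }
  if (is.null(db)) {
    stopifnot(length(bv) == 1L)
    return(da)
  }
  stopifnot(length(da) == length(db), all(da == db | da == 1L | db == 1L))
  pmax(da, db)
}

# ---- elementwise binary ops -------------------------------------------------

ag_ew2 <- function(tp, a, b, fwd, bwd_a, bwd_b) {
  av <- hval(a); bv <- hval(b)
  td <- ew_dims(av, bv)
  ae <- if (is.null(td)) av else bc_expand(if (is.null(dim(av)) && length(av) == 1L) array(av, rep(1L, length(td))) else av, td)
  be <- if (is.null(td)) bv else bc_expand(if (is.null(dim(bv)) && length(bv) == 1L) array(bv, rep(1L, length(td))) else bv, td)
  out <- fwd(ae, be)
  ag_record(tp, out, parents = c(hid(a), hid(b)), backfn = function(g) {
    list(
      if (is.na(hid(a))) NULL else bc_reduce(bwd_a(g, ae, be, out), dim(av)),
      if (is.na(hid(b))) NULL else bc_reduce(bwd_b(g, ae, be, out), dim(bv))
    )
  })
}

ag_add <- function(tp, a, b) ag_ew2(tp, a, b, `+`,
  function(g, a, b, y) g, function(g, a, b, y) g)

ag_sub <- function(tp, a, b) ag_ew2(tp, a, b, `-`,
  function(g, a, b, y) g, function(g, a, b, y) -g)

ag_mul <- function(tp, a, b) ag_ew2(tp, a, b, `*`,
  function(g, a, b, y) g * b, function(g, a, b, y) g * a)

ag_div <- function(tp, a, b) ag_ew2(tp, a, b, `/`,
  function(g, a, b, y) g / b, function(g, a, b, y) -g * a / (b * b))

ag_emax <- function(tp, a, b) ag_ew2(tp, a, b, pmax,
  function(g, a, b, y) g * (a >= b), function(g, a, b, y) g * (a < b))

ag_emin <- function(tp, a, b) ag_ew2(tp, a, b, pmin,
  function(g, a, b, y) g * (a <= b), function(g, a, b, y) g * (a > b))

# ---- elementwise unary ops --------------------------------------------------

ag_ew1 <- function(tp, a, fwd, bwd) {
  av <- hval(a)
  out <- fwd(av)
  ag_record(tp, out, parents = hid(a), backfn = function(g) list(bwd(g, av, out)))
}

ag_neg      <- function(tp, a) ag_ew1(tp, a, function(x) -x, function(g, x, y) -g)
ag_addc     <- function(tp, a, k) ag_ew1(tp, a, function(x) x + k, function(g, x, y) g)
ag_mulc     <- function(tp, a, k) ag_ew1(tp, a, function(x) x * k, function(g, x, y) g * k)
ag_pow2     <- function(tp, a) ag_ew1(tp, a, function(x) x * x, function(g, x, y) 2 * g * x)
ag_sqrt     <- function(tp, a) ag_ew1(tp, a, sqrt, function(g, x, y) 0.5 * g / pmax(y, 1e-12))
ag_atan     <- function(tp, a) ag_ew1(tp, a, atan, function(g, x, y) g / (1 + x * x))
ag_clampmin <- function(tp, a, k) ag_ew1(tp, a, function(x) pmax(x, k),
                                         function(g, x, y) g * (x > k))
ag_sigmoid  <- function(tp, a) ag_ew1(tp, a, stats::plogis,
                                      function(g, x, y) g * y * (1 - y))
ag_silu     <- function(tp, a) ag_ew1(tp, a, function(x) x * stats::plogis(x),
  function(g, x, y) {
    s <- stats::plogis(x)
    g * (s + x * s * (1 - s))
  })

# ---- reductions -------------------------------------------------------------

ag_sum <- function(tp, a) {
  av <- hval(a)
  ag_record(tp, sum(av), parents = hid(a), backfn = function(g) {
    out <- av; out[] <- g
    list(out)
  })
}

ag_mean <- function(tp, a) {
  av <- hval(a)
  n <- length(av)
  ag_record(tp, sum(av) / n, parents = hid(a), backfn = function(g) {
    out <- av; out[] <- g / n
    list(out)
  })
}

# mean over axes `ax`, keeping singletons
ag_mean_axes <- function(tp, a, ax) {
  av <- hval(a)
  d <- dim(av)
  n <- prod(d[ax])
  out <- axis_sum_keep(av, ax) / n
  ag_record(tp, out, parents = hid(a), backfn = function(g) {
    list(bc_expand(g / n, d))
  })
}

# ---- shape ops --------------------------------------------------------------

ag_reshape <- function(tp, a, d) {
  av <- hval(a)
  od <- dim(av)
  out <- av
  dim(out) <- d
  ag_record(tp, out, parents = hid(a), backfn = function(g) {
    dim(g) <- od
    list(g)
  })
}

ag_aperm <- function(tp, a, perm) {
  av <- hval(a)
  out <- aperm(av, perm)
  ag_record(tp, out, parents = hid(a), backfn = function(g) list(aperm(g, order(perm))))
}

# narrow along dimension `dm` to indices from:to
ag_narrow <- function(tp, a, dm, from, to) {
  av <- hval(a)
  d <- dim(av)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[dm]] <- from:to
  out <- do.call(`[`, c(list(av), idx, list(drop = FALSE)))
  ag_record(tp, out, parents = hid(a), backfn = function(g) {
    dx <- array(0, d)
    dx_idx <- c(list(dx), idx, list(g))
    list(do.call(`[<-`, dx_idx))
  })
}

# concatenate handles along dimension `dm`
ag_concat <- function(tp, hs, dm) {
  vs <- lapply(hs, hval)
  d0 <- dim(vs[[1L]])
  sizes <- vapply(vs, function(v) dim(v)[dm], integer(1))
  dd <- d0
  dd[dm] <- sum(sizes)
  out <- array(0, dd)
  off <- 0L
  idx <- rep(list(quote(expr = )), length(dd))
  for (k in seq_along(vs)) {
    idx[[dm]] <- (off + 1L):(off + sizes[k])
    out <- do.call(`[<-`, c(list(out), idx, list(vs[[k]])))
    off <- off + sizes[k]
  }
  ag_record(tp, out, parents = vapply(hs, hid, integer(1)), backfn = function(g) {
    res <- vector("list", length(vs))
    off <- 0L
    for (k in seq_along(vs)) {
      idx[[dm]] <- (off + 1L):(off + sizes[k])
      res[[k]] <- do.call(`[`, c(list(g), idx, list(drop = FALSE)))
      off <- off + sizes[k]
    }
    res
  })
}

# row gather from a matrix (scatter-add on the way back)
ag_index_rows <- function(tp, a, idx) {
  av <- hval(a)
  out <- av[idx, , drop = FALSE]
  ag_record(tp, out, parents = hid(a), backfn = function(g) {
    dx <- matrix(0, nrow(av), ncol(av))
    agg <- rowsum(g, group = idx, reorder = FALSE)
    dx[as.integer(rownames(agg)), ] <- agg
    list(dx)
  })
}

# zero padding of a (B,C,H,W) map; pad = c(left, right, top, bottom)
ag_pad2d <- function(tp, a, pad) {
  av <- hval(a)
  d <- dim(av)
  stopifnot(length(d) == 4L, all(pad >= 0))
  out <- array(0, c(d[1], d[2], d[3] + pad[3] + pad[4], d[4] + pad[1] + pad[2]))
  hr <- (pad[3] + 1L):(pad[3] + d[3])
  wr <- (pad[1] + 1L):(pad[1] + d[4])
  out[, , hr, wr] <- av
  ag_record(tp, out, parents = hid(a), backfn = function(g) {
    list(g[, , hr, wr, drop = FALSE])
  })
}

# ---- neural-network primitives ---------------------------------------------

im2col <- function(xp, kh, kw, s, Ho, Wo) {
  d <- dim(xp)
  B <- d[1]; C <- d[2]
  out <- array(0, c(C, kh, kw, B, Ho, Wo))
  hi <- seq.int(1L, by = s, length.out = Ho)
  wi <- seq.int(1L, by = s, length.out = Wo)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      sl <- xp[, , hi + i - 1L, wi + j - 1L, drop = FALSE]
      out[, i, j, , , ] <- aperm(sl, c(2, 1, 3, 4))
    }
  }
  dim(out) <- c(C * kh * kw, B * Ho * Wo)
  out
}

col2im <- function(dcols, C, kh, kw, s, B, Ho, Wo, Hp, Wp) {
  dxp <- array(0, c(B, C, Hp, Wp))
  dim(dcols) <- c(C, kh, kw, B, Ho, Wo)
  hi <- seq.int(1L, by = s, length.out = Ho)
  wi <- seq.int(1L, by = s, length.out = Wo)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      sl <- dcols[, i, j, , , , drop = FALSE]
      dim(sl) <- c(C, B, Ho, Wo)
      dxp[, , hi + i - 1L, wi + j - 1L] <-
        dxp[, , hi + i - 1L, wi + j - 1L, drop = FALSE] + aperm(sl, c(2, 1, 3, 4))
    }
  }
  dxp
}

#' 2-D convolution with asymmetric zero padding and channel groups
#'
#' @param tp tape or NULL.
#' @param x handle, (B, C, H, W).
#' @param w handle, weights (Cout, Cin/groups, kh, kw).
#' @param b handle or NULL, bias (Cout).
#' @param stride integer stride (both axes).
#' @param pad c(left, right, top, bottom) zero padding in pixels.
#' @param groups channel groups.
#' @keywords internal
ag_conv2d <- function(tp, x, w, b = NULL, stride = 1L, pad = c(0L, 0L, 0L, 0L),
                      groups = 1L) {
  xv <- hval(x); wv <- hval(w); bv <- if (is.null(b)) NULL else hval(b)
  xd <- dim(xv)
  stopifnot(length(xd) == 4L)
  wd <- dim(wv)
  B <- xd[1]; C <- xd[2]; H <- xd[3]; W <- xd[4]
  Cout <- wd[1]; Cg <- wd[2]; kh <- wd[3]; kw <- wd[4]
  stopifnot(C %% groups == 0L, Cout %% groups == 0L, Cg == C %/% groups)
  Hp <- H + pad[3] + pad[4]; Wp <- W + pad[1] + pad[2]
  if (Hp < kh || Wp < kw) {
    stop(sprintf("conv2d: padded input %dx%d smaller than kernel %dx%d",
                 Hp, Wp, kh, kw))
  }
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  xp <- if (all(pad == 0L)) xv else {
    tmp <- array(0, c(B, C, Hp, Wp))
    tmp[, , (pad[3] + 1L):(pad[3] + H), (pad[1] + 1L):(pad[1] + W)] <- xv
    tmp
  }
  cpg <- C %/% groups
  opg <- Cout %/% groups
  y <- array(0, c(B, Cout, Ho, Wo))
  cols_list <- vector("list", groups)
  wm_list <- vector("list", groups)
  for (gi in seq_len(groups)) {
    cs <- ((gi - 1L) * cpg + 1L):(gi * cpg)
    os <- ((gi - 1L) * opg + 1L):(gi * opg)
    cols <- im2col(xp[, cs, , , drop = FALSE], kh, kw, stride, Ho, Wo)
    wm <- matrix(aperm(wv[os, , , , drop = FALSE], c(2, 3, 4, 1)), ncol = opg)
    ym <- crossprod(wm, cols)                      # (opg, B*Ho*Wo)
    y[, os, , ] <- aperm(array(ym, c(opg, B, Ho, Wo)), c(2, 1, 3, 4))
    cols_list[[gi]] <- cols
    wm_list[[gi]] <- wm
  }
  if (!is.null(bv)) y <- y + bc_expand(array(bv, c(1L, Cout, 1L, 1L)), dim(y))
  ag_record(tp, y, parents = c(hid(x), hid(w), if (is.null(b)) NA_integer_ else hid(b)),
    backfn = function(g) {
      dw <- array(0, wd)
      need_dx <- !is.na(hid(x))
      dxp <- if (need_dx) array(0, c(B, C, Hp, Wp)) else NULL
      for (gi in seq_len(groups)) {
        cs <- ((gi - 1L) * cpg + 1L):(gi * cpg)
        os <- ((gi - 1L) * opg + 1L):(gi * opg)
        dym <- matrix(aperm(g[, os, , , drop = FALSE], c(2, 1, 3, 4)), nrow = opg)
        dwm <- cols_list[[gi]] %*% t(dym)          # (cpg*kh*kw, opg)
        dw[os, , , ] <- aperm(array(dwm, c(cpg, kh, kw, opg)), c(4, 1, 2, 3))
        if (need_dx) {
          dcols <- wm_list[[gi]] %*% dym
          dxp[, cs, , ] <- col2im(dcols, cpg, kh, kw, stride, B, Ho, Wo, Hp, Wp)
        }
      }
      dx <- if (need_dx) {
        dxp[, , (pad[3] + 1L):(pad[3] + H), (pad[1] + 1L):(pad[1] + W), drop = FALSE]
      } else NULL
      db <- if (!is.null(bv)) as.numeric(axis_sum_keep(g, c(1L, 3L, 4L))) else NULL
      list(dx, dw, db)
    })
}

#' Depthwise 1-D convolution over (B, C, L) with symmetric "same" padding
#'
#' One kernel of odd length k per channel; sequence length is preserved.
#' @keywords internal
ag_dwconv1d <- function(tp, x, w, b = NULL) {
  xv <- hval(x); wv <- hval(w); bv <- if (is.null(b)) NULL else hval(b)
  d <- dim(xv)
  stopifnot(length(d) == 3L)
  B <- d[1]; C <- d[2]; L <- d[3]
  k <- ncol(wv)
  stopifnot(nrow(wv) == C, k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(B, C, L + 2L * p))
  xp[, , (p + 1L):(p + L)] <- xv
  y <- array(0, c(B, C, L))
  for (t in seq_len(k)) {
    wt <- bc_expand(array(wv[, t], c(1L, C, 1L)), c(B, C, L))
    y <- y + wt * xp[, , t:(t + L - 1L), drop = FALSE]
  }
  if (!is.null(bv)) y <- y + bc_expand(array(bv, c(1L, C, 1L)), c(B, C, L))
  ag_record(tp, y, parents = c(hid(x), hid(w), if (is.null(b)) NA_integer_ else hid(b)),
    backfn = function(g) {
      dw <- matrix(0, C, k)
      dxp <- array(0, c(B, C, L + 2L * p))
      for (t in seq_len(k)) {
        sl <- xp[, , t:(t + L - 1L), drop = FALSE]
        dw[, t] <- as.numeric(axis_sum_keep(g * sl, c(1L, 3L)))
        wt <- bc_expand(array(wv[, t], c(1L, C, 1L)), c(B, C, L))
        dxp[, , t:(t + L - 1L)] <- dxp[, , t:(t + L - 1L), drop = FALSE] + g * wt
      }
      dx <- dxp[, , (p + 1L):(p + L), drop = FALSE]
      db <- if (!is.null(bv)) as.numeric(axis_sum_keep(g, c(1L, 3L))) else NULL
      list(dx, dw, db)
    })
}

#' Batch normalization over (B, C, H, W)
#'
#' Uses biased batch statistics in training mode; `rm`/`rv` are plain arrays
#' (running stats, treated as constants).
#' @keywords internal
ag_bn2d <- function(tp, x, gamma, beta, rm, rv, training = FALSE, eps = 1e-3) {
  xv <- hval(x); gv <- hval(gamma); bv <- hval(beta)
  d <- dim(xv)
  B <- d[1]; C <- d[2]
  N <- B * d[3] * d[4]
  if (training) {
    mu <- as.numeric(axis_sum_keep(xv, c(1L, 3L, 4L))) / N
    xc <- xv - bc_expand(array(mu, c(1L, C, 1L, 1L)), d)
    var <- as.numeric(axis_sum_keep(xc * xc, c(1L, 3L, 4L))) / N
  } else {
    mu <- rm
    var <- rv
    xc <- xv - bc_expand(array(mu, c(1L, C, 1L, 1L)), d)
  }
  ivar <- 1 / sqrt(var + eps)
  xhat <- xc * bc_expand(array(ivar, c(1L, C, 1L, 1L)), d)
  y <- xhat * bc_expand(array(gv, c(1L, C, 1L, 1L)), d) +
    bc_expand(array(bv, c(1L, C, 1L, 1L)), d)
  h <- ag_record(tp, y, parents = c(hid(x), hid(gamma), hid(beta)),
    backfn = function(g) {
      dgamma <- as.numeric(axis_sum_keep(g * xhat, c(1L, 3L, 4L)))
      dbeta <- as.numeric(axis_sum_keep(g, c(1L, 3L, 4L)))
      dxhat <- g * bc_expand(array(gv, c(1L, C, 1L, 1L)), d)
      if (training) {
        s1 <- axis_sum_keep(dxhat, c(1L, 3L, 4L))
        s2 <- axis_sum_keep(dxhat * xhat, c(1L, 3L, 4L))
        dx <- (dxhat - bc_expand(s1, d) / N - xhat * bc_expand(s2, d) / N) *
          bc_expand(array(ivar, c(1L, C, 1L, 1L)), d)
      } else {
        dx <- dxhat * bc_expand(array(ivar, c(1L, C, 1L, 1L)), d)
      }
      list(dx, dgamma, dbeta)
    })
  attr(h, "batch_mean") <- if (training) mu else NULL
  attr(h, "batch_var") <- if (training) var else NULL
  h
}

#' Group normalization over (B, C, ...) with G contiguous channel groups
#' @keywords internal
ag_gn <- function(tp, x, gamma, beta, groups, eps = 1e-5) {
  xv <- hval(x); gv <- hval(gamma); bv <- hval(beta)
  d <- dim(xv)
  B <- d[1]; C <- d[2]
  S <- prod(d[-(1:2)])
  G <- groups
  cg <- C %/% G
  stopifnot(C %% G == 0L)
  x4 <- xv
  dim(x4) <- c(B, cg, G, S)
  N <- cg * S
  mu <- axis_sum_keep(x4, c(2L, 4L)) / N              # (B,1,G,1)
  xc <- x4 - bc_expand(mu, dim(x4))
  var <- axis_sum_keep(xc * xc, c(2L, 4L)) / N
  ivar <- 1 / sqrt(var + eps)
  xhat <- xc * bc_expand(ivar, dim(x4))
  gma <- array(gv, c(1L, cg, G, 1L))
  bta <- array(bv, c(1L, cg, G, 1L))
  y <- xhat * bc_expand(gma, dim(x4)) + bc_expand(bta, dim(x4))
  dim(y) <- d
  ag_record(tp, y, parents = c(hid(x), hid(gamma), hid(beta)),
    backfn = function(g) {
      g4 <- g
      dim(g4) <- c(B, cg, G, S)
      dgamma <- as.numeric(axis_sum_keep(g4 * xhat, c(1L, 4L)))
      dbeta <- as.numeric(axis_sum_keep(g4, c(1L, 4L)))
      dxhat <- g4 * bc_expand(gma, dim(g4))
      s1 <- axis_sum_keep(dxhat, c(2L, 4L))
      s2 <- axis_sum_keep(dxhat * xhat, c(2L, 4L))
      dx <- (dxhat - bc_expand(s1, dim(g4)) / N - xhat * bc_expand(s2, dim(g4)) / N) *
        bc_expand(ivar, dim(g4))
      dim(dx) <- d
      list(dx, dgamma, dbeta)
    })
}

#' Max pooling with square kernel, stride and symmetric padding
#' @keywords internal
ag_maxpool2d <- function(tp, x, k, stride = 1L, pad = 0L) {
  xv <- hval(x)
  d <- dim(xv)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(-Inf, c(B, C, Hp, Wp))
  xp[, , (pad + 1L):(pad + H), (pad + 1L):(pad + W)] <- xv
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  hi <- seq.int(1L, by = stride, length.out = Ho)
  wi <- seq.int(1L, by = stride, length.out = Wo)
  y <- array(-Inf, c(B, C, Ho, Wo))
  amax <- array(1L, c(B, C, Ho, Wo))
  off <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      off <- off + 1L
      sl <- xp[, , hi + i - 1L, wi + j - 1L, drop = FALSE]
      upd <- sl > y
      y[upd] <- sl[upd]
      amax[upd] <- off
    }
  }
  ag_record(tp, y, parents = hid(x), backfn = function(g) {
    dxp <- array(0, c(B, C, Hp, Wp))
    off <- 0L
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        off <- off + 1L
        m <- (amax == off) * g
        dxp[, , hi + i - 1L, wi + j - 1L] <-
          dxp[, , hi + i - 1L, wi + j - 1L, drop = FALSE] + m
      }
    }
    list(dxp[, , (pad + 1L):(pad + H), (pad + 1L):(pad + W), drop = FALSE])
  })
}

#' Adaptive average pooling of (B,C,H,W) to a target (oh, ow) grid
#' @keywords internal
ag_adaptive_avgpool2d <- function(tp, x, oh, ow) {
  xv <- hval(x)
  d <- dim(xv)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (oh > H || ow > W) {
    stop(sprintf("adaptive pool target %dx%d exceeds input %dx%d", oh, ow, H, W))
  }
  hs <- floor((seq_len(oh) - 1L) * H / oh) + 1L
  he <- ceiling(seq_len(oh) * H / oh)
  ws <- floor((seq_len(ow) - 1L) * W / ow) + 1L
  we <- ceiling(seq_len(ow) * W / ow)
  y <- array(0, c(B, C, oh, ow))
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      sl <- xv[, , hs[i]:he[i], ws[j]:we[j], drop = FALSE]
      y[, , i, j] <- axis_sum_keep(sl, c(3L, 4L)) / prod(dim(sl)[3:4])
    }
  }
  ag_record(tp, y, parents = hid(x), backfn = function(g) {
    dx <- array(0, d)
    for (i in seq_len(oh)) {
      for (j in seq_len(ow)) {
        n <- (he[i] - hs[i] + 1L) * (we[j] - ws[j] + 1L)
        gg <- bc_expand(g[, , i, j, drop = FALSE] / n,
                        c(B, C, he[i] - hs[i] + 1L, we[j] - ws[j] + 1L))
        dx[, , hs[i]:he[i], ws[j]:we[j]] <-
          dx[, , hs[i]:he[i], ws[j]:we[j], drop = FALSE] + gg
      }
    }
    list(dx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @keywords internal
ag_upsample2 <- function(tp, x) {
  xv <- hval(x)
  d <- dim(xv)
  H <- d[3]; W <- d[4]
  y <- xv[, , rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), drop = FALSE]
  ag_record(tp, y, parents = hid(x), backfn = function(g) {
    dx <- array(0, d)
    for (i in 0:1) {
      for (j in 0:1) {
        dx <- dx + g[, , seq.int(1L + i, 2L * H, 2L), seq.int(1L + j, 2L * W, 2L),
                     drop = FALSE]
      }
    }
    list(dx)
  })
}

#' Batched matrix multiply: (B, M, K) x (B, K, N) -> (B, M, N)
#' @keywords internal
ag_bmm <- function(tp, a, b) {
  av <- hval(a); bv <- hval(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1] == db[1], da[3] == db[2])
  B <- da[1]
  y <- array(0, c(B, da[2], db[3]))
  for (i in seq_len(B)) {
    y[i, , ] <- matrix(av[i, , ], da[2], da[3]) %*% matrix(bv[i, , ], db[2], db[3])
  }
  ag_record(tp, y, parents = c(hid(a), hid(b)), backfn = function(g) {
    ga <- array(0, da)
    gb <- array(0, db)
    for (i in seq_len(B)) {
      gi <- matrix(g[i, , ], da[2], db[3])
      ga[i, , ] <- gi %*% t(matrix(bv[i, , ], db[2], db[3]))
      gb[i, , ] <- t(matrix(av[i, , ], da[2], da[3])) %*% gi
    }
    list(ga, gb)
  })
}

#' Softmax over the last dimension
#' @keywords internal
ag_softmax_last <- function(tp, x) {
  xv <- hval(x)
  d <- dim(xv)
  n <- d[length(d)]
  m <- matrix(xv, ncol = n)            # last dim is slowest-varying? no:
  # R is column-major: first dim varies fastest, so matrix(x, ncol = n) puts
  # the last dimension into columns exactly when x is reshaped with all
  # leading dims collapsed into rows. That is the case here.
  mx <- do.call(pmax, c(as.data.frame(m), list(0)))  # rowwise max (with 0 floor for stability)
  e <- exp(m - mx)
  y <- e / rowSums(e)
  out <- array(y, d)
  ag_record(tp, out, parents = hid(x), backfn = function(g) {
    gm <- matrix(g, ncol = n)
    dot <- rowSums(gm * y)
    dx <- y * (gm - dot)
    list(array(dx, d))
  })
}

#' Mean binary cross-entropy with logits
#'
#' @param x handle of logits (any shape).
#' @param target plain array of the same shape with entries in \[0,1\].
#' @keywords internal
ag_bce_logits <- function(tp, x, target) {
  xv <- hval(x)
  tv <- target
  n <- length(xv)
  # numerically stable: max(x,0) - x*t + log1p(exp(-|x|))
  val <- sum(pmax(xv, 0) - xv * tv + log1p(exp(-abs(xv)))) / n
  ag_record(tp, val, parents = hid(x), backfn = function(g) {
    list((stats::plogis(xv) - tv) * (g / n))
  })
}
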