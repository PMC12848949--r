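# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every operation works in two modes: given plain matrices it simply computes
# the value (inference path), and given tape-attached nodes it additionally
# records a backward closure. This keeps a single forward implementation for
# both training and prediction. All quantities are matrices; column vectors
# are n x 1 matrices; scalars are 1 x 1.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_active <- function() !is.null(.ad$tape)

is_adnode <- function(x) inherits(x, "adnode")

ad_val <- function(x) if (is_adnode(x)) x$v else x

ad_record <- function(node) {
  t <- .ad$tape
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[t$n]] <- node
  node
}

# leaf parameter node; gradient collected after ad_backward()
ad_leaf <- function(v) {
  stopifnot(ad_active())
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bw <- NULL
  class(n) <- "adnode"
  ad_record(n)
}

ad_make <- function(v, bw) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bw <- bw
  class(n) <- "adnode"
  ad_record(n)
}

ad_acc <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Wrap an op result: if no input is a node (or no tape), return the value.
ad_wrap <- function(v, inputs, bw) {
  if (!ad_active() || !any(vapply(inputs, is_adnode, logical(1)))) return(v)
  ad_make(v, bw)
}

ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), ad_active())
  loss$g <- 1
  t <- .ad$tape
  for (k in seq.int(t$n, 1L)) {
    nd <- t$nodes[[k]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

ad_grad <- function(node) node$g

## ---- elementary ops --------------------------------------------------------

ad_mm <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  v <- va %*% vb
  ad_wrap(v, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g %*% t(vb))
    if (is_adnode(b)) ad_acc(b, crossprod(va, g))
  })
}

# a %*% t(b)
ad_mm_nt <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  v <- tcrossprod(va, vb)
  ad_wrap(v, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g %*% vb)
    if (is_adnode(b)) ad_acc(b, crossprod(g, va))
  })
}

ad_add <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_wrap(va + vb, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g)
    if (is_adnode(b)) ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_wrap(va - vb, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g)
    if (is_adnode(b)) ad_acc(b, -g)
  })
}

ad_mul <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_wrap(va * vb, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g * vb)
    if (is_adnode(b)) ad_acc(b, g * va)
  })
}

ad_div <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_wrap(va / vb, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g / vb)
    if (is_adnode(b)) ad_acc(b, -g * va / (vb * vb))
  })
}

# k * a + c with scalar constants k, c
ad_affine <- function(a, k = 1, c = 0) {
  va <- ad_val(a)
  ad_wrap(k * va + c, list(a), function(g) ad_acc(a, k * g))
}

# add a length-F bias vector to every row of an N x F matrix
ad_add_bias <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  v <- va + matrix(vb, nrow(va), length(vb), byrow = TRUE)
  ad_wrap(v, list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g)
    if (is_adnode(b)) ad_acc(b, colSums(g))
  })
}

ad_elu <- function(a) {
  x <- ad_val(a)
  v <- x
  neg <- which(x < 0) # which() drops NaN so diverged values propagate as-is
  v[neg] <- exp(x[neg]) - 1
  d <- array(1, dim(x))
  d[neg] <- exp(x[neg])
  ad_wrap(v, list(a), function(g) ad_acc(a, g * d))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  x <- ad_val(a)
  v <- ifelse(x > 0, x, slope * x)
  d <- ifelse(x > 0, 1, slope)
  ad_wrap(v, list(a), function(g) ad_acc(a, g * d))
}

ad_sigmoid <- function(a) {
  x <- ad_val(a)
  s <- 1 / (1 + exp(-x))
  ad_wrap(s, list(a), function(g) ad_acc(a, g * s * (1 - s)))
}

ad_exp <- function(a) {
  v <- exp(ad_val(a))
  ad_wrap(v, list(a), function(g) ad_acc(a, g * v))
}

ad_log <- function(a) {
  x <- ad_val(a)
  ad_wrap(log(x), list(a), function(g) ad_acc(a, g / x))
}

ad_sum <- function(a) {
  x <- ad_val(a)
  ad_wrap(sum(x), list(a), function(g) ad_acc(a, array(g, dim(x))))
}

ad_mean <- function(a) {
  x <- ad_val(a)
  n <- length(x)
  ad_wrap(sum(x) / n, list(a), function(g) ad_acc(a, array(g / n, dim(x))))
}

ad_cbind <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  na <- ncol(va)
  ad_wrap(cbind(va, vb), list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g[, seq_len(na), drop = FALSE])
    if (is_adnode(b)) ad_acc(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_rbind <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  na <- nrow(va)
  ad_wrap(rbind(va, vb), list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g[seq_len(na), , drop = FALSE])
    if (is_adnode(b)) ad_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

ad_pmax <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  take_a <- va >= vb  # ties go to a
  ad_wrap(pmax(va, vb), list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g * take_a)
    if (is_adnode(b)) ad_acc(b, g * !take_a)
  })
}

ad_pmin <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  take_a <- va <= vb
  ad_wrap(pmin(va, vb), list(a, b), function(g) {
    if (is_adnode(a)) ad_acc(a, g * take_a)
    if (is_adnode(b)) ad_acc(b, g * !take_a)
  })
}

## ---- gather / scatter ------------------------------------------------------

# gather rows: out[k, ] = a[idx[k], ]
ad_rows <- function(a, idx) {
  va <- ad_val(a)
  v <- va[idx, , drop = FALSE]
  ad_wrap(v, list(a), function(g) {
    gs <- rowsum(g, group = idx)
    out <- matrix(0, nrow(va), ncol(va))
    out[as.integer(rownames(gs)), ] <- gs
    ad_acc(a, out)
  })
}

# segment sum: out[s, ] = sum over k with seg[k] == s of a[k, ]; out has nseg rows
ad_segment_sum <- function(a, seg, nseg) {
  va <- ad_val(a)
  gs <- rowsum(va, group = seg)
  v <- matrix(0, nseg, ncol(va))
  v[as.integer(rownames(gs)), ] <- gs
  ad_wrap(v, list(a), function(g) ad_acc(a, g[seg, , drop = FALSE]))
}

ad_segment_mean <- function(a, seg, nseg) {
  cnt <- tabulate(seg, nbins = nseg)
  s <- ad_segment_sum(a, seg, nseg)
  ad_affine(ad_mul(s, matrix(1 / pmax(cnt, 1L), nseg, ncol(ad_val(a)))), 1, 0)
}

# per-segment, per-column extremum; empty segments give 0
ad_segment_extreme <- function(a, seg, nseg, which = c("max", "min")) {
  which <- match.arg(which)
  va <- ad_val(a)
  f <- ncol(va)
  v <- matrix(0, nseg, f)
  rows_by <- split(seq_along(seg), seg)
  argrow <- matrix(NA_integer_, nseg, f)
  for (nm in names(rows_by)) {
    s <- as.integer(nm)
    rows <- rows_by[[nm]]
    sub <- va[rows, , drop = FALSE]
    idx <- if (which == "max") apply(sub, 2, which.max) else apply(sub, 2, which.min)
    v[s, ] <- sub[cbind(idx, seq_len(f))]
    argrow[s, ] <- rows[idx]
  }
  ad_wrap(v, list(a), function(g) {
    out <- matrix(0, nrow(va), f)
    for (s in as.integer(names(rows_by))) {
      out[cbind(argrow[s, ], seq_len(f))] <- out[cbind(argrow[s, ], seq_len(f))] + g[s, ]
    }
    ad_acc(a, out)
  })
}

# softmax of a column vector e (E x 1) within segments; every segment in
# 1..nseg must be non-empty for the value rows that are used downstream.
ad_segment_softmax <- function(e, seg, nseg) {
  ve <- as.vector(ad_val(e))
  mx <- vapply(split(ve, seg), max, numeric(1))
  mx_full <- rep(0, nseg)
  mx_full[as.integer(names(mx))] <- mx
  ex <- exp(ve - mx_full[seg])
  den <- rep(1, nseg)
  dsum <- rowsum(matrix(ex), group = seg)
  den[as.integer(rownames(dsum))] <- dsum
  alpha <- ex / den[seg]
  v <- matrix(alpha, ncol = 1)
  ad_wrap(v, list(e), function(g) {
    gv <- as.vector(g)
    s <- rep(0, nseg)
    ssum <- rowsum(matrix(gv * alpha), group = seg)
    s[as.integer(rownames(ssum))] <- ssum
    ad_acc(e, matrix(alpha * (gv - s[seg]), ncol = 1))
  })
}

# scale row k of matrix a by w[k] (w an E x 1 column)
ad_rowscale <- function(a, w) {
  va <- ad_val(a); vw <- as.vector(ad_val(w))
  v <- va * vw
  ad_wrap(v, list(a, w), function(g) {
    if (is_adnode(a)) ad_acc(a, g * vw)
    if (is_adnode(w)) ad_acc(w, matrix(rowSums(g * va), ncol = 1))
  })
}

# row-wise L2 normalization; rows with norm <= eps map to zero rows
ad_l2norm_rows <- function(a, eps = 1e-12) {
  va <- ad_val(a)
  r <- sqrt(rowSums(va * va))
  scale <- ifelse(r > eps, 1 / r, 0)
  v <- va * scale
  ad_wrap(v, list(a), function(g) {
    dot <- rowSums(g * v)
    ad_acc(a, (g - v * dot) * scale)
  })
}

# rowSums(a * mask) for a constant 0/1 mask; returns n x 1
ad_rowsums_mask <- function(a, mask) {
  va <- ad_val(a)
  v <- matrix(rowSums(va * mask), ncol = 1)
  ad_wrap(v, list(a), function(g) ad_acc(a, mask * as.vector(g)))
}

# fused softmax + mean negative log-likelihood; labels are 1-based classes
ad_softmax_xent <- function(logits, labels) {
  x <- ad_val(logits)
  n <- nrow(x)
  mx <- apply(x, 1, max)
  ex <- exp(x - mx)
  p <- ex / rowSums(ex)
  picked <- p[cbind(seq_len(n), labels)]
  v <- -mean(log(pmax(picked, 1e-300)))
  ad_wrap(v, list(logits), function(g) {
    y <- matrix(0, n, ncol(x))
    y[cbind(seq_len(n), labels)] <- 1
    ad_acc(logits, g * (p - y) / n)
  })
}

ad_softmax_rows <- function(logits) {
  x <- ad_val(logits)
  mx <- apply(x, 1, max)
  ex <- exp(x - mx)
  p <- ex / rowSums(ex)
  ad_wrap(p, list(logits), function(g) {
    dot <- rowSums(g * p)
    ad_acc(logits, p * (g - dot))
  })
}
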