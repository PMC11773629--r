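# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value is a numeric matrix (scalars are 1x1). Operations build a tape
# of nodes; ag_backward() traverses it in reverse creation order. Leaf
# parameters (ag_param) persist across tapes and accumulate gradients in
# place, which is what the Adam steps consume. Constant-only subgraphs are
# never recorded, so the same code paths double as plain numeric evaluators.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L

ag_tape_active <- function() !is.null(.ag$tape)

ag_tape_start <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

#' @noRd
ag_record <- function(nd) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- nd
  .ag$n <- n
  invisible(NULL)
}

is_ag <- function(x) inherits(x, "ag_node")

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

ag_value <- function(x) if (is_ag(x)) x$value else as_mat(x)

ag_req <- function(x) is_ag(x) && isTRUE(x$req)

#' Create a constant (non-differentiated) node
#' @noRd
ag_const <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- as_mat(value)
  nd$grad <- NULL
  nd$req <- FALSE
  class(nd) <- "ag_node"
  nd
}

#' Create a leaf parameter; gradients accumulate into $grad across a tape
#' @noRd
ag_param <- function(value) {
  nd <- ag_const(value)
  nd$req <- TRUE
  nd
}

# inputs: list of nodes/plain values; grads: list parallel to inputs of
# functions(g) returning the gradient contribution for that input (only
# consulted for inputs that require grad).
ag_op <- function(value, inputs, grads) {
  req_in <- vapply(inputs, ag_req, logical(1))
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$req <- any(req_in)
  class(nd) <- "ag_node"
  if (nd$req && ag_tape_active()) {
    nd$pb <- list(inputs = inputs[req_in], grads = grads[req_in])
    ag_record(nd)
  }
  nd
}

ag_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar node over the active tape
#' @noRd
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  if (!ag_tape_active()) stop("no active tape; wrap the forward pass in ag_tape_start()")
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$grad)) next
    pb <- nd$pb
    g <- nd$grad
    for (j in seq_along(pb$inputs)) {
      ag_accum(pb$inputs[[j]], pb$grads[[j]](g, nd))
    }
    nd$grad <- NULL # free as we go
  }
  invisible(NULL)
}

# ---- broadcasting helpers ----------------------------------------------------

bc_to <- function(a, nr, nc) {
  da <- dim(a)
  if (da[1L] == nr && da[2L] == nc) return(a)
  if (da[1L] == 1L && da[2L] == 1L) return(matrix(a[1L], nr, nc))
  if (da[1L] == 1L && da[2L] == nc) return(matrix(a, nr, nc, byrow = TRUE))
  if (da[1L] == nr && da[2L] == 1L) return(matrix(a, nr, nc))
  stop("incompatible broadcast: ", da[1L], "x", da[2L], " to ", nr, "x", nc)
}

# reduce gradient g (nr x nc) back to the shape of a
bc_back <- function(g, da) {
  dg <- dim(g)
  if (identical(dg, da)) return(g)
  if (da[1L] == 1L && da[2L] == 1L) return(matrix(sum(g), 1L, 1L))
  if (da[1L] == 1L) return(matrix(colSums(g), 1L))
  if (da[2L] == 1L) return(matrix(rowSums(g), ncol = 1L))
  stop("bad gradient reduction")
}

bshape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  c(max(da[1L], db[1L]), max(da[2L], db[2L]))
}

# ---- arithmetic --------------------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sh <- bshape(av, bv)
  v <- bc_to(av, sh[1L], sh[2L]) + bc_to(bv, sh[1L], sh[2L])
  ag_op(v, list(a, b), list(
    function(g, nd) bc_back(g, dim(av)),
    function(g, nd) bc_back(g, dim(bv))
  ))
}

ag_sub <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sh <- bshape(av, bv)
  v <- bc_to(av, sh[1L], sh[2L]) - bc_to(bv, sh[1L], sh[2L])
  ag_op(v, list(a, b), list(
    function(g, nd) bc_back(g, dim(av)),
    function(g, nd) -bc_back(g, dim(bv))
  ))
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sh <- bshape(av, bv)
  ae <- bc_to(av, sh[1L], sh[2L]); be <- bc_to(bv, sh[1L], sh[2L])
  ag_op(ae * be, list(a, b), list(
    function(g, nd) bc_back(g * be, dim(av)),
    function(g, nd) bc_back(g * ae, dim(bv))
  ))
}

ag_div <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sh <- bshape(av, bv)
  ae <- bc_to(av, sh[1L], sh[2L]); be <- bc_to(bv, sh[1L], sh[2L])
  v <- ae / be
  ag_op(v, list(a, b), list(
    function(g, nd) bc_back(g / be, dim(av)),
    function(g, nd) bc_back(-g * ae / (be * be), dim(bv))
  ))
}

ag_neg <- function(a) {
  ag_op(-ag_value(a), list(a), list(function(g, nd) -g))
}

ag_scale <- function(a, s) { # s plain scalar
  ag_op(ag_value(a) * s, list(a), list(function(g, nd) g * s))
}

ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av %*% bv, list(a, b), list(
    function(g, nd) g %*% t(bv),
    function(g, nd) crossprod(av, g)
  ))
}

# y = x %*% w + b  with b a 1 x m row
ag_linear <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  v <- xv %*% wv
  v <- v + matrix(bv, nrow(v), ncol(v), byrow = TRUE)
  ag_op(v, list(x, w, b), list(
    function(g, nd) g %*% t(wv),
    function(g, nd) crossprod(xv, g),
    function(g, nd) matrix(colSums(g), 1L)
  ))
}

# ---- elementwise nonlinearities ----------------------------------------------

ag_exp <- function(a) {
  v <- exp(ag_value(a))
  ag_op(v, list(a), list(function(g, nd) g * v))
}

ag_log <- function(a, eps = 0) {
  av <- ag_value(a)
  ag_op(log(av + eps), list(a), list(function(g, nd) g / (av + eps)))
}

ag_sqrt <- function(a, eps = 0) {
  v <- sqrt(ag_value(a) + eps)
  ag_op(v, list(a), list(function(g, nd) g * 0.5 / v))
}

ag_square <- function(a) {
  av <- ag_value(a)
  ag_op(av * av, list(a), list(function(g, nd) 2 * g * av))
}

ag_abs <- function(a) {
  av <- ag_value(a)
  ag_op(abs(av), list(a), list(function(g, nd) g * sign(av)))
}

ag_cos <- function(a) {
  av <- ag_value(a)
  ag_op(cos(av), list(a), list(function(g, nd) -g * sin(av)))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  ag_op(v, list(a), list(function(g, nd) g * v * (1 - v)))
}

ag_softplus <- function(a) {
  av <- ag_value(a)
  # numerically stable log(1 + exp(x))
  v <- pmax(av, 0) + log1p(exp(-abs(av)))
  ag_op(v, list(a), list(function(g, nd) g / (1 + exp(-av))))
}

ag_tanh <- function(a) {
  v <- tanh(ag_value(a))
  ag_op(v, list(a), list(function(g, nd) g * (1 - v * v)))
}

ag_leakyrelu <- function(a, slope = 0.01) {
  av <- ag_value(a)
  pos <- av > 0
  v <- av * (pos + slope * !pos)
  ag_op(v, list(a), list(function(g, nd) g * (pos + slope * !pos)))
}

# ---- reductions --------------------------------------------------------------

ag_sum <- function(a) {
  av <- ag_value(a)
  ag_op(matrix(sum(av), 1L, 1L), list(a),
        list(function(g, nd) matrix(g[1L], nrow(av), ncol(av))))
}

ag_mean <- function(a) {
  av <- ag_value(a)
  n <- length(av)
  ag_op(matrix(mean(av), 1L, 1L), list(a),
        list(function(g, nd) matrix(g[1L] / n, nrow(av), ncol(av))))
}

ag_colsums <- function(a) {
  av <- ag_value(a)
  ag_op(matrix(colSums(av), 1L), list(a),
        list(function(g, nd) matrix(g, nrow(av), ncol(av), byrow = TRUE)))
}

ag_rowsums <- function(a) {
  av <- ag_value(a)
  ag_op(matrix(rowSums(av), ncol = 1L), list(a),
        list(function(g, nd) matrix(g, nrow(av), ncol(av))))
}

ag_colmeans <- function(a) {
  av <- ag_value(a)
  n <- nrow(av)
  ag_op(matrix(colMeans(av), 1L), list(a),
        list(function(g, nd) matrix(g / n, nrow(av), ncol(av), byrow = TRUE)))
}

# ---- structural ops ----------------------------------------------------------

# idx: integer vector; 0 selects an implicit all-zero row
ag_gather_rows <- function(a, idx) {
  av <- ag_value(a)
  m <- ncol(av)
  n <- nrow(av)
  is_perm <- length(idx) == n && !anyNA(idx) && all(idx > 0L) &&
    !anyDuplicated(idx)
  if (is_perm) {
    out <- av[idx, , drop = FALSE]
    return(ag_op(out, list(a), list(function(g, nd) {
      dX <- g
      dX[idx, ] <- g
      dX
    })))
  }
  out <- matrix(0, length(idx), m)
  nz <- which(idx > 0L)
  out[nz, ] <- av[idx[nz], , drop = FALSE]
  ag_op(out, list(a), list(function(g, nd) {
    dX <- matrix(0, n, m)
    if (length(nz)) {
      acc <- rowsum(g[nz, , drop = FALSE], group = idx[nz])
      dX[as.integer(rownames(acc)), ] <- acc
    }
    dX
  }))
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  widths <- vapply(vals, ncol, integer(1))
  stops <- cumsum(widths)
  starts <- stops - widths + 1L
  v <- do.call(cbind, vals)
  grads <- lapply(seq_along(nodes), function(j) {
    force(j)
    function(g, nd) g[, starts[j]:stops[j], drop = FALSE]
  })
  ag_op(v, nodes, grads)
}

ag_slice_cols <- function(a, cols) {
  av <- ag_value(a)
  ag_op(av[, cols, drop = FALSE], list(a), list(function(g, nd) {
    dX <- matrix(0, nrow(av), ncol(av))
    dX[, cols] <- g
    dX
  }))
}

ag_rbind <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  heights <- vapply(vals, nrow, integer(1))
  stops <- cumsum(heights)
  starts <- stops - heights + 1L
  v <- do.call(rbind, vals)
  grads <- lapply(seq_along(nodes), function(j) {
    force(j)
    function(g, nd) g[starts[j]:stops[j], , drop = FALSE]
  })
  ag_op(v, nodes, grads)
}

# reshape an (n*m x 1) column into an n x m matrix filled row-major
ag_reshape_rowmajor <- function(a, nr, nc) {
  av <- ag_value(a)
  stopifnot(ncol(av) == 1L, nrow(av) == nr * nc)
  ag_op(matrix(av, nr, nc, byrow = TRUE), list(a),
        list(function(g, nd) matrix(as.vector(t(g)), ncol = 1L)))
}

# a %*% t(b)
ag_matmul_t <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(tcrossprod(av, bv), list(a, b), list(
    function(g, nd) g %*% bv,
    function(g, nd) crossprod(g, av)
  ))
}

ag_softmax_rows <- function(a) {
  av <- ag_value(a)
  e <- exp(av - max(av))
  v <- e / rowSums(e)
  ag_op(v, list(a), list(function(g, nd) {
    tmp <- g * v
    tmp - v * rowSums(tmp)
  }))
}

# Row-wise layer norm with affine parameters gamma, beta (1 x m each)
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ag_value(a)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  m <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc * xc)
  isd <- 1 / sqrt(va + eps)
  xhat <- xc * isd
  v <- xhat * matrix(gv, nrow(av), m, byrow = TRUE) +
    matrix(bv, nrow(av), m, byrow = TRUE)
  ag_op(v, list(a, gamma, beta), list(
    function(g, nd) {
      dxh <- g * matrix(gv, nrow(g), m, byrow = TRUE)
      (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * isd
    },
    function(g, nd) matrix(colSums(g * xhat), 1L),
    function(g, nd) matrix(colSums(g), 1L)
  ))
}

# Max over contiguous groups of `k` rows laid out as blocks: rows
# ((g-1)*k+1):(g*k) reduce to output row g. Backward routes to the first
# maximal row of each group (deterministic tie-break).
ag_block_rowmax <- function(a, k) {
  av <- ag_value(a)
  n <- nrow(av)
  stopifnot(n %% k == 0L)
  G <- n %/% k
  sel <- seq(1L, n, by = k)
  v <- av[sel, , drop = FALSE]
  if (k > 1L) for (i in 2:k) v <- pmax(v, av[sel + (i - 1L), , drop = FALSE])
  ag_op(v, list(a), list(function(g, nd) {
    dX <- matrix(0, n, ncol(av))
    remaining <- matrix(TRUE, G, ncol(av))
    for (i in 1:k) {
      ri <- sel + (i - 1L)
      take <- remaining & (av[ri, , drop = FALSE] == v)
      dX[ri, ] <- g * take
      remaining <- remaining & !take
    }
    dX
  }))
}

# ---- optimizer ---------------------------------------------------------------

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Adam state for a flat list of ag_param nodes
#' @noRd
adam_init <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0))
}

adam_step <- function(opt, clip = NULL) {
  opt$t <- opt$t + 1L
  if (!is.null(clip)) {
    tot <- 0
    for (p in opt$params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
    nrm <- sqrt(tot)
    if (is.finite(nrm) && nrm > clip) {
      sc <- clip / nrm
      for (p in opt$params) if (!is.null(p$grad)) p$grad <- p$grad * sc
    }
  }
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / c1) / (sqrt(opt$v[[i]] / c2) + opt$eps)
  }
  opt
}
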