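# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The torsion-prediction network is small (a few thousand parameters, token
# sequences of a handful of rotatable bonds), so an eager tape of matrix ops
# in plain R is fast enough for desk-scale training while keeping every
# gradient exact. Each node stores its value and a backward closure; the tape
# is replayed in reverse to accumulate parameter gradients. Gradient
# correctness is verified against central finite differences in the test
# suite.

ad_tape <- function(params) {
  env <- new.env(parent = emptyenv())
  env$nodes <- vector("list", 256L)
  env$k <- 0L
  env$params <- params           # environment: name -> matrix
  env$grads <- new.env(parent = emptyenv())
  env
}

ad_node <- function(tape, value, parents = integer(0), backward = NULL,
                    param = NULL) {
  # force all promises BEFORE taking an id: an argument expression may itself
  # create tape nodes, and must do so ahead of this one
  force(value); force(parents); force(backward); force(param)
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- list(id = tape$k, value = value, parents = parents,
               backward = backward, param = param)
  tape$nodes[[tape$k]] <- node
  node
}

ad_value <- function(x) if (is.list(x) && !is.null(x$id)) x$value else x

ad_const <- function(tape, value) ad_node(tape, value)

ad_param <- function(tape, name) {
  ad_node(tape, tape$params[[name]], param = name)
}

# g is the incoming gradient (same shape as the node value)
ad_matmul <- function(tape, a, b) {
  A <- a$value; B <- b$value
  ad_node(tape, A %*% B, c(a$id, b$id),
          backward = function(g) list(g %*% t(B), crossprod(A, g)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, c(a$id, b$id),
          backward = function(g) list(g, g))
}

# broadcast a 1 x d bias over the rows of a
ad_bias <- function(tape, a, b) {
  ad_node(tape, sweep(a$value, 2, as.numeric(b$value), `+`),
          c(a$id, b$id),
          backward = function(g)
            list(g, matrix(colSums(g), 1)))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, a$id, backward = function(g) list(g * s))
}

ad_add_const <- function(tape, a, m) {
  ad_node(tape, a$value + m, a$id, backward = function(g) list(g))
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, a$id,
          backward = function(g) list(g * mask))
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), a$id, backward = function(g) list(t(g)))
}

ad_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  ad_node(tape, a$value[, idx, drop = FALSE], a$id,
          backward = function(g) {
            out <- matrix(0, nrow(g), nc)
            out[, idx] <- g
            list(out)
          })
}

ad_rows_select <- function(tape, a, idx) {
  nr <- nrow(a$value)
  ad_node(tape, a$value[idx, , drop = FALSE], a$id,
          backward = function(g) {
            out <- matrix(0, nr, ncol(g))
            for (r in seq_along(idx)) {
              out[idx[r], ] <- out[idx[r], ] + g[r, ]
            }
            list(out)
          })
}

# embedding lookup: rows of a parameter table (duplicate indices accumulate)
ad_embed <- function(tape, name, idx) {
  tab <- tape$params[[name]]
  node <- ad_node(tape, tab[idx, , drop = FALSE])
  node$parents <- integer(0)
  # store scatter info for the backward pass via a param-gradient closure
  tape$nodes[[node$id]]$embed <- list(name = name, idx = idx,
                                      shape = dim(tab))
  tape$nodes[[node$id]]
}

ad_concat_cols <- function(tape, items) {
  vals <- lapply(items, `[[`, "value")
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths); starts <- c(1, head(ends, -1) + 1)
  ad_node(tape, do.call(cbind, vals),
          vapply(items, `[[`, integer(1), "id"),
          backward = function(g)
            lapply(seq_along(items), function(k)
              g[, starts[k]:ends[k], drop = FALSE]))
}

ad_rbind <- function(tape, items) {
  vals <- lapply(items, `[[`, "value")
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights); starts <- c(1, head(ends, -1) + 1)
  ad_node(tape, do.call(rbind, vals),
          vapply(items, `[[`, integer(1), "id"),
          backward = function(g)
            lapply(seq_along(items), function(k)
              g[starts[k]:ends[k], , drop = FALSE]))
}

ad_mean_rows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  k <- length(idx)
  ad_node(tape, matrix(colMeans(a$value[idx, , drop = FALSE]), 1), a$id,
          backward = function(g) {
            out <- matrix(0, nr, ncol(g))
            for (r in idx) out[r, ] <- out[r, ] + g / k
            list(out)
          })
}

# row-wise softmax with an optional additive mask (e.g. causal -Inf mask)
ad_softmax_rows <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x <- x + mask
  x <- x - apply(x, 1, max)
  e <- exp(x)
  p <- e / rowSums(e)
  ad_node(tape, p, a$id,
          backward = function(g) {
            gs <- rowSums(g * p)
            list((g - gs) * p)
          })
}

ad_layernorm <- function(tape, a, gamma_name, beta_name, eps = 1e-5) {
  x <- a$value
  gamma <- tape$params[[gamma_name]]; beta <- tape$params[[beta_name]]
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(as.numeric(gamma), each = nrow(x)), 2,
             as.numeric(beta), `+`)
  d <- ncol(x)
  node <- ad_node(tape, y, a$id,
                  backward = function(g) {
                    gg <- g * rep(as.numeric(gamma), each = nrow(g))
                    t1 <- rowSums(gg)
                    t2 <- rowSums(gg * xhat)
                    dx <- inv * (gg - t1 / d - xhat * t2 / d)
                    list(dx)
                  })
  tape$nodes[[node$id]]$lnorm <- list(gamma = gamma_name, beta = beta_name,
                                      xhat = xhat)
  tape$nodes[[node$id]]
}

# L2-normalize each row (the (sin, cos) output head)
ad_l2norm_rows <- function(tape, a, eps = 1e-12) {
  x <- a$value
  nrm <- sqrt(rowSums(x^2) + eps)
  y <- x / nrm
  ad_node(tape, y, a$id,
          backward = function(g) {
            dot <- rowSums(g * y)
            list((g - y * dot) / nrm)
          })
}

# mean over all elements -> 1x1
ad_mean_all <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1, 1), a$id,
          backward = function(g)
            list(matrix(g[1, 1] / n, nrow(a$value), ncol(a$value))))
}

ad_mul <- function(tape, a, b) {  # elementwise
  ad_node(tape, a$value * b$value, c(a$id, b$id),
          backward = function(g) list(g * b$value, g * a$value))
}

ad_backward <- function(tape, loss_node) {
  grads_n <- vector("list", tape$k)
  grads_n[[loss_node$id]] <- matrix(1, 1, 1)
  for (id in seq(tape$k, 1)) {
    node <- tape$nodes[[id]]
    g <- grads_n[[id]]
    if (is.null(g)) next
    if (!is.null(node$param)) {
      prev <- tape$grads[[node$param]]
      tape$grads[[node$param]] <- if (is.null(prev)) g else prev + g
    }
    if (!is.null(node$embed)) {
      prev <- tape$grads[[node$embed$name]]
      if (is.null(prev)) prev <- matrix(0, node$embed$shape[1],
                                        node$embed$shape[2])
      for (r in seq_along(node$embed$idx)) {
        prev[node$embed$idx[r], ] <- prev[node$embed$idx[r], ] + g[r, ]
      }
      tape$grads[[node$embed$name]] <- prev
    }
    if (!is.null(node$lnorm)) {
      gname <- node$lnorm$gamma; bname <- node$lnorm$beta
      gprev <- tape$grads[[gname]]
      bprev <- tape$grads[[bname]]
      gg <- matrix(colSums(g * node$lnorm$xhat), 1)
      bb <- matrix(colSums(g), 1)
      tape$grads[[gname]] <- if (is.null(gprev)) gg else gprev + gg
      tape$grads[[bname]] <- if (is.null(bprev)) bb else bprev + bb
    }
    if (!is.null(node$backward) && length(node$parents) > 0) {
      pg <- node$backward(g)
      for (k in seq_along(node$parents)) {
        pid <- node$parents[k]
        if (is.null(grads_n[[pid]])) {
          grads_n[[pid]] <- pg[[k]]
        } else {
          grads_n[[pid]] <- grads_n[[pid]] + pg[[k]]
        }
      }
    }
  }
  invisible(tape$grads)
}
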