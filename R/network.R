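# The torsion-prediction network. Two stages:
#   (1) a graph stage: atom features + graph position vectors run through
#       full (unmasked) multi-head self-attention, then a per-rotatable-bond
#       readout combining the bond's atoms, terminal groups and neighboring
#       edge features into one torsion representation tau_l^0;
#   (2) a sequence stage: a transformer encoder (no added positional
#       encoding; Gaussian noise on the input supplies sampling diversity)
#       followed by an autoregressive decoder that emits one normalized
#       torsion angle per step, conditioned on the conformer's relative
#       energy (start token) and on all previously generated angles.
# Output angles are parameterized as L2-normalized (cos, sin) pairs to avoid
# the branch cut at +/- pi.

#' Model configuration
#'
#' @param hidden model width D.
#' @param heads attention heads (must divide `hidden`).
#' @param atom_layers depth of the atomic self-attention stack.
#' @param encoder_layers,decoder_layers transformer depths.
#' @param ff_mult width multiplier of the position-wise feed-forward layers.
#' @param noise_std standard deviation of the Gaussian noise added to the
#'   torsion representations before the encoder (representation units);
#'   0 makes the encoder deterministic.
#' @param max_atoms maximum heavy-atom count (fixes the adjacency-projection
#'   input width).
#' @param wl_iterations,wl_buckets Weisfeiler-Lehman refinement rounds and
#'   hash-bucket vocabulary for the WL embedding.
#' @param d_wl,d_deg,d_adj widths of the three position-vector parts.
#' @param pos_mode `"full"` (WL + degree + adjacency), `"learnable"`
#'   (index-based embedding), or `"none"` — the three ablation variants.
#' @param energy_mode `"start_token"` (energy embedding as the first decoder
#'   token) or `"every_step"` (additionally added to every decoder token).
#' @param loss `"cosine"` (mean 1 - cos of the wrapped error) or
#'   `"sincos_mse"`.
#' @param seed parameter-initialization seed.
#' @return object of class `tc_config`.
#' @export
model_config <- function(hidden = 128, heads = 4, atom_layers = 2,
                         encoder_layers = 4, decoder_layers = 4,
                         ff_mult = 2, noise_std = 5.0, max_atoms = 64,
                         wl_iterations = 3, wl_buckets = 1024,
                         d_wl = 8, d_deg = 4, d_adj = 8,
                         pos_mode = c("full", "learnable", "none"),
                         energy_mode = c("start_token", "every_step"),
                         loss = c("cosine", "sincos_mse"), seed = 1) {
  pos_mode <- match.arg(pos_mode)
  energy_mode <- match.arg(energy_mode)
  loss <- match.arg(loss)
  stopifnot(hidden %% heads == 0, atom_layers >= 1, encoder_layers >= 1,
            decoder_layers >= 1, noise_std >= 0)
  structure(as.list(environment()), class = "tc_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

xavier <- function(fi, fo) {
  a <- sqrt(6 / (fi + fo))
  matrix(stats::runif(fi * fo, -a, a), fi, fo)
}

init_layer <- function(p, prefix, d, dff) {
  p[[paste0(prefix, "Wq")]] <- xavier(d, d)
  p[[paste0(prefix, "bq")]] <- matrix(0, 1, d)
  p[[paste0(prefix, "Wk")]] <- xavier(d, d)
  p[[paste0(prefix, "bk")]] <- matrix(0, 1, d)
  p[[paste0(prefix, "Wv")]] <- xavier(d, d)
  p[[paste0(prefix, "bv")]] <- matrix(0, 1, d)
  p[[paste0(prefix, "Wo")]] <- xavier(d, d)
  p[[paste0(prefix, "bo")]] <- matrix(0, 1, d)
  p[[paste0(prefix, "ln1g")]] <- matrix(1, 1, d)
  p[[paste0(prefix, "ln1b")]] <- matrix(0, 1, d)
  if (!is.null(dff)) {
    p[[paste0(prefix, "W1")]] <- xavier(d, dff)
    p[[paste0(prefix, "b1")]] <- matrix(0, 1, dff)
    p[[paste0(prefix, "W2")]] <- xavier(dff, d)
    p[[paste0(prefix, "b2")]] <- matrix(0, 1, d)
    p[[paste0(prefix, "ln2g")]] <- matrix(1, 1, d)
    p[[paste0(prefix, "ln2b")]] <- matrix(0, 1, d)
  }
  p
}

#' Initialize a model
#'
#' @param config a `tc_config`.
#' @return object of class `tc_model` (config + parameter list).
#' @export
model_init <- function(config = model_config()) {
  with_seed(config$seed, {
    d <- config$hidden
    dff <- d * config$ff_mult
    P <- pos_width(config)
    p <- list()
    if (config$pos_mode == "full") {
      p$E_wl <- matrix(stats::rnorm(config$wl_buckets * config$d_wl,
                                    sd = 0.1), config$wl_buckets)
      p$E_deg <- matrix(stats::rnorm(7 * config$d_deg, sd = 0.1), 7)
      p$W_adj <- xavier(config$max_atoms, config$d_adj)
    } else if (config$pos_mode == "learnable") {
      p$E_idx <- matrix(stats::rnorm(config$max_atoms * P, sd = 0.1),
                        config$max_atoms)
    }
    p$W_embed <- xavier(ATOM_FEATURE_WIDTH + P, d)
    p$b_embed <- matrix(0, 1, d)
    for (t in seq_len(config$atom_layers)) {
      p <- init_layer(p, sprintf("atom%d_", t), d, dff)
    }
    p$W_read <- xavier(4 * d + 3 * BOND_FEATURE_WIDTH, d)
    p$b_read <- matrix(0, 1, d)
    for (n in seq_len(config$encoder_layers)) {
      p <- init_layer(p, sprintf("enc%d_", n), d, dff)
    }
    for (m in seq_len(config$decoder_layers)) {
      p <- init_layer(p, sprintf("dec%d_self_", m), d, NULL)
      p <- init_layer(p, sprintf("dec%d_cross_", m), d, NULL)
      p[[sprintf("dec%d_W1", m)]] <- xavier(d, dff)
      p[[sprintf("dec%d_b1", m)]] <- matrix(0, 1, dff)
      p[[sprintf("dec%d_W2", m)]] <- xavier(dff, d)
      p[[sprintf("dec%d_b2", m)]] <- matrix(0, 1, d)
      p[[sprintf("dec%d_ln3g", m)]] <- matrix(1, 1, d)
      p[[sprintf("dec%d_ln3b", m)]] <- matrix(0, 1, d)
    }
    p$We1 <- xavier(1, d)
    p$be1 <- matrix(0, 1, d)
    p$We2 <- xavier(d, d)
    p$be2 <- matrix(0, 1, d)
    p$W_ang <- xavier(2, d)
    p$b_ang <- matrix(0, 1, d)
    p$W_out <- xavier(d, 2)
    p$b_out <- matrix(0, 1, 2)
    structure(list(config = config, params = p,
                   feature_widths = c(atom = ATOM_FEATURE_WIDTH,
                                      bond = BOND_FEATURE_WIDTH),
                   version = as.character(utils::packageVersion(
                     "torsionconf"))),
              class = "tc_model")
  })
}

#' @export
print.tc_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<tc_model> D=%d heads=%d T=%d N=%d M=%d pos=%s ",
                     "(%d parameters)\n"),
              x$config$hidden, x$config$heads, x$config$atom_layers,
              x$config$encoder_layers, x$config$decoder_layers,
              x$config$pos_mode, np))
  invisible(x)
}

params_env <- function(params) {
  list2env(params, new.env(parent = emptyenv()))
}

# ---- forward building blocks (tape) ----------------------------------------

tape_mha <- function(tape, q, kv, prefix, heads, mask = NULL,
                     attn_tag = NULL) {
  P <- function(nm) ad_param(tape, paste0(prefix, nm))
  Q <- ad_bias(tape, ad_matmul(tape, q, P("Wq")), P("bq"))
  K <- ad_bias(tape, ad_matmul(tape, kv, P("Wk")), P("bk"))
  V <- ad_bias(tape, ad_matmul(tape, kv, P("Wv")), P("bv"))
  d <- ncol(Q$value)
  dk <- d %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    qh <- ad_cols(tape, Q, idx)
    kh <- ad_cols(tape, K, idx)
    vh <- ad_cols(tape, V, idx)
    att <- ad_softmax_rows(
      tape, ad_scale(tape, ad_matmul(tape, qh, ad_transpose(tape, kh)),
                     1 / sqrt(dk)), mask)
    if (!is.null(attn_tag)) {
      if (is.null(tape$attn)) tape$attn <- list()
      tape$attn[[paste0(attn_tag, "_h", h)]] <- att$value
    }
    outs[[h]] <- ad_matmul(tape, att, vh)
  }
  o <- if (heads == 1) outs[[1]] else ad_concat_cols(tape, outs)
  ad_bias(tape, ad_matmul(tape, o, P("Wo")), P("bo"))
}

tape_ffn <- function(tape, x, prefix) {
  P <- function(nm) ad_param(tape, paste0(prefix, nm))
  h <- ad_relu(tape, ad_bias(tape, ad_matmul(tape, x, P("W1")), P("b1")))
  ad_bias(tape, ad_matmul(tape, h, P("W2")), P("b2"))
}

tape_encoder_layer <- function(tape, x, prefix, heads, mask = NULL,
                               attn_tag = NULL) {
  a <- tape_mha(tape, x, x, prefix, heads, mask, attn_tag)
  x <- ad_layernorm(tape, ad_add(tape, x, a),
                    paste0(prefix, "ln1g"), paste0(prefix, "ln1b"))
  f <- tape_ffn(tape, x, prefix)
  ad_layernorm(tape, ad_add(tape, x, f),
               paste0(prefix, "ln2g"), paste0(prefix, "ln2b"))
}

tape_decoder_layer <- function(tape, x, mem, m, heads, causal_mask,
                               attn_tag = NULL) {
  pre_self <- sprintf("dec%d_self_", m)
  pre_cross <- sprintf("dec%d_cross_", m)
  a <- tape_mha(tape, x, x, pre_self, heads, causal_mask,
                if (is.null(attn_tag)) NULL else paste0(attn_tag, "_self"))
  x <- ad_layernorm(tape, ad_add(tape, x, a),
                    paste0(pre_self, "ln1g"), paste0(pre_self, "ln1b"))
  a2 <- tape_mha(tape, x, mem, pre_cross, heads, NULL,
                 if (is.null(attn_tag)) NULL else paste0(attn_tag, "_cross"))
  x <- ad_layernorm(tape, ad_add(tape, x, a2),
                    paste0(pre_cross, "ln1g"), paste0(pre_cross, "ln1b"))
  P <- function(nm) ad_param(tape, sprintf("dec%d_%s", m, nm))
  h <- ad_relu(tape, ad_bias(tape, ad_matmul(tape, x, P("W1")), P("b1")))
  f <- ad_bias(tape, ad_matmul(tape, h, P("W2")), P("b2"))
  ad_layernorm(tape, ad_add(tape, x, f),
               sprintf("dec%d_ln3g", m), sprintf("dec%d_ln3b", m))
}

edge_readout_matrix <- function(graph, specs) {
  t(vapply(specs, function(s) {
    e_ai <- colMeans(do.call(rbind, lapply(s$a_group, function(a)
      bond_feature_of(graph, a, s$i))))
    e_bj <- colMeans(do.call(rbind, lapply(s$b_group, function(b)
      bond_feature_of(graph, b, s$j))))
    e_ij <- bond_feature_of(graph, s$i, s$j)
    c(e_ai, e_ij, e_bj)
  }, numeric(3 * BOND_FEATURE_WIDTH)))
}

forward_tau0 <- function(tape, graph, specs, config, keep_attention = FALSE) {
  n <- graph$n
  if (n < 1) stop("empty molecule")
  feat <- ad_const(tape, graph$atom_features)
  h0 <- switch(config$pos_mode,
    none = feat,
    learnable = {
      if (n > config$max_atoms) stop("molecule exceeds max_atoms")
      ad_concat_cols(tape, list(feat, ad_embed(tape, "E_idx", seq_len(n))))
    },
    full = {
      wb <- wl_buckets(graph, config$wl_iterations, config$wl_buckets)
      pos_wl <- ad_embed(tape, "E_wl", wb)
      pos_d <- ad_embed(tape, "E_deg", pmin(graph$degree, 6) + 1L)
      pos_a <- ad_matmul(tape, ad_const(tape,
                                        padded_adjacency(graph,
                                                         config$max_atoms)),
                         ad_param(tape, "W_adj"))
      ad_concat_cols(tape, list(feat, pos_wl, pos_d, pos_a))
    })
  x <- ad_bias(tape, ad_matmul(tape, h0, ad_param(tape, "W_embed")),
               ad_param(tape, "b_embed"))
  for (t in seq_len(config$atom_layers)) {
    x <- tape_encoder_layer(tape, x, sprintf("atom%d_", t), config$heads,
                            attn_tag = if (keep_attention)
                              sprintf("atom%d", t) else NULL)
  }
  H <- x
  if (length(specs) == 0) return(list(tau0 = NULL, H = H))
  rows <- lapply(specs, function(s) {
    ad_concat_cols(tape, list(
      ad_mean_rows(tape, H, s$a_group),
      ad_rows_select(tape, H, s$i),
      ad_rows_select(tape, H, s$j),
      ad_mean_rows(tape, H, s$b_group)))
  })
  h_atoms <- if (length(rows) == 1) rows[[1]] else ad_rbind(tape, rows)
  e_edges <- ad_const(tape, edge_readout_matrix(graph, specs))
  tau0 <- ad_bias(tape,
                  ad_matmul(tape,
                            ad_concat_cols(tape, list(h_atoms, e_edges)),
                            ad_param(tape, "W_read")),
                  ad_param(tape, "b_read"))
  list(tau0 = tau0, H = H)
}

forward_encoder <- function(tape, tau0, config, noise = NULL,
                            keep_attention = FALSE) {
  x <- if (is.null(noise)) tau0 else ad_add_const(tape, tau0, noise)
  for (nl in seq_len(config$encoder_layers)) {
    x <- tape_encoder_layer(tape, x, sprintf("enc%d_", nl), config$heads,
                            attn_tag = if (keep_attention)
                              sprintf("enc%d", nl) else NULL)
  }
  x
}

causal_mask <- function(L) {
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- -Inf
  m
}

# Teacher-forced (or prefix) decoder forward. prev_angles has length L-1:
# the angles feeding token slots 2..L. Token slot 1 is the energy embedding.
forward_decoder <- function(tape, mem, energy, prev_angles, config,
                            keep_attention = FALSE) {
  d <- config$hidden
  L <- length(prev_angles) + 1
  e <- ad_const(tape, matrix(energy, 1, 1))
  u <- ad_bias(tape, ad_matmul(tape, e, ad_param(tape, "We1")),
               ad_param(tape, "be1"))
  u <- ad_bias(tape, ad_matmul(tape, ad_relu(tape, u),
                               ad_param(tape, "We2")),
               ad_param(tape, "be2"))
  tgt <- if (L == 1) {
    u
  } else {
    angfeat <- cbind(cos(prev_angles), sin(prev_angles))
    tok <- ad_bias(tape, ad_matmul(tape, ad_const(tape, angfeat),
                                   ad_param(tape, "W_ang")),
                   ad_param(tape, "b_ang"))
    ad_rbind(tape, list(u, tok))
  }
  tgt <- ad_add_const(tape, tgt, sinusoidal_encoding(0:(L - 1), d))
  if (config$energy_mode == "every_step" && L > 1) {
    tgt <- ad_add(tape, tgt, ad_rbind(tape, rep(list(u), L)))
  }
  mask <- causal_mask(L)
  x <- tgt
  for (m in seq_len(config$decoder_layers)) {
    x <- tape_decoder_layer(tape, x, mem, m, config$heads, mask,
                            attn_tag = if (keep_attention)
                              sprintf("dec%d", m) else NULL)
  }
  out <- ad_bias(tape, ad_matmul(tape, x, ad_param(tape, "W_out")),
                 ad_param(tape, "b_out"))
  ad_l2norm_rows(tape, out)  # columns: (cos, sin), unit rows
}

sincos_to_angle <- function(y) wrap_angle(atan2(y[, 2], y[, 1]))

# ---- public operations -----------------------------------------------------

#' Update atom representations by full self-attention
#'
#' @param model `tc_model`.
#' @param graph `tc_molgraph`.
#' @return numeric matrix n x D of updated atom representations.
#' @export
update_atoms <- function(model, graph) {
  if (graph$n < 1) stop("empty molecule")
  tape <- ad_tape(params_env(model$params))
  # readout needs specs; here we only want H, so forward the atom stack
  res <- forward_tau0(tape, graph, specs = list(), config = model$config)
  res$H$value
}

#' Read out initial torsion representations
#'
#' @param model `tc_model`.
#' @param graph `tc_molgraph`.
#' @param specs non-empty list of `tc_torsion`.
#' @return numeric matrix L x D (one row per rotatable bond).
#' @export
readout_torsions <- function(model, graph, specs) {
  if (length(specs) == 0) stop("no torsion specs supplied")
  tape <- ad_tape(params_env(model$params))
  res <- forward_tau0(tape, graph, specs, model$config)
  res$tau0$value
}

#' Encode torsion representations (with sampling noise)
#'
#' @param model `tc_model`.
#' @param tau0 L x D matrix of initial torsion representations.
#' @param noise_std Gaussian noise standard deviation; defaults to the model
#'   config value. 0 gives a deterministic map.
#' @param seed seed for the noise draw.
#' @return L x D matrix of encoded representations.
#' @export
model_encode <- function(model, tau0, noise_std = NULL, seed = 1) {
  noise_std <- noise_std %||% model$config$noise_std
  noise <- if (noise_std > 0) {
    with_seed(seed, matrix(stats::rnorm(length(tau0), sd = noise_std),
                           nrow(tau0)))
  } else NULL
  tape <- ad_tape(params_env(model$params))
  forward_encoder(tape, ad_const(tape, tau0), model$config, noise)$value
}

#' Autoregressive decode of a torsion-angle sequence
#'
#' With `teacher_angles` supplied, all steps are computed in one
#' teacher-forced pass (step l sees the true angles of steps < l). Without,
#' the decoder runs free: each step consumes its own previous predictions.
#'
#' @param model `tc_model`.
#' @param mem L x D encoded torsion representations.
#' @param energy conditioning relative energy, kcal/mol (>= 0).
#' @param teacher_angles optional numeric vector of length L.
#' @return list with `angles` (wrapped, radians) and `sincos`
#'   (L x 2 unit-norm matrix).
#' @export
decode_autoregressive <- function(model, mem, energy, teacher_angles = NULL) {
  stopifnot(energy >= 0)
  L <- nrow(mem)
  if (L == 0) stop("empty torsion sequence")
  config <- model$config
  env <- params_env(model$params)
  if (!is.null(teacher_angles)) {
    if (length(teacher_angles) != L) {
      stop("teacher_angles length ", length(teacher_angles),
           " does not match torsion count ", L)
    }
    tape <- ad_tape(env)
    y <- forward_decoder(tape, ad_const(tape, mem), energy,
                         utils::head(teacher_angles, -1)[seq_len(L - 1)],
                         config)
    return(list(angles = sincos_to_angle(y$value), sincos = y$value))
  }
  angles <- numeric(0)
  y_last <- NULL
  for (l in seq_len(L)) {
    tape <- ad_tape(env)
    mem_l <- ad_const(tape, mem)
    y <- forward_decoder(tape, mem_l, energy, angles, config)
    angles <- c(angles, sincos_to_angle(
      y$value[l, , drop = FALSE]))
    y_last <- y$value
  }
  list(angles = wrap_angle(angles), sincos = y_last)
}

#' Predict torsion-angle sequences for a molecule
#'
#' Runs the full pipeline (graph stage, noisy encoder, free-running decoder)
#' `n_samples` times; samples differ only through the encoder noise draw and
#' are deterministic per (seed, sample index). Predictions depend only on the
#' 2D graph, the conditioning energy and the seed — never on any 3D input.
#'
#' @param model `tc_model`.
#' @param graph `tc_molgraph`.
#' @param specs torsion specs; defaults to [find_rotatable_bonds()].
#' @param energy conditioning relative energy (kcal/mol); may be a vector of
#'   length `n_samples` for per-sample conditioning.
#' @param n_samples number of angle sequences to draw.
#' @param seed base seed for the noise draws.
#' @param keep_attention if TRUE, attach the attention maps of the last
#'   sample as attribute `"attention"`.
#' @return list of numeric angle vectors (wrapped radians), one per sample.
#'   Rigid molecules give empty vectors with a warning.
#' @export
model_predict <- function(model, graph, specs = NULL, energy = 0,
                          n_samples = 1, seed = 1, keep_attention = FALSE) {
  specs <- specs %||% find_rotatable_bonds(graph)
  if (length(specs) == 0) {
    warning("molecule has no rotatable bonds; returning empty sequences")
    return(rep(list(numeric(0)), n_samples))
  }
  energies <- rep_len(energy, n_samples)
  tau0 <- readout_torsions(model, graph, specs)
  out <- vector("list", n_samples)
  attn <- NULL
  for (s in seq_len(n_samples)) {
    seed_s <- (as.numeric(seed) * 100003 + s) %% 2147483647
    mem <- model_encode(model, tau0, seed = seed_s)
    dec <- decode_autoregressive(model, mem, energies[s])
    out[[s]] <- dec$angles
  }
  if (keep_attention) {
    tape <- ad_tape(params_env(model$params))
    res <- forward_tau0(tape, graph, specs, model$config,
                        keep_attention = TRUE)
    mem <- forward_encoder(tape, res$tau0, model$config, NULL,
                           keep_attention = TRUE)
    forward_decoder(tape, mem, energies[n_samples],
                    utils::head(out[[n_samples]], -1), model$config,
                    keep_attention = TRUE)
    attr(out, "attention") <- tape$attn
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the weights, the model
#' config, and the feature-vocabulary widths.
#'
#' @param model `tc_model`.
#' @param path checkpoint path.
#' @return `path` (save) or a `tc_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$params), !is.null(obj$config))
  structure(obj, class = "tc_model")
}
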