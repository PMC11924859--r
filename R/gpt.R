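#' Character vocabulary of a cell corpus
#'
#' The ordered distinct characters of the corpus (code-point sort) plus
#' the `<EOS>` end-of-cell token, mapped to dense ids from 1.
#'
#' @param corpus character vector of cell contents.
#' @return a `table_vocab`: `chars`, `codes` (code points), `eos_id`,
#'   `size`.
#' @export
build_vocab <- function(corpus) {
  corpus <- corpus[!is.na(corpus)]
  if (length(corpus) == 0 || all(!nzchar(corpus))) {
    abort("build_vocab: empty corpus")
  }
  codes <- sort(unique(unlist(lapply(corpus, utf8ToInt), use.names = FALSE)))
  structure(list(chars = intToUtf8(codes, multiple = TRUE), codes = codes,
                 eos_id = length(codes) + 1L, size = length(codes) + 1L),
            class = "table_vocab")
}

#' @export
print.table_vocab <- function(x, ...) {
  cat(sprintf("<table_vocab: %d characters + <EOS>>\n", x$size - 1L))
  invisible(x)
}

# Encode text to vocabulary ids; characters absent from the vocabulary
# are dropped (the embedding cannot be extended after training).
encode_text <- function(text, vocab) {
  ids <- match(utf8ToInt(text), vocab$codes)
  ids[!is.na(ids)]
}

#' Transformer language-model configuration
#'
#' Decoder-only architecture: learned token and positional embeddings,
#' `n_layers` pre-norm blocks of causal multi-head self-attention and a
#' GELU feed-forward of width `4 * d_model`, a final layer norm, and a
#' generative head tied to the token embedding. The `"paper"` preset
#' (6 layers, 6 heads, 384 dims, 256 context) matches the full-scale
#' model; the `"tiny"` preset (2, 2, 64, 64) is sized for CPU training
#' on synthetic corpora.
#'
#' @param preset `"tiny"` or `"paper"`, or `NULL` to give sizes directly.
#' @param n_layers,n_heads,d_model,context_len architecture sizes.
#' @param d_ff feed-forward width, default `4 * d_model`.
#' @return an `lm_config` list.
#' @export
lm_config <- function(preset = NULL, n_layers = 6L, n_heads = 6L,
                      d_model = 384L, context_len = 256L,
                      d_ff = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "paper"))
    if (preset == "tiny") {
      n_layers <- 2L; n_heads <- 2L; d_model <- 64L; context_len <- 64L
    } else {
      n_layers <- 6L; n_heads <- 6L; d_model <- 384L; context_len <- 256L
    }
  }
  d_ff <- d_ff %||% (4L * d_model)
  if (d_model %% n_heads != 0) abort("lm_config: d_model must be divisible by n_heads")
  if (context_len < 2) abort("lm_config: context_len must be >= 2")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 context_len = as.integer(context_len),
                 d_ff = as.integer(d_ff)),
            class = "lm_config")
}

init_params <- function(vocab_size, cfg, head = FALSE) {
  d <- cfg$d_model; dff <- cfg$d_ff
  sdv <- 0.02
  res_scale <- 1 / sqrt(2 * cfg$n_layers)
  p <- list(
    wte = matrix(rnorm(vocab_size * d, 0, sdv), vocab_size, d),
    wpe = matrix(rnorm(cfg$context_len * d, 0, sdv), cfg$context_len, d))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d.", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "w_qkv")]] <- matrix(rnorm(d * 3 * d, 0, sdv), d, 3 * d)
    p[[paste0(pre, "b_qkv")]] <- rep(0, 3 * d)
    p[[paste0(pre, "w_o")]] <- matrix(rnorm(d * d, 0, sdv * res_scale), d, d)
    p[[paste0(pre, "b_o")]] <- rep(0, d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "w_fc")]] <- matrix(rnorm(d * dff, 0, sdv), d, dff)
    p[[paste0(pre, "b_fc")]] <- rep(0, dff)
    p[[paste0(pre, "w_proj")]] <- matrix(rnorm(dff * d, 0, sdv * res_scale), dff, d)
    p[[paste0(pre, "b_proj")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  if (head) {
    p$head_w <- rep(0, d)
    p$head_b <- 0
  }
  p
}

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  rstd <- 1 / sqrt(v + eps)
  xhat <- xc * rstd
  y <- sweep(xhat, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(y = y, xhat = xhat, rstd = rstd)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = cache$rstd * (dxhat - m1 - xhat * m2),
       dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

add_bias <- function(x, b) sweep(x, 2, b, "+")

# Forward pass through the transformer trunk. ids: B x T matrix of
# vocabulary ids. Returns the final-layer-norm output (B*T rows, row
# (b-1)*T + t is position t of sequence b) plus the caches needed for
# backprop.
trunk_fwd <- function(p, cfg, ids) {
  B <- nrow(ids); T <- ncol(ids)
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  ids_vec <- as.vector(t(ids))
  pos_vec <- rep(seq_len(T), B)
  x <- p$wte[ids_vec, , drop = FALSE] + p$wpe[pos_vec, , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  scale <- 1 / sqrt(dh)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d.", l)
    ln1 <- ln_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    qkv <- add_bias(ln1$y %*% p[[paste0(pre, "w_qkv")]], p[[paste0(pre, "b_qkv")]])
    att <- matrix(0, B * T, d)
    P_list <- vector("list", B * H)
    for (b in seq_len(B)) {
      rows <- (b - 1) * T + seq_len(T)
      for (h in seq_len(H)) {
        cols <- (h - 1) * dh + seq_len(dh)
        Qh <- qkv[rows, cols, drop = FALSE]
        Kh <- qkv[rows, d + cols, drop = FALSE]
        Vh <- qkv[rows, 2 * d + cols, drop = FALSE]
        S <- (Qh %*% t(Kh)) * scale
        S[upper.tri(S)] <- -Inf  # causal: t attends only to positions <= t
        S <- S - apply(S, 1, max)
        P <- exp(S)
        P <- P / rowSums(P)
        att[rows, cols] <- P %*% Vh
        P_list[[(b - 1) * H + h]] <- P
      }
    }
    proj <- add_bias(att %*% p[[paste0(pre, "w_o")]], p[[paste0(pre, "b_o")]])
    x1 <- x + proj
    ln2 <- ln_fwd(x1, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    fc_pre <- add_bias(ln2$y %*% p[[paste0(pre, "w_fc")]], p[[paste0(pre, "b_fc")]])
    fc_act <- gelu_fwd(fc_pre)
    mlp <- add_bias(fc_act %*% p[[paste0(pre, "w_proj")]], p[[paste0(pre, "b_proj")]])
    x2 <- x1 + mlp
    caches[[l]] <- list(x = x, ln1 = ln1, qkv = qkv, P_list = P_list,
                        att = att, x1 = x1, ln2 = ln2, fc_pre = fc_pre,
                        fc_act = fc_act)
    x <- x2
  }
  lnf <- ln_fwd(x, p$lnf_g, p$lnf_b)
  list(xf = lnf$y, lnf = lnf, x_last = x, caches = caches,
       ids_vec = ids_vec, pos_vec = pos_vec, B = B, T = T)
}

# Backward pass; dxf is the gradient at the final-layer-norm output.
# Returns the full gradient list (wte gradient excludes any tied head
# contribution, which the caller adds).
trunk_bwd <- function(p, cfg, fwd, dxf) {
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  B <- fwd$B; T <- fwd$T
  scale <- 1 / sqrt(dh)
  g <- list()
  lb <- ln_bwd(dxf, fwd$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("l%d.", l)
    cc <- fwd$caches[[l]]
    # MLP branch
    dmlp <- dx
    g[[paste0(pre, "b_proj")]] <- colSums(dmlp)
    g[[paste0(pre, "w_proj")]] <- crossprod(cc$fc_act, dmlp)
    dfc_act <- tcrossprod(dmlp, p[[paste0(pre, "w_proj")]])
    dfc_pre <- dfc_act * gelu_bwd(cc$fc_pre)
    g[[paste0(pre, "b_fc")]] <- colSums(dfc_pre)
    g[[paste0(pre, "w_fc")]] <- crossprod(cc$ln2$y, dfc_pre)
    dln2y <- tcrossprod(dfc_pre, p[[paste0(pre, "w_fc")]])
    lb2 <- ln_bwd(dln2y, cc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dx1 <- dx + lb2$dx
    # attention branch
    dproj <- dx1
    g[[paste0(pre, "b_o")]] <- colSums(dproj)
    g[[paste0(pre, "w_o")]] <- crossprod(cc$att, dproj)
    datt <- tcrossprod(dproj, p[[paste0(pre, "w_o")]])
    dqkv <- matrix(0, B * T, 3 * d)
    for (b in seq_len(B)) {
      rows <- (b - 1) * T + seq_len(T)
      for (h in seq_len(H)) {
        cols <- (h - 1) * dh + seq_len(dh)
        P <- cc$P_list[[(b - 1) * H + h]]
        Qh <- cc$qkv[rows, cols, drop = FALSE]
        Kh <- cc$qkv[rows, d + cols, drop = FALSE]
        Vh <- cc$qkv[rows, 2 * d + cols, drop = FALSE]
        dO <- datt[rows, cols, drop = FALSE]
        dP <- tcrossprod(dO, Vh)
        dV <- crossprod(P, dO)
        dS <- P * (dP - rowSums(dP * P))
        dqkv[rows, cols] <- (dS %*% Kh) * scale
        dqkv[rows, d + cols] <- (crossprod(dS, Qh)) * scale
        dqkv[rows, 2 * d + cols] <- dV
      }
    }
    g[[paste0(pre, "b_qkv")]] <- colSums(dqkv)
    g[[paste0(pre, "w_qkv")]] <- crossprod(cc$ln1$y, dqkv)
    dln1y <- tcrossprod(dqkv, p[[paste0(pre, "w_qkv")]])
    lb1 <- ln_bwd(dln1y, cc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dx <- dx1 + lb1$dx
  }
  # embedding gradients
  g$wte <- matrix(0, nrow(p$wte), d)
  agg <- rowsum(dx, fwd$ids_vec)
  g$wte[as.integer(rownames(agg)), ] <- agg
  g$wpe <- matrix(0, nrow(p$wpe), d)
  aggp <- rowsum(dx, fwd$pos_vec)
  g$wpe[as.integer(rownames(aggp)), ] <- aggp
  g
}

# Language-model loss and gradient on one batch. targets: B x T matrix of
# next-character ids, NA where no loss applies. Tied head: logits =
# xf %*% t(wte).
lm_loss_grad <- function(p, cfg, ids, targets, want_grad = TRUE) {
  fwd <- trunk_fwd(p, cfg, ids)
  logits <- tcrossprod(fwd$xf, p$wte)
  tgt <- as.vector(t(targets))
  valid <- which(!is.na(tgt))
  lmax <- apply(logits, 1, max)
  ex <- exp(logits - lmax)
  Z <- rowSums(ex)
  logp <- logits - lmax - log(Z)
  loss <- -mean(logp[cbind(valid, tgt[valid])])
  if (!want_grad) return(list(loss = loss))
  probs <- ex / Z
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[valid, ] <- probs[valid, , drop = FALSE] / length(valid)
  dlogits[cbind(valid, tgt[valid])] <-
    dlogits[cbind(valid, tgt[valid])] - 1 / length(valid)
  dxf <- dlogits %*% p$wte
  g <- trunk_bwd(p, cfg, fwd, dxf)
  g$wte <- g$wte + crossprod(dlogits, fwd$xf)  # tied generative head
  list(loss = loss, grad = g)
}

adam_state <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(p = p, st = st)
}

#' Pre-train the character-level table language model
#'
#' Auto-regressive next-character objective over cell contents, each
#' terminated by `<EOS>`: the cells are packed into one id stream and
#' trained on fixed-length windows of `context_len` characters with
#' cross-entropy loss, Adam, and a generative head tied to the token
#' embedding. Deterministic given `seed`.
#'
#' @param corpus character vector of cell contents.
#' @param config an [lm_config()].
#' @param seed RNG seed.
#' @param steps optimizer steps (>= 1).
#' @param lr Adam learning rate.
#' @param batch_size sequences per step.
#' @param vocab optionally a pre-built [build_vocab()] vocabulary.
#' @return a `table_lm`: `params`, `config`, `vocab`, `loss_trace`.
#' @export
pretrain_lm <- function(corpus, config = lm_config(preset = "tiny"),
                        seed = 1L, steps = 200L, lr = 1e-3,
                        batch_size = 16L, vocab = NULL) {
  if (steps < 1) abort("pretrain_lm: `steps` must be >= 1")
  vocab <- vocab %||% build_vocab(corpus)
  T <- config$context_len
  stream <- unlist(lapply(corpus, function(s) c(encode_text(s, vocab),
                                                vocab$eos_id)),
                   use.names = FALSE)
  if (length(stream) < T + 1) {
    stream <- rep(stream, ceiling((T + 1) / length(stream)))
  }
  if (length(stream) < T + 1) abort("pretrain_lm: sequence packing produced zero batches")
  starts <- seq(1L, length(stream) - T, by = T)
  withr::with_seed(seed, {
    p <- init_params(vocab$size, config)
    st <- adam_state(p)
    trace <- numeric(steps)
    for (step in seq_len(steps)) {
      s <- sample(starts, batch_size, replace = TRUE)
      ids <- t(vapply(s, function(k) stream[k:(k + T - 1)], integer(T)))
      tgt <- t(vapply(s, function(k) stream[(k + 1):(k + T)], integer(T)))
      lg <- lm_loss_grad(p, config, ids, tgt)
      trace[step] <- lg$loss
      upd <- adam_step(p, lg$grad, st, lr)
      p <- upd$p; st <- upd$st
    }
    structure(list(params = p, config = config, vocab = vocab,
                   loss_trace = trace),
              class = "table_lm")
  })
}

#' @export
print.table_lm <- function(x, ...) {
  cat(sprintf("<table_lm: %d layers, %d heads, d=%d, context=%d, vocab=%d, %s params>\n",
              x$config$n_layers, x$config$n_heads, x$config$d_model,
              x$config$context_len, x$vocab$size,
              format(n_params(x$params), big.mark = ",")))
  if (length(x$loss_trace)) {
    cat(sprintf("  final training loss: %.4f nats/char\n",
                tail(x$loss_trace, 1)))
  }
  invisible(x)
}

n_params <- function(p) sum(vapply(p, length, integer(1)))

#' Mean next-character loss of a language model on a corpus
#'
#' @param lm a `table_lm`.
#' @param corpus character vector of cells.
#' @return mean cross-entropy in nats per character.
#' @export
lm_corpus_loss <- function(lm, corpus) {
  T <- lm$config$context_len
  stream <- unlist(lapply(corpus, function(s) c(encode_text(s, lm$vocab),
                                                lm$vocab$eos_id)),
                   use.names = FALSE)
  if (length(stream) < T + 1) stream <- rep(stream, ceiling((T + 1) / length(stream)))
  starts <- seq(1L, length(stream) - T, by = T)
  ids <- t(vapply(starts, function(k) stream[k:(k + T - 1)], integer(T)))
  tgt <- t(vapply(starts, function(k) stream[(k + 1):(k + T)], integer(T)))
  lm_loss_grad(lm$params, lm$config, ids, tgt, want_grad = FALSE)$loss
}

#' Next-character logits at every position of an id sequence
#'
#' @param lm a `table_lm`.
#' @param ids integer vector of vocabulary ids (length <= context_len).
#' @return matrix, one row per position, one column per vocabulary id.
#' @export
lm_logits <- function(lm, ids) {
  fwd <- trunk_fwd(lm$params, lm$config, matrix(ids, nrow = 1))
  tcrossprod(fwd$xf, lm$params$wte)
}

#' Encode a vertical cell pair for the merge classifier
#'
#' The input is `upper | <EOS> | lower` (`|` the concatenation
#' operator). When the result exceeds `context_len`, the tail of the
#' upper cell and the head of the lower cell are kept — the upper
#' truncated to at most `floor((context_len - 1) / 2)` characters when
#' both sides are long — so the `<EOS>` boundary, which carries the
#' merge signal, is always present.
#'
#' @param upper,lower cell strings (upper may be empty).
#' @param vocab a [build_vocab()] vocabulary.
#' @param context_len maximum sequence length (>= 3).
#' @return integer id sequence.
#' @export
encode_pair <- function(upper, lower, vocab, context_len) {
  if (context_len < 3) abort("encode_pair: `context_len` must be >= 3")
  u <- encode_text(upper, vocab)
  l <- encode_text(lower, vocab)
  L <- context_len
  if (length(u) + length(l) + 1 > L) {
    keep_l <- min(length(l), L - 1 - min(length(u), floor((L - 1) / 2)))
    keep_u <- min(length(u), L - 1 - keep_l)
    u <- if (keep_u > 0) tail(u, keep_u) else integer(0)
    l <- if (keep_l > 0) head(l, keep_l) else integer(0)
  }
  c(u, vocab$eos_id, l)
}

cls_batch_fwd <- function(p, cfg, seqs) {
  lens <- lengths(seqs)
  T <- max(lens)
  B <- length(seqs)
  ids <- matrix(1L, B, T)
  for (b in seq_len(B)) {
    ids[b, seq_len(lens[b])] <- seqs[[b]]
    if (lens[b] < T) ids[b, (lens[b] + 1):T] <- seqs[[b]][lens[b]]  # pad
  }
  fwd <- trunk_fwd(p, cfg, ids)
  last_rows <- (seq_len(B) - 1) * T + lens
  xl <- fwd$xf[last_rows, , drop = FALSE]
  z <- as.vector(xl %*% p$head_w) + p$head_b
  list(fwd = fwd, last_rows = last_rows, xl = xl, z = z,
       prob = 1 / (1 + exp(-z)))
}

#' Fine-tune the table LM into a row-merge classifier
#'
#' The generative head is replaced by a single sigmoid neuron reading
#' the representation at the final input position; all remaining weights
#' are initialized from the pre-trained language model and the whole
#' network is trained with binary cross-entropy (Adam, two epochs,
#' learning rate 2e-4 by default).
#'
#' @param lm a pre-trained `table_lm`.
#' @param instances tibble with columns `upper`, `lower`, `label` (0/1).
#' @param epochs training epochs (0 returns the untrained head).
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param batch_size instances per step.
#' @return a `merge_classifier`: `params`, `config`, `vocab`,
#'   `loss_trace`.
#' @export
finetune_merger <- function(lm, instances, epochs = 2L, lr = 2e-4,
                            seed = 1L, batch_size = 16L) {
  if (length(unique(instances$label)) < 2 && epochs > 0) {
    abort("finetune_merger: need both classes in `instances`")
  }
  cfg <- lm$config
  vocab <- lm$vocab
  p <- lm$params
  p$head_w <- rep(0, cfg$d_model)
  p$head_b <- 0
  seqs <- lapply(seq_len(nrow(instances)), function(i) {
    encode_pair(instances$upper[i], instances$lower[i], vocab, cfg$context_len)
  })
  y <- as.numeric(instances$label)
  trace <- numeric(0)
  withr::with_seed(seed, {
    st <- adam_state(p)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(seqs))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (bi in batches) {
        out <- cls_batch_fwd(p, cfg, seqs[bi])
        eps <- 1e-12
        trace <- c(trace, -mean(y[bi] * log(out$prob + eps) +
                                  (1 - y[bi]) * log(1 - out$prob + eps)))
        dz <- (out$prob - y[bi]) / length(bi)
        g_head_w <- as.vector(crossprod(out$xl, dz))
        g_head_b <- sum(dz)
        dxf <- matrix(0, nrow(out$fwd$xf), cfg$d_model)
        dxf[out$last_rows, ] <- outer(dz, p$head_w)
        g <- trunk_bwd(p, cfg, out$fwd, dxf)
        g$head_w <- g_head_w
        g$head_b <- g_head_b
        upd <- adam_step(p, g, st, lr)
        p <- upd$p; st <- upd$st
      }
    }
  })
  structure(list(params = p, config = cfg, vocab = vocab, loss_trace = trace),
            class = "merge_classifier")
}

#' @export
print.merge_classifier <- function(x, ...) {
  cat(sprintf("<merge_classifier: %d layers, d=%d, context=%d, vocab=%d>\n",
              x$config$n_layers, x$config$d_model, x$config$context_len,
              x$vocab$size))
  invisible(x)
}

#' Merge probability for a vertical cell pair
#'
#' @param clf a `merge_classifier`.
#' @param upper,lower cell strings.
#' @return probability in (0, 1) that the cells should be merged.
#' @export
score_pair <- function(clf, upper, lower) {
  score_pairs(clf, upper, lower)[1]
}

#' @rdname score_pair
#' @export
score_pairs <- function(clf, upper, lower) {
  seqs <- mapply(function(u, l) encode_pair(u, l, clf$vocab, clf$config$context_len),
                 upper, lower, SIMPLIFY = FALSE)
  cls_batch_fwd(clf$params, clf$config, seqs)$prob
}

#' Predicted labels and accuracy of a merge classifier
#'
#' @param clf a `merge_classifier` (or scorer function).
#' @param instances tibble `upper`, `lower`, `label`.
#' @param threshold decision threshold.
#' @return list with `accuracy` and `pred` (0/1 vector).
#' @export
merge_accuracy <- function(clf, instances, threshold = 0.5) {
  pr <- pair_scorer(clf)(instances$upper, instances$lower)
  pred <- as.integer(pr > threshold)
  list(accuracy = mean(pred == instances$label), pred = pred)
}

# Accept either a merge_classifier or a plain function(upper, lower) -> prob
# (e.g. an oracle), and return a vectorized scorer.
pair_scorer <- function(clf) {
  if (inherits(clf, "merge_classifier")) {
    function(upper, lower) score_pairs(clf, upper, lower)
  } else if (is.function(clf)) {
    function(upper, lower) mapply(clf, upper, lower)
  } else {
    abort("expected a merge_classifier or a scorer function")
  }
}

#' Max-voting row merge (language-model canonicalization)
#'
#' Scans the grid top-down, maintaining the current merged row group.
#' For the group vs. the next physical row, every column pair in which
#' both cells are non-empty is scored by the classifier; the row score
#' is the mean of the scored pairs, and the rows merge only when the
#' score strictly exceeds `threshold` (a score of exactly 0.5 does not
#' merge). Column pairs with an empty cell are excluded from the vote;
#' if every pair is excluded the rows do not merge. Merged cells are
#' joined with a single space; empty cells absorb content unchanged.
#'
#' @param table a (possibly over-segmented) [logical_table()] or
#'   character matrix.
#' @param clf a `merge_classifier`, or a `function(upper, lower)`
#'   returning a merge probability (an oracle).
#' @param threshold vote threshold (strict).
#' @return a [logical_table()] with attribute `row_groups` (the physical
#'   rows merged into each output row).
#' @export
merge_rows <- function(table, clf, threshold = 0.5) {
  cells <- if (is_logical_table(table)) table$cells else table
  scorer <- pair_scorer(clf)
  R <- nrow(cells)
  if (R == 0) return(logical_table(cells))
  out <- list()
  groups <- list()
  cur <- cells[1, ]
  cur_rows <- 1L
  join_cols <- function(a, b) {
    ifelse(!nzchar(a), b, ifelse(!nzchar(b), a, paste(a, b)))
  }
  for (r in seq_len(R)[-1]) {
    low <- cells[r, ]
    valid <- nzchar(cur) & nzchar(low)
    sc <- if (any(valid)) mean(scorer(cur[valid], low[valid])) else NA_real_
    if (!is.na(sc) && sc > threshold) {
      cur <- join_cols(cur, low)
      cur_rows <- c(cur_rows, r)
    } else {
      out[[length(out) + 1]] <- cur
      groups[[length(groups) + 1]] <- cur_rows
      cur <- low
      cur_rows <- r
    }
  }
  out[[length(out) + 1]] <- cur
  groups[[length(groups) + 1]] <- cur_rows
  res <- logical_table(do.call(rbind, out))
  attr(res, "row_groups") <- groups
  res
}

#' An oracle pair scorer from gold row groups
#'
#' Returns 1 for consecutive fragment pairs of a split cell recorded in
#' the simulated-overflow output and 0 otherwise; used to isolate the
#' voting mechanics from classifier quality.
#'
#' @param sim result of [simulate_overflow()].
#' @return `function(upper, lower)` returning 0 or 1.
#' @export
oracle_scorer <- function(sim) {
  pos <- sim$instances[sim$instances$label == 1L, ]
  function(upper, lower) {
    vapply(seq_along(upper), function(i) {
      # the upper side may already be a merged group; the true fragment
      # is then a suffix of it (preceded by the joining space)
      hit <- pos$lower == lower[i] &
        (pos$upper == upper[i] |
           endsWith(upper[i], paste0(" ", pos$upper)))
      as.numeric(any(hit))
    }, numeric(1))
  }
}
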