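#' Model configuration for the convolutional coder
#'
#' The coder realizes the conditional model `P(UCD | CCD, A, Y, G)`: one
#' linear projection (embedding table) shared by every ICD-10 code cell of
#' the `L x W` grid, demographic projections added to every non-pad cell, a
#' convolutional trunk, global pooling, and a softmax regression over the
#' `V` vocabulary codes.
#'
#' Numerical conventions that make width-padding exactly neutral: the pad
#' embedding is frozen at the zero vector, demographic projections are added
#' to non-pad cells only, convolutions carry no bias terms, and activations
#' are ReLU, so an all-padding region of the grid stays exactly zero through
#' the whole trunk and cannot influence global max pooling. Appending
#' padding columns (a wider `W`) therefore leaves the output unchanged.
#'
#' @param vocab `ucd_vocabulary` the model will be built for (fixes `V`).
#' @param embed_dim Shared projection width (default 32).
#' @param conv_channels Integer vector, output channels of the successive
#'   3x3 convolution blocks (default `c(48, 64, 96)`).
#' @param conv_kernel Kernel heights/widths (odd, default `c(3, 3)`).
#' @param pooling `"global_max"` (default) or `"global_mean"`.
#' @param use_gender Include the gender projection (ablation switch).
#' @param use_row_embedding Add a trainable per-row (certificate line)
#'   embedding to non-pad cells; the fixed 6-line layout makes rows
#'   semantically distinct (Part I vs Part II), which the promotion rules
#'   depend on, while translation invariance along the rank-in-line axis is
#'   preserved.
#' @param L,W Grid dimensions (default 6 x 20).
#' @param Y Number of year states (default 16).
#' @param n_age Number of age bins (25).
#' @param base_year First modelled calendar year.
#' @param seed Seed for parameter initialization.
#' @return Object of class `ucd_model_config`.
#' @export
model_config <- function(vocab = NULL, embed_dim = 32L,
                         conv_channels = c(48L, 64L, 96L),
                         conv_kernel = c(3L, 3L),
                         pooling = c("global_max", "global_mean"),
                         use_gender = TRUE, use_row_embedding = TRUE,
                         L = 6L, W = 20L, Y = 16L, n_age = 25L,
                         base_year = 2000L, seed = 42L) {
  pooling <- match.arg(pooling)
  stopifnot(embed_dim >= 1, length(conv_channels) >= 1, all(conv_channels >= 1),
            length(conv_kernel) == 2, all(conv_kernel %% 2 == 1),
            conv_kernel[1] <= L, conv_kernel[2] <= W, L >= 6, W >= 1)
  structure(
    list(
      V = if (is.null(vocab)) NA_integer_ else vocab$V,
      embed_dim = as.integer(embed_dim),
      conv_channels = as.integer(conv_channels),
      conv_kernel = as.integer(conv_kernel),
      pooling = pooling,
      use_gender = isTRUE(use_gender),
      use_row_embedding = isTRUE(use_row_embedding),
      L = as.integer(L), W = as.integer(W), Y = as.integer(Y),
      n_age = as.integer(n_age), base_year = as.integer(base_year),
      seed = as.integer(seed)
    ),
    class = "ucd_model_config"
  )
}

#' Build an (untrained) coder
#'
#' Initializes all parameters from `config$seed` (two builds with the same
#' seed are identical). The code embedding table has `V + 2` rows: row 1 is
#' the pad entry, frozen at zero; the last row is the trainable
#' unknown-code entry.
#'
#' @param config A `ucd_model_config`.
#' @param vocab The `ucd_vocabulary` (its fingerprint is stored and checked
#'   at every prediction).
#' @return Object of class `ucd_coder`.
#' @export
build_model <- function(config, vocab) {
  stopifnot(inherits(config, "ucd_model_config"),
            inherits(vocab, "ucd_vocabulary"))
  if (is.na(config$V)) config$V <- vocab$V
  if (config$V != vocab$V) {
    stop(sprintf("config built for V=%d but vocabulary has V=%d",
                 config$V, vocab$V))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- config$embed_dim
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  params <- list(
    E = rmat(vocab$V + 2L, d, 0.08),
    A = rmat(config$n_age, d, 0.08),
    Yr = rmat(config$Y, d, 0.08),
    G = if (config$use_gender) rmat(2L, d, 0.08) else NULL,
    R = if (config$use_row_embedding) rmat(config$L, d, 0.08) else NULL
  )
  params$E[1, ] <- 0  # pad embedding frozen at the zero vector
  c_in <- d
  for (l in seq_along(config$conv_channels)) {
    c_out <- config$conv_channels[l]
    params[[paste0("conv", l)]] <-
      rmat(c_out, kh * kw * c_in, sqrt(2 / (kh * kw * c_in)))
    c_in <- c_out
  }
  params$W_out <- rmat(vocab$V, c_in, sqrt(2 / c_in))
  params$b_out <- numeric(vocab$V)
  structure(
    list(config = config, params = params,
         vocab_fingerprint = vocab_fingerprint(vocab), history = NULL),
    class = "ucd_coder"
  )
}

#' @export
print.ucd_coder <- function(x, ...) {
  np <- sum(vapply(x$params[!vapply(x$params, is.null, TRUE)], length, 0))
  cat(sprintf(
    "<ucd_coder> V=%d, embed_dim=%d, conv=[%s], %s, %s parameters%s\n",
    x$config$V, x$config$embed_dim,
    paste(x$config$conv_channels, collapse = ","), x$config$pooling,
    format(np, big.mark = ","),
    if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# ---- internal batched forward / backward ----------------------------------
# The grid batch is a (L*W) x n index matrix; inside the trunk activations
# live in C x (L*W_eff*n) matrices with the position index running
# row-fastest within each sample. The im2col / col2im / pooling inner loops
# are compiled (src/kernels.cpp); the matrix products go through BLAS.

# batch: list(grid = (L*W) x n integer matrix, age, year, gender 0-based ints)
coder_forward <- function(params, config, batch, crop = TRUE, keep = FALSE) {
  L <- config$L; W <- config$W; d <- config$embed_dim
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
  n <- ncol(batch$grid)
  n_layers <- length(config$conv_channels)

  if (crop) {
    # columns beyond the last occupied one (plus the trunk's receptive
    # margin) are exactly zero through every layer and cannot win the max
    # pool, so they can be skipped without changing the output
    nz <- which(rowSums(batch$grid != 0L) > 0)
    cmax <- if (length(nz)) ceiling(max(nz) / L) else 1L
    W_eff <- min(W, as.integer(cmax + n_layers * (kw - 1L) %/% 2L))
  } else {
    W_eff <- W
  }
  P <- L * W_eff
  total <- P * n
  r_vec <- rep(rep.int(seq_len(L), W_eff), times = n)
  s_vec <- rep(seq_len(n), each = P)

  idxvec <- as.vector(batch$grid[seq_len(P), , drop = FALSE])
  Et <- t(params$E)
  X <- Et[, idxvec + 1L, drop = FALSE]
  nonpad <- idxvec != 0L

  demo <- t(params$A)[, batch$age + 1L, drop = FALSE] +
    t(params$Yr)[, batch$year + 1L, drop = FALSE]
  if (config$use_gender) {
    demo <- demo + t(params$G)[, batch$gender + 1L, drop = FALSE]
  }
  D <- demo[, s_vec, drop = FALSE]
  if (config$use_row_embedding) {
    D <- D + t(params$R)[, r_vec, drop = FALSE]
  }
  X[, nonpad] <- X[, nonpad, drop = FALSE] + D[, nonpad, drop = FALSE]

  acts <- vector("list", n_layers)
  xcols <- if (keep) vector("list", n_layers) else NULL
  A_cur <- X
  for (l in seq_len(n_layers)) {
    Xcol <- cpp_im2col(A_cur, L, W_eff, n, kh, kw)
    Z <- params[[paste0("conv", l)]] %*% Xcol
    Z[Z < 0] <- 0
    if (keep) {
      xcols[[l]] <- Xcol
      acts[[l]] <- Z
    }
    A_cur <- Z
  }

  C <- config$conv_channels[n_layers]
  if (config$pooling == "global_max") {
    mp <- cpp_maxpool(A_cur, P, n)
    pooled <- mp$pooled
    argp <- mp$arg
  } else {
    pooled <- t(rowsum(t(A_cur), group = s_vec)) / (L * W)
    argp <- NULL
  }

  logits <- params$W_out %*% pooled + params$b_out
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  probs <- sweep(ex, 2, colSums(ex), "/")

  list(probs = probs, pooled = pooled, argp = argp, acts = acts,
       xcols = xcols, X = X, idxvec = idxvec, nonpad = nonpad,
       r_vec = r_vec, s_vec = s_vec, P = P, total = total,
       W_eff = W_eff, n = n)
}

coder_backward <- function(params, config, batch, fw, gold_idx) {
  n <- fw$n
  V <- config$V
  d <- config$embed_dim
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]
  n_layers <- length(config$conv_channels)
  total <- fw$total; P <- fw$P
  W_eff <- fw$W_eff; L <- config$L

  dlogits <- fw$probs
  dlogits[(seq_len(n) - 1L) * V + gold_idx] <-
    dlogits[(seq_len(n) - 1L) * V + gold_idx] - 1
  dlogits <- dlogits / n

  grads <- list(
    W_out = tcrossprod(dlogits, fw$pooled),
    b_out = rowSums(dlogits)
  )
  dpooled <- crossprod(params$W_out, dlogits)

  if (config$pooling == "global_max") {
    dA <- cpp_maxpool_grad(dpooled, fw$argp, P)
  } else {
    dA <- (dpooled / (config$L * config$W))[, fw$s_vec, drop = FALSE]
  }

  for (l in rev(seq_len(n_layers))) {
    c_in <- if (l == 1) d else config$conv_channels[l - 1]
    dZ <- dA
    dZ[fw$acts[[l]] <= 0] <- 0
    grads[[paste0("conv", l)]] <- tcrossprod(dZ, fw$xcols[[l]])
    dXcol <- crossprod(params[[paste0("conv", l)]], dZ)
    dA <- cpp_col2im(dXcol, c_in, L, W_eff, n, kh, kw)
  }

  dX <- dA
  dX[, !fw$nonpad] <- 0
  tdX <- t(dX)

  g <- rowsum(tdX, group = fw$idxvec)
  rn <- as.integer(rownames(g))
  dE <- matrix(0, V + 2L, d)
  keep <- rn > 0L
  dE[rn[keep] + 1L, ] <- g[keep, , drop = FALSE]
  grads$E <- dE

  ds <- rowsum(tdX, group = fw$s_vec)  # n x d per-sample sums
  agg <- function(groups, nlev) {
    gg <- rowsum(ds, group = groups)
    out <- matrix(0, nlev, d)
    out[as.integer(rownames(gg)) + 1L, ] <- gg
    out
  }
  grads$A <- agg(batch$age, config$n_age)
  grads$Yr <- agg(batch$year, config$Y)
  if (config$use_gender) grads$G <- agg(batch$gender, 2L)
  if (config$use_row_embedding) {
    gr <- rowsum(tdX, group = fw$r_vec)
    out <- matrix(0, config$L, d)
    out[as.integer(rownames(gr)), ] <- gr
    grads$R <- out
  }
  grads
}

prep_batch <- function(certs, vocab, config) {
  L <- config$L; W <- config$W
  grid <- vapply(certs, function(ct) as.vector(encode_grid(ct, vocab, L, W)),
                 integer(L * W))
  dem <- lapply(certs, demographics, base_year = config$base_year,
                n_years = config$Y)
  list(
    grid = grid,
    age = vapply(dem, `[[`, 0L, "age_bin"),
    year = vapply(dem, `[[`, 0L, "year_index"),
    gender = vapply(dem, `[[`, 0L, "gender")
  )
}

check_fingerprint <- function(coder, vocab) {
  if (!identical(coder$vocab_fingerprint, vocab_fingerprint(vocab))) {
    stop("vocabulary fingerprint mismatch: this coder was trained on a different vocabulary")
  }
}

# ---- prediction ------------------------------------------------------------

#' Predicted probability distribution over the vocabulary
#'
#' @param coder A `ucd_coder`.
#' @param cert A single `ucd_certificate`.
#' @param vocab The vocabulary the coder was built on (fingerprint-checked).
#' @param crop Internal exactness-preserving optimization: skip convolution
#'   over grid columns that are provably all-zero. Results are identical
#'   either way; `FALSE` forces the full-width computation.
#' @return Named numeric vector of length `V`, summing to 1.
#' @export
predict_proba <- function(coder, cert, vocab, crop = TRUE) {
  p <- predict_proba_batch(coder, list(cert), vocab, crop = crop)
  stats::setNames(p[1, ], colnames(p))
}

#' @rdname predict_proba
#' @param certs List of certificates.
#' @return `predict_proba_batch()`: `n x V` matrix of probabilities, columns
#'   named by vocabulary code.
#' @export
predict_proba_batch <- function(coder, certs, vocab, crop = TRUE) {
  stopifnot(inherits(coder, "ucd_coder"))
  check_fingerprint(coder, vocab)
  out <- matrix(NA_real_, length(certs), coder$config$V,
                dimnames = list(NULL, vocab$codes))
  bs <- 512L
  i <- 1L
  while (i <= length(certs)) {
    j <- min(i + bs - 1L, length(certs))
    batch <- prep_batch(certs[i:j], vocab, coder$config)
    fw <- coder_forward(coder$params, coder$config, batch, crop = crop)
    out[i:j, ] <- t(fw$probs)
    i <- j + 1L
  }
  out
}

#' Top-k most probable codes
#'
#' Codes in non-increasing probability; ties broken deterministically by
#' vocabulary index.
#'
#' @inheritParams predict_proba
#' @param k Number of codes, `1 <= k <= V`.
#' @return data.frame with columns `code`, `prob` (k rows).
#' @export
predict_topk <- function(coder, cert, vocab, k) {
  if (k < 1 || k > coder$config$V) stop("k must be in 1..V")
  p <- predict_proba(coder, cert, vocab)
  ord <- order(-p, seq_along(p))[seq_len(k)]
  data.frame(code = names(p)[ord], prob = unname(p[ord]),
             stringsAsFactors = FALSE)
}

#' Predicted underlying cause (argmax) for a set of certificates
#'
#' @inheritParams predict_proba_batch
#' @return Character vector of predicted codes, aligned with `certs`.
#' @export
predict_ucd <- function(coder, certs, vocab) {
  p <- predict_proba_batch(coder, certs, vocab)
  vocab$codes[max.col(p, ties.method = "first")]
}

# ---- training --------------------------------------------------------------

adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (nm == "E") g[1, ] <- 0  # pad embedding stays frozen
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(state = state, params = params)
}

#' Train the coder by Adam on mini-batch cross-entropy
#'
#' Parameters are updated with the Adam optimizer on the mini-batch
#' cross-entropy of the softmax output against the gold UCD labels. After
#' each epoch the validation accuracy is measured; the parameters of the
#' best validation epoch are retained. Fully deterministic for a fixed
#' `seed` (single-threaded BLAS).
#'
#' @param coder An (untrained or trained) `ucd_coder`.
#' @param train_certs,val_certs Labeled certificate lists (disjoint).
#' @param vocab The vocabulary.
#' @param opt_params List of optimizer settings: `lr` (1e-3),
#'   `batch_size` (256), `epochs` (15), `seed` (1).
#' @param quiet Suppress per-epoch messages.
#' @return The trained `ucd_coder`, with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_accuracy`) attached.
#' @export
train_coder <- function(coder, train_certs, val_certs, vocab,
                        opt_params = list(), quiet = FALSE) {
  stopifnot(inherits(coder, "ucd_coder"))
  check_fingerprint(coder, vocab)
  if (length(train_certs) == 0) stop("empty training set")
  opt <- utils::modifyList(
    list(lr = 1e-3, batch_size = 256L, epochs = 15L, seed = 1L), opt_params)

  golds <- vapply(train_certs, `[[`, "", "gold_ucd")
  if (anyNA(golds)) stop("all training certificates must carry a gold UCD")
  gi <- unname(vocab$index[golds])
  if (anyNA(gi)) {
    stop(sprintf("training label(s) outside the vocabulary: %s",
                 paste(unique(golds[is.na(gi)]), collapse = ", ")))
  }
  batch_all <- prep_batch(train_certs, vocab, coder$config)
  val_gold <- vapply(val_certs, `[[`, "", "gold_ucd")

  params <- coder$params
  config <- coder$config
  state <- list(t = 0L, m = list(), v = list())
  N <- length(train_certs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = params)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(opt$seed))
  for (epoch in seq_len(opt$epochs)) {
    ord <- sample.int(N)
    total_loss <- 0
    i <- 1L
    while (i <= N) {
      j <- min(i + opt$batch_size - 1L, N)
      sel <- ord[i:j]
      batch <- list(grid = batch_all$grid[, sel, drop = FALSE],
                    age = batch_all$age[sel], year = batch_all$year[sel],
                    gender = batch_all$gender[sel])
      fw <- coder_forward(params, config, batch, crop = TRUE, keep = TRUE)
      nb <- length(sel)
      pg <- fw$probs[(seq_len(nb) - 1L) * config$V + gi[sel]]
      total_loss <- total_loss - sum(log(pmax(pg, 1e-12)))
      grads <- coder_backward(params, config, batch, fw, gi[sel])
      upd <- adam_step(state, params, grads, lr = opt$lr)
      state <- upd$state
      params <- upd$params
      i <- j + 1L
    }
    train_loss <- total_loss / N

    val_acc <- NA_real_
    if (length(val_certs)) {
      tmp_coder <- coder; tmp_coder$params <- params
      vp <- predict_proba_batch(tmp_coder, val_certs, vocab)
      val_pred <- vocab$codes[max.col(vp, ties.method = "first")]
      val_acc <- mean(val_pred == val_gold)
      if (val_acc >= best$acc) best <- list(acc = val_acc, params = params)
    } else {
      best <- list(acc = NA_real_, params = params)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_accuracy = val_acc))
    ucd_log("epoch %d/%d: train_loss=%.4f val_accuracy=%s", epoch, opt$epochs,
            train_loss, ifelse(is.na(val_acc), "NA", sprintf("%.4f", val_acc)),
            quiet = quiet)
  }

  coder$params <- best$params
  coder$history <- history
  coder
}

# ---- persistence -----------------------------------------------------------

#' Save / load a coder checkpoint
#'
#' The checkpoint is a single self-describing archive holding the
#' configuration, all parameter arrays, the vocabulary fingerprint and the
#' training history; `load_coder(save_coder(x))` reproduces bit-identical
#' predictions.
#'
#' @param coder A `ucd_coder`.
#' @param path Checkpoint file path.
#' @export
save_coder <- function(coder, path) {
  stopifnot(inherits(coder, "ucd_coder"))
  saveRDS(list(format = "ucdcoder-checkpoint-1",
               config = unclass(coder$config), params = coder$params,
               vocab_fingerprint = coder$vocab_fingerprint,
               history = coder$history),
          path)
  invisible(path)
}

#' @rdname save_coder
#' @return `load_coder()` returns the restored `ucd_coder`.
#' @export
load_coder <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ucdcoder-checkpoint-1")) {
    stop("not a ucdcoder checkpoint")
  }
  structure(
    list(config = structure(x$config, class = "ucd_model_config"),
         params = x$params, vocab_fingerprint = x$vocab_fingerprint,
         history = x$history),
    class = "ucd_coder"
  )
}
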