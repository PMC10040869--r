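# Exact t-SNE (van der Maaten & Hinton 2008), implemented here because no
# t-SNE package ships with the environment. Sized for visualization of
# desk-scale libraries (O(n^2) memory/time). Deterministic: PCA
# initialization, no random jitter, so identical input rows remain coincident
# throughout the symmetric gradient dynamics.

tsne_embed <- function(x, perplexity = 30, max_iter = 300, seed = 1,
                       learning_rate = 100, exaggeration = 4,
                       exaggeration_iter = 100) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 rows to embed", call. = FALSE)
  # identical rows are embedded once and share a coordinate: zero input
  # distance otherwise destabilizes the repulsive dynamics (duplicates would
  # drift apart from rounding-level asymmetries)
  key <- apply(x, 1, paste, collapse = ",")
  first <- !duplicated(key)
  if (any(!first)) {
    yu <- tsne_embed(x[first, , drop = FALSE], perplexity, max_iter, seed,
                     learning_rate, exaggeration, exaggeration_iter)
    return(yu[match(key, key[first]), , drop = FALSE])
  }
  n <- nrow(x)
  if (n < 2) stop("need at least 2 distinct rows to embed", call. = FALSE)
  perplexity <- min(perplexity, max(1, floor((n - 1) / 3)))

  d2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  # deterministic init: first two principal coordinates, scaled small
  pc <- tryCatch(stats::prcomp(x, rank. = 2, center = TRUE, scale. = FALSE)$x,
                 error = function(e) NULL)
  if (is.null(pc) || ncol(pc) < 2) {
    pc <- cbind(seq_len(n), rep(0, n))
  }
  Y <- pc[, 1:2, drop = FALSE]
  sds <- apply(Y, 2, stats::sd)
  sds[sds == 0] <- 1
  Y <- sweep(Y, 2, sds, "/") * 1e-4

  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  for (it in seq_len(max_iter)) {
    mom <- if (it < 250) 0.5 else 0.8
    Pe <- if (it <= exaggeration_iter) P * exaggeration else P
    yd2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - learning_rate * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}
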