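# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the GLM oracle builds design matrices and residual sums
# of squares from first principles (QR projections, extra-sum-of-squares F),
# and the BH oracle is a direct sort-and-step-up transcription.

# Type II extra-sum-of-squares ANCOVA for an additive model: for each term,
# SS = RSS(model without the term) - RSS(full model).
oracle_ancova <- function(df, response, terms) {
  y <- df[[response]]
  rss <- function(fml) {
    X <- stats::model.matrix(fml, df)
    qr_ <- qr(X)
    r <- y - X %*% qr.coef(qr_, y)
    list(rss = sum(r^2), p = qr_$rank)
  }
  full <- rss(stats::reformulate(terms))
  df_res <- nrow(df) - full$p
  out <- lapply(terms, function(tm) {
    red_terms <- setdiff(terms, tm)
    red <- rss(if (length(red_terms)) stats::reformulate(red_terms) else ~1)
    ss <- red$rss - full$rss
    df_t <- full$p - red$p
    Fv <- (ss / df_t) / (full$rss / df_res)
    data.frame(term = tm, SS = ss, F = Fv,
               p = stats::pf(Fv, df_t, df_res, lower.tail = FALSE),
               np2 = ss / (ss + full$rss))
  })
  do.call(rbind, out)
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Brute-force per-voxel accumulation for parcellation.
oracle_parcellate <- function(volume, labels, K) {
  sums <- numeric(K)
  counts <- numeric(K)
  v <- as.vector(volume)
  l <- as.vector(labels)
  for (i in seq_along(v)) {
    if (l[i] > 0) {
      sums[l[i]] <- sums[l[i]] + v[i]
      counts[l[i]] <- counts[l[i]] + 1
    }
  }
  sums / counts
}
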