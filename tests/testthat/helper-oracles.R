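# Independent reference routes used to cross-check the package's metric and
# probability code. These are deliberately naive (explicit loops, exhaustive
# pair enumeration) so they share no code path with the implementation.

random_aa_seq <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

oracle_weighted_precision <- function(y_true, y_pred) {
  out <- 0
  for (k in sort(unique(y_true))) {
    tp <- 0; fp <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == k) {
        if (y_true[i] == k) tp <- tp + 1 else fp <- fp + 1
      }
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    out <- out + (sum(y_true == k) / length(y_true)) * prec
  }
  out
}

oracle_weighted_f1 <- function(y_true, y_pred) {
  out <- 0
  for (k in sort(unique(y_true))) {
    tp <- sum(y_true == k & y_pred == k)
    prec <- if (sum(y_pred == k) == 0) 0 else tp / sum(y_pred == k)
    rec <- tp / sum(y_true == k)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    out <- out + (sum(y_true == k) / length(y_true)) * f1
  }
  out
}

# Exhaustive concordant/discordant pair count; ties worth 0.5.
oracle_binary_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_pairwise_auc <- function(y_true, scores) {
  classes <- sort(unique(y_true))
  vals <- c()
  for (j in classes) for (k in classes) {
    if (j >= k) next
    idx <- y_true %in% c(j, k)
    a1 <- oracle_binary_auc(scores[idx, as.character(k)], y_true[idx] == k)
    a2 <- oracle_binary_auc(scores[idx, as.character(j)], y_true[idx] == j)
    vals <- c(vals, (a1 + a2) / 2)
  }
  mean(vals)
}

# Build an aacap_model by hand (identity standardisation) so probability and
# prediction code can be exercised against chosen parameters.
manual_model <- function(intercepts, coef_matrix) {
  structure(
    list(classes = 0:2, intercepts = intercepts, coef = coef_matrix,
         lambda = 0, center = rep(0, ncol(coef_matrix)),
         scale = rep(1, ncol(coef_matrix))),
    class = "aacap_model"
  )
}
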