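# Independent brute-force oracles the implementations are checked against.

# truncated centered moving average by direct windowed mean
oracle_running_mean <- function(x, w) {
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - hl):min(n, i + hr)
    mean(x[idx])
  }, numeric(1))
}

# exhaustive scan over all epoch starts; earliest maximizer
oracle_epoch_start <- function(x, w) {
  means <- vapply(seq_len(length(x) - w + 1L),
                  function(s) mean(x[s:(s + w - 1L)]), numeric(1))
  which.max(means) - 1L
}

# pairwise Mann-Whitney AUC, ties count one half
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# one-vs-one AUC by direct enumeration of class pairs
oracle_ovo_auc <- function(true, prob) {
  lev <- levels(true)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    sel <- true %in% pr
    a1 <- oracle_auc(prob[sel, pr[1]], true[sel] == pr[1])
    a2 <- oracle_auc(prob[sel, pr[2]], true[sel] == pr[2])
    (a1 + a2) / 2
  }, numeric(1))
  mean(vals)
}
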