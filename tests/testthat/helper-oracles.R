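# Independent reference implementations used as test oracles.
# Deliberately naive (explicit loops, no shared code with the package).

# Mann-Whitney pair-counting AUC: fraction of (positive, negative) pairs
# ordered correctly, ties counted one half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive confusion counts under score >= cutoff => positive.
count_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= cutoff
    if (pred && labels[i]) tp <- tp + 1
    if (pred && !labels[i]) fp <- fp + 1
    if (!pred && !labels[i]) tn <- tn + 1
    if (!pred && labels[i]) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Exhaustive Youden search over candidate thresholds (every score and Inf).
exhaustive_youden <- function(scores, labels) {
  best_j <- -Inf
  for (th in c(Inf, sort(unique(scores)))) {
    cc <- count_confusion(scores, labels, th)
    sens <- cc$tp / (cc$tp + cc$fn)
    spec <- cc$tn / (cc$tn + cc$fp)
    if (sens + spec - 1 > best_j + 1e-12) best_j <- sens + spec - 1
  }
  best_j
}

# Direct loop-based windowed features: per-second max-min, then RMS of
# complete groups of three.
naive_axis_score <- function(x, rate) {
  n_sec <- floor(length(x) / rate)
  amp <- numeric(n_sec)
  for (w in seq_len(n_sec)) {
    win <- x[((w - 1) * rate + 1):(w * rate)]
    amp[w] <- max(win) - min(win)
  }
  n_grp <- floor(n_sec / 3)
  rms <- numeric(n_grp)
  for (g in seq_len(n_grp)) {
    grp <- amp[((g - 1) * 3 + 1):(g * 3)]
    rms[g] <- sqrt(mean(grp^2))
  }
  list(amp = amp, rms = rms, score = mean(rms))
}

random_cohort <- function(n, allow_ties = TRUE) {
  repeat {
    scores <- if (allow_ties) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    } else {
      stats::runif(n)
    }
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(labels) && !all(labels)) {
      return(list(scores = scores, labels = labels))
    }
  }
}

static_series <- function(duration = 5, rate = 50, g = c(0, 0, 1)) {
  n <- duration * rate
  data.frame(t = (seq_len(n) - 1) / rate,
             ax = rep(g[1], n), ay = rep(g[2], n), az = rep(g[3], n))
}
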