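# Independent oracles, deliberately not sharing code with R/.

# 2x2 dioptric power matrix of sphere S with plus-cylinder C at axis a (deg).
# The meridian at the cylinder axis carries power S; the perpendicular S + C.
power_matrix <- function(S, C, axis) {
  a <- axis * pi / 180
  matrix(c(S + C * sin(a)^2, -C * sin(a) * cos(a),
           -C * sin(a) * cos(a), S + C * cos(a)^2), 2, 2)
}

# sphero-cylinder (plus form) from a symmetric 2x2 power matrix
sphcyl_from_matrix <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  i <- which.min(e$values)
  S <- e$values[i]
  C <- max(e$values) - S
  v <- e$vectors[, i]
  axis <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(S = S, C = C, axis = axis)
}

# angular separation between two cylinder axes, accounting for 180-wrap
axis_gap <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# brute-force Mann-Whitney AUC over all positive-negative pairs
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# trapezoidal AUC from an ROC coordinate set
auc_trapezoid <- function(sens, spec) {
  fpr <- 1 - spec
  o <- order(fpr, sens)
  fpr <- c(0, fpr[o], 1)
  tpr <- c(0, sens[o], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# O(n^2) Kendall tau-b with tie correction
taub_pairs <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# least-squares coefficients via SVD pseudoinverse (intercept first)
ols_pinv <- function(X, y) {
  X1 <- cbind(1, X)
  s <- svd(X1)
  c(s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u) %*% y)
}

random_astig <- function(n, max_cyl = 4) {
  astig(runif(n, 0.05, max_cyl), runif(n, 0, 180))
}
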