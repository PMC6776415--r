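# Brute-force oracles, written independently of the package internals:
# plain triple loops and Floyd-Warshall only. Used to freeze expected values
# for the graph metrics on small random graphs.

oracle_fw <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && len[i, j] > 0) d[i, j] <- len[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_normalise <- function(w) {
  mx <- max(w)
  if (mx > 0) w / mx else w
}

oracle_degree_strength <- function(w) {
  wn <- oracle_normalise(w)
  a <- (w > 0) * 1
  n <- nrow(w)
  deg <- numeric(n)
  str <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    deg[i] <- deg[i] + a[i, j]
    str[i] <- str[i] + wn[i, j]
  }
  list(degree = deg, strength = str)
}

oracle_clustering <- function(w) {
  wn <- oracle_normalise(w)
  a <- (w > 0) * 1
  n <- nrow(w)
  cu <- numeric(n)
  cw <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k < 2) next
    tu <- 0
    tw <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tu <- tu + a[i, j] * a[i, h] * a[j, h]
      tw <- tw + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    cu[i] <- (tu / 2) * 2 / (k * (k - 1))
    cw[i] <- (tw / 2) * 2 / (k * (k - 1))
  }
  list(unweighted = cu, weighted = cw)
}

oracle_efficiency_pathlength <- function(w) {
  wn <- oracle_normalise(w)
  a <- (w > 0) * 1
  n <- nrow(w)
  lenw <- ifelse(wn > 0, 1 / wn, 0)
  du <- oracle_fw(a)
  dw <- oracle_fw(lenw)
  summar <- function(d) {
    eff <- numeric(n)
    pl <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      invs <- c()
      fins <- c()
      for (j in seq_len(n)) {
        if (j == i) next
        invs <- c(invs, if (is.finite(d[i, j])) 1 / d[i, j] else 0)
        if (is.finite(d[i, j])) fins <- c(fins, d[i, j])
      }
      eff[i] <- mean(invs)
      if (length(fins)) pl[i] <- mean(fins)
    }
    list(eff = eff, pl = pl)
  }
  list(unweighted = summar(du), weighted = summar(dw))
}

oracle_local_efficiency <- function(w) {
  wn <- oracle_normalise(w)
  a <- (w > 0) * 1
  n <- nrow(w)
  eu <- numeric(n)
  ew <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub_a <- a[nb, nb, drop = FALSE]
    sub_l3 <- ifelse(wn[nb, nb] > 0, (1 / wn[nb, nb])^(1 / 3), 0)
    du <- oracle_fw(sub_a)
    d3 <- oracle_fw(sub_l3)
    su <- 0
    sw <- 0
    for (j in seq_len(k)) for (h in seq_len(k)) {
      if (j == h) next
      if (is.finite(du[j, h])) su <- su + 1 / du[j, h]
      if (is.finite(d3[j, h])) {
        sw <- sw + (wn[i, nb[j]] * wn[i, nb[h]])^(1 / 3) / d3[j, h]
      }
    }
    eu[i] <- su / (k * (k - 1))
    ew[i] <- sw / (k * (k - 1))
  }
  list(unweighted = eu, weighted = ew)
}

# shortest-path counts from the distance matrix and edge lengths
oracle_sigma <- function(len, d, tol = 1e-9) {
  n <- nrow(len)
  sigma <- matrix(0, n, n)
  for (h in seq_len(n)) {
    sigma[h, h] <- 1
    ord <- order(d[h, ])
    for (j in ord) {
      if (j == h || !is.finite(d[h, j])) next
      s <- 0
      for (k in seq_len(n)) {
        if (k != j && len[k, j] > 0 &&
            abs(d[h, k] + len[k, j] - d[h, j]) < tol) {
          s <- s + sigma[h, k]
        }
      }
      sigma[h, j] <- s
    }
  }
  sigma
}

oracle_betweenness <- function(w) {
  wn <- oracle_normalise(w)
  a <- (w > 0) * 1
  n <- nrow(w)
  one <- function(len) {
    d <- oracle_fw(len)
    sigma <- oracle_sigma(len, d)
    b <- numeric(n)
    for (i in seq_len(n)) for (h in seq_len(n)) for (j in seq_len(n)) {
      if (h == j || h == i || j == i) next
      if (!is.finite(d[h, j]) || sigma[h, j] == 0) next
      if (abs(d[h, i] + d[i, j] - d[h, j]) < 1e-9) {
        b[i] <- b[i] + sigma[h, i] * sigma[i, j] / sigma[h, j]
      }
    }
    b / ((n - 1) * (n - 2))
  }
  list(unweighted = one(a), weighted = one(ifelse(wn > 0, 1 / wn, 0)))
}

# random symmetric weighted graph for the oracle suite
random_weight_matrix <- function(n, p = 0.5, binary = FALSE) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) {
      w[i, j] <- w[j, i] <- if (binary) 1 else runif(1, 0.1, 2)
    }
  }
  w
}
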