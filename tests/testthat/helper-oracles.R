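## Independent brute-force oracles used across tests. These deliberately
## avoid the package's own code paths.

## tiny glog2-scale study built directly from a matrix
make_study <- function(values, group, id = "T", class = "LC",
                       scale = "glog2") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_study(id, class, values, group, scale = scale)
}

## classical pooled two-sample t-statistic, naive loops
oracle_t_stat <- function(x_case, x_ctrl) {
  n1 <- length(x_case); n2 <- length(x_ctrl)
  sp2 <- (sum((x_case - mean(x_case))^2) + sum((x_ctrl - mean(x_ctrl))^2)) /
    (n1 + n2 - 2)
  (mean(x_case) - mean(x_ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## mean local clustering coefficient by explicit triangle counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  locals <- c()
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      tri <- tri + adj[nb[i], nb[j]]
    locals <- c(locals, 2 * tri / (k * (k - 1)))
  }
  if (!length(locals)) 0 else mean(locals)
}

## upper-tail hypergeometric by explicit log-space enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  terms <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  sum(exp(terms))
}

## BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## winner rule by explicit counting for a single gene's direction row
oracle_winner <- function(row, is_lc, sigma, min_total = 7, min_lc = 5) {
  sum(row == sigma) >= min_total && sum(row[is_lc] == sigma) >= min_lc
}

## random GeneNetwork: G(n, p) over labelled nodes, weights in [0.5, 1]
random_network <- function(n_nodes, p) {
  labs <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(labs, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  gene_network(unique(c(edges)), edges, runif(nrow(edges), 0.5, 1))
}

## Breslow partial-likelihood Newton solver for a single binary covariate,
## written independently of the survival package
oracle_cox_beta <- function(time, event, x, tol = 1e-12, maxit = 100) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  beta <- 0
  for (it in seq_len(maxit)) {
    U <- 0; I <- 0
    for (t in unique(time[event == 1])) {
      d <- which(time == t & event == 1)
      risk <- which(time >= t)
      w <- exp(beta * x[risk])
      xbar <- sum(w * x[risk]) / sum(w)
      x2bar <- sum(w * x[risk]^2) / sum(w)
      U <- U + sum(x[d]) - length(d) * xbar
      I <- I + length(d) * (x2bar - xbar^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}
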