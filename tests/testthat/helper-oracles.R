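# Independent reference implementations used to cross-check the package's
# statistical routines. These deliberately avoid the code paths the package
# uses (hand-coded Newton/IRLS instead of stats::glm, hand step-up instead
# of p.adjust, Prim's algorithm instead of igraph).

# Benjamini-Hochberg step-up, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
}

# logistic regression by damped Newton iterations to machine precision
oracle_logistic <- function(X, y, tol = 1e-14, maxit = 200) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  vc <- solve(info)
  se <- unname(sqrt(diag(vc)))
  list(coef = as.numeric(beta), se = se, z = as.numeric(beta) / se)
}

# quasipoisson log-link: Newton on the Poisson score, Pearson dispersion,
# t statistics on n - p df
oracle_quasipoisson <- function(X, y, offset = rep(0, length(y)),
                                tol = 1e-14, maxit = 200) {
  X <- cbind(1, X)
  beta <- c(log(mean(y) + 0.1) - mean(offset), rep(0, ncol(X) - 1))
  for (it in seq_len(maxit)) {
    mu <- exp(as.numeric(X %*% beta) + offset)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(as.numeric(X %*% beta) + offset)
  phi <- sum((y - mu)^2 / mu) / (length(y) - ncol(X))
  se <- unname(sqrt(diag(solve(info)) * phi))
  tstat <- as.numeric(beta) / se
  list(coef = as.numeric(beta), se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df = length(y) - ncol(X)))
}

# negative binomial log-link ML: alternate Newton in beta (fixed theta)
# with golden-section ML in log(theta)
oracle_nb <- function(X, y, offset = rep(0, length(y)), tol = 1e-12,
                      maxit = 200) {
  X <- cbind(1, X)
  nb_ll <- function(beta, ltheta) {
    th <- exp(ltheta)
    mu <- exp(as.numeric(X %*% beta) + offset)
    sum(lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
          th * log(th / (th + mu)) + y * log(mu / (th + mu)))
  }
  beta_step <- function(beta, ltheta, inner = 100) {
    th <- exp(ltheta)
    for (it in seq_len(inner)) {
      mu <- exp(as.numeric(X %*% beta) + offset)
      w <- mu * th / (th + mu)            # NB2 working weights, log link
      score <- crossprod(X, (y - mu) * th / (th + mu))
      info <- crossprod(X * w, X)
      step <- solve(info, score)
      beta <- beta + step
      if (max(abs(step)) < tol) break
    }
    beta
  }
  beta <- c(log(mean(y) + 0.1) - mean(offset), rep(0, ncol(X) - 1))
  ltheta <- log(1)
  for (outer in seq_len(maxit)) {
    beta <- beta_step(beta, ltheta)
    opt <- optimize(function(lt) nb_ll(beta, lt), c(-8, 12),
                    maximum = TRUE, tol = 1e-12)
    if (abs(opt$maximum - ltheta) < 1e-10) { ltheta <- opt$maximum; break }
    ltheta <- opt$maximum
  }
  beta <- beta_step(beta, ltheta)
  list(coef = as.numeric(beta), theta = exp(ltheta))
}

# minimum spanning tree edge total by Prim's algorithm on a distance matrix
oracle_mst_edges <- function(dm) {
  n <- nrow(dm)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- NULL
  while (sum(in_tree) < n) {
    sub <- dm[in_tree, !in_tree, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    from <- which(in_tree)[k[1]]
    to <- which(!in_tree)[k[2]]
    edges <- rbind(edges, c(min(from, to), max(from, to), dm[from, to]))
    in_tree[to] <- TRUE
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}
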