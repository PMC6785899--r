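# Independent oracles used across the suite. Each recomputes a quantity by
# brute force / exhaustive enumeration, never by calling the implementation
# it checks.

# Detection power by exhaustive enumeration over (alt count, forward split).
power_oracle <- function(depth, vaf, min_alt = 4L, min_per_strand = 1L) {
  if (depth == 0) return(0)
  total <- 0
  for (a in 0:depth) {
    pa <- dbinom(a, depth, vaf)
    if (pa == 0) next
    for (f in 0:a) {
      if (a >= min_alt && f >= min_per_strand && (a - f) >= min_per_strand) {
        total <- total + pa * dbinom(f, a, 0.5)
      }
    }
  }
  total
}

# NNLS residual oracle: best residual over a simplex grid of weight
# fractions (step `by`) scaled by a 1-D optimal magnitude per grid point.
grid_nnls_oracle <- function(S, y, by = 0.01) {
  K <- ncol(S)
  fracs <- seq(0, 1, by = by)
  if (K > 4) stop("grid oracle supports K <= 4")
  if (K == 1) {
    grid <- matrix(1, 1, 1)
  } else {
    free <- as.matrix(do.call(expand.grid, rep(list(fracs), K - 1)))
    s <- rowSums(free)
    free <- free[s <= 1 + 1e-9, , drop = FALSE]
    grid <- cbind(free, pmax(1 - rowSums(free), 0))
  }
  P <- S %*% t(grid)                       # 96 x G mixture profiles
  # optimal scale per profile: argmin_s ||s p - y|| = <p,y>/<p,p>
  pp <- colSums(P^2)
  py <- as.vector(crossprod(P, y))
  s <- ifelse(pp > 0, pmax(py / pp, 0), 0)
  R <- sweep(P, 2, s, `*`) - y
  sqrt(min(colSums(R^2)))
}

# Exact two-sample Mann-Whitney p by complete enumeration of group
# assignments (tie-free data, n1 + n2 choose n1 assignments).
mw_exact_oracle <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_stat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  switch(alternative,
         less = mean(all_u <= obs),
         greater = mean(all_u >= obs),
         two.sided = {
           mu <- n1 * n2 / 2
           mean(abs(all_u - mu) >= abs(obs - mu))
         })
}

# Fisher two-sided p by hypergeometric enumeration (sum of table
# probabilities <= observed, the standard convention).
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank chi-squared by direct observed-minus-expected accumulation over
# distinct event times (two groups).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0; obs1 <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs1 <- obs1 + d1
  }
  (o_minus_e)^2 / v
}

# Recount a pileup from reads by brute force, one read at a time.
pileup_recount_oracle <- function(sim, ref) {
  L <- nchar(ref$sequence)
  o <- ref$origin_coordinate
  depth <- integer(L)
  base_counts <- list()
  rd <- sim$reads
  for (i in seq_len(nrow(rd))) {
    span <- seq.int(rd$start[i], rd$start[i] + rd$insert_size[i] - 1L)
    span <- span[span >= o & span < o + L]
    depth[span - o + 1L] <- depth[span - o + 1L] + 1L
    obs <- setNames(ctdnatrack::ref_base(ref, span), span)
    m <- sim$mismatches[sim$mismatches$read_id == rd$read_id[i], , drop = FALSE]
    if (nrow(m)) obs[as.character(rd$start[i] + m$offset)] <- m$base
    for (ps in names(obs)) {
      key <- paste(ps, obs[[ps]], rd$strand[i])
      base_counts[[key]] <- (base_counts[[key]] %||% 0L) + 1L
    }
  }
  list(depth = depth, base_counts = base_counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
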