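## Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture_space_small <- function() {
  if (is.null(.fixtures$space_small))
    .fixtures$space_small <- make_source_space(42, 6, c(10, 10, 10), seed = 0)
  .fixtures$space_small
}

fixture_space_mid <- function() {
  if (is.null(.fixtures$space_mid))
    .fixtures$space_mid <- make_source_space(162, 20, c(16, 16, 16), seed = 0)
  .fixtures$space_mid
}

fixture_leadfield_mid <- function() {
  if (is.null(.fixtures$lf_mid))
    .fixtures$lf_mid <- make_leadfield(fixture_space_mid(), 24, seed = 0)
  .fixtures$lf_mid
}

## ---- independent oracles -------------------------------------------------

## signed modularity, re-derived from the definition (independent of the
## package's signed_modularity)
oracle_signed_q <- function(W, labels) {
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  same <- outer(labels, labels, `==`)
  q <- 0
  if (vp > 0) q <- q + sum((Wp - outer(sp, sp) / vp) * same) / vp
  if (vn > 0) q <- q - sum((Wn - outer(sn, sn) / vn) * same) / (vp + vn)
  q
}

## all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list(1L)
  for (i in seq_len(n - 1L)) {
    nxt <- vector("list", 0)
    for (p in out) {
      m <- max(p)
      for (lab in seq_len(m + 1L)) nxt[[length(nxt) + 1L]] <- c(p, lab)
    }
    out <- nxt
  }
  out
}

## exhaustive maximization of signed modularity over all partitions
oracle_best_partition_q <- function(W) {
  parts <- all_partitions(nrow(W))
  best <- -Inf
  for (p in parts) {
    q <- oracle_signed_q(W, p)
    if (q > best) best <- q
  }
  best
}

## independent random-effects model-selection updates (variational
## Dirichlet scheme, written directly from the update equations)
oracle_bms <- function(logev, alpha0 = 1, n_iter = 200) {
  M <- ncol(logev)
  alpha <- rep(alpha0, M)
  for (i in seq_len(n_iter)) {
    lu <- sweep(logev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha <- alpha0 + colSums(g)
  }
  alpha / sum(alpha)
}

## best assignment under exhaustive permutation matching of component
## rows to reference rows, by mean |correlation|
match_components <- function(est, ref) {
  k <- nrow(ref)
  perms <- fmripeb_perms(k)
  cors <- abs(cor(t(est), t(ref)))  # est x ref
  best <- -Inf; best_r <- NULL
  for (i in seq_len(nrow(perms))) {
    r <- cors[cbind(perms[i, ], seq_len(k))]
    if (mean(r) > best) { best <- mean(r); best_r <- r }
  }
  best_r
}

## small local permutation enumerator (kept independent of package internals)
fmripeb_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- fmripeb_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, append, values = n, after = pos - 1L))))
}

## planted sign-pattern states used across dFC tests
planted_states_pair <- function(N) {
  s1 <- rep(c(1, -1), length.out = N) / sqrt(N)
  s2 <- rep(c(1, 1, -1, -1), length.out = N) / sqrt(N)
  list(s1, s2)
}
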