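# Analytic and brute-force oracles, independent of the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Erlang-C closed form for an M/M/c queue.
erlang_c_wq <- function(lambda, mean_service, c) {
  a <- lambda * mean_service
  stopifnot(a < c)
  B <- 1
  for (k in 1:c) B <- a * B / (k + a * B)
  rho <- a / c
  C <- B / (1 - rho * (1 - B))
  C * mean_service / (c - a)
}
erlang_c_lq <- function(lambda, mean_service, c)
  lambda * erlang_c_wq(lambda, mean_service, c)

# --- brute-force centralities on a binary adjacency matrix ----------------

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  P <- diag(n)
  for (k in seq_len(n - 1)) {
    P <- P %*% A
    D[D == Inf & P > 0] <- k
  }
  diag(D) <- 0
  D
}

bf_harmonic <- function(A, mode = c("out", "in")) {
  mode <- match.arg(mode)
  D <- bf_distances(A)
  if (mode == "in") D <- t(D)
  diag(D) <- Inf
  rowSums(1 / D)
}

# geodesic counting via matrix powers: walks of length d(s,t) are exactly
# the shortest paths
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  Ak <- vector("list", n)
  Ak[[1]] <- A
  for (k in seq_len(n - 1)[-1]) Ak[[k]] <- Ak[[k - 1]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(if (d == 0) 1 else 0)
    Ak[[d]][s, t]
  }
  out <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    d <- D[s, t]
    if (!is.finite(d) || d == 0) next
    if (is.finite(D[s, v]) && is.finite(D[v, t]) && D[s, v] + D[v, t] == d)
      out[v] <- out[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
  }
  out
}

bf_bonacich_series <- function(A, beta, terms = 60) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  P <- diag(n)
  for (k in 0:terms) {
    S <- S + beta^k * (P %*% A)
    P <- P %*% A
  }
  cvec <- as.numeric(S %*% rep(1, n))
  cvec * sqrt(n / sum(cvec^2))
}

adjacency_to_log <- function(A, labels = NULL) {
  n <- nrow(A)
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  idx <- which(A > 0, arr.ind = TRUE)
  tibble::tibble(source = labels[idx[, 1]], target = labels[idx[, 2]])
}

sym_binary <- function(A) {
  S <- ((A + t(A)) > 0) * 1
  diag(S) <- 0
  S
}

random_digraph <- function(n, p = 0.4) {
  A <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

# --- small model builders -------------------------------------------------

single_stage_model <- function(dist, capacity, lambda) {
  process_model(list(subprocess("S", dist, capacity = capacity)),
                tibble::tibble(from = character(), to = character()),
                arrival_rate = lambda)
}

constant_forkjoin_model <- function(init = 2, contract = 5, budget = 3,
                                    pi = 1, dsr = 1, sponsor = 1,
                                    lambda = 0.2) {
  sps <- list(
    subprocess("Init", dist_constant(init)),
    subprocess("Contract", dist_constant(contract)),
    subprocess("Budget", dist_constant(budget)),
    subprocess("PI", dist_constant(pi)),
    subprocess("DSR", dist_constant(dsr)),
    subprocess("Sponsor", dist_constant(sponsor))
  )
  routing <- tibble::tibble(
    from = c("Init", "Init", "Contract", "Budget", "PI", "DSR"),
    to = c("Contract", "Budget", "PI", "PI", "DSR", "Sponsor"))
  process_model(sps, routing, arrival_rate = lambda)
}

summary_value <- function(exp, measure) {
  s <- exp$summary
  s$mean[match(measure, s$measure)]
}

summary_ci <- function(exp, measure) {
  s <- exp$summary
  s$ci_halfwidth[match(measure, s$measure)]
}
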