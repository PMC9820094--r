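# Independent oracles used across the test files.

# Exact optimal partitioning by plain O(n^2) dynamic programming (no
# pruning), minimizing sum of within-segment squared deviations plus
# `beta` per change point; ties broken towards fewer change points.
# Returns 0-based change points.
op_segment_oracle <- function(x, beta) {
  n <- length(x)
  S <- cumsum(c(0, x))
  S2 <- cumsum(c(0, x^2))
  segcost <- function(a, b) {  # half-open [a, b)
    s <- S[b + 1L] - S[a + 1L]
    s2 <- S2[b + 1L] - S2[a + 1L]
    max(0, s2 - s^2 / (b - a))
  }
  F <- c(-beta, rep(Inf, n))
  K <- integer(n + 1L)
  last <- integer(n + 1L)
  tol <- 1e-9
  for (t in 1:n) {
    best <- Inf; arg <- -1L; bestK <- 0L
    for (s in 0:(t - 1L)) {
      v <- F[s + 1L] + segcost(s, t) + beta
      k <- K[s + 1L] + 1L
      if (v < best - tol || (v <= best + tol && (arg < 0L || k < bestK))) {
        best <- v; arg <- s; bestK <- k
      }
    }
    F[t + 1L] <- best; last[t + 1L] <- arg; K[t + 1L] <- bestK
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- last[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  # F[0] = -beta cancels the first segment's +beta, so F[n] is already
  # sum(RSS) + beta * (#change points)
  list(change_points = cps, cost = F[n + 1L])
}

# Literal enumeration over all change-point placements with at most kmax
# change points (for tiny n).
enum_segment_oracle <- function(x, beta, kmax = 4L) {
  n <- length(x)
  segrss <- function(cps) {
    bounds <- c(0L, cps, n)
    sum(vapply(seq_len(length(bounds) - 1L), function(i) {
      seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  best <- list(cost = segrss(integer(0)), cps = integer(0))
  for (k in seq_len(min(kmax, n - 1L))) {
    combos <- utils::combn(n - 1L, k)
    for (j in seq_len(ncol(combos))) {
      cps <- combos[, j]
      cost <- segrss(cps) + beta * k
      if (cost < best$cost - 1e-9) best <- list(cost = cost, cps = cps)
    }
  }
  best
}

# Random piecewise-constant trace with known change points.
random_step_trace <- function(n, max_cps = 3L, level_range = c(0, 500),
                              noise_sd = 20) {
  k <- sample(0:max_cps, 1L)
  cps <- if (k > 0L) sort(sample(seq_len(n - 1L), k)) else integer(0)
  bounds <- c(0L, cps, n)
  levels <- runif(k + 1L, level_range[1], level_range[2])
  x <- numeric(n)
  for (i in seq_len(k + 1L)) {
    x[(bounds[i] + 1L):bounds[i + 1L]] <- levels[i]
  }
  x + rnorm(n, 0, noise_sd)
}

# Definitional set-filter oracle for the staged inference.
inference_oracle <- function(table, terminal_obs, discriminator_obs) {
  m <- feasibility_matrix(table)
  arrs <- rownames(m)
  neg <- terminal_obs$experiment[terminal_obs$observed == "no_bifc"]
  pos <- discriminator_obs$experiment[discriminator_obs$observed == "bifc_seen"]
  stage1 <- arrs[!vapply(arrs, function(a)
    any(m[a, neg, drop = TRUE] == "feasible"), logical(1))]
  keep <- vapply(stage1, function(a) {
    if (a == "monomer") return(TRUE)
    all(m[a, pos, drop = TRUE] == "feasible")
  }, logical(1))
  final <- stage1[keep]
  list(stage1 = setdiff(stage1, "monomer"),
       final = setdiff(final, "monomer"),
       monomer = "monomer" %in% final)
}

# Random tri-state feasibility table over the standard ids.
random_table <- function() {
  arrs <- c("monomer", paste0("dimer_", c("AB", "BC", "CD", "DA")),
            paste0("tetramer_", c("A", "B", "C", "D")))
  exps <- c("nn", "vcn_vnc", "vnn_vcc", "cc", "loop3")
  entries <- expand.grid(arrangement = arrs, experiment = exps,
                         stringsAsFactors = FALSE)
  entries$verdict <- sample(c("feasible", "blocked", "infeasible"),
                            nrow(entries), replace = TRUE)
  as_feasibility_table(entries, provenance = "random")
}

random_observations <- function(exps, n = NULL) {
  if (is.null(n)) n <- sample(0:length(exps), 1L)
  if (n == 0L) return(bifc_observations(character(0), character(0)))
  bifc_observations(sample(exps, n),
                    sample(c("bifc_seen", "no_bifc"), n, replace = TRUE))
}
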