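# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Direct-summation autocorrelation estimator: C(k) = sum_t x_t x_{t+k} / (N-k).
naive_autocorr <- function(x, dt, tau_max) {
  n <- length(x)
  kmax <- floor(tau_max / dt + 1e-9)
  C <- numeric(kmax + 1L)
  for (k in 0:kmax) {
    C[k + 1L] <- sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k)
  }
  list(lags = (0:kmax) * dt, C = C)
}

# Pairwise minimum-image distance, one pair at a time.
oracle_dist <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Count waters within cutoff of any region atom by full pairwise scan.
oracle_count <- function(region_xyz, water_xyz, cutoff, box = NULL) {
  hits <- 0L
  for (w in seq_len(nrow(water_xyz))) {
    for (a in seq_len(nrow(region_xyz))) {
      if (oracle_dist(water_xyz[w, ], region_xyz[a, ], box) <= cutoff) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# Tie-corrected Kruskal-Wallis H from first principles (mean-rank form).
oracle_kw_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, g, mean)
  sizes <- lengths(groups)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Monte-Carlo permutation p-value for Kruskal-Wallis using oracle_kw_h.
oracle_kw_perm_p <- function(groups, n_perm, seed) {
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    v <- sample(values)
    gr <- lapply(seq_along(sizes), function(j) v[idx_start[j]:idx_end[j]])
    if (oracle_kw_h(gr) >= h_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

# Minimal hand-built PDB text.
pdb_lines <- function(records) {
  paste(vapply(records, function(r) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$type %||% "ATOM", r$serial, r$name, r$alt %||% " ", r$resname,
            r$chain, r$resseq, " ", r$x, r$y, r$z, r$occ %||% 1, r$b %||% 0,
            r$elem %||% substr(trimws(r$name), 1, 1))
  }, ""), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_rec <- function(serial, name, resname, chain, resseq, x, y, z, ...) {
  c(list(serial = serial, name = name, resname = resname, chain = chain,
         resseq = resseq, x = x, y = y, z = z), list(...))
}

# A tiny two-region count frame for core-pipeline tests.
toy_counts <- function(counts_by_rep, chain = "A", resseq = 1L,
                       resname = "DA", alpha = "BB", dt = 10) {
  do.call(rbind, lapply(seq_along(counts_by_rep), function(r) {
    cc <- counts_by_rep[[r]]
    data.frame(chain = chain, resseq = resseq, resname = resname,
               alpha = alpha, replicate = r,
               time_ps = dt * (seq_along(cc) - 1), count = cc,
               stringsAsFactors = FALSE)
  }))
}
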