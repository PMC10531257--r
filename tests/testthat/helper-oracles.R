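# Independent brute-force oracles.  These deliberately share no code with
# the package: plain loops and first-principles definitions, so agreement
# is evidence, not tautology.

# --- LFP double-threshold scan: explicit sample-by-sample enumeration ----
# Returns peak indices (1-based) after an explicit refractory merge
# (first event kept).
oracle_lfp_scan <- function(x, upper, lower, refractory_n) {
  peaks <- integer(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (x[i] > upper || x[i] < lower) {
      j <- i
      while (j < n && (x[j + 1L] > upper || x[j + 1L] < lower)) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(abs(x[seg]))])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) < 2L) return(peaks)
  kept <- peaks[1L]
  for (p in peaks[-1L]) {
    if (p - kept[length(kept)] >= refractory_n) kept <- c(kept, p)
  }
  kept
}

# --- burst runs: exhaustive enumeration over all index windows ----------
oracle_burst_runs <- function(t, max_isi_s, min_spikes) {
  n <- length(t)
  found <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_spikes) next
      gaps <- if (j > i) diff(t[i:j]) else numeric(0)
      if (any(gaps > max_isi_s)) next
      # maximal: cannot extend left or right
      left_ok <- i == 1L || t[i] - t[i - 1L] > max_isi_s
      right_ok <- j == n || t[j + 1L] - t[j] > max_isi_s
      if (left_ok && right_ok) {
        found[[length(found) + 1L]] <- data.frame(start = t[i], end = t[j],
                                                  n = j - i + 1L)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(start = numeric(0), end = numeric(0), n = integer(0)))
  }
  unique(do.call(rbind, found))
}

# --- graph metrics: all-pairs BFS + triangle counting -------------------
# adj: symmetric logical adjacency matrix without self loops
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]]) links <- links + 1
      }
    }
    cc[v] <- links / (k * (k - 1) / 2)
  }
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (dist[s, w] > d) { dist[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  pl <- vapply(seq_len(n), function(v) {
    dd <- dist[v, -v]
    dd <- dd[is.finite(dd)]
    if (!length(dd)) NA_real_ else mean(dd)
  }, numeric(1))
  list(degree = deg, clustering = cc, path_length = pl)
}

random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::runif(sum(up)) < p
  adj | t(adj)
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# --- small assembly helpers ---------------------------------------------
constant_recording <- function(value, nr = 2, nc = 2, nt = 10, fs = 9000,
                               filtered = FALSE) {
  mea_recording(array(value, c(nr, nc, nt)), fs,
                electrode_grid(nr, nc), filtered = filtered)
}

trace_recording <- function(x, fs = 9000, filtered = TRUE) {
  # one trace replicated on a minimal 2 x 2 grid
  mea_recording(array(rep(x, each = 4), c(2, 2, length(x))), fs,
                electrode_grid(2, 2), filtered = filtered)
}

triangular_pulse <- function(peak_uv, n_rise, n_fall = n_rise) {
  peak_uv * c(seq(0, 1, length.out = n_rise + 1)[-1],
              seq(1, 0, length.out = n_fall + 1)[-1])
}

# random mixed trace for detector-vs-oracle fuzzing: Gaussian noise plus
# a few planted triangular pulses of random sign/amplitude/width
random_lfp_trace <- function(n, fs) {
  x <- stats::rnorm(n, 0, 10)
  n_pulse <- sample(0:4, 1)
  for (k in seq_len(n_pulse)) {
    w <- sample(30:400, 1)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 30, 200)
    at <- sample(1:(n - 2 * w), 1)
    x[at:(at + 2 * w - 1)] <- x[at:(at + 2 * w - 1)] +
      triangular_pulse(amp, w)
  }
  x
}
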