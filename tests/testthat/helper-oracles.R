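# Independent brute-force oracles the implementation is checked against.

# All-pairs BFS eccentricity reciprocals, hand-rolled from the edge list
# (no graph library): returns named score vector, NA for singleton nodes.
bfs_eccentricity_oracle <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  vapply(nodes, function(v) {
    dist <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    dist[v] <- 0
    frontier <- v
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[u] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    ecc <- max(dist, na.rm = TRUE)
    if (ecc == 0) NA_real_ else 1 / ecc
  }, numeric(1))
}

# Profile grid search for the 4PL least-squares minimum: for fixed
# (ic50, hill) the model is linear in (bottom, top), solved exactly.
grid_4pl_sse <- function(x, y,
                         ic50_grid = exp(seq(log(min(x) / 3), log(max(x) * 3),
                                             length.out = 80)),
                         hill_grid = seq(0.3, 6, by = 0.1)) {
  best <- Inf
  for (ic in ic50_grid) {
    for (h in hill_grid) {
      w <- 1 / (1 + (ic / x)^h)
      A <- cbind(1 - w, w)
      fit <- stats::lm.fit(A, y)
      sse <- sum(fit$residuals^2)
      if (sse < best) best <- sse
    }
  }
  best
}

fpl_curve <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / x)^hill)
}

sse_4pl <- function(fit, x, y) {
  sum((y - fpl_curve(x, fit$bottom, fit$top, fit$ic50, fit$hill))^2)
}

# Grid search for the median-effect line minimum on the log-linearized
# scale (the quantity fit_median_effect minimizes by least squares).
grid_median_effect_sse <- function(doses, fa,
                                   m_grid = seq(0.05, 5, by = 0.005)) {
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  best <- Inf
  for (m in m_grid) {
    # optimal intercept for fixed slope is the mean residual
    b <- mean(y - m * x)
    sse <- sum((y - m * x - b)^2)
    if (sse < best) best <- sse
  }
  best
}

sse_median_effect <- function(fit, doses, fa) {
  y <- log10(fa / (1 - fa))
  pred <- fit$m * (log10(doses) - log10(fit$dm))
  sum((y - pred)^2)
}

# Titration series straight from a planted curve (no plate detour).
make_series <- function(bottom, top, ic50, hill,
                        conc = qhts_concentrations(), noise_sd = 0,
                        seed = NULL) {
  y <- fpl_curve(conc, bottom, top, ic50, hill)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  data.frame(concentration = conc, response = y)
}

# Small random connected graph as an edge data.frame (tree + extra edges).
random_connected_graph <- function(n, extra = n %/% 2) {
  stopifnot(n >= 2)
  to <- 2:n
  from <- vapply(to, function(i) sample.int(i - 1, 1), integer(1))
  edges <- cbind(paste0("v", from), paste0("v", to))
  if (extra > 0) {
    a <- sample.int(n, extra, replace = TRUE)
    b <- sample.int(n, extra, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, cbind(paste0("v", pmin(a, b)[keep]),
                                paste0("v", pmax(a, b)[keep])))
  }
  edges <- unique(edges)
  data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE)
}
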