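# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# Zooming grid search over (mesor, amplitude, acrophase) minimizing RSS of
# mu + A*cos(2*pi*(t - phi)/24). Refines around the incumbent until the grid
# resolution is below `res`.
gridSearchHarmonic <- function(t, y, res = 1e-6) {
  best <- c(mu = mean(y), A = (max(y) - min(y)) / 2, phi = 0)
  widths <- c(mu = max(diff(range(y)), 1e-3), A = max(diff(range(y)), 1e-3), phi = 12)
  best_rss <- Inf
  repeat {
    mus <- seq(best["mu"] - widths["mu"], best["mu"] + widths["mu"], length.out = 13)
    As <- seq(max(0, best["A"] - widths["A"]), best["A"] + widths["A"], length.out = 13)
    phis <- seq(best["phi"] - widths["phi"], best["phi"] + widths["phi"], length.out = 25)
    for (mu in mus) for (A in As) for (phi in phis) {
      r <- y - (mu + A * cos(2 * pi * (t - phi) / 24))
      rss <- sum(r^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- c(mu = mu, A = A, phi = phi)
      }
    }
    widths <- widths * 0.25
    if (all(widths < res)) break
  }
  list(mu = unname(best["mu"]), amplitude = unname(best["A"]),
       acrophase_h = unname(best["phi"]) %% 24,
       a = unname(best["A"] * cos(2 * pi * best["phi"] / 24)),
       b = unname(best["A"] * sin(2 * pi * best["phi"] / 24)),
       rss = best_rss)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (tie- and zero-free differences assumed).
wilcoxonEnumerationP <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Exhaustive MIC over ALL contiguous rank partitions of both axes for tiny n
# and small grids: the oracle the hill-climbing search is checked against.
micExhaustiveTiny <- function(x, y, max_bins = 4L, max_cells = 9L) {
  n <- length(x)
  stopifnot(n <= 14L)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  mi_of <- function(ix, iy, r, c) {
    tab <- tabulate((iy - 1L) * r + ix, nbins = r * c)
    p <- matrix(tab / sum(tab), r, c)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }
  partitions <- function(k) {  # all cut vectors (k-1 ascending cuts in 1..n-1)
    m <- utils::combn(n - 1L, k - 1L)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }
  binify <- function(rk, cuts) findInterval(rk, cuts + 0.5) + 1L
  best <- 0
  for (r in 2:max_bins) for (c in 2:max_bins) {
    if (r * c > max_cells) next
    for (cx in partitions(r)) for (cy in partitions(c)) {
      mi <- mi_of(binify(rx, cx), binify(ry, cy), r, c)
      best <- max(best, mi / log(min(r, c)))
    }
  }
  min(1, best)
}

# Small CT fixture: one participant, one target gene + reference at fixed
# times, chosen CTs.
makeCtFixture <- function(ct_target, ct_ref = rep(20, length(ct_target)),
                          times = c(9, 13, 17, 21), gene = "PER2") {
  stopifnot(length(ct_target) == length(ct_ref), length(ct_target) == length(times))
  CtTable(data.frame(
    participant = "P01", day = 1L, time_h = rep(times, 2),
    gene = rep(c(gene, "GAPDH"), each = length(times)),
    ct = c(ct_target, ct_ref)))
}

writeTempTable <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
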