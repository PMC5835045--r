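# Independent oracles used to validate the package implementations.
# These deliberately share no code with the functions they check.

# Brute-force one-sided Mann-Whitney p-value by full enumeration of label
# assignments, with U computed directly from pairwise comparisons.
mwu_brute_force <- function(x, y, alternative = "greater") {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, function(ix) u_of(pooled[ix], pooled[-ix]))
  if (alternative == "greater") mean(us >= u_obs - 1e-9)
  else mean(us <= u_obs + 1e-9)
}

# Queue-based flood-fill count of 8-connected foreground components with an
# area filter; independent of EBImage labeling.
flood_fill_count <- function(binary, min_area, max_area) {
  H <- nrow(binary); W <- ncol(binary)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (start in which(binary != 0)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    area <- 0L
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      area <- area + 1L
      y <- (p - 1L) %% H + 1L; x <- (p - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1L || yy > H || xx < 1L || xx > W) next
        q <- (xx - 1L) * H + yy
        if (binary[q] != 0 && !seen[q]) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
    if (area >= min_area && area <= max_area) count <- count + 1L
  }
  count
}

# Greedy matched-pairs scoring of detected vs true event times.
score_events <- function(detected, truth, window = 0.5) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= window)
    if (length(j)) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}
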