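# Shared helpers: small optical configs and oracles used across tests.

cfg_default <- optical_config()

# Intersection-over-union of truth cell i against its best-overlap label.
mask_iou <- function(mask, truth_mask, i) {
  tm <- truth_mask == i
  labs <- table(mask[tm])
  labs <- labs[names(labs) != "0"]
  if (length(labs) == 0L) return(0)
  k <- as.integer(names(which.max(labs)))
  sum(tm & mask == k) / sum(tm | mask == k)
}

# Brute-force isolation oracle: all-vs-all distances, no shortcuts.
isolation_oracle <- function(pairs, s1, s2, thr) {
  pts <- rbind(cbind(s1$row, s1$col), cbind(s2$row, s2$col))
  chan <- rep(1:2, c(nrow(s1), nrow(s2)))
  idx <- c(seq_len(nrow(s1)), seq_len(nrow(s2)))
  vapply(seq_len(nrow(pairs)), function(i) {
    own <- (chan == 1 & idx == pairs$idx1[i]) |
      (chan == 2 & idx == pairs$idx2[i])
    ok <- TRUE
    for (j in which(!own)) {
      d1 <- sqrt((pts[j, 1] - pairs$row1[i])^2 +
                   (pts[j, 2] - pairs$col1[i])^2)
      d2 <- sqrt((pts[j, 1] - pairs$row2[i])^2 +
                   (pts[j, 2] - pairs$col2[i])^2)
      if (min(d1, d2) < thr) { ok <- FALSE; break }
    }
    ok
  }, logical(1))
}

# Match detected centroids to truth positions; returns per-detection
# distance to the nearest truth point (px).
truth_errors <- function(spots, truth_rc) {
  D <- outer(spots$row, truth_rc[, 1], "-")^2 +
    outer(spots$col, truth_rc[, 2], "-")^2
  sqrt(apply(D, 1, min))
}
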