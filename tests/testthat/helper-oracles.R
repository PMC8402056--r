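# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the vectorized implementations they check.

# Stack-based flood fill connected-component labeling.
flood_fill_labels <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 4) list(c(-1,0), c(1,0), c(0,-1), c(0,1))
          else list(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in offs) {
          r <- p[1] + o[1]; c <- p[2] + o[2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] == 1 && lab[r, c] == 0L) {
            lab[r, c] <- nxt
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Loop-coded seeded watershed with the same documented semantics as
# seeded_watershed(): quantized bins, monotone water level, synchronous
# one-ring updates, ridge on multi-label contact.
brute_watershed <- function(elev, seeds, region = NULL, connectivity = 8,
                            nlevels = 256) {
  h <- nrow(elev); w <- ncol(elev)
  if (is.null(region)) region <- matrix(TRUE, h, w)
  offs <- if (connectivity == 4) list(c(-1,0), c(1,0), c(0,-1), c(0,1))
          else list(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  rng <- range(elev[region])
  bin <- matrix(0, h, w)
  if (rng[2] > rng[1])
    for (i in seq_len(h)) for (j in seq_len(w))
      bin[i, j] <- min(floor((elev[i, j] - rng[1]) / (rng[2] - rng[1]) * nlevels),
                       nlevels - 1)
  state <- matrix(0L, h, w)
  for (s in seq_len(nrow(seeds))) state[seeds[s, 1], seeds[s, 2]] <- s
  level <- -Inf
  repeat {
    frontier <- list(); fbins <- numeric(0)
    for (j in seq_len(w)) for (i in seq_len(h)) {
      if (!region[i, j] || state[i, j] != 0L) next
      labs <- integer(0)
      for (o in offs) {
        r <- i + o[1]; c <- j + o[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && state[r, c] > 0L)
          labs <- c(labs, state[r, c])
      }
      if (length(labs)) {
        frontier[[length(frontier) + 1L]] <- list(i = i, j = j, labs = unique(labs))
        fbins <- c(fbins, bin[i, j])
      }
    }
    if (!length(frontier)) break
    level <- max(level, min(fbins))
    changed <- FALSE
    for (k in seq_along(frontier)) {
      f <- frontier[[k]]
      if (bin[f$i, f$j] > level) next
      state[f$i, f$j] <- if (length(f$labs) == 1L) f$labs else -1L
      changed <- TRUE
    }
    if (!changed) break
  }
  basins <- state; basins[state < 0L] <- 0L
  list(basins = basins, ridge = state == -1L)
}

# Align-corners bilinear crop-and-resize of an RGB array: output pixel
# centres span the pixel-centre rectangle [r1, r2] x [c1, c2].
crop_resize_oracle <- function(px, r1, r2, c1, c2, ho, wo) {
  out <- array(0, c(ho, wo, 3))
  for (p in seq_len(ho)) for (q in seq_len(wo)) {
    sr <- r1 + (p - 1) * (r2 - r1) / (ho - 1)
    sc <- c1 + (q - 1) * (c2 - c1) / (wo - 1)
    r0 <- min(floor(sr), nrow(px) - 1); c0 <- min(floor(sc), ncol(px) - 1)
    fr <- sr - r0; fc <- sc - c0
    for (k in 1:3)
      out[p, q, k] <- px[r0, c0, k] * (1 - fr) * (1 - fc) +
        px[r0 + 1, c0, k] * fr * (1 - fc) +
        px[r0, c0 + 1, k] * (1 - fr) * fc +
        px[r0 + 1, c0 + 1, k] * fr * fc
  }
  out
}

# Probability map with ear probability p on `mask` pixels and q elsewhere.
two_level_pmap <- function(mask, p_in, p_out) {
  S <- array(0, c(nrow(mask), ncol(mask), 2))
  S[, , 2] <- ifelse(mask == 1, p_in, p_out)
  S[, , 1] <- 1 - S[, , 2]
  probability_map(S)
}

# All binary 3x3 masks (512), as a list of matrices.
all_3x3_masks <- function() {
  lapply(0:511, function(v) matrix(as.integer(intToBits(v)[1:9]), 3, 3))
}
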