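# Shared fixtures and independent oracles.

# One comet embedded in a constant-background image.
fixture_comet_image <- function(head_radius = 10, head_peak = 200,
                                tail_length = 0, tail_fraction = 0,
                                orientation = 0.5, background = 10,
                                pad = 12) {
  p <- comet_params(NULL, head_radius = head_radius, head_peak = head_peak,
                    tail_length = tail_length,
                    tail_fraction = tail_fraction,
                    orientation = orientation)
  r <- render_comet(p)
  ph <- nrow(r$patch); pw <- ncol(r$patch)
  h <- ph + 2 * pad; w <- pw + 2 * pad
  px <- matrix(background, h, w)
  rs <- pad + seq_len(ph); cs <- pad + seq_len(pw)
  px[rs, cs] <- px[rs, cs] + round(r$patch)
  emb <- function(m) { x <- matrix(FALSE, h, w); x[rs, cs] <- m; x }
  list(image = comet_image(px),
       comet_mask = emb(r$comet_mask), head_mask = emb(r$head_mask),
       tail_mask = emb(r$tail_mask), render = r,
       roi = roi_circle(c((h - 1) / 2, (w - 1) / 2), max(h, w) / 2))
}

# Brute-force Otsu: scan all thresholds, maximise between-class variance.
otsu_bruteforce <- function(counts) {
  n <- length(counts)
  lev <- seq_len(n) - 1
  total <- sum(counts)
  best <- -Inf; best_t <- NA
  for (t in 0:(n - 2)) {
    c0 <- counts[lev <= t]; c1 <- counts[lev > t]
    w0 <- sum(c0) / total; w1 <- sum(c1) / total
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lev[lev <= t] * c0) / sum(c0)
    mu1 <- sum(lev[lev > t] * c1) / sum(c1)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  as.integer(best_t)
}

# Brute-force triangle: explicit point-to-line distance per bin, same tie
# conventions (lowest peak, bright side on equal reach, first max from the
# peak toward the tail end).
triangle_bruteforce <- function(counts) {
  n <- length(counts)
  nonempty <- which(counts > 0)
  peak <- which.max(counts)
  lo <- nonempty[1]; hi <- nonempty[length(nonempty)]
  end <- if ((peak - lo) > (hi - peak)) lo else hi
  x1 <- peak; y1 <- counts[peak]; x2 <- end; y2 <- counts[end]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  xs <- seq(peak, end)
  d <- abs((y2 - y1) * xs - (x2 - x1) * counts[xs] + x2 * y1 - y2 * x1) /
    len
  as.integer(xs[which.max(d)] - 1)
}

# Brute-force multi-object JI: enumerate every GT x pred object pair by
# exhaustive pixel counting.
multi_ji_bruteforce <- function(gt, pred, min_overlap = 0.5) {
  gt_ids <- sort(setdiff(unique(as.vector(gt)), 0))
  jis <- vapply(gt_ids, function(g) {
    gm <- gt == g
    pred_ids <- sort(setdiff(unique(as.vector(pred)), 0))
    if (length(pred_ids) == 0) return(0)
    inter <- vapply(pred_ids, function(p) sum(gm & pred == p), numeric(1))
    best <- pred_ids[order(-inter, pred_ids)][1]
    bi <- inter[match(best, pred_ids)]
    if (bi / sum(gm) < min_overlap) return(0)
    bi / (sum(gm) + sum(pred == best) - bi)
  }, numeric(1))
  mean(jis)
}

# Minimal 24-bit uncompressed BMP writer (independent of the package's
# reader) for grey values 0..255 stored in all three channels.
write_bmp24 <- function(grey, path) {
  h <- nrow(grey); w <- ncol(grey)
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  data_size <- row_bytes * h
  con <- file(path, "wb"); on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("BM", con, eos = NULL)
  u32(54 + data_size); u32(0); u32(54)
  u32(40); u32(w); u32(h); u16(1); u16(24); u32(0); u32(data_size)
  u32(2835); u32(2835); u32(0); u32(0)
  for (r in h:1) {               # bottom-up rows
    row <- as.integer(rep(grey[r, ], each = 3))   # B, G, R equal
    row <- c(row, rep(0L, row_bytes - w * 3))
    writeBin(as.raw(row), con)
  }
  invisible(path)
}
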