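# Fixtures are generated in code; nothing is read from disk.

# Crisp two-phase disk image with its analytic ground truth.
make_disk_image <- function(n = 64, radius = 12, bg = 0.1, fg = 0.9) {
  ctr <- (n - 1) / 2
  rr <- matrix(seq_len(n) - 1, n, n)
  cc <- t(rr)
  disk <- sqrt((rr - ctr)^2 + (cc - ctr)^2) <= radius
  img <- matrix(bg, n, n)
  img[disk] <- fg
  list(image = img, disk = disk, center = c(ctr, ctr), radius = radius)
}

random_gray <- function(nr = 16, nc = 16) matrix(runif(nr * nc), nr, nc)

random_mask <- function(nr = 16, nc = 16, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# Brute-force sliding-window grayscale morphology with a disk, window
# clipped to the image (the package operation's boundary convention).
oracle_morph <- function(img, radius, mode) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  filt <- function(x, f) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rs <- r + offs$dr; cs <- c + offs$dc
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      out[r, c] <- f(x[cbind(rs[ok], cs[ok])])
    }
    out
  }
  open_ <- function(x) filt(filt(x, min), max)
  close_ <- function(x) filt(filt(x, max), min)
  switch(mode, open = open_(img), close = close_(img),
         "open-close" = close_(open_(img)))
}

# Independent 8-connected labeling by queue-based flood fill.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue <- c(queue, (c2 - 1L) * nr + r2)
        }
      }
    }
  }
  lab
}

# Canonical form of a labeling: for comparing two labelings that may number
# components differently.
partition_signature <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  sets <- lapply(ids, function(i) which(lab == i))
  sets[order(vapply(sets, min, integer(1)))]
}
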