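# Independent brute-force oracles.  These deliberately re-derive every
# quantity with naive loops so they share no code with the implementation.

# naive moments over a vector of gray values (population denominators)
oracle_moments <- function(vals) {
  n <- length(vals)
  m <- 0
  for (v in vals) m <- m + v / n
  v2 <- v3 <- v4 <- 0
  for (v in vals) {
    v2 <- v2 + (v - m)^2 / n
    v3 <- v3 + (v - m)^3 / n
    v4 <- v4 + (v - m)^4 / n
  }
  counts <- integer(256)
  for (v in vals) counts[v + 1L] <- counts[v + 1L] + 1L
  ent <- 0
  for (k in counts) if (k > 0) {
    q <- k / n
    ent <- ent - q * log2(q)
  }
  list(mean = m, variance = v2,
       skewness = if (v2 > 0) v3 / v2^1.5 else NA_real_,
       kurtosis = if (v2 > 0) v4 / v2^2 else NA_real_,
       entropy = ent)
}

# exhaustive ordered-pair enumeration for GLCM features at one angle
oracle_glcm <- function(px, mask, d, angle, symmetric = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, 256, 256)
  nr <- nrow(px); nc <- ncol(px)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, c] && mask[r2, c2]) {
      i <- px[r, c] + 1L; j <- px[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  p <- counts / tot
  con <- eng <- hmg <- ent <- 0
  for (i in 1:256) for (j in 1:256) if (p[i, j] > 0) {
    con <- con + (i - j)^2 * p[i, j]
    eng <- eng + p[i, j]^2
    hmg <- hmg + p[i, j] / (1 + (i - j)^2)
    ent <- ent - p[i, j] * log2(p[i, j])
  }
  c(contrast = con, energy = eng, homogeneity = hmg, entropy = ent)
}

# crossing-number point-in-polygon, written independently of the package
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# term-by-term absolute error variance for the D-study
oracle_error_variance <- function(comp, n_e, n_v, n_i) {
  eff <- gtheory_effects()
  tot <- 0
  for (e in setdiff(eff, "S")) {
    div <- 1
    if (grepl("E", e)) div <- div * n_e
    if (grepl("V", e)) div <- div * n_v
    if (grepl("I", e)) div <- div * n_i
    tot <- tot + comp[[e]] / div
  }
  tot
}

# random test image + blob mask
random_image_mask <- function(nr, nc, levels = 0:255) {
  px <- matrix(sample(levels, nr * nc, replace = TRUE), nr, nc)
  storage.mode(px) <- "integer"
  mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
  if (!any(mask)) mask[1] <- TRUE
  list(px = px, mask = mask)
}

named_components <- function(...) {
  v <- setNames(numeric(15), gtheory_effects())
  args <- c(...)
  v[names(args)] <- args
  v
}
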