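# Shared fixtures and independent oracles used across the suite.

# minimal stack: constant-value channels with a few foreground voxels
makeTinyStack <- function(Z = 2, H = 16, W = 16, bg = 10 / 255,
                          fg = 200 / 255) {
  v <- array(bg, dim = c(3, Z, H, W))
  AxonStack(v, c(axon = 1, myelin = 2, nuclei = 3),
            pixelSizeUm = 0.31, zStepUm = 2)
}

# logical disk mask (independent of the package's internal rasterizer)
diskMask <- function(H, W, cy, cx, r) {
  outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") <= r^2
}

# annular-arc mask for wrap-fraction oracles
arcMask <- function(H, W, cy, cx, rin, rout, coverage, offset = 0) {
  d2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")
  ring <- d2 > rin^2 & d2 <= rout^2
  if (coverage >= 1) return(ring)
  ang <- atan2(outer(seq_len(H) - cy, rep(1, W)),
               outer(rep(1, H), seq_len(W) - cx))
  ring & ((ang - offset) %% (2 * pi)) < coverage * 2 * pi
}

# brute-force run finder: maximal runs of TRUE in a logical vector
runsOracle <- function(pass) {
  out <- NULL
  i <- 1L
  n <- length(pass)
  while (i <= n) {
    if (pass[i]) {
      j <- i
      while (j < n && pass[j + 1L]) j <- j + 1L
      out <- rbind(out, c(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# exhaustive two-sided Mann-Whitney p via rank sums (independent of the
# package's pairwise-comparison U computation)
mwPermOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  W <- function(ii) sum(r[ii])
  uFromW <- function(w) w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  obs <- abs(uFromW(W(seq_len(n1))) - mu)
  labs <- combn(n1 + n2, n1)
  devs <- apply(labs, 2, function(ii) abs(uFromW(W(ii)) - mu))
  mean(devs >= obs - 1e-9)
}

# write a small set of synthetic fields + manifest into dir; returns the
# manifest path
writePlateFixture <- function(dir, conditions = c("DMSO", "cmpA"),
                              fieldsPer = 2, seed0 = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- NULL
  s <- seed0
  for (cc in conditions) {
    for (f in seq_len(fieldsPer)) {
      s <- s + 1
      sp <- noiseFree(syntheticFieldSpec(
        wrapEvents = wrapEvent(5, 1, 4, 1.0), nNuclei = 5, seed = s))
      fl <- generateField(sp)
      p <- file.path(dir, sprintf("%s_f%d.tif", cc, f))
      writeStack(fl$stack, p)
      rows <- rbind(rows, data.frame(
        well_id = paste0("W", match(cc, conditions)),
        field_id = paste0("f", f), condition = cc, path = basename(p)))
    }
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(rows, mp, row.names = FALSE)
  mp
}
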