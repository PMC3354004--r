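# Independent reference implementations of the dip statistic used as oracles.
#
# (1) dip_oracle_r(): a direct, unoptimized R implementation: global bisection
#     over the fit error, checking feasibility of every mode placement with
#     brute-force convex-minorant / concave-majorant recomputation and
#     chain-extrapolation junction bounds. Shares only the mathematical
#     definition with the package's C implementation, none of its code paths
#     (no incremental hulls, no tangent/envelope structures, no bracketing).
#
# (2) scipy_dip_oracle(): an exhaustive small-n oracle that minimizes the
#     sup-distance over the unimodal CDF class by solving one linear program
#     per candidate mode placement (splits and atoms) with SciPy's HiGHS
#     solver (tests/testthat/oracle_dip.py).

oracle_gcm_idx <- function(xs, ys) {
  m <- length(xs)
  hull <- c(1L)
  for (j in seq_len(m)[-1]) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((ys[b] - ys[a]) * (xs[j] - xs[a]) >= (ys[j] - ys[a]) * (xs[b] - xs[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, j)
  }
  hull
}

oracle_hull_eval <- function(xs, ys, idx) {
  out <- numeric(length(xs))
  for (k in seq_len(length(idx) - 1)) {
    a <- idx[k]; b <- idx[k + 1]
    sel <- seq(a, b)
    out[sel] <- ys[a] + (ys[b] - ys[a]) * (xs[sel] - xs[a]) / (xs[b] - xs[a])
  }
  out[idx] <- ys[idx]
  out
}

dip_oracle_r <- function(x, tol = 1e-11) {
  x <- sort(as.numeric(x)); n <- length(x)
  u <- unique(x); m <- length(u)
  cc <- cumsum(tabulate(match(x, u), nbins = m))
  LO <- c(0, cc[-m]); HI <- cc
  if (m == 1) return(0)
  prefdev <- function(uu, ll, hh) {
    D <- numeric(m); Dx <- numeric(m)
    for (k in seq_len(m)) {
      if (k == 1) { D[1] <- hh[1] - ll[1]; Dx[1] <- 0; next }
      g <- oracle_gcm_idx(uu[1:k], ll[1:k])
      gv <- oracle_hull_eval(uu[1:k], ll[1:k], g)
      D[k] <- max(hh[1:k] - gv)
      Dx[k] <- max(hh[1:(k - 1)] - gv[1:(k - 1)])
    }
    list(D = D, Dx = Dx)
  }
  a <- prefdev(u, LO, HI)
  b <- prefdev(-rev(u), -rev(cc), -rev(LO))
  DL <- a$D; DLx <- a$Dx
  DR <- rev(b$D); DRx <- rev(b$Dx)

  lam_sweep <- function(uu, LOv, HIv, e) {
    L <- HIv - e; U <- LOv + e
    Lam <- numeric(m); ext <- rep(-Inf, m)
    for (k in seq_len(m)) {
      v <- -Inf
      if (k >= 3) for (j in 2:(k - 1)) for (i in 1:(j - 1)) {
        sl <- (Lam[j] - U[i]) / (uu[j] - uu[i])
        v <- max(v, Lam[j] + sl * (uu[k] - uu[j]))
      }
      ext[k] <- v
      Lam[k] <- max(L[k], v)
    }
    list(Lam = Lam, ext = ext)
  }
  feasible <- function(E) {
    e <- E / 2
    ls <- lam_sweep(u, LO, HI, e)
    rs <- lam_sweep(-rev(u), -rev(cc), -rev(LO), e)
    Lam <- ls$Lam; extL <- ls$ext
    Xi <- -rev(rs$Lam); extR <- -rev(rs$ext)
    for (k in seq_len(m)) {
      if (DL[k] <= E + 1e-12 && DR[k] <= E + 1e-12 && Lam[k] <= Xi[k] + 1e-12)
        return(TRUE)
      if (DLx[k] <= E + 1e-12 && DRx[k] <= E + 1e-12 &&
          extL[k] <= LO[k] + e + 1e-12 && HI[k] - e <= extR[k] + 1e-12 &&
          extL[k] <= extR[k] + 1e-12) return(TRUE)
    }
    FALSE
  }
  lo <- 0; hi <- n
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi / (2 * n)
}

scipy_dip_oracle <- function(xs_list) {
  script <- testthat::test_path("oracle_dip.py")
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(xs = lapply(xs_list, as.numeric)), infile,
                       digits = NA)
  out <- system2("python", shQuote(script), stdin = infile, stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))$dip
}
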