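# Independent oracle implementations used to cross-check the descriptor
# engine, aligners and rank statistics. These are deliberately written as
# plain loops over the defining formulas, sharing only the residue property
# *tables* (data) with the package, never its computation paths.

AA <- aa_alphabet()

rand_peptides <- function(n, min_len = 5, max_len = 40, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    len <- if (min_len == max_len) min_len else {
      sample(seq(min_len, max_len), 1)
    }
    paste(sample(AA, len, replace = TRUE), collapse = "")
  }, character(1))
}

chou_norm <- function(x) {
  x <- x[AA]
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
}

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  for (i in seq_along(AA)) out[i] <- sum(ch == AA[i]) / length(ch)
  out
}

# Chou type-1 pseudo composition, direct transcription of the defining sums
oracle_pse1 <- function(seq, props, lambda, w) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    acc <- 0
    for (i in 1:(L - j)) {
      s <- 0
      for (p in props) s <- s + (p[ch[i + j]] - p[ch[i]])^2
      acc <- acc + s / length(props)
    }
    theta[j] <- acc / (L - j)
  }
  f <- oracle_aac(seq)
  denom <- 1 + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# type-2 series (amphiphilic product) correlations
oracle_pse2 <- function(seq, props, lambda, w) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  tau <- c()
  for (j in 1:lambda) {
    for (p in props) {
      acc <- 0
      for (i in 1:(L - j)) acc <- acc + p[ch[i]] * p[ch[i + j]]
      tau <- c(tau, acc / (L - j))
    }
  }
  f <- oracle_aac(seq)
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

oracle_pseaac <- function(seq, lambda = 3, w = 0.05) {
  lib <- scale_library()
  h1 <- chou_norm(lib$hydrophobicity)
  h2 <- chou_norm(lib$hydrophilicity)
  h3 <- chou_norm(lib$sidechain_mass)
  unname(c(oracle_pse1(seq, list(h1, h2, h3), lambda, w),
    oracle_pse1(seq, list(h1, h2), 2, w),
    oracle_pse2(seq, list(h1, h2), lambda, w),
    oracle_pse2(seq, list(h1), lambda, w),
    oracle_pse2(seq, list(h2), lambda, w)))
}

oracle_ctd <- function(seq) {
  lib <- scale_library()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  comp <- trans <- distr <- c()
  for (prop in lib$ctd_groups) {
    g <- integer(L)
    for (k in 1:3) {
      members <- strsplit(prop[k], "")[[1]]
      for (i in 1:L) if (ch[i] %in% members) g[i] <- k
    }
    for (k in 1:3) comp <- c(comp, sum(g == k) / L)
    for (ab in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0
      for (i in 1:(L - 1)) {
        if ((g[i] == ab[1] && g[i + 1] == ab[2]) ||
            (g[i] == ab[2] && g[i + 1] == ab[1])) cnt <- cnt + 1
      }
      trans <- c(trans, cnt / (L - 1))
    }
    for (k in 1:3) {
      pos <- which(g == k)
      if (!length(pos)) {
        distr <- c(distr, rep(0, 5))
      } else {
        n <- length(pos)
        for (q in c(0.0001, 0.25, 0.5, 0.75, 1)) {
          distr <- c(distr, pos[max(1, ceiling(q * n))] / L * 100)
        }
      }
    }
  }
  c(comp, trans, distr)
}

oracle_qso <- function(seq, lag = 3, w = 0.1) {
  lib <- scale_library()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  f <- oracle_aac(seq)
  socn <- qso <- c()
  for (m in list(lib$qso_physchem, lib$qso_grantham)) {
    tau <- numeric(lag)
    for (d in 1:lag) {
      for (i in 1:(L - d)) tau[d] <- tau[d] + m[ch[i], ch[i + d]]^2
    }
    socn <- c(socn, tau)
    denom <- sum(f) + w * sum(tau)
    qso <- c(qso, f / denom, w * tau / denom)
  }
  c(socn, qso)
}

oracle_physchem <- function(seq) {
  lib <- scale_library()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- c()
  for (nm in c("cruciani", "zscales", "fasgai", "tscales", "vhse",
               "protfp", "stscales", "mswhim", "blosum_idx")) {
    m <- lib[[nm]]
    for (j in 1:ncol(m)) {
      acc <- 0
      for (i in 1:L) acc <- acc + m[ch[i], j]
      out <- c(out, acc / L)
    }
  }
  f <- oracle_aac(seq)
  names(f) <- AA
  out <- c(out, 100 * (f["A"] + 2.9 * f["V"] + 3.9 * (f["I"] + f["L"])))
  for (p in c("hydrophobicity", "hydrophilicity", "sidechain_mass",
              "polarity")) {
    x <- lib[[p]][ch]
    for (d in 1:3) {
      den <- sum((x - mean(x))^2)
      if (L - d < 1 || den == 0) {
        out <- c(out, 0)
      } else {
        num <- 0
        for (i in 1:(L - d)) num <- num + (x[i] - x[i + d])^2
        out <- c(out, (L - 1) / (2 * (L - d)) * num / den)
      }
    }
  }
  h <- chou_norm(lib$hydrophobicity)[ch]
  hw <- chou_norm(lib$hydrophilicity)[ch]
  cc <- function(x, y) {
    acc <- 0
    for (i in 1:(L - 1)) acc <- acc + (x[i] - mean(x)) * (y[i + 1] - mean(y))
    acc / (L - 1)
  }
  out <- c(out, cc(h, h))
  out <- c(out, -sum(lib$boman[ch]) / L)
  out <- c(out, cc(h, hw), cc(hw, h))
  pk <- lib$pk$bjellqvist
  charge_at <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pk["Nterm"])) +
      sum(ch == "K") / (1 + 10^(pH - pk["K"])) +
      sum(ch == "R") / (1 + 10^(pH - pk["R"])) +
      sum(ch == "H") / (1 + 10^(pH - pk["H"]))
    neg <- 1 / (1 + 10^(pk["Cterm"] - pH)) +
      sum(ch == "D") / (1 + 10^(pk["D"] - pH)) +
      sum(ch == "E") / (1 + 10^(pk["E"] - pH)) +
      sum(ch == "C") / (1 + 10^(pk["C"] - pH)) +
      sum(ch == "Y") / (1 + 10^(pk["Y"] - pH))
    unname(pos - neg)
  }
  out <- c(out, charge_at(7.0))
  acc <- 0
  for (i in 1:(L - 1)) acc <- acc + lib$diwv[ch[i], ch[i + 1]]
  out <- c(out, 10 / L * acc)
  he <- lib$hydrophobicity[ch]
  for (delta in c(100, 160)) {
    s1 <- s2 <- 0
    for (i in 1:L) {
      s1 <- s1 + he[i] * cos(i * delta * pi / 180)
      s2 <- s2 + he[i] * sin(i * delta * pi / 180)
    }
    out <- c(out, sqrt(s1^2 + s2^2) / L)
  }
  out <- c(out, stats::uniroot(charge_at, c(0, 14), tol = 1e-12)$root)
  unname(out)
}

oracle_kmers <- function(seq, motifs = np_motifs()) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  dip <- as.vector(t(outer(AA, AA, paste0)))
  out <- numeric(400)
  for (i in 1:(L - 1)) {
    d <- paste0(ch[i], ch[i + 1])
    out[match(d, dip)] <- out[match(d, dip)] + 1
  }
  out <- out / (L - 1)
  for (m in motifs) {
    cnt <- 0
    if (L >= 3) {
      for (i in 1:(L - 2)) {
        if (paste0(ch[i], ch[i + 1], ch[i + 2]) == m) cnt <- cnt + 1
      }
    }
    out <- c(out, cnt)
  }
  out
}

oracle_conformation <- function(seq) {
  lib <- scale_library()
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(6)
  for (j in 1:6) {
    for (i in seq_along(ch)) out[j] <- out[j] + lib$conformation[ch[i], j]
    out[j] <- out[j] / length(ch)
  }
  out
}

oracle_features <- function(seq) {
  c(oracle_aac(seq), oracle_pseaac(seq), oracle_ctd(seq), oracle_qso(seq),
    oracle_physchem(seq), oracle_kmers(seq), oracle_conformation(seq))
}

# Exhaustive pairwise concordance AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# Affine-gap local alignment score (Smith-Waterman, Gotoh 3-state), same
# scoring convention as the package aligner: a gap of length k costs
# open + k * extend.
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  S <- env$BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- Ix <- Iy <- matrix(0, n + 1, m + 1)
  Ix[, ] <- Iy[, ] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                       S[x[i - 1], y[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# Global affine-gap alignment (Gotoh) returning the match count of an
# optimal alignment under match 2 / mismatch -1 / gap open 5 extend 2.
oracle_nw_matches <- function(a, b, match = 2, mismatch = -1, open = 5,
                              extend = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    }
  }
  # traceback counting matches
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  matches <- 0
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      if (x[i - 1] == y[j - 1]) matches <- matches + 1
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- isTRUE(all.equal(Ix[i, j], M[i - 1, j] - open - extend))
      i <- i - 1
      state <- if (from_m) 1 else 2
      if (i == 1 && j == 1) break
    } else {
      from_m <- isTRUE(all.equal(Iy[i, j], M[i, j - 1] - open - extend))
      j <- j - 1
      state <- if (from_m) 1 else 3
      if (i == 1 && j == 1) break
    }
    if (i == 1 && j == 1) break
    if (i == 1) state <- 3
    if (j == 1) state <- 2
  }
  matches
}
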