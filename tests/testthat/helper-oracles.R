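# Independent brute-force oracles: scalar loops over sites and enumerated
# allele-copy pairs, written from the textbook definitions and never sharing
# code with the package internals.

# allele copies at one site for one population: vector of 0/1 of length an
.copies <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
}

# mean pairwise difference per site by enumerating all copy pairs
oracle_pi_sum <- function(geno) {
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    cp <- .copies(geno[s, ])
    n <- length(cp)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      diffs <- diffs + (cp[i] != cp[j])
    tot <- tot + diffs / choose(n, 2)
  }
  unname(tot)
}

# dxy per site by enumerating all cross-population copy pairs
oracle_dxy_sum <- function(geno_a, geno_b) {
  tot <- 0
  for (s in seq_len(nrow(geno_a))) {
    ca <- .copies(geno_a[s, ]); cb <- .copies(geno_b[s, ])
    if (!length(ca) || !length(cb)) next
    diffs <- 0
    for (i in seq_along(ca)) for (j in seq_along(cb))
      diffs <- diffs + (ca[i] != cb[j])
    tot <- tot + diffs / (length(ca) * length(cb))
  }
  unname(tot)
}

# Weir & Cockerham (1984) a, b, c components, scalar per site
oracle_wc_site <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  n1 <- length(ga); n2 <- length(gb)
  if (n1 == 0 || n2 == 0) return(c(a = 0, b = 0, c = 0))
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- mean(ga == 1); h2 <- mean(gb == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_fst <- function(geno_a, geno_b) {
  num <- den <- 0
  for (s in seq_len(nrow(geno_a))) {
    ga <- geno_a[s, ]; gb <- geno_b[s, ]
    n1 <- sum(!is.na(ga)); n2 <- sum(!is.na(gb))
    if (n1 == 0 || n2 == 0 || n1 + n2 <= 2) next
    w <- oracle_wc_site(ga, gb)
    num <- num + w["a"]
    den <- den + sum(w)
  }
  unname(num / den)
}

oracle_hudson_fst <- function(geno_a, geno_b) {
  num <- den <- 0
  for (s in seq_len(nrow(geno_a))) {
    ca <- .copies(geno_a[s, ]); cb <- .copies(geno_b[s, ])
    n1 <- length(ca); n2 <- length(cb)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(ca); p2 <- mean(cb)
    num <- num + (p1 - p2)^2
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# textbook Tajima (1989) D from a 0/1 haplotype matrix (rows sites)
oracle_tajima_d <- function(hap) {
  n <- ncol(hap)
  seg <- apply(hap, 1, function(x) length(unique(x)) > 1)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    k <- k + sum(hap[, i] != hap[, j])
  k <- k / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# D statistic and fd terms by literal per-site products
oracle_d_stat <- function(p1, p2, p3) {
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  sum(abba - baba) / sum(abba + baba)
}

oracle_fd <- function(p1, p2, p3) {
  num <- den <- 0
  for (s in seq_along(p1)) {
    num <- num + (1 - p1[s]) * p2[s] * p3[s] - p1[s] * (1 - p2[s]) * p3[s]
    pd <- max(p2[s], p3[s])
    den <- den + (1 - p1[s]) * pd * pd - p1[s] * (1 - pd) * pd
  }
  if (num <= 0) 0 else num / den
}

# closed-form weighted delete-one jackknife variance (Busing et al. 1999),
# evaluated independently from per-block totals
oracle_jackknife_se <- function(num_j, den_j) {
  g <- length(num_j)
  theta <- sum(num_j) / sum(den_j)
  W <- sum(den_j)
  loo <- sapply(seq_len(g), function(j) sum(num_j[-j]) / sum(den_j[-j]))
  h <- W / den_j
  theta_dot <- g * theta - sum((1 - den_j / W) * loo)
  tau <- h * theta - (h - 1) * loo
  sqrt(sum((tau - theta_dot)^2 / (h - 1)) / g)
}

# haplotype-frequency LD r^2 = D^2 / (pA(1-pA) pB(1-pB))
oracle_hap_r2 <- function(hapA, hapB) {
  pA <- mean(hapA); pB <- mean(hapB)
  Dab <- mean(hapA & hapB) - pA * pB
  Dab^2 / (pA * (1 - pA) * pB * (1 - pB))
}
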