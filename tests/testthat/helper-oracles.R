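# Independent oracles, deliberately naive and free of the package's
# optimisations (no windowing, no pruning, no match precomputation).

.o_lcp <- function(a, b) {
  m <- min(nchar(a), nchar(b)); k <- 0L
  while (k < m && substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1))
    k <- k + 1L
  k
}
.o_rev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
.o_lcs <- function(a, b) .o_lcp(.o_rev(a), .o_rev(b))

# longest common substring length between two short strings (plain DP,
# row-vectorised: cur[j] = (prev[j-1] + 1) if av[i] == bv[j] else 0)
.o_lcsubstr <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(0L)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- (c(0L, prev[-nb]) + 1L) * (av[i] == bv)
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

# brute-force minimum N-insertion count over every decomposition: all
# (v_used, j_used) pairs down to zero for every maximal V/J candidate, all
# D alleles, all placements (via longest common substring).
oracle_min_insertions <- function(read, germ, min_d_len = 3) {
  g <- data.table::as.data.table(germ)
  L <- nchar(read)
  vml <- vapply(g[type == "V", seq], function(s) .o_lcp(read, s), integer(1))
  jml <- vapply(g[type == "J", seq], function(s) .o_lcs(read, s), integer(1))
  vmax <- max(vml); jmax <- max(jml)
  dseqs <- g[type == "D", seq]
  best <- Inf
  for (vu in vmax:0) {
    for (ju in jmax:0) {
      if (vu + ju > L) next
      jxn <- substr(read, vu + 1, L - ju)
      jl <- nchar(jxn)
      best <- min(best, jl)  # D absent
      if (jl >= min_d_len) {
        for (ds in dseqs) {
          m <- .o_lcsubstr(jxn, ds)
          if (m >= min_d_len) best <- min(best, jl - m)
        }
      }
    }
  }
  best
}

# reconstruction of a read from an annotated scenario row
oracle_reconstruct <- function(row, germ) {
  g <- data.table::as.data.table(germ)
  seq_of <- stats::setNames(g$seq, g$name)
  len_of <- stats::setNames(g$len, g$name)
  v <- substr(seq_of[row$v_allele], 1, len_of[row$v_allele] - row$v_trim)
  j <- substr(seq_of[row$j_allele], row$j_trim + 1, len_of[row$j_allele])
  if (!is.na(row$d_allele)) {
    d <- substr(seq_of[row$d_allele], row$d5_trim + 1,
                len_of[row$d_allele] - row$d3_trim)
    paste0(v, ifelse(is.na(row$np1), "", row$np1), d,
           ifelse(is.na(row$np2), "", row$np2), j)
  } else {
    paste0(v, ifelse(is.na(row$np1), "", row$np1), j)
  }
}

# brute-force palindromic extension length
oracle_pal <- function(ins, terminal, side = c("left", "right")) {
  side <- match.arg(side)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(x) .o_rev(comp(x))
  kmax <- min(nchar(ins), nchar(terminal))
  p <- 0L
  for (k in seq_len(kmax)) {
    ok <- if (side == "left") {
      substr(ins, 1, k) == rc(substr(terminal, nchar(terminal) - k + 1,
                                     nchar(terminal)))
    } else {
      substr(ins, nchar(ins) - k + 1, nchar(ins)) == rc(substr(terminal, 1, k))
    }
    if (ok) p <- k else break
  }
  p
}

# closed-form weighted least squares via the normal equations
oracle_wls <- function(y, X, w = rep(1, length(y))) {
  XtWX <- t(X) %*% (X * w)
  XtWy <- t(X) %*% (w * y)
  beta <- solve(XtWX, XtWy)
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(solve(XtWX)) * sigma2))
}
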