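# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Exhaustive global-alignment score: enumerates every global alignment of a
# and b (all monotone edit paths), scoring runs of gaps as
# gap_open + run_length * gap_extend. `score_fun(x, y)` scores one aligned
# residue pair.
enum_align_score <- function(a, b, score_fun, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= n && j <= m) {
      rec(i + 1L, j + 1L, "M", acc + score_fun(av[i], bv[j]))
    }
    if (i <= n) {
      rec(i + 1L, j, "D",
          acc + gap_extend + if (last != "D") gap_open else 0)
    }
    if (j <= m) {
      rec(i, j + 1L, "I",
          acc + gap_extend + if (last != "I") gap_open else 0)
    }
  }
  rec(1L, 1L, "start", 0)
  best
}

simple_dna_score <- function(match, mismatch) {
  function(x, y) if (x == y) match else mismatch
}

# Standard genetic code, written out independently of any package table.
ORACLE_CODE <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # codons enumerated first-base slowest: TTT TTC TTA TTG TCT ...
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  stats::setNames(aa, codons)
})

# NG86 oracle for a pair of codon vectors: direct enumeration of neighbor
# codons for site counts and of mutational orderings for differences,
# then Jukes-Cantor correction.
oracle_ng86 <- function(codons_a, codons_b) {
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    cv <- strsplit(codon, "")[[1]]
    total <- 0
    for (p in 1:3) {
      alts <- setdiff(bases, cv[p])
      neigh <- sapply(alts, function(x) {
        w <- cv
        w[p] <- x
        paste0(w, collapse = "")
      })
      aas <- ORACLE_CODE[neigh]
      ok <- aas != "*"
      if (any(ok)) total <- total + mean(aas[ok] == ORACLE_CODE[codon])
    }
    total
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  Sd <- 0
  Nd <- 0
  for (k in seq_along(codons_a)) {
    ca <- strsplit(codons_a[k], "")[[1]]
    cb <- strsplit(codons_b[k], "")[[1]]
    dp <- which(ca != cb)
    if (!length(dp)) next
    path_scores <- list()
    for (ord in perms(dp)) {
      cur <- ca
      s <- 0
      ns <- 0
      blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        nxt[p] <- cb[p]
        a1 <- ORACLE_CODE[paste0(cur, collapse = "")]
        a2 <- ORACLE_CODE[paste0(nxt, collapse = "")]
        if (a1 == "*" || a2 == "*") {
          blocked <- TRUE
          break
        }
        if (a1 == a2) s <- s + 1 else ns <- ns + 1
        cur <- nxt
      }
      if (!blocked) path_scores[[length(path_scores) + 1]] <- c(s, ns)
    }
    avg <- Reduce(`+`, path_scores) / length(path_scores)
    Sd <- Sd + avg[1]
    Nd <- Nd + avg[2]
  }
  S <- (sum(sapply(codons_a, syn_sites)) + sum(sapply(codons_b, syn_sites))) / 2
  N <- 3 * length(codons_a) - S
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS,
       dN = jc(pN), dS = jc(pS))
}

# Closed-form Welch two-sample t statistic and two-sided p value.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

# Random sense-codon vector (no stops).
random_sense_codons <- function(n) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  sample(sense, n, replace = TRUE)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
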