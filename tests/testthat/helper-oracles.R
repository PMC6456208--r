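# Independent oracles used by the tests.  These deliberately share no code
# with the package: the genetic code comes from Biostrings, pathway
# enumeration is written out explicitly, and the Fisher/rank-sum references
# enumerate probabilities in plain arithmetic.

.oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(.oracle_code) <- names(Biostrings::GENETIC_CODE)
.oracle_bases <- c("A", "C", "G", "T")
.oracle_stops <- names(.oracle_code)[.oracle_code == "*"]

oracle_ng_sites <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa <- .oracle_code[[codon]]
  s <- 0
  for (i in 1:3) {
    muts <- character(0)
    for (b in .oracle_bases) {
      if (b == nt[i]) next
      m <- nt; m[i] <- b
      muts <- c(muts, paste(m, collapse = ""))
    }
    muts <- muts[!muts %in% .oracle_stops]
    if (length(muts))
      s <- s + sum(.oracle_code[muts] == aa) / length(muts)
  }
  c(s = s, n = 3 - s)
}

# all orderings of 1..n for n <= 3, written out
.oracle_perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

oracle_ng_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  tot_s <- 0; tot_n <- 0; nv <- 0
  for (ord in .oracle_perms[[length(dp)]]) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (i in ord) {
      nxt <- cur; nxt[dp[i]] <- b[dp[i]]
      to <- paste(nxt, collapse = "")
      if (to %in% .oracle_stops) { ok <- FALSE; break }
      if (.oracle_code[[paste(cur, collapse = "")]] == .oracle_code[[to]])
        s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; nv <- nv + 1 }
  }
  if (nv == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_s / nv, nd = tot_n / nv)
}

# memoised oracle tables over all sense-codon pairs (built on first use)
oracle_ng_tables <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    sense <- setdiff(names(.oracle_code), .oracle_stops)
    s_sites <- vapply(sense, function(cd) oracle_ng_sites(cd)[["s"]],
                      numeric(1))
    sd <- matrix(NA_real_, 64, 64,
                 dimnames = list(names(.oracle_code), names(.oracle_code)))
    nd <- sd
    for (a in sense) for (b in sense) {
      d <- oracle_ng_diffs(a, b)
      sd[a, b] <- d[["sd"]]; nd[a, b] <- d[["nd"]]
    }
    tabs <<- list(s_sites = s_sites, sd = sd, nd = nd)
    tabs
  }
})

oracle_kaks <- function(sx, sy) {
  tab <- oracle_ng_tables()
  n <- nchar(sx) %/% 3
  st <- seq(1, by = 3, length.out = n)
  cx <- substring(sx, st, st + 2); cy <- substring(sy, st, st + 2)
  if (cx[n] %in% .oracle_stops && cy[n] %in% .oracle_stops) {
    cx <- cx[-n]; cy <- cy[-n]
  }
  sd <- tab$sd[cbind(cx, cy)]; nd <- tab$nd[cbind(cx, cy)]
  use <- !is.na(sd)
  S <- (sum(tab$s_sites[cx[use]]) + sum(tab$s_sites[cy[use]])) / 2
  N <- 3 * sum(use) - S
  pS <- sum(sd[use]) / S; pN <- sum(nd[use]) / N
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  c(Ks = jc(pS), Ka = jc(pN))
}

# exact two-sided Fisher p by direct enumeration over margin-fixed tables,
# in plain (non-log) arithmetic -- valid for small totals
oracle_fisher_2xk <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); N <- sum(tab)
  k <- length(cs)
  cells <- list()
  fill <- function(j, left, acc) {
    if (j == k) {
      if (left <= cs[k]) cells[[length(cells) + 1]] <<- c(acc, left)
      return(invisible())
    }
    for (v in 0:min(left, cs[j])) fill(j + 1, left - v, c(acc, v))
  }
  fill(1, r1, integer(0))
  probs <- vapply(cells, function(row1)
    prod(choose(cs, row1)) / choose(N, r1), numeric(1))
  obs <- prod(choose(cs, tab[1, ])) / choose(N, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by explicit combn enumeration (mid-ranks)
oracle_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  na <- length(a); N <- length(pooled)
  W <- sum(rk[seq_len(na)])
  e <- na * (N + 1) / 2
  combos <- utils::combn(N, na)
  ws <- apply(combos, 2, function(idx) sum(rk[idx]))
  p <- mean(abs(ws - e) >= abs(W - e) - 1e-9)
  list(W = W, p = p)
}

# brute-force longest ORF over 6 frames (ATG..stop, stop included)
oracle_longest_orf <- function(seq, min_len) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  best_len <- 0
  for (s in c(seq, rc(seq))) {
    L <- nchar(s)
    for (f in 0:2) {
      i <- f + 1
      while (i + 2 <= L) {
        if (substr(s, i, i + 2) == "ATG") {
          j <- i
          while (j + 2 <= L) {
            cd <- substr(s, j, j + 2)
            if (.oracle_code[[cd]] == "*") {
              len <- j + 2 - i + 1
              if (len >= min_len && len > best_len) best_len <- len
              break
            }
            j <- j + 3
          }
        }
        i <- i + 3
      }
    }
  }
  best_len
}

gt_is_het_vec <- function(g) {
  vapply(strsplit(g, "/", fixed = TRUE),
         function(p) p[1] != p[2], logical(1))
}

# small helper: write a VCF fixture with AD depths for the io tests
write_test_vcf <- function(path, records, sample_ids) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_sheet <- function(ids, sexes, roles = "progeny") {
  sample_sheet(data.frame(sample_id = ids, sex = sexes, role = roles,
                          group = "g", stringsAsFactors = FALSE))
}
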