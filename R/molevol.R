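#' Nei-Gojobori synonymous and non-synonymous site counts for one codon
#'
#' For each of the three codon positions, the synonymous share of that site
#' is the fraction of the possible single-base changes that leave the amino
#' acid unchanged; changes creating a stop codon are excluded from the
#' denominator.  The synonymous site count \code{s} is the sum of the three
#' shares and \code{n = 3 - s}.
#'
#' @param codon a sense codon (3 characters over A, C, G, T).
#' @return Named numeric vector \code{c(s = , n = )} with \code{s + n == 3}.
#' @export
#' @examples
#' ng_sites("GGG")  # third position fully synonymous: s = 1
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("ambiguous or malformed codon: ", codon)
  if (is_stop_codon(codon)) stop("stop codon has no NG86 site counts: ", codon)
  aa <- translate_codon(codon)
  nt <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(.BASES, nt[pos])) {
      mut <- nt
      mut[pos] <- b
      mcd <- paste(mut, collapse = "")
      if (is_stop_codon(mcd)) next
      valid <- valid + 1L
      if (translate_codon(mcd) == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

#' Nei-Gojobori synonymous and non-synonymous differences between two codons
#'
#' Differences are counted along all minimal mutational pathways between the
#' codons (one pathway per ordering of the differing positions).  Pathways
#' passing through a stop codon are excluded; the returned counts are
#' averages over the remaining pathways.  If every pathway passes through a
#' stop codon, \code{NA}s are returned and the codon pair should be skipped.
#'
#' @param codon_a,codon_b sense codons.
#' @return Named numeric vector \code{c(sd = , nd = )}; \code{sd + nd} equals
#'   the number of differing positions (when defined).
#' @export
#' @examples
#' ng_differences("TTT", "GTA")  # two pathways, averaged
ng_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!grepl("^[ACGT]{3}$", cd)) stop("ambiguous or malformed codon: ", cd)
    if (is_stop_codon(cd)) stop("stop codon in NG86 difference count: ", cd)
  }
  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  diff_pos <- which(a != b)
  ndiff <- length(diff_pos)
  if (ndiff == 0L) return(c(sd = 0, nd = 0))

  perms <- if (ndiff == 1L) list(diff_pos) else {
    out <- list()
    gen <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1L]] <<- prefix; return() }
      for (i in seq_along(rest)) gen(c(prefix, rest[i]), rest[-i])
    }
    gen(integer(0L), diff_pos)
    out
  }

  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- a
    sd <- 0L; nd <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (is_stop_codon(to)) { blocked <- TRUE; break }
      if (translate_codon(from) == translate_codon(to)) sd <- sd + 1L
      else nd <- nd + 1L
      cur <- nxt
    }
    if (!blocked) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p observed proportion of differing sites, in \code{[0, 0.75)}.
#' @return Corrected distance \code{d = -(3/4) * log(1 - (4/3) * p)}.
#' @export
#' @examples
#' jukes_cantor(0.10)
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("proportion of differences must be non-negative")
  if (any(p >= 0.75)) stop("Jukes-Cantor correction saturates at p >= 0.75")
  -0.75 * log(1 - p * 4 / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and non-synonymous (N) sites, averaged over the two
#' sequences, and synonymous (Sd) / non-synonymous (Nd) differences by
#' pathway averaging, then applies the Jukes-Cantor correction to the
#' proportions pS = Sd/S and pN = Nd/N.  Codons containing non-ACGT symbols,
#' stop codons, or pairs whose every mutational pathway passes through a stop
#' are skipped and counted in \code{codons_skipped}.
#'
#' @param seq_x,seq_y aligned in-frame nucleotide sequences of equal length,
#'   a multiple of 3.  A terminal stop codon (in both sequences) is dropped
#'   before analysis.
#' @return An object of class \code{"kaks"}: list with \code{S}, \code{N},
#'   \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{Ks}, \code{Ka},
#'   \code{KaKs} (NA when Ks = 0), \code{codons_used},
#'   \code{codons_skipped}.
#' @export
#' @examples
#' ka_ks("TTTGGGAAACCC", "TTCGGGAAACCC")
ka_ks <- function(seq_x, seq_y) {
  seq_x <- toupper(seq_x); seq_y <- toupper(seq_y)
  if (nchar(seq_x) != nchar(seq_y))
    stop("sequences must be aligned to equal length")
  if (nchar(seq_x) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  n_cod <- nchar(seq_x) %/% 3L
  if (n_cod == 0L) stop("empty alignment")
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  cod_x <- substring(seq_x, starts, starts + 2L)
  cod_y <- substring(seq_y, starts, starts + 2L)

  # drop a shared terminal stop before analysis
  if (n_cod > 1L && is_stop_codon(cod_x[n_cod]) && is_stop_codon(cod_y[n_cod])) {
    cod_x <- cod_x[-n_cod]; cod_y <- cod_y[-n_cod]
  }

  tab <- ng_tables()
  ok <- grepl("^[ACGT]{3}$", cod_x) & grepl("^[ACGT]{3}$", cod_y) &
    !(cod_x %in% .STOP_CODONS) & !(cod_y %in% .STOP_CODONS)
  sd <- rep(NA_real_, length(cod_x)); nd <- sd
  sd[ok] <- tab$sd[cbind(cod_x[ok], cod_y[ok])]
  nd[ok] <- tab$nd[cbind(cod_x[ok], cod_y[ok])]
  usable <- ok & !is.na(sd)          # NA inside ok: all pathways stop-blocked
  if (!any(usable)) stop("no analyzable codons in alignment")

  S <- (sum(tab$s_sites[cod_x[usable]]) + sum(tab$s_sites[cod_y[usable]])) / 2
  N <- 3 * sum(usable) - S
  Sd <- sum(sd[usable]); Nd <- sum(nd[usable])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 KaKs = if (Ks > 0) Ka / Ks else NA_real_,
                 codons_used = sum(usable),
                 codons_skipped = length(cod_x) - sum(usable)),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori rates: Ks = %.4f  Ka = %.4f  (Ka/Ks = %s)\n",
    x$Ks, x$Ka, ifelse(is.na(x$KaKs), "undef", sprintf("%.3f", x$KaKs))))
  cat(sprintf("  sites S = %.2f, N = %.2f; differences Sd = %.2f, Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  codons used %d, skipped %d\n", x$codons_used,
              x$codons_skipped))
  invisible(x)
}

#' Longest open reading frame over all six frames
#'
#' Scans ATG-to-stop ORFs (stop codon included in the span) in the three
#' forward and three reverse-complement frames.  Ties are broken in favour of
#' the forward strand, then the lowest frame, then the lowest start.
#'
#' @param seq nucleotide sequence.
#' @param min_len minimum ORF length in nt including the stop (default 150).
#' @return \code{NULL} if no ORF of at least \code{min_len}; otherwise a list
#'   with \code{strand} (\code{"+"}/\code{"-"}), \code{frame} (0-2),
#'   \code{start}, \code{end} (0-based half-open, in coordinates of the
#'   reported strand) and \code{cds} (the ORF sequence including its stop).
#' @export
find_orf <- function(seq, min_len = 150L) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  revcomp <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))

  best <- NULL
  strands <- c("+", "-")
  for (si in 1:2) {
    s <- if (si == 1L) seq else revcomp
    L <- nchar(s)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3L
      if (n_cod < 2L) next
      starts <- frame + seq.int(1L, by = 3L, length.out = n_cod)
      cods <- substring(s, starts, starts + 2L)
      is_atg <- cods == "ATG"
      is_stp <- cods %in% .STOP_CODONS
      open_at <- NA_integer_
      for (i in seq_len(n_cod)) {
        if (is.na(open_at) && is_atg[i]) open_at <- i
        if (!is.na(open_at) && is_stp[i]) {
          len <- (i - open_at + 1L) * 3L
          cand_start <- frame + (open_at - 1L) * 3L  # 0-based
          better <- is.null(best) || len > best$len
          if (better && len >= min_len) {
            best <- list(strand = strands[si], frame = frame,
                         start = cand_start, end = cand_start + len,
                         len = len,
                         cds = substr(s, cand_start + 1L, cand_start + len))
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$len <- NULL
  best
}

#' Phase X and Y alleles into a coding alignment
#'
#' Substitutes the X- and Y-linked bases of classified SNPs into a reference
#' coding sequence to obtain the two phased alleles.  For segregation
#' pattern 1 sites the Y base is the allele absent from the female
#' homozygotes.
#'
#' @param ref_cds reference coding sequence.
#' @param snps data frame with columns \code{pos} (1-based position in
#'   \code{ref_cds}), \code{x_base}, \code{y_base} (single nucleotides).
#' @return List with elements \code{seq_x} and \code{seq_y}.
#' @export
phase_alleles <- function(ref_cds, snps) {
  ref_cds <- toupper(ref_cds)
  if (is.null(snps) || nrow(snps) == 0L)
    return(list(seq_x = ref_cds, seq_y = ref_cds))
  if (any(snps$pos < 1L | snps$pos > nchar(ref_cds)))
    stop("SNP position outside the coding sequence")
  if (anyDuplicated(snps$pos)) {
    dup <- snps[snps$pos %in% snps$pos[duplicated(snps$pos)], ]
    agree <- all(tapply(paste(dup$x_base, dup$y_base), dup$pos,
                        function(v) length(unique(v)) == 1L))
    if (!agree) stop("conflicting bases at duplicated CDS position")
    snps <- snps[!duplicated(snps$pos), ]
  }
  x <- strsplit(ref_cds, "")[[1L]]
  y <- x
  x[snps$pos] <- toupper(snps$x_base)
  y[snps$pos] <- toupper(snps$y_base)
  list(seq_x = paste(x, collapse = ""), seq_y = paste(y, collapse = ""))
}

#' Molecular-clock divergence time
#'
#' T = K / (2 r) x generation time: the substitution rate K accumulates on
#' both diverging lineages at the neutral per-generation rate r.
#'
#' @param K substitution rate (typically the synonymous rate Ks).
#' @param r neutral substitution rate per site per generation
#'   (default 6.5e-9).
#' @param generation_years years per generation (default 1).
#' @return Divergence time in years.
#' @export
#' @examples
#' divergence_time(0.0736)  # ~5.66 million years
divergence_time <- function(K, r = 6.5e-9, generation_years = 1) {
  if (any(K < 0)) stop("substitution rate K must be non-negative")
  if (r <= 0) stop("neutral rate r must be positive")
  K / (2 * r) * generation_years
}

#' Exact two-sided Wilcoxon rank-sum test with mid-ranks
#'
#' The exact null distribution of the rank sum of the first group is computed
#' over all equally likely assignments of the pooled (mid-)ranks to the
#' groups, by a counting recursion over integer-doubled ranks; ties therefore
#' need no approximation.  Two-sided p is the probability of a rank sum at
#' least as far from its null expectation as the observed one.
#'
#' @param group_a,group_b numeric samples (combined size <= 30 recommended).
#' @return List with \code{W} (rank sum of \code{group_a}) and \code{p}.
#' @export
#' @examples
#' rank_sum_exact(c(1, 2), c(3, 4))
rank_sum_exact <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  pooled <- c(group_a, group_b)
  r2 <- as.integer(round(2 * rank(pooled)))  # mid-ranks doubled -> integers
  na <- length(group_a); N <- length(pooled)
  W2 <- sum(r2[seq_len(na)])

  # count[k + 1, w + 1] = number of k-subsets of r2 with doubled-rank sum w
  maxw <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  cnt <- matrix(0, nrow = na + 1L, ncol = maxw + 1L)
  cnt[1L, 1L] <- 1
  for (r in r2) {
    kmax <- na
    for (k in kmax:1) {
      wrange <- which(cnt[k, ] > 0)
      wnew <- wrange + r
      keep <- wnew <= maxw + 1L
      cnt[k + 1L, wnew[keep]] <- cnt[k + 1L, wnew[keep]] + cnt[k, wrange[keep]]
    }
  }
  counts <- cnt[na + 1L, ]
  total <- sum(counts)
  e2 <- na * (N + 1)                 # doubled-rank null expectation
  dev_obs <- abs(W2 - e2)
  ws <- which(counts > 0) - 1L
  p <- sum(counts[ws + 1L][abs(ws - e2) >= dev_obs - 1e-9]) / total
  list(W = W2 / 2, p = p)
}

#' Per-gene X-Y substitution rates and divergence times
#'
#' Runs the full divergence pipeline for each unigene carrying classified
#' pattern-1 SNPs: finds the longest ORF in the unigene, maps the SNPs into
#' CDS coordinates (complementing alleles for reverse-strand ORFs), phases
#' the X and Y alleles and computes NG86 + Jukes-Cantor rates and the clock
#' time T = Ks / 2r.
#'
#' @param ref_seqs named character vector of unigene sequences (from
#'   \code{\link{read_fasta}}).
#' @param classifications site classification table from
#'   \code{\link{classify_sites}} (pattern-1 rows are used).
#' @param variants the \code{variant_table} the classifications came from
#'   (provides REF/ALT base strings).
#' @param config analysis configuration, see \code{\link{spinsex_config}}.
#' @return Data frame: unigene, n_snps_used, S, N, Sd, Nd, Ks, Ka, KaKs,
#'   T_years.  Genes without a qualifying ORF are omitted.
#' @export
xy_divergence <- function(ref_seqs, classifications, variants,
                          config = spinsex_config()) {
  p1 <- classifications[classifications$pattern == "P1", , drop = FALSE]
  sites <- variants$sites
  out <- list()
  for (u in unique(p1$unigene)) {
    if (!u %in% names(ref_seqs)) next
    seq <- ref_seqs[[u]]
    orf <- find_orf(seq, min_len = config$min_orf)
    if (is.null(orf)) next
    rows <- p1[p1$unigene == u, , drop = FALSE]
    snp <- merge(rows, sites, by = c("unigene", "pos"))
    alleles <- strsplit(paste(snp$ref, snp$alt, sep = ","), ",", fixed = TRUE)
    x_base <- mapply(function(al, i) al[i + 1L], alleles, snp$x_allele)
    y_base <- mapply(function(al, i) al[i + 1L], alleles, snp$y_allele)
    if (orf$strand == "+") {
      cds_pos <- snp$pos - orf$start
    } else {
      L <- nchar(seq)
      rev_pos <- L - snp$pos + 1L          # 1-based on the reverse strand
      cds_pos <- rev_pos - orf$start
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      x_base <- unname(comp[x_base]); y_base <- unname(comp[y_base])
    }
    inside <- cds_pos >= 1L & cds_pos <= (orf$end - orf$start)
    if (!any(inside)) next
    ph <- phase_alleles(orf$cds, data.frame(pos = cds_pos[inside],
                                            x_base = x_base[inside],
                                            y_base = y_base[inside]))
    kk <- ka_ks(ph$seq_x, ph$seq_y)
    out[[u]] <- data.frame(unigene = u, n_snps_used = sum(inside),
                           S = kk$S, N = kk$N, Sd = kk$Sd, Nd = kk$Nd,
                           Ks = kk$Ks, Ka = kk$Ka, KaKs = kk$KaKs,
                           T_years = divergence_time(kk$Ks, config$r,
                                                     config$generation_years))
  }
  if (!length(out))
    return(data.frame(unigene = character(), n_snps_used = integer(),
                      S = numeric(), N = numeric(), Sd = numeric(),
                      Nd = numeric(), Ks = numeric(), Ka = numeric(),
                      KaKs = numeric(), T_years = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$unigene), , drop = FALSE]
}

#' Summarise substitution rates for a set of genes
#'
#' Reports mean and standard error of per-gene Ks and Ka, and the divergence
#' time both as the clock applied to the mean Ks and as the mean of per-gene
#' times (the two aggregations differ for skewed Ks distributions).
#'
#' @param rates data frame from \code{\link{xy_divergence}}.
#' @param r,generation_years clock parameters.
#' @return List with \code{n}, \code{mean_Ks}, \code{se_Ks}, \code{mean_Ka},
#'   \code{se_Ka}, \code{T_from_mean_Ks}, \code{mean_T}, \code{se_T} (years).
#' @export
summarise_rates <- function(rates, r = 6.5e-9, generation_years = 1) {
  n <- nrow(rates)
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  list(n = n,
       mean_Ks = mean(rates$Ks), se_Ks = se(rates$Ks),
       mean_Ka = mean(rates$Ka), se_Ka = se(rates$Ka),
       T_from_mean_Ks = divergence_time(mean(rates$Ks), r, generation_years),
       mean_T = mean(rates$T_years), se_T = se(rates$T_years))
}
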