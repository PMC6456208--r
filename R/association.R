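# log-sum-exp over a vector of log probabilities
logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

# log point probabilities of every 2xk table with the margins of `tab`,
# together with the log probability of `tab` itself.  Used by the exact test
# and exposed to the test suite via the enumeration-sums-to-one property.
enumerate_2xk_logprobs <- function(tab) {
  r1 <- sum(tab[1L, ]); N <- sum(tab)
  cs <- colSums(tab)
  k <- ncol(tab)
  lden <- lchoose(N, r1)
  if (k == 2L) {
    a_min <- max(0L, r1 - cs[2L]); a_max <- min(r1, cs[1L])
    a <- a_min:a_max
    lp <- lchoose(cs[1L], a) + lchoose(cs[2L], r1 - a) - lden
    obs <- lchoose(cs[1L], tab[1L, 1L]) + lchoose(cs[2L], tab[1L, 2L]) - lden
  } else {
    lp <- numeric(0L)
    for (a in 0L:min(r1, cs[1L])) {
      b_min <- max(0L, r1 - a - cs[3L]); b_max <- min(r1 - a, cs[2L])
      if (b_min > b_max) next
      b <- b_min:b_max
      lp <- c(lp, lchoose(cs[1L], a) + lchoose(cs[2L], b) +
                lchoose(cs[3L], r1 - a - b) - lden)
    }
    obs <- lchoose(cs[1L], tab[1L, 1L]) + lchoose(cs[2L], tab[1L, 2L]) +
      lchoose(cs[3L], tab[1L, 3L]) - lden
  }
  list(lp = lp, obs = obs)
}

#' Exact test of independence for a 2 x k contingency table (k = 2 or 3)
#'
#' Two-sided exact p-value by the point-probability criterion: the sum of
#' the probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within a 1e-7
#' relative slack).  The 2 x 3 case is the Freeman-Halton test by full
#' enumeration over the two free cells.  All probabilities are carried in
#' log space, so p-values far below double underflow in a product form
#' (e.g. 1e-70) are computed without approximation.
#'
#' Columns whose total is zero are dropped before testing.
#'
#' @param tab integer matrix with 2 rows and 2 or 3 columns (after dropping
#'   zero columns) of non-negative counts.
#' @return The two-sided exact p-value.
#' @export
#' @examples
#' fisher_exact_2xk(rbind(c(102, 2), c(108, 0)))
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("table must have 2 rows")
  if (any(tab < 0)) stop("negative counts")
  if (sum(tab) == 0) stop("empty table")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  k <- ncol(tab)
  if (k > 3L) stop("k > 3 unsupported")
  if (k == 1L) return(1)
  en <- enumerate_2xk_logprobs(tab)
  sel <- en$lp <= en$obs + log1p(1e-7)
  min(1, exp(logsumexp(en$lp[sel])))
}

#' Classify a marker's sex linkage from its association p-value
#'
#' @param p two-sided exact p-value.
#' @param config thresholds \code{p_msy} (default 1e-60),
#'   \code{p_significant} (1e-10) and \code{p_weak} (1e-5); see
#'   \code{\link{spinsex_config}}.
#' @return One of \code{"MSY"}, \code{"SEX_ASSOCIATED"},
#'   \code{"RECOMBINING_OR_RECENT"}, \code{"NO_ASSOCIATION"}.
#' @export
#' @examples
#' classify_sex_linkage(2.9e-63)
classify_sex_linkage <- function(p, config = spinsex_config()) {
  if (p < 0 || p > 1) stop("p-value outside [0, 1]")
  if (p < config$p_msy) "MSY"
  else if (p < config$p_significant) "SEX_ASSOCIATED"
  else if (p <= config$p_weak) "RECOMBINING_OR_RECENT"
  else "NO_ASSOCIATION"
}

#' Build the 2 x k genotype-by-sex table for a marker
#'
#' Rows: males; females and monoecious individuals pooled.  Columns: the
#' genotype classes present (aa / ab / bb), in allele-index order.
#'
#' @param genotypes character vector of \code{"i/j"} genotype codes.
#' @param sexes matching vector of \code{"male"}, \code{"female"},
#'   \code{"monoecious"}.
#' @return Integer matrix 2 x k with dimnames.
#' @export
sex_genotype_table <- function(genotypes, sexes) {
  if (length(genotypes) != length(sexes)) stop("length mismatch")
  keep <- !is.na(genotypes)
  genotypes <- genotypes[keep]; sexes <- sexes[keep]
  male <- sexes == "male"
  classes <- sort(unique(genotypes))
  tab <- rbind(male = vapply(classes, function(g)
                 sum(genotypes == g & male), integer(1L)),
               female_mono = vapply(classes, function(g)
                 sum(genotypes == g & !male), integer(1L)))
  colnames(tab) <- classes
  tab
}

#' Count recombinants for a sex-linked marker in a segregating population
#'
#' A recombinant is an individual whose genotype contradicts the expected
#' coupling between genotype class and sex.  With the default coupling
#' (\code{het_male}), males are expected heterozygous and females
#' homozygous, as for a marker fixed between X and Y in the cross fathers.
#'
#' @param genotypes character vector of \code{"i/j"} genotype codes (NA
#'   individuals are ignored).
#' @param sexes matching vector of sex labels; monoecious individuals are
#'   counted with females.
#' @param coupling \code{"het_male"} (default) or \code{"het_female"}.
#' @return List: \code{n_recombinants} (NA when no variant),
#'   \code{no_variant} (TRUE when the marker is monomorphic in the
#'   population), \code{n_scored}.
#' @export
count_recombinants <- function(genotypes, sexes, coupling = "het_male") {
  if (length(genotypes) != length(sexes)) stop("length mismatch")
  coupling <- match.arg(coupling, c("het_male", "het_female"))
  keep <- !is.na(genotypes)
  g <- genotypes[keep]; s <- sexes[keep]
  if (length(unique(g)) <= 1L)
    return(list(n_recombinants = NA_integer_, no_variant = TRUE,
                n_scored = length(g)))
  het <- gt_is_het(g)
  male <- s == "male"
  expected_het <- if (coupling == "het_male") male else !male
  list(n_recombinants = sum(het != expected_het), no_variant = FALSE,
       n_scored = length(g))
}

#' Sex-association scan over markers
#'
#' Runs \code{\link{sex_genotype_table}}, \code{\link{fisher_exact_2xk}} and
#' \code{\link{classify_sex_linkage}} for each marker of a long-format
#' genotype table.
#'
#' @param marker_genotypes data frame with columns \code{marker},
#'   \code{sample}, \code{genotype} (\code{"i/j"} codes), \code{sex}.
#' @param config analysis configuration.
#' @return Data frame: \code{marker}, \code{p}, \code{category}.
#' @export
association_scan <- function(marker_genotypes, config = spinsex_config()) {
  markers <- unique(marker_genotypes$marker)
  p <- numeric(length(markers)); cat_ <- character(length(markers))
  for (i in seq_along(markers)) {
    rows <- marker_genotypes[marker_genotypes$marker == markers[i], ]
    tab <- sex_genotype_table(rows$genotype, rows$sex)
    p[i] <- fisher_exact_2xk(tab)
    cat_[i] <- classify_sex_linkage(p[i], config)
  }
  data.frame(marker = markers, p = p, category = cat_,
             stringsAsFactors = FALSE)
}
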