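#' Analysis configuration
#'
#' All thresholds used by the pipeline, with the defaults of the underlying
#' study design.  Any subset can be overridden via \code{...}; unknown keys
#' are an error.
#'
#' @param ... named overrides of the default keys.
#'
#' @details Keys:
#' \describe{
#'   \item{hom_fraction}{Depth-rule threshold: a sample is called homozygous
#'     when the minor allele carries strictly less than this fraction of the
#'     total site depth (default 0.10).}
#'   \item{min_total_depth}{Sites with total depth below this in a sample are
#'     MISSING for that sample (default 10).}
#'   \item{require_complete}{If TRUE (default) a site must be callable in all
#'     progeny samples to be classified.}
#'   \item{min_per_sex}{Minimum called samples per sex when
#'     \code{require_complete} is FALSE (default 4).}
#'   \item{min_qual}{Optional minimum VCF QUAL; \code{NA} (default) disables
#'     the filter.}
#'   \item{p_msy, p_significant, p_weak}{Sex-association thresholds: p <
#'     \code{p_msy} (1e-60) is MSY; p < \code{p_significant} (1e-10) is
#'     sex-associated; p <= \code{p_weak} (1e-5) is recombining-or-recent;
#'     larger p is no association.}
#'   \item{r}{Neutral substitution rate per site per generation
#'     (default 6.5e-9).}
#'   \item{generation_years}{Years per generation (default 1).}
#'   \item{min_orf}{Minimum open reading frame length in nt (default 150).}
#'   \item{pseudocount}{RPKM pseudocount added before log2 (default 0.01).}
#'   \item{de_p}{p-value cutoff for differential expression (default 0.01).}
#'   \item{min_length}{Minimum unigene length for the DE fraction
#'     (default 400 nt).}
#'   \item{min_snps}{Minimum qualifying SNPs per gene for the Y/X expression
#'     ratio (default 2).}
#' }
#'
#' @return A named list of class \code{"spinsex_config"}.
#' @export
#' @examples
#' cfg <- spinsex_config(min_total_depth = 8)
#' cfg$hom_fraction
spinsex_config <- function(...) {
  cfg <- list(
    hom_fraction     = 0.10,
    min_total_depth  = 10L,
    require_complete = TRUE,
    min_per_sex      = 4L,
    min_qual         = NA_real_,
    p_msy            = 1e-60,
    p_significant    = 1e-10,
    p_weak           = 1e-5,
    r                = 6.5e-9,
    generation_years = 1,
    min_orf          = 150L,
    pseudocount      = 0.01,
    de_p             = 0.01,
    min_length       = 400L,
    min_snps         = 2L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "spinsex_config")
}

#' Read a key-value configuration file
#'
#' The file format is one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored.  Values are coerced to the type of the
#' corresponding default.
#'
#' @param path path to the configuration file.
#' @return A \code{\link{spinsex_config}} list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- spinsex_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (toupper(val) == "NA") NA
                  else if (is.logical(cfg[[key]])) as.logical(val)
                  else if (is.integer(cfg[[key]])) as.integer(val)
                  else as.numeric(val)
  }
  cfg
}

#' Write a configuration to a key-value file
#'
#' @param cfg a \code{\link{spinsex_config}} list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 15),
                            character(1L))), path)
  invisible(path)
}

#' @export
print.spinsex_config <- function(x, ...) {
  cat("spinsex analysis configuration\n")
  for (k in names(x)) cat(sprintf("  %-17s %s\n", k, format(x[[k]])))
  invisible(x)
}
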