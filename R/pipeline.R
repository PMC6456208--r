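#' Run the sex-linkage discovery pipeline on a variant table
#'
#' Convenience wrapper: genotype calling, segregation-pattern
#' classification and unigene aggregation in one call.
#'
#' @param variants a \code{variant_table} from \code{\link{read_variants}}.
#' @param config analysis configuration; see \code{\link{spinsex_config}}.
#' @return List of class \code{"sexlink_result"}: \code{genotypes}
#'   (a \code{genotype_matrix}), \code{classifications} (per-site data
#'   frame) and \code{summary} (a \code{segregation_summary}).
#' @export
#' @examples
#' \donttest{
#' sim <- generate_dataset(sim_config(n_msy = 5, n_par = 5, n_auto = 5,
#'                                    n_ortholog = 0), tempdir())
#' res <- sexlink_pipeline(sim$variants)
#' res$summary
#' }
sexlink_pipeline <- function(variants, config = spinsex_config()) {
  gm <- genotype_matrix(variants, config)
  cl <- classify_sites(gm, config)
  structure(list(genotypes = gm, classifications = cl,
                 summary = aggregate_unigenes(cl)),
            class = "sexlink_result")
}

#' @export
print.sexlink_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Run every analysis stage on a dataset directory
#'
#' Expects the file layout written by \code{\link{generate_dataset}}
#' (\code{reference.fasta}, \code{variants.vcf}, \code{counts.tsv},
#' \code{samples.tsv}) and writes the per-stage TSV results next to an
#' output prefix.
#'
#' @param dir dataset directory.
#' @param out_dir output directory (created if needed).
#' @param config analysis configuration.
#' @return Invisibly, a list with \code{sexlink}, \code{divergence},
#'   \code{divergence_summary}, \code{de}, \code{de_fraction}, \code{yx}.
#' @export
run_all <- function(dir, out_dir, config = spinsex_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  variants <- read_variants(file.path(dir, "variants.vcf"), samples,
                            min_qual = config$min_qual)
  ref <- read_fasta(file.path(dir, "reference.fasta"))

  sexlink <- sexlink_pipeline(variants, config)
  write_results(sexlink$classifications,
                file.path(out_dir, "segregation.tsv"))

  rates <- xy_divergence(ref, sexlink$classifications, variants, config)
  write_results(rates, file.path(out_dir, "xy_divergence.tsv"))

  counts <- read_results(file.path(dir, "counts.tsv"))
  de <- sex_de_scan(counts, nchar(ref), samples, config)
  write_results(de, file.path(out_dir, "expression_de.tsv"))
  frac <- de_fraction(de, config$de_p, config$min_length)

  yx <- yx_scan(variants, sexlink$genotypes, sexlink$classifications, config)
  write_results(yx, file.path(out_dir, "yx_ratio.tsv"))

  invisible(list(sexlink = sexlink, divergence = rates,
                 divergence_summary = summarise_rates(rates, config$r,
                                                      config$generation_years),
                 de = de, de_fraction = frac, yx = yx))
}
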